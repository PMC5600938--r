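// Time-unrolled forward and backward (BPTT) passes for the two-layer
// recurrent convolutional network family. Layer activations for a mini-batch
// are stored as (npix * B) x C matrices (pixel index fastest, column-major
// within an image, images stacked down the rows). Convolutions are im2col +
// GEMM against the linked BLAS; the top-down pathway is the exact adjoint of
// a stride-2 convolution (a transposed convolution with output stride 2).
//
// Everything is templated on the real type: the float instantiation is used
// for training throughput, the double instantiation for analytic checks such
// as finite-difference gradient verification.

#include <RcppArmadillo.h>
#if defined(__GLIBC__)
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

constexpr double LRN_C = 1.0;
constexpr double LRN_ALPHA = 1e-4;
constexpr double LRN_BETA = 0.5;
constexpr int LRN_N = 5; // window: k - 2 ... k + 2, truncated at the edges

// The unrolled passes allocate multi-hundred-MB im2col buffers every
// mini-batch; keep such blocks on the heap instead of returning them to the
// OS so repeated batches reuse the same pages.
void tune_allocator() {
#if defined(__GLIBC__)
  static bool done = false;
  if (!done) {
    mallopt(M_MMAP_THRESHOLD, 1 << 30);
    mallopt(M_TRIM_THRESHOLD, 1 << 30);
    done = true;
  }
#endif
}

struct ConvGeom {
  int side_in = 0, side_out = 0, k = 0, stride = 1, pad = 0;
  ivec src; // length side_out^2 * k^2; source pixel or -1 (zero padding)
};

ConvGeom make_geom(int side_in, int k, int stride) {
  ConvGeom g;
  g.side_in = side_in;
  g.k = k;
  g.stride = stride;
  g.pad = (k - 1) / 2;
  g.side_out = (side_in + 2 * g.pad - k) / stride + 1;
  const int npix_out = g.side_out * g.side_out;
  g.src.set_size(static_cast<uword>(npix_out) * k * k);
  for (int dj = 0; dj < k; ++dj) {
    for (int di = 0; di < k; ++di) {
      const int o = di + k * dj;
      for (int jo = 0; jo < g.side_out; ++jo) {
        for (int io = 0; io < g.side_out; ++io) {
          const int i = io * stride + di - g.pad;
          const int j = jo * stride + dj - g.pad;
          const int p = io + g.side_out * jo;
          g.src[static_cast<uword>(o) * npix_out + p] =
              (i >= 0 && i < side_in && j >= 0 && j < side_in)
                  ? (i + side_in * j)
                  : -1;
        }
      }
    }
  }
  return g;
}

// X: (npix_in * B) x C  ->  (npix_out * B) x (k*k*C), column o + k*k*c
// matching R's natural flattening of a (k, k, C_in, C_out) kernel array.
template <typename eT>
Mat<eT> im2col(const Mat<eT>& X, const ConvGeom& g, int B) {
  const int npix_in = g.side_in * g.side_in;
  const int npix_out = g.side_out * g.side_out;
  const int kk = g.k * g.k;
  const int C = X.n_cols;
  Mat<eT> Xc(static_cast<uword>(npix_out) * B, static_cast<uword>(kk) * C);
  for (int c = 0; c < C; ++c) {
    const eT* xc = X.colptr(c);
    for (int o = 0; o < kk; ++o) {
      eT* dst = Xc.colptr(static_cast<uword>(o) + static_cast<uword>(kk) * c);
      const sword* src = g.src.memptr() + static_cast<uword>(o) * npix_out;
      for (int b = 0; b < B; ++b) {
        const eT* xb = xc + static_cast<uword>(b) * npix_in;
        eT* db = dst + static_cast<uword>(b) * npix_out;
        for (int p = 0; p < npix_out; ++p) {
          const sword s = src[p];
          db[p] = (s >= 0) ? xb[s] : eT(0);
        }
      }
    }
  }
  return Xc;
}

// Adjoint of im2col: scatter-add columns back onto the input grid.
template <typename eT>
void col2im_add(Mat<eT>& X, const Mat<eT>& Xc, const ConvGeom& g, int B) {
  const int npix_in = g.side_in * g.side_in;
  const int npix_out = g.side_out * g.side_out;
  const int kk = g.k * g.k;
  const int C = X.n_cols;
  for (int c = 0; c < C; ++c) {
    eT* xc = X.colptr(c);
    for (int o = 0; o < kk; ++o) {
      const eT* src =
          Xc.colptr(static_cast<uword>(o) + static_cast<uword>(kk) * c);
      const sword* map = g.src.memptr() + static_cast<uword>(o) * npix_out;
      for (int b = 0; b < B; ++b) {
        eT* xb = xc + static_cast<uword>(b) * npix_in;
        const eT* sb = src + static_cast<uword>(b) * npix_out;
        for (int p = 0; p < npix_out; ++p) {
          const sword s = map[p];
          if (s >= 0) xb[s] += sb[p];
        }
      }
    }
  }
}

// 2x2 max pooling with stride 2; records the winning source row per output
// element (first-encountered maximum wins, a fixed deterministic tie-break).
template <typename eT>
Mat<eT> maxpool(const Mat<eT>& X, int side, int B, umat& argmax) {
  const int so = side / 2;
  const int npix_in = side * side;
  const int npix_out = so * so;
  const int C = X.n_cols;
  Mat<eT> Y(static_cast<uword>(npix_out) * B, C);
  argmax.set_size(static_cast<uword>(npix_out) * B, C);
  for (int c = 0; c < C; ++c) {
    const eT* xc = X.colptr(c);
    eT* yc = Y.colptr(c);
    uword* ac = argmax.colptr(c);
    for (int b = 0; b < B; ++b) {
      const uword off_in = static_cast<uword>(b) * npix_in;
      const uword off_out = static_cast<uword>(b) * npix_out;
      for (int jo = 0; jo < so; ++jo) {
        for (int io = 0; io < so; ++io) {
          const int i0 = 2 * io, j0 = 2 * jo;
          uword best = off_in + i0 + side * j0;
          eT bv = xc[best];
          const int di[3] = {1, 0, 1};
          const int dj[3] = {0, 1, 1};
          for (int q = 0; q < 3; ++q) {
            const uword idx = off_in + (i0 + di[q]) + side * (j0 + dj[q]);
            if (xc[idx] > bv) { bv = xc[idx]; best = idx; }
          }
          const uword po = off_out + io + so * jo;
          yc[po] = bv;
          ac[po] = best;
        }
      }
    }
  }
  return Y;
}

template <typename eT>
void maxpool_backward(Mat<eT>& dX, const Mat<eT>& dY, const umat& argmax) {
  const int C = dX.n_cols;
  for (int c = 0; c < C; ++c) {
    eT* d = dX.colptr(c);
    const eT* g = dY.colptr(c);
    const uword* a = argmax.colptr(c);
    for (uword r = 0; r < dY.n_rows; ++r) d[a[r]] += g[r];
  }
}

// Sliding-window sum over the feature (column) dimension, window k-2 ... k+2
// truncated at the edges.
template <typename eT>
Mat<eT> window_sum(const Mat<eT>& M) {
  const int C = M.n_cols;
  const int half = LRN_N / 2;
  Mat<eT> S = cumsum(M, 1);
  Mat<eT> W(M.n_rows, C);
  for (int c = 0; c < C; ++c) {
    const int hi = std::min(C - 1, c + half);
    const int lo = c - half;
    if (lo <= 0) {
      W.col(c) = S.col(hi);
    } else {
      W.col(c) = S.col(hi) - S.col(lo - 1);
    }
  }
  return W;
}

// Local response normalization applied to r = relu(z):
//   h_k = r_k * (c + alpha * sum_{|k'-k|<=2} r_k'^2)^(-beta)
template <typename eT>
void lrn_forward(const Mat<eT>& r, Mat<eT>& d, Mat<eT>& h) {
  Mat<eT> r2 = square(r);
  d = eT(LRN_C) + eT(LRN_ALPHA) * window_sum(r2);
  // beta = 1/2: d^(-beta) = 1/sqrt(d), much cheaper than pow()
  h = r / sqrt(d);
}

// Backward through LRN and ReLU: given dL/dh, r (= relu(z)) and the stored
// denominators d, returns dL/dz.
template <typename eT>
Mat<eT> lrn_relu_backward(const Mat<eT>& dh, const Mat<eT>& r,
                          const Mat<eT>& d) {
  // d^(-beta-1) = 1 / (d * sqrt(d)) for beta = 1/2
  Mat<eT> rsd = eT(1) / sqrt(d);
  Mat<eT> u = dh % r % (rsd / d);
  Mat<eT> w = window_sum(u);
  Mat<eT> dr = dh % rsd - eT(2 * LRN_ALPHA * LRN_BETA) * (r % w);
  // ReLU mask: zero where the pre-activation was non-positive
  const eT* rp = r.memptr();
  eT* dp = dr.memptr();
  const uword n = dr.n_elem;
  for (uword i = 0; i < n; ++i) {
    if (rp[i] <= eT(0)) dp[i] = eT(0);
  }
  return dr;
}

// Per-image, per-feature global max over space; records the winning row.
template <typename eT>
Mat<eT> global_max(const Mat<eT>& H, int npix, int B, umat& argmax) {
  const int C = H.n_cols;
  Mat<eT> F(B, C);
  argmax.set_size(B, C);
  for (int c = 0; c < C; ++c) {
    const eT* hc = H.colptr(c);
    for (int b = 0; b < B; ++b) {
      const uword off = static_cast<uword>(b) * npix;
      uword best = off;
      eT bv = hc[off];
      for (int p = 1; p < npix; ++p) {
        if (hc[off + p] > bv) { bv = hc[off + p]; best = off + p; }
      }
      F(b, c) = bv;
      argmax(b, c) = best;
    }
  }
  return F;
}

struct SpecC {
  int side1, side2, C, kb, T, nclass;
  bool lateral, topdown;
};

template <typename eT>
struct WeightsC {
  Mat<eT> k1b, k2b;     // (kb*kb*Cin) x C
  Mat<eT> k1l, k2l;     // (3*3*C) x C
  Mat<eT> kt;           // (3*3*C) x C, stride-2 kernel whose adjoint is used
  Row<eT> b1, b2, bro;  // biases
  Mat<eT> Wro;          // C x nclass
};

template <typename eT>
Mat<eT> to_mat(SEXP s) {
  Rcpp::NumericMatrix m(s);
  Mat<eT> out(m.nrow(), m.ncol());
  std::copy(m.begin(), m.end(), out.memptr());
  return out;
}

// Kernel arrays arrive flattened to (k*k*Cin) x Cout matrices R-side.
template <typename eT>
WeightsC<eT> unpack_weights(const Rcpp::List& w, const SpecC& sp) {
  WeightsC<eT> W;
  W.k1b = to_mat<eT>(w["k1b"]);
  W.k2b = to_mat<eT>(w["k2b"]);
  W.b1 = conv_to<Row<eT>>::from(
      Rcpp::as<arma::rowvec>(Rcpp::NumericVector(w["b1"])));
  W.b2 = conv_to<Row<eT>>::from(
      Rcpp::as<arma::rowvec>(Rcpp::NumericVector(w["b2"])));
  W.Wro = to_mat<eT>(w["W_ro"]);
  W.bro = conv_to<Row<eT>>::from(
      Rcpp::as<arma::rowvec>(Rcpp::NumericVector(w["b_ro"])));
  if (sp.lateral) {
    W.k1l = to_mat<eT>(w["k1l"]);
    W.k2l = to_mat<eT>(w["k2l"]);
  }
  if (sp.topdown) W.kt = to_mat<eT>(w["kt"]);
  return W;
}

SpecC unpack_spec(const Rcpp::List& spec) {
  SpecC sp;
  sp.side1 = Rcpp::as<int>(spec["input_side"]);
  sp.side2 = sp.side1 / 2;
  sp.C = Rcpp::as<int>(spec["features"]);
  sp.kb = Rcpp::as<int>(spec["bu_kernel"]);
  sp.T = Rcpp::as<int>(spec["n_timesteps"]);
  sp.nclass = Rcpp::as<int>(spec["n_classes"]);
  sp.lateral = Rcpp::as<bool>(spec["lateral"]);
  sp.topdown = Rcpp::as<bool>(spec["top_down"]);
  return sp;
}

template <typename eT>
struct States {
  std::vector<Mat<eT>> r1, d1, h1, r2, d2, h2, p1, f;
  std::vector<umat> pool_arg, gmax_arg;
  std::vector<Mat<eT>> yhat; // B x nclass per time step
  // im2col products cached during the forward pass for reuse in backward
  Mat<eT> xcol_in;                  // input, layer-1 bottom-up
  std::vector<Mat<eT>> xcol_l2b;    // pooled h1, layer-2 bottom-up, per t
  std::vector<Mat<eT>> xcol_l1l;    // h1[t-1], layer-1 lateral, per t
  std::vector<Mat<eT>> xcol_l2l;    // h2[t-1], layer-2 lateral, per t
};

template <typename eT>
void forward_pass(const Mat<eT>& X, const WeightsC<eT>& W, const SpecC& sp,
                  int B, States<eT>& st, bool keep_cols = false) {
  const ConvGeom g1 = make_geom(sp.side1, sp.kb, 1);
  const ConvGeom g2 = make_geom(sp.side2, sp.kb, 1);
  const ConvGeom gl1 = make_geom(sp.side1, 3, 1);
  const ConvGeom gl2 = make_geom(sp.side2, 3, 1);
  const ConvGeom gs = make_geom(sp.side1, 3, 2); // stride-2; adjoint = top-down
  const int npix2 = sp.side2 * sp.side2;
  const int T = sp.T;
  st.r1.resize(T); st.d1.resize(T); st.h1.resize(T);
  st.r2.resize(T); st.d2.resize(T); st.h2.resize(T);
  st.p1.resize(T); st.f.resize(T);
  st.pool_arg.resize(T); st.gmax_arg.resize(T);
  st.yhat.resize(T);
  st.xcol_l2b.resize(T); st.xcol_l1l.resize(T); st.xcol_l2l.resize(T);

  // The input is replicated at every time step, so the bottom-up drive of
  // layer 1 is constant over time and computed once.
  Mat<eT> xcol_in = im2col(X, g1, B);
  const Mat<eT> z1_base = xcol_in * W.k1b;
  if (keep_cols) st.xcol_in = std::move(xcol_in);

  for (int t = 0; t < T; ++t) {
    Mat<eT> z1 = z1_base;
    if (t > 0 && sp.lateral) {
      Mat<eT> xc = im2col(st.h1[t - 1], gl1, B);
      z1 += xc * W.k1l;
      if (keep_cols) st.xcol_l1l[t] = std::move(xc);
    }
    if (t > 0 && sp.topdown) {
      Mat<eT> U = st.h2[t - 1] * W.kt.t();
      Mat<eT> td(z1.n_rows, z1.n_cols, fill::zeros);
      col2im_add(td, U, gs, B);
      z1 += td;
    }
    z1.each_row() += W.b1;
    Mat<eT> r1 = arma::max(z1, Mat<eT>(z1.n_rows, z1.n_cols, fill::zeros));
    lrn_forward(r1, st.d1[t], st.h1[t]);
    st.r1[t] = std::move(r1);

    st.p1[t] = maxpool(st.h1[t], sp.side1, B, st.pool_arg[t]);
    Mat<eT> xc2 = im2col(st.p1[t], g2, B);
    Mat<eT> z2 = xc2 * W.k2b;
    if (keep_cols) st.xcol_l2b[t] = std::move(xc2);
    if (t > 0 && sp.lateral) {
      Mat<eT> xcl = im2col(st.h2[t - 1], gl2, B);
      z2 += xcl * W.k2l;
      if (keep_cols) st.xcol_l2l[t] = std::move(xcl);
    }
    z2.each_row() += W.b2;
    Mat<eT> r2 = arma::max(z2, Mat<eT>(z2.n_rows, z2.n_cols, fill::zeros));
    lrn_forward(r2, st.d2[t], st.h2[t]);
    st.r2[t] = std::move(r2);

    st.f[t] = global_max(st.h2[t], npix2, B, st.gmax_arg[t]);
    Mat<eT> logits = st.f[t] * W.Wro;
    logits.each_row() += W.bro;
    st.yhat[t] = eT(1) / (eT(1) + exp(-logits));
  }
}

// Mean over the batch of the per-image cross-entropy summed across time
// steps and classes; fills gradient matrices (same shapes as the weights).
template <typename eT>
double backward_pass(const Mat<eT>& X, const Mat<eT>& Y, const WeightsC<eT>& W,
                     const SpecC& sp, int B, const States<eT>& st,
                     WeightsC<eT>& G) {
  const ConvGeom g1 = make_geom(sp.side1, sp.kb, 1);
  const ConvGeom g2 = make_geom(sp.side2, sp.kb, 1);
  const ConvGeom gl1 = make_geom(sp.side1, 3, 1);
  const ConvGeom gl2 = make_geom(sp.side2, 3, 1);
  const ConvGeom gs = make_geom(sp.side1, 3, 2);
  const int npix1 = sp.side1 * sp.side1;
  const int npix2 = sp.side2 * sp.side2;
  const int T = sp.T;

  G.k1b.zeros(W.k1b.n_rows, W.k1b.n_cols);
  G.k2b.zeros(W.k2b.n_rows, W.k2b.n_cols);
  G.b1.zeros(W.b1.n_elem);
  G.b2.zeros(W.b2.n_elem);
  G.Wro.zeros(W.Wro.n_rows, W.Wro.n_cols);
  G.bro.zeros(W.bro.n_elem);
  if (sp.lateral) {
    G.k1l.zeros(W.k1l.n_rows, W.k1l.n_cols);
    G.k2l.zeros(W.k2l.n_rows, W.k2l.n_cols);
  }
  if (sp.topdown) G.kt.zeros(W.kt.n_rows, W.kt.n_cols);

  const eT eps = eT(1e-7);
  double loss = 0.0;
  for (int t = 0; t < T; ++t) {
    Mat<eT> yh = clamp(st.yhat[t], eps, eT(1) - eps);
    loss += accu(-(Y % log(yh) + (eT(1) - Y) % log(eT(1) - yh))) /
            static_cast<double>(B);
  }

  std::vector<Mat<eT>> dh1(T), dh2(T);
  for (int t = 0; t < T; ++t) {
    dh1[t].zeros(static_cast<uword>(npix1) * B, sp.C);
    dh2[t].zeros(static_cast<uword>(npix2) * B, sp.C);
  }

  for (int t = T - 1; t >= 0; --t) {
    // readout
    Mat<eT> dlogit = (st.yhat[t] - Y) / eT(B);
    G.Wro += st.f[t].t() * dlogit;
    G.bro += sum(dlogit, 0);
    Mat<eT> df = dlogit * W.Wro.t();
    // scatter df onto the argmax locations of layer 2
    for (int c = 0; c < sp.C; ++c) {
      eT* d = dh2[t].colptr(c);
      const uword* a = st.gmax_arg[t].colptr(c);
      for (int b = 0; b < B; ++b) d[a[b]] += df(b, c);
    }

    // layer 2
    Mat<eT> dz2 = lrn_relu_backward(dh2[t], st.r2[t], st.d2[t]);
    G.b2 += sum(dz2, 0);
    G.k2b += st.xcol_l2b[t].t() * dz2;
    Mat<eT> dp1(static_cast<uword>(npix2) * B, sp.C, fill::zeros);
    {
      Mat<eT> dXc = dz2 * W.k2b.t();
      col2im_add(dp1, dXc, g2, B);
    }
    maxpool_backward(dh1[t], dp1, st.pool_arg[t]);
    if (t > 0 && sp.lateral) {
      G.k2l += st.xcol_l2l[t].t() * dz2;
      Mat<eT> dXc = dz2 * W.k2l.t();
      col2im_add(dh2[t - 1], dXc, gl2, B);
    }

    // layer 1
    Mat<eT> dz1 = lrn_relu_backward(dh1[t], st.r1[t], st.d1[t]);
    G.b1 += sum(dz1, 0);
    G.k1b += st.xcol_in.t() * dz1;
    if (t > 0 && sp.lateral) {
      G.k1l += st.xcol_l1l[t].t() * dz1;
      Mat<eT> dXc = dz1 * W.k1l.t();
      col2im_add(dh1[t - 1], dXc, gl1, B);
    }
    if (t > 0 && sp.topdown) {
      // forward was out = col2im(h2[t-1] * kt^T); adjoint:
      Mat<eT> dU = im2col(dz1, gs, B);
      G.kt += dU.t() * st.h2[t - 1];
      dh2[t - 1] += dU * W.kt;
    }
  }
  return loss;
}

template <typename eT>
Rcpp::List trace_to_list(const States<eT>& st) {
  Rcpp::List out(st.yhat.size());
  for (size_t t = 0; t < st.yhat.size(); ++t) {
    out[t] = Rcpp::wrap(conv_to<arma::mat>::from(st.yhat[t]));
  }
  return out;
}

template <typename eT>
Rcpp::List grads_to_list(const WeightsC<eT>& G, const SpecC& sp) {
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("k1b") = Rcpp::wrap(conv_to<arma::mat>::from(G.k1b)),
      Rcpp::Named("k2b") = Rcpp::wrap(conv_to<arma::mat>::from(G.k2b)),
      Rcpp::Named("b1") = Rcpp::wrap(conv_to<arma::rowvec>::from(G.b1)),
      Rcpp::Named("b2") = Rcpp::wrap(conv_to<arma::rowvec>::from(G.b2)),
      Rcpp::Named("W_ro") = Rcpp::wrap(conv_to<arma::mat>::from(G.Wro)),
      Rcpp::Named("b_ro") = Rcpp::wrap(conv_to<arma::rowvec>::from(G.bro)));
  if (sp.lateral) {
    out["k1l"] = Rcpp::wrap(conv_to<arma::mat>::from(G.k1l));
    out["k2l"] = Rcpp::wrap(conv_to<arma::mat>::from(G.k2l));
  }
  if (sp.topdown) out["kt"] = Rcpp::wrap(conv_to<arma::mat>::from(G.kt));
  return out;
}

template <typename eT>
Rcpp::List forward_impl(const Rcpp::NumericMatrix& x, const Rcpp::List& w,
                        const Rcpp::List& spec) {
  const SpecC sp = unpack_spec(spec);
  const int B = x.ncol();
  Mat<eT> X(x.nrow(), 1);
  // images arrive as (npix x B); reshape to (npix*B) x 1 (one input channel)
  X.set_size(static_cast<uword>(x.nrow()) * B, 1);
  std::copy(x.begin(), x.end(), X.memptr());
  const WeightsC<eT> W = unpack_weights<eT>(w, sp);
  States<eT> st;
  forward_pass(X, W, sp, B, st, false);
  return trace_to_list(st);
}

template <typename eT>
Rcpp::List loss_grad_impl(const Rcpp::NumericMatrix& x,
                          const Rcpp::NumericMatrix& y, const Rcpp::List& w,
                          const Rcpp::List& spec) {
  const SpecC sp = unpack_spec(spec);
  const int B = x.ncol();
  Mat<eT> X(static_cast<uword>(x.nrow()) * B, 1);
  std::copy(x.begin(), x.end(), X.memptr());
  Mat<eT> Y = to_mat<eT>(Rcpp::wrap(y));
  const WeightsC<eT> W = unpack_weights<eT>(w, sp);
  States<eT> st;
  forward_pass(X, W, sp, B, st, true);
  WeightsC<eT> G;
  const double loss = backward_pass(X, Y, W, sp, B, st, G);
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("grads") = grads_to_list(G, sp),
      Rcpp::Named("trace") = trace_to_list(st));
}

} // namespace

//' @noRd
// [[Rcpp::export(name = "cpp_forward")]]
Rcpp::List cpp_forward(Rcpp::NumericMatrix x, Rcpp::List weights,
                       Rcpp::List spec, std::string precision = "single") {
  tune_allocator();
  if (precision == "double") return forward_impl<double>(x, weights, spec);
  return forward_impl<float>(x, weights, spec);
}

//' @noRd
// [[Rcpp::export(name = "cpp_loss_grad")]]
Rcpp::List cpp_loss_grad(Rcpp::NumericMatrix x, Rcpp::NumericMatrix y,
                         Rcpp::List weights, Rcpp::List spec,
                         std::string precision = "single") {
  tune_allocator();
  if (precision == "double") return loss_grad_impl<double>(x, y, weights, spec);
  return loss_grad_impl<float>(x, y, weights, spec);
}
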