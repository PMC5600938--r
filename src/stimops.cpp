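// Pixel-level compositing for debris scenes. All randomness (fragment
// classes, crop sizes, crop and paste offsets) is drawn R-side; this routine
// only pastes the chosen crops, so scene generation stays a pure function of
// the R seed while the per-pixel work runs at C speed.

#include <Rcpp.h>

// [[Rcpp::export(name = "cpp_paste_fragments")]]
Rcpp::List cpp_paste_fragments(Rcpp::NumericMatrix canvas,
                               Rcpp::List sources,
                               Rcpp::IntegerMatrix frags) {
  const int res = canvas.nrow();
  Rcpp::NumericMatrix out(Rcpp::clone(canvas));
  Rcpp::NumericMatrix debris(res, res);
  const int n = frags.nrow();
  for (int f = 0; f < n; ++f) {
    const int cls = frags(f, 0); // 0-based index into sources
    const int side = frags(f, 1);
    const int crop_top = frags(f, 2) - 1;  // to 0-based
    const int crop_left = frags(f, 3) - 1;
    const int paste_top = frags(f, 4) - 1;
    const int paste_left = frags(f, 5) - 1;
    Rcpp::NumericMatrix src = sources[cls];
    for (int j = 0; j < side; ++j) {
      const double* sc = &src(0, crop_left + j);
      double* oc = &out(0, paste_left + j);
      double* dc = &debris(0, paste_left + j);
      for (int i = 0; i < side; ++i) {
        if (sc[crop_top + i] > 0) {
          oc[paste_top + i] = 1.0;
          dc[paste_top + i] = 1.0;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("image") = out,
                            Rcpp::Named("debris") = debris);
}
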