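test_that("spec invariants are enforced", {
  expect_error(arch_spec(NULL, lateral = FALSE, top_down = FALSE,
                         n_timesteps = 4), "one time step")
  expect_error(arch_spec(NULL, lateral = TRUE, n_timesteps = 1), "at least two")
  expect_error(arch_spec("Z"), "unknown preset")
  expect_error(arch_spec(NULL, input_side = 31), "even")
})

test_that("custom spec accounting matches a hand count", {
  # 1x1 kernels, 1 feature, no recurrence:
  # layer1 1+1, layer2 1+1, readout 10+10 = 24 parameters;
  # units 32^2 + 16^2 + 10 = 1290
  sp <- arch_spec(NULL, features = 1, bu_kernel = 1)
  expect_identical(count_parameters(sp), 24L)
  expect_identical(count_units(sp), 1290L)
})

test_that("weight accounting is independent of the unrolling length", {
  s4 <- arch_spec(NULL, lateral = TRUE, top_down = TRUE, n_timesteps = 4,
                  features = 3, input_side = 8)
  s2 <- arch_spec(NULL, lateral = TRUE, top_down = TRUE, n_timesteps = 2,
                  features = 3, input_side = 8)
  expect_identical(count_parameters(s4), count_parameters(s2))
  w4 <- init_weights(s4, seed = 5)
  w2 <- init_weights(s2, seed = 5)
  expect_identical(unclass(w4), unclass(w2)) # same tensors whatever T is
})

test_that("preactivation reduces to the convolution sum", {
  # 1x1 kernels, 1 feature, constant input c: z = w * c + b everywhere
  sp <- arch_spec(NULL, features = 1, bu_kernel = 1, input_side = 4)
  w <- init_weights(sp, seed = 1)
  w$k1b[] <- 0.5
  w$b1[] <- 0.25
  states <- list(input = array(2, c(4, 4, 1)))
  z <- preactivation(1, 0, states, w, sp)
  expect_equal(as.numeric(z), rep(0.5 * 2 + 0.25, 16))
  expect_error(preactivation(3, 0, states, w, sp), "layer")
})

test_that("recurrent terms vanish at the first step and add linearly", {
  sp <- tiny_spec(input_side = 8, features = 3)
  spB <- tiny_spec(lateral = FALSE, top_down = FALSE, input_side = 8,
                   features = 3)
  w <- init_weights(sp, seed = 2)
  wB <- init_weights(spB, seed = 99)
  for (s in c("k1b", "k2b", "b1", "b2", "W_ro", "b_ro")) wB[[s]] <- w[[s]]
  img <- random_images(8, 1, seed = 3)
  tr <- forward(matrix(img, 8, 8), w, sp, precision = "double")
  trB <- forward(matrix(img, 8, 8), wB, spB, precision = "double")
  # step 0 of the recurrent net equals the feedforward output
  expect_equal(tr[1, ], trB[1, ], tolerance = 1e-12)

  # zeroed recurrent weights collapse the whole trace onto the feedforward one
  w0 <- w
  w0$k1l[] <- 0; w0$k2l[] <- 0; w0$kt[] <- 0
  tr0 <- forward(matrix(img, 8, 8), w0, sp, precision = "double")
  for (t in 1:4) expect_equal(tr0[t, ], trB[1, ], tolerance = 1e-12)

  # the first-step output is independent of the recurrent weights
  w2 <- w
  w2$k1l[] <- rnorm(length(w2$k1l))
  w2$kt[] <- rnorm(length(w2$kt))
  tr2 <- forward(matrix(img, 8, 8), w2, sp, precision = "double")
  expect_equal(tr2[1, ], tr[1, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(tr2[4, ], tr[4, ])))
})

test_that("layer output implements ReLU plus divisive normalization", {
  z <- array(-abs(rnorm(4 * 4 * 6)), c(4, 4, 6))
  expect_equal(layer_output(z), array(0, c(4, 4, 6))) # all non-positive

  # single active unit of value 1, silent neighbours
  z <- array(0, c(1, 1, 6))
  z[1, 1, 3] <- 1
  h <- layer_output(z)
  expect_equal(h[1, 1, 3], (1 + 1e-4)^(-0.5))
  # saturation: x -> infinity gives 1 / sqrt(alpha) = 100
  z[1, 1, 3] <- 1e9
  expect_equal(layer_output(z)[1, 1, 3], 100, tolerance = 1e-6)
})

test_that("readout is global max pool, linear map, sigmoid", {
  sp <- arch_spec(NULL, features = 1, bu_kernel = 1, input_side = 4)
  w <- init_weights(sp, seed = 1)
  h <- array(rnorm(2 * 2 * 1), c(2, 2, 1))
  w$W_ro[] <- 0; w$b_ro[] <- 0
  expect_equal(readout(h, w), rep(0.5, 10))

  # k = 1 feature, max 2, weight 1, bias -2 -> sigmoid(0) = 0.5
  h[] <- c(2, 0.5, -1, 0)
  w$W_ro[] <- 1; w$b_ro[] <- -2
  expect_equal(readout(h, w), rep(0.5, 10))

  # positive scaling never moves the spatial argmax
  f1 <- apply(h, 3, which.max)
  f2 <- apply(h * 3.7, 3, which.max)
  expect_identical(f1, f2)
})

test_that("fast forward pass equals the op-composed reference", {
  for (preset in list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE),
                      c(FALSE, FALSE))) {
    sp <- tiny_spec(lateral = preset[1], top_down = preset[2],
                    features = 3, input_side = 8)
    w <- init_weights(sp, seed = 17)
    img <- matrix(random_images(8, 1, seed = 23), 8, 8)
    fast <- forward(img, w, sp, precision = "double")
    ref <- bltnet:::forward_reference(img, w, sp)
    expect_equal(unclass(fast), unclass(ref), tolerance = 1e-12)
    expect_equal(nrow(fast), sp$n_timesteps)
    expect_true(all(fast > 0 & fast < 1))
  }
})

test_that("feedforward presets emit a single-step trace", {
  sp <- arch_spec("B")
  w <- init_weights(sp, seed = 1)
  tr <- forward(matrix(rnorm(1024), 32, 32), w, sp)
  expect_identical(nrow(tr), 1L)
})

test_that("checkpoints round-trip through JSON", {
  sp <- tiny_spec(features = 2, input_side = 4)
  w <- init_weights(sp, seed = 31)
  path <- withr::local_tempfile(fileext = ".json")
  save_weights(w, sp, path)
  back <- load_weights(path)
  expect_equal(unclass(back$weights), unclass(w), tolerance = 1e-12)
  expect_identical(back$spec$features, sp$features)
  img <- matrix(random_images(4, 1, seed = 2), 4, 4)
  expect_equal(forward(img, back$weights, back$spec, precision = "double"),
               forward(img, w, sp, precision = "double"), tolerance = 1e-12)
})
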