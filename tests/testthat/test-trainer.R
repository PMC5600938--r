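test_that("the loss matches closed-form evaluations", {
  y <- encode_labels(3)
  # perfect prediction, no weights: zero loss (up to output clamping)
  perfect <- matrix(rep(y, each = 4), 4, 10)
  expect_equal(blt_loss(perfect, y), 0, tolerance = 1e-5)
  # chance outputs: 4 steps x 10 classes x ln 2
  expect_equal(blt_loss(matrix(0.5, 4, 10), y), 40 * log(2))
  # L2 term: a single weight of 2 at lambda = 5e-4 adds 0.002
  sp <- arch_spec(NULL, features = 1, bu_kernel = 1, input_side = 4)
  w <- init_weights(sp, seed = 1)
  for (s in names(w)) w[[s]][] <- 0
  base <- blt_loss(matrix(0.5, 4, 10), y, w, sp)
  w$k1b[] <- 2
  expect_equal(blt_loss(matrix(0.5, 4, 10), y, w, sp) - base, 0.002)
  expect_error(blt_loss(matrix(0.5, 4, 7), y), "mismatch")
})

test_that("the learning-rate schedule decays exponentially in epochs", {
  cfg <- training_config()
  expect_equal(lr_schedule(0, cfg), 0.1)
  expect_equal(lr_schedule(40, cfg), 0.01)
  expect_equal(lr_schedule(80, cfg), 0.001)
  # continuous exponent between the checkpoints
  expect_equal(lr_schedule(20, cfg), 0.1 * 0.1^0.5)
  expect_error(lr_schedule(-1, cfg))
})

test_that("momentum follows the two-line update rule", {
  w <- c(1, 2); g <- c(0.5, -1)
  # mu = 0: plain gradient descent
  s <- momentum_step(w, g, list(v = c(0, 0)), lr = 0.1, momentum = 0)
  expect_equal(s$w, w - 0.1 * g)
  # zero gradient forever: weights constant
  s2 <- momentum_step(w, c(0, 0), list(v = c(0, 0)), lr = 0.1)
  expect_equal(s2$w, w)
  # two steps with constant gradient: displacement -lr * g * (1 + 1.9)
  s3 <- momentum_step(w, g, list(v = c(0, 0)), lr = 0.1, momentum = 0.9)
  s4 <- momentum_step(s3$w, g, s3$state, lr = 0.1, momentum = 0.9)
  expect_equal(s4$w - w, -0.1 * g * (1 + 1.9))
  expect_error(momentum_step(w, 1, list(v = c(0, 0)), 0.1), "mismatch")
})

test_that("top-n prediction uses the final step with index tie-breaks", {
  tr <- rbind(c(rep(0, 7), 1, 0, 0))
  expect_identical(predict_topn(tr, 1), 7L)
  expect_identical(predict_topn(rbind(c(.9, .8, .7, rep(.1, 7))), 3), c(0L, 1L, 2L))
  expect_identical(predict_topn(rbind(rep(0.5, 10)), 2), c(0L, 1L))
  # only the final step matters
  tr2 <- rbind(c(1, rep(0, 9)), c(rep(0, 9), 1))
  expect_identical(predict_topn(tr2, 1), 9L)
  expect_error(predict_topn(tr, 11), "exceed")
})

test_that("BPTT gradients match central finite differences", {
  sp <- tiny_spec(features = 2, input_side = 4)
  w <- init_weights(sp, seed = 3)
  set.seed(9)
  x <- matrix(rnorm(16 * 2), 16, 2)
  y <- matrix(rbinom(20, 1, 0.3), 2, 10)
  res <- bltnet:::cpp_loss_grad(x, y, bltnet:::pack_for_cpp(w, sp),
                                unclass(sp), "double")
  g <- unlist(lapply(bltnet:::weight_slots(sp),
                     function(s) as.numeric(res$grads[[s]])))
  flat <- bltnet:::flatten_weights(w, sp)
  loss_at <- function(f) {
    ww <- bltnet:::unflatten_weights(f, w, sp)
    bltnet:::cpp_loss_grad(x, y, bltnet:::pack_for_cpp(ww, sp),
                           unclass(sp), "double")$loss
  }
  h <- 1e-5
  idx <- seq(1, length(flat), by = 3) # probe a third of the parameters
  fd <- vapply(idx, function(i) {
    fp <- flat; fp[i] <- fp[i] + h
    fm <- flat; fm[i] <- fm[i] - h
    (loss_at(fp) - loss_at(fm)) / (2 * h)
  }, 0)
  rel <- abs(g[idx] - fd) / pmax(1e-8, abs(g[idx]) + abs(fd))
  expect_lt(max(rel), 1e-4)
})

test_that("training is deterministic, counts updates, and reduces the loss", {
  cfg_s <- stimulus_config(task = "debris", n_fragments = 0, seed = 33)
  tr <- generate_dataset(cfg_s, 250, role = "train")
  spec <- arch_spec("B")
  cfg <- training_config(epochs = 3, seed = 5)
  m1 <- train(spec, tr, config = cfg)
  # floor(250 / 100) = 2 mini-batches per epoch, 3 epochs
  expect_identical(m1$n_updates, 6L)
  expect_identical(nrow(m1$log), 3L)
  # the loss comes down on an easy unoccluded task
  expect_lt(m1$log$loss[3], m1$log$loss[1])
  # full determinism given (spec, data, config)
  m2 <- train(spec, tr, config = cfg)
  expect_equal(unclass(m1$weights), unclass(m2$weights), tolerance = 1e-12)
  expect_identical(m1$log, m2$log)
  expect_error(train(spec, tr, config = training_config(batch_size = 1000)),
               "smaller than one mini-batch")
})

test_that("evaluation scores exact set matches and per-digit hits", {
  cfg_s <- stimulus_config(task = "clutter", n_digits = 3, seed = 44)
  tr <- generate_dataset(cfg_s, 200, role = "train")
  te <- generate_dataset(cfg_s, 30, role = "test")
  m <- train(arch_spec("B"), tr, config = training_config(epochs = 1, seed = 2))
  ev <- evaluate(m, te)
  expect_equal(nrow(ev$predictions), 30)
  expect_equal(nrow(ev$digit_predictions), 90) # 3 digits per image
  expect_true(all(ev$predictions$correct %in% 0:1))
  # image-level correctness == all three digits recovered
  agg <- tapply(ev$digit_predictions$correct, ev$digit_predictions$image, all)
  expect_equal(as.integer(agg), ev$predictions$correct)
  # error rate consistent with the table
  expect_equal(ev$error_rate, 1 - mean(ev$predictions$correct))
  # evaluation only reads the final time step: a three-digit prediction set
  expect_true(all(vapply(strsplit(ev$predictions$predicted, ";"),
                         length, 0L) == 3))
})
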