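#' Training configuration
#'
#' Defaults are the reference training regime: mini-batches of 100 images,
#' 100 epochs, momentum 0.9, initial learning rate 0.1 decayed continuously by
#' a factor of 0.1 every 40 epochs, and L2 regularization with coefficient
#' 0.0005 applied to all trainable parameters.
#'
#' @param batch_size images per mini-batch.
#' @param epochs passes through the training set.
#' @param momentum momentum coefficient `mu`.
#' @param lr initial learning rate `eta`.
#' @param decay_rate multiplicative decay `delta`.
#' @param decay_step epochs per decay step `d`.
#' @param lambda L2 coefficient.
#' @param seed seed for weight initialization and epoch shuffling.
#' @param precision `"single"` (default) or `"double"` arithmetic in the
#'   compute core.
#' @param time_average_loss if `TRUE`, the cross-entropy term of the training
#'   objective is averaged instead of summed over time steps — equivalent to
#'   training a T-step network at learning rate `lr / T`. The reference
#'   objective sums over time, which hands every recurrent network an
#'   effective step size four times the feedforward one; at heavily reduced
#'   training scale that traps the recurrent models in a base-rate attractor
#'   they never leave, so desk-scale replications enable this option (see the
#'   vignette). The default keeps the literal summed objective.
#' @return An object of class `blt_training_config`.
#' @export
training_config <- function(batch_size = 100L, epochs = 100L, momentum = 0.9,
                            lr = 0.1, decay_rate = 0.1, decay_step = 40L,
                            lambda = 5e-4, seed = 1L,
                            precision = c("single", "double"),
                            time_average_loss = FALSE) {
  stopifnot(batch_size > 0, epochs > 0, momentum >= 0, lr > 0,
            decay_rate > 0, decay_step > 0, lambda >= 0)
  structure(
    list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         momentum = momentum, lr = lr, decay_rate = decay_rate,
         decay_step = as.integer(decay_step), lambda = lambda,
         seed = as.integer(seed), precision = match.arg(precision),
         time_average_loss = isTRUE(time_average_loss)),
    class = "blt_training_config"
  )
}

#' Learning-rate schedule
#'
#' `epsilon(e) = eta * delta^(e / d)` with a continuous exponent, so the rate
#' decays smoothly within a decay period; at whole multiples of `d` (epochs 0,
#' 40, 80 under the defaults) it equals the staircase reading exactly
#' (0.1, 0.01, 0.001).
#'
#' @param epoch epoch index `e >= 0` (0-based).
#' @param config a [training_config()].
#' @return The learning rate for that epoch.
#' @examples
#' lr_schedule(40, training_config())  # 0.01
#' @export
lr_schedule <- function(epoch, config = training_config()) {
  stopifnot(epoch >= 0)
  config$lr * config$decay_rate^(epoch / config$decay_step)
}

#' Multi-hot ground-truth encoding
#'
#' @param labels integer vector of digit classes present (0-9), or a list of
#'   such vectors.
#' @param n_classes number of classes.
#' @return A binary vector (or matrix, one row per label set) with 1 at each
#'   present class.
#' @export
encode_labels <- function(labels, n_classes = 10L) {
  one <- function(l) {
    y <- numeric(n_classes)
    y[l + 1] <- 1
    y
  }
  if (is.list(labels)) {
    t(vapply(labels, one, numeric(n_classes)))
  } else {
    one(labels)
  }
}

#' Training loss for one output trace
#'
#' Cross-entropy between the sigmoid outputs and the multi-hot ground truth,
#' summed across every time step and class, plus the L2 penalty
#' `lambda * ||w||^2` over all trainable parameters. Outputs are clamped to
#' `[1e-7, 1 - 1e-7]` inside the logarithms.
#'
#' @param trace `n_timesteps x n_classes` matrix of outputs (a `blt_trace`).
#' @param y binary ground-truth vector of length `n_classes`.
#' @param weights optional weight set for the L2 term.
#' @param spec spec matching `weights` (required with `weights`).
#' @param lambda L2 coefficient.
#' @return Scalar loss.
#' @examples
#' tr <- matrix(0.5, 4, 10)
#' blt_loss(tr, encode_labels(3))  # 40 * log(2)
#' @export
blt_loss <- function(trace, y, weights = NULL, spec = NULL, lambda = 5e-4) {
  if (ncol(trace) != length(y)) {
    stop("trace and ground truth have mismatched class counts.")
  }
  yh <- pmin(pmax(trace, 1e-7), 1 - 1e-7)
  ym <- matrix(y, nrow(trace), length(y), byrow = TRUE)
  loss <- -sum(ym * log(yh) + (1 - ym) * log(1 - yh))
  if (!is.null(weights)) {
    loss <- loss + lambda * sum(flatten_weights(weights, spec)^2)
  }
  loss
}

#' One momentum update
#'
#' The classical momentum rule: `v <- mu * v - eps * grad`,
#' `w <- w + v`. Velocity persists across mini-batches.
#'
#' @param w numeric parameter vector.
#' @param grad gradient of the loss at `w`.
#' @param state list with `v` (velocity; zeros initially).
#' @param lr learning rate `eps`.
#' @param momentum coefficient `mu`.
#' @return list with updated `w` and `state`.
#' @export
momentum_step <- function(w, grad, state, lr, momentum = 0.9) {
  if (length(grad) != length(w)) stop("gradient/parameter shape mismatch.")
  v <- momentum * state$v - lr * grad
  list(w = w + v, state = list(v = v))
}

#' Train a network
#'
#' Minimizes the time-summed cross-entropy plus L2 penalty by mini-batch
#' momentum SGD, backpropagating through the unrolled graph (weights shared
#' across time steps). The per-image loss is averaged within each mini-batch.
#' Training data are shuffled every epoch from a seeded stream; the whole run
#' is a pure function of `(spec, data, config)`. The validation split is used
#' for monitoring only.
#'
#' @param spec a [arch_spec()].
#' @param train_split,val_split `blt_dataset` splits (raw pixel values;
#'   normalization statistics are fitted on the training split here).
#' @param config a [training_config()].
#' @param noise_sigma standard deviation of Gaussian noise added to normalized
#'   images (0 for none); noise is resampled once per image per epoch.
#' @param norm_stats optional pre-fitted [fit_normalization()] statistics.
#' @param verbose print one line per epoch.
#' @return An object of class `blt_model`: trained weights, the spec, the
#'   normalization statistics, the config, and a per-epoch `log` tibble with
#'   `epoch`, `loss`, `train_err`, `val_err` and `lr`.
#' @export
train <- function(spec, train_split, val_split = NULL,
                  config = training_config(), noise_sigma = 0,
                  norm_stats = NULL, verbose = FALSE) {
  if (is.null(norm_stats)) norm_stats <- fit_normalization(train_split)
  n <- dim(train_split$images)[3]
  npix <- spec$input_side^2
  if (dim(train_split$images)[1] != spec$input_side) {
    stop("training images do not match `spec$input_side`.")
  }
  xall <- matrix(normalize(train_split$images, norm_stats), npix, n)
  yall <- encode_labels(train_split$labels, spec$n_classes)
  n_targets <- length(train_split$labels[[1]])

  weights <- init_weights(spec, seed = derive_seed(config$seed, 11L),
                          output_bias = stats::qlogis(n_targets / 10))
  cw <- pack_for_cpp(weights, spec)
  flat <- flatten_weights(weights, spec)
  vel <- numeric(length(flat))
  spec_l <- unclass(spec)

  xval <- NULL
  if (!is.null(val_split)) {
    nv <- dim(val_split$images)[3]
    xval <- matrix(normalize(val_split$images, norm_stats), npix, nv)
  }

  n_batches <- floor(n / config$batch_size)
  if (n_batches < 1) stop("training split smaller than one mini-batch.")
  log <- vector("list", config$epochs)
  set.seed(derive_seed(config$seed, 13L))
  for (e in seq_len(config$epochs) - 1L) {
    lr <- lr_schedule(e, config)
    ord <- sample.int(n)
    epoch_loss <- 0
    n_correct <- 0L
    n_seen <- 0L
    for (bi in seq_len(n_batches)) {
      idx <- ord[((bi - 1) * config$batch_size + 1):(bi * config$batch_size)]
      xb <- xall[, idx, drop = FALSE]
      if (noise_sigma > 0) {
        xb <- xb + matrix(rnorm(length(xb), sd = noise_sigma), nrow(xb))
      }
      yb <- yall[idx, , drop = FALSE]
      res <- cpp_loss_grad(xb, yb, cw, spec_l, config$precision)
      if (!is.finite(res$loss)) {
        stop(sprintf(
          "training diverged (non-finite loss) at epoch %d, batch %d; try a smaller learning rate.",
          e, bi
        ))
      }
      gflat <- unlist(lapply(weight_slots(spec),
                             function(s) as.numeric(res$grads[[s]])),
                      use.names = FALSE)
      if (config$time_average_loss) gflat <- gflat / spec$n_timesteps
      gflat <- gflat + 2 * config$lambda * flat
      vel <- config$momentum * vel - lr * gflat
      flat <- flat + vel
      weights <- unflatten_weights(flat, weights, spec)
      cw <- pack_for_cpp(weights, spec)
      epoch_loss <- epoch_loss + res$loss + config$lambda * sum(flat^2)
      yh_final <- res$trace[[length(res$trace)]]
      pred_ok <- topn_correct(yh_final, train_split$labels[idx], n_targets)
      n_correct <- n_correct + sum(pred_ok)
      n_seen <- n_seen + length(pred_ok)
    }
    val_err <- NA_real_
    if (!is.null(xval)) {
      val_err <- eval_error(xval, val_split$labels, cw, spec_l, n_targets,
                            config$precision, config$batch_size)$error
    }
    log[[e + 1]] <- tibble::tibble(
      epoch = e, loss = epoch_loss / n_batches,
      train_err = 1 - n_correct / n_seen, val_err = val_err, lr = lr
    )
    if (verbose) {
      message(sprintf("epoch %3d  loss %8.4f  train_err %.4f  val_err %s  lr %.5f",
                      e, epoch_loss / n_batches, 1 - n_correct / n_seen,
                      ifelse(is.na(val_err), "-", sprintf("%.4f", val_err)), lr))
    }
  }
  structure(
    list(weights = weights, spec = spec, norm_stats = norm_stats,
         config = config, noise_sigma = noise_sigma,
         n_updates = as.integer(n_batches * config$epochs),
         log = dplyr::bind_rows(log)),
    class = "blt_model"
  )
}

#' @export
print.blt_model <- function(x, ...) {
  last <- utils::tail(x$log, 1)
  cat(sprintf(
    "<blt_model> %s, trained %d epochs; final train error %.4f%s\n",
    x$spec$name, nrow(x$log), last$train_err,
    if (is.finite(last$val_err)) sprintf(", val error %.4f", last$val_err) else ""
  ))
  invisible(x)
}

# Correctness of top-n predictions for a batch output matrix.
topn_correct <- function(yhat, labels, n_targets) {
  vapply(seq_len(nrow(yhat)), function(b) {
    pred <- predict_topn_vec(yhat[b, ], n_targets)
    setequal(pred, labels[[b]])
  }, logical(1))
}

predict_topn_vec <- function(y, n) {
  sort(order(-y)[seq_len(n)] - 1L)
}

#' Top-n prediction from an output trace
#'
#' Takes the `n` classes with the largest sigmoid outputs at the final time
#' step as the predicted label set, with ties broken by ascending class index.
#'
#' @param trace a `blt_trace` (matrix `n_timesteps x n_classes`) or a single
#'   output vector.
#' @param n number of digits in the task.
#' @return Sorted integer vector of `n` predicted classes.
#' @examples
#' predict_topn(rbind(c(.9, .8, .7, rep(.1, 7))), 3)  # 0 1 2
#' @export
predict_topn <- function(trace, n) {
  y <- if (is.matrix(trace)) trace[nrow(trace), ] else trace
  if (n > length(y)) stop("`n` cannot exceed the number of classes.")
  if (n < 1) stop("`n` must be at least 1.")
  predict_topn_vec(y, n)
}

# Batched error evaluation against packed weights.
eval_error <- function(x, labels, cw, spec_l, n_targets, precision,
                       batch = 200L) {
  n <- ncol(x)
  correct <- logical(n)
  final <- matrix(0, n, spec_l$n_classes)
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(n, start + batch - 1)
    out <- cpp_forward(x[, idx, drop = FALSE], cw, spec_l, precision)
    yh <- out[[length(out)]]
    final[idx, ] <- yh
    correct[idx] <- topn_correct(yh, labels[idx], n_targets)
  }
  list(error = 1 - mean(correct), correct = correct, yhat = final)
}

#' Evaluate a trained model on a test split
#'
#' Normalizes the split with the model's own training statistics, runs the
#' forward pass, takes top-n predictions at the final time step (n = number of
#' digits per image in the split) and scores each image as correct only when
#' the predicted set equals the label set. Per-digit correctness (is each true
#' digit among the predictions?) is recorded alongside for the clustered
#' statistics.
#'
#' @param model a [train()]ed `blt_model`.
#' @param test_split a `blt_dataset`.
#' @param noise_sigma Gaussian noise added to the normalized test images
#'   (seeded by `noise_seed`).
#' @param noise_seed seed for the noise draw.
#' @return An object of class `blt_eval`: `error_rate`, `n`, `predictions`
#'   (tibble: `image`, `predicted`, `labels`, `correct`) and
#'   `digit_predictions` (tibble: `image`, `digit`, `correct`).
#' @export
evaluate <- function(model, test_split, noise_sigma = 0, noise_seed = 1L) {
  spec <- model$spec
  if (dim(test_split$images)[1] != spec$input_side) {
    stop("test images do not match the model's input resolution.")
  }
  n <- dim(test_split$images)[3]
  x <- matrix(normalize(test_split$images, model$norm_stats),
              spec$input_side^2, n)
  if (noise_sigma > 0) {
    set.seed(derive_seed(noise_seed, 17L))
    x <- x + matrix(rnorm(length(x), sd = noise_sigma), nrow(x))
  }
  n_targets <- length(test_split$labels[[1]])
  cw <- pack_for_cpp(model$weights, spec)
  res <- eval_error(x, test_split$labels, cw, unclass(spec), n_targets,
                    model$config$precision)
  preds <- lapply(seq_len(n), function(b) predict_topn_vec(res$yhat[b, ], n_targets))
  predictions <- tibble::tibble(
    image = seq_len(n),
    predicted = vapply(preds, paste, "", collapse = ";"),
    labels = vapply(test_split$labels, paste, "", collapse = ";"),
    correct = as.integer(res$correct)
  )
  digit_predictions <- tibble::tibble(
    image = rep(seq_len(n), lengths(test_split$labels)),
    digit = unlist(test_split$labels),
    correct = as.integer(unlist(lapply(seq_len(n), function(b) {
      test_split$labels[[b]] %in% preds[[b]]
    })))
  )
  structure(
    list(error_rate = res$error, n = n, model = spec$name,
         condition = if (!is.null(test_split$config)) {
           condition_tag(test_split$config)
         } else "unknown",
         predictions = predictions, digit_predictions = digit_predictions),
    class = "blt_eval"
  )
}

#' @export
print.blt_eval <- function(x, ...) {
  cat(sprintf("<blt_eval> %s on %s: error %.2f%% (n = %d)\n",
              x$model, x$condition, 100 * x$error_rate, x$n))
  invisible(x)
}

#' Build a paired prediction table for two models
#'
#' Aligns the per-image (or per-digit) correctness records of two evaluations
#' of the same test split into the paired binary table the statistical tests
#' consume. With `per_digit = TRUE` each row is one (image, digit) pair and
#' the image is the cluster.
#'
#' @param eval_a,eval_b `blt_eval` objects over the identical image set.
#' @param per_digit use per-digit correctness rows (multi-label tasks).
#' @return A tibble with `image`, `cluster`, `correct_a`, `correct_b`.
#' @export
prediction_table <- function(eval_a, eval_b, per_digit = FALSE) {
  if (eval_a$n != eval_b$n) stop("models were evaluated on different image sets.")
  if (per_digit) {
    tibble::tibble(
      image = eval_a$digit_predictions$image,
      digit = eval_a$digit_predictions$digit,
      cluster = eval_a$digit_predictions$image,
      correct_a = eval_a$digit_predictions$correct,
      correct_b = eval_b$digit_predictions$correct
    )
  } else {
    tibble::tibble(
      image = eval_a$predictions$image,
      cluster = eval_a$predictions$image,
      correct_a = eval_a$predictions$correct,
      correct_b = eval_b$predictions$correct
    )
  }
}
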