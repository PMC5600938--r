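# broom-style accessors and ggplot2 autoplot methods for the fitted objects.

#' Tidy the per-epoch training log of a model
#'
#' @param x a `blt_model`.
#' @param ... unused.
#' @return The per-epoch log tibble (`epoch`, `loss`, `train_err`, `val_err`,
#'   `lr`).
#' @method tidy blt_model
#' @export
tidy.blt_model <- function(x, ...) {
  x$log
}

#' One-row summary of a trained model
#'
#' @param x a `blt_model`.
#' @param ... unused.
#' @return A tibble with the architecture name, parameter and unit counts,
#'   epochs trained and final train/validation errors.
#' @method glance blt_model
#' @export
glance.blt_model <- function(x, ...) {
  last <- utils::tail(x$log, 1)
  tibble::tibble(
    architecture = x$spec$name,
    n_parameters = count_parameters(x$spec),
    n_units = count_units(x$spec),
    epochs = nrow(x$log),
    train_err = last$train_err,
    val_err = last$val_err
  )
}

#' @method tidy blt_eval
#' @export
tidy.blt_eval <- function(x, ...) {
  x$predictions
}

#' @method glance blt_eval
#' @export
glance.blt_eval <- function(x, ...) {
  tibble::tibble(model = x$model, condition = x$condition,
                 error_rate = x$error_rate, n = x$n)
}

#' @method tidy blt_experiment
#' @export
tidy.blt_experiment <- function(x, ...) {
  x$results
}

#' Training curves for a fitted model
#'
#' @param object a `blt_model`.
#' @param ... unused.
#' @return A ggplot of train/validation error by epoch.
#' @method autoplot blt_model
#' @export
autoplot.blt_model <- function(object, ...) {
  df <- object$log |>
    tidyr::pivot_longer(dplyr::any_of(c("train_err", "val_err")),
                        names_to = "split", values_to = "error") |>
    dplyr::filter(is.finite(.data$error))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$error,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "error rate",
                  title = paste("Training curves:", object$spec$name))
}

#' Error rates across conditions for an experiment
#'
#' @param object a `blt_experiment`.
#' @param ... unused.
#' @return A ggplot of error rate by difficulty level and architecture.
#' @method autoplot blt_experiment
#' @export
autoplot.blt_experiment <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = factor(.data$level), y = .data$error_rate,
                               colour = .data$architecture,
                               group = .data$architecture)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~task, scales = "free_x") +
    ggplot2::labs(x = "difficulty level", y = "test error rate",
                  colour = "model")
}
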