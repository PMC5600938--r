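#' McNemar's test for paired classifier correctness
#'
#' Compares two models on the same images through the discordant pairs: `b`
#' images only model A got right, `c` images only model B got right. The
#' default statistic is the continuity-corrected chi-square
#' `(|b - c| - 1)^2 / (b + c)` on 1 degree of freedom; with `exact = TRUE` the
#' p-value comes from the exact binomial sign test on `(b, b + c)`. With no
#' discordant pairs the models are indistinguishable and `p = 1`.
#'
#' @param correct_a,correct_b equal-length binary vectors of per-image
#'   correctness.
#' @param exact use the exact binomial test instead of the chi-square
#'   approximation.
#' @return An object of class `blt_test_result` with `statistic`, `p_value`,
#'   `b`, `c`, `n` and `method`.
#' @examples
#' a <- c(1, 1, 0, 1, 0, 1)
#' b <- c(1, 0, 0, 1, 1, 1)
#' mcnemar(a, b)
#' @export
mcnemar <- function(correct_a, correct_b, exact = FALSE) {
  if (length(correct_a) != length(correct_b)) {
    stop("paired correctness vectors must have equal length.")
  }
  b <- sum(correct_a == 1 & correct_b == 0)
  cc <- sum(correct_a == 0 & correct_b == 1)
  if (b + cc == 0) {
    stat <- 0
    p <- 1
  } else if (exact) {
    stat <- NA_real_
    p <- binom.test(b, b + cc, 0.5)$p.value
  } else {
    stat <- (abs(b - cc) - 1)^2 / (b + cc)
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(
    list(statistic = stat, p_value = p, b = b, c = cc,
         n = length(correct_a),
         method = if (exact) "exact binomial" else "continuity-corrected chi-square"),
    class = "blt_test_result"
  )
}

#' Cluster-adjusted McNemar test for correlated paired outcomes
#'
#' When several correctness records come from the same image (one per target
#' digit in a multi-digit scene), the records within an image are dependent
#' and the plain McNemar variance is too small. The adjusted statistic keeps
#' the McNemar numerator — the total discordance difference — but estimates
#' its variance from the per-cluster discordance differences:
#' `T = (sum_k (b_k - c_k))^2 / sum_k (b_k - c_k)^2`, referred to chi-square
#' with 1 df. With every cluster containing a single record it reduces to the
#' uncorrected McNemar statistic `(b - c)^2 / (b + c)`.
#'
#' @param table a tibble with columns `cluster`, `correct_a`, `correct_b` (one
#'   row per paired record), e.g. from [prediction_table()].
#' @return A `blt_test_result` with `statistic`, `p_value`, per-test counts
#'   and the number of clusters.
#' @export
clustered_mcnemar <- function(table) {
  need <- c("cluster", "correct_a", "correct_b")
  if (!all(need %in% names(table))) {
    stop("`table` must have columns cluster, correct_a, correct_b.")
  }
  if (nrow(table) == 0) stop("empty prediction table.")
  per <- table |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      d = sum(.data$correct_a == 1 & .data$correct_b == 0) -
        sum(.data$correct_a == 0 & .data$correct_b == 1),
      .groups = "drop"
    )
  num <- sum(per$d)^2
  den <- sum(per$d^2)
  if (den == 0) {
    stat <- 0
    p <- 1
  } else {
    stat <- num / den
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(
    list(statistic = stat, p_value = p,
         b = sum(table$correct_a == 1 & table$correct_b == 0),
         c = sum(table$correct_a == 0 & table$correct_b == 1),
         n = nrow(table), n_clusters = nrow(per),
         method = "cluster-adjusted McNemar"),
    class = "blt_test_result"
  )
}

#' @export
print.blt_test_result <- function(x, ...) {
  cat(sprintf("<%s> chi2 = %s, p = %.4g (b = %d, c = %d, n = %d)\n",
              x$method,
              ifelse(is.na(x$statistic), "-", sprintf("%.4g", x$statistic)),
              x$p_value, x$b, x$c, x$n))
  invisible(x)
}

#' @method tidy blt_test_result
#' @export
tidy.blt_test_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value,
                 b = x$b, c = x$c, n = x$n, method = x$method)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' The standard step-up rule at level `q`: with ordered p-values `p_(1) <=
#' ... <= p_(m)`, reject all hypotheses with `p <= p_(k*)` where `k*` is the
#' largest `k` such that `p_(k) <= (k / m) q`. One family per group of
#' pairwise comparisons (one image set = one family).
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param q target false discovery rate.
#' @return A list with `reject` (logical, in input order), `threshold` (the
#'   largest rejected p-value, 0 when none) and `adjusted` (BH-adjusted
#'   p-values).
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))$reject
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) {
    return(list(reject = logical(0), threshold = 0, adjusted = numeric(0)))
  }
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1].")
  }
  adjusted <- stats::p.adjust(pvals, method = "BH")
  reject <- adjusted <= q
  threshold <- if (any(reject)) max(pvals[reject]) else 0
  list(reject = reject, threshold = threshold, adjusted = adjusted)
}

#' Robustness slope: OLS fit of error rate on difficulty level
#'
#' Fits an ordinary least-squares line to a model's error rates across ordinal
#' task-difficulty levels (e.g. light = 1, moderate = 2, heavy = 3) and
#' returns its slope: the per-level increase in error.
#'
#' @param error_rates numeric vector of error rates, one per level.
#' @param difficulties numeric difficulty scores (default `1:K`).
#' @return The OLS slope.
#' @examples
#' fit_error_slope(c(0.10, 0.20, 0.30))  # 0.10
#' @export
fit_error_slope <- function(error_rates, difficulties = seq_along(error_rates)) {
  if (length(error_rates) < 2) stop("need at least two difficulty levels.")
  if (length(unique(difficulties)) < 2) {
    stop("difficulty levels must not be constant.")
  }
  unname(coef(lm(error_rates ~ difficulties))[2])
}

# OLS slope weights for fixed predictor values: slope = sum(w * y).
slope_weights <- function(x) {
  xc <- x - mean(x)
  xc / sum(xc^2)
}

#' Permutation test for a difference in robustness slopes
#'
#' Tests whether two models' error rates grow at different rates with task
#' difficulty. Under the null hypothesis the two models are exchangeable, so
#' each permutation swaps the two models' predictions for a random subset of
#' images (an independent fair coin per image; all records of an image,
#' e.g. its per-digit rows, swap together). Error rates per level, each
#' model's OLS slope and the slope difference are recomputed for every
#' permutation to form the null distribution; the two-tailed p-value is
#' `(1 + #{|null| >= |observed|}) / (1 + n_perm)`.
#'
#' @param table a tibble with columns `image`, `level`, `correct_a`,
#'   `correct_b`; one row per (image, record), every image at exactly one
#'   level. Build it by stacking [prediction_table()]s across levels.
#' @param n_perm number of permutations.
#' @param difficulties optional numeric scores for the levels (defaults to
#'   their rank order).
#' @param seed RNG seed for the permutation stream.
#' @return An object of class `blt_slope_test`: `observed` slope difference
#'   (a minus b), `slope_a`, `slope_b`, `null` (numeric vector of length
#'   `n_perm`), `p_value` and `n_perm`.
#' @export
slope_permutation_test <- function(table, n_perm = 10000L,
                                   difficulties = NULL, seed = 1L) {
  if (n_perm < 1) stop("`n_perm` must be at least 1.")
  need <- c("image", "level", "correct_a", "correct_b")
  if (!all(need %in% names(table))) {
    stop("`table` must have columns image, level, correct_a, correct_b.")
  }
  levels_ord <- sort(unique(table$level))
  K <- length(levels_ord)
  if (K < 2) stop("need at least two difficulty levels.")
  if (is.null(difficulties)) difficulties <- seq_len(K)
  w <- slope_weights(difficulties)

  lvl <- match(table$level, levels_ord)
  # image keys must be unique across levels
  img_key <- paste(table$level, table$image, sep = "\r")
  imgs <- unique(img_key)
  img_idx <- match(img_key, imgs)
  n_img <- length(imgs)

  # per-level row aggregation: error rate = 1 - mean(correct)
  counts <- tabulate(lvl, K)
  agg <- function(correct) {
    rowsum(correct, lvl)[, 1] / counts
  }
  a <- as.numeric(table$correct_a)
  b <- as.numeric(table$correct_b)
  err_a <- 1 - agg(a)
  err_b <- 1 - agg(b)
  slope_a <- sum(w * err_a)
  slope_b <- sum(w * err_b)
  observed <- slope_a - slope_b

  # Vectorized permutations in chunks: for flip f in {0,1} per image,
  # swapped accuracy means are mean(a) - mean((a - b) * f) per level, so the
  # null slope difference needs only the per-level aggregation of (a - b) * f.
  d <- a - b
  set.seed(derive_seed(seed, 23L))
  null <- numeric(n_perm)
  chunk <- max(1L, min(n_perm, floor(2e7 / n_img)))
  done <- 0L
  # per-level x image count matrix of d
  D <- rowsum(d * 1, group = paste(lvl, img_idx, sep = "\r"))
  key_parts <- strsplit(rownames(D), "\r", fixed = TRUE)
  D_lvl <- as.integer(vapply(key_parts, `[`, "", 1))
  D_img <- as.integer(vapply(key_parts, `[`, "", 2))
  M <- matrix(0, K, n_img)
  M[cbind(D_lvl, D_img)] <- D[, 1]
  while (done < n_perm) {
    m <- min(chunk, n_perm - done)
    Fm <- matrix(runif(n_img * m) < 0.5, n_img, m)
    # per-level sum of d over flipped images, each column one permutation
    swap <- M %*% Fm                      # K x m
    delta_err <- sweep(swap, 1, counts, "/")
    # a' = a - d*f, b' = b + d*f  =>  err_a' = err_a + sum(d f)/n_l and
    # err_b' = err_b - sum(d f)/n_l, so the difference shifts by 2*delta.
    diff_err <- (err_a - err_b) + 2 * delta_err
    null[(done + 1):(done + m)] <- as.numeric(crossprod(w, diff_err))
    done <- done + m
  }
  p <- (1 + sum(abs(null) >= abs(observed))) / (1 + n_perm)
  structure(
    list(observed = observed, slope_a = slope_a, slope_b = slope_b,
         error_a = err_a, error_b = err_b, levels = levels_ord,
         null = null, p_value = p, n_perm = as.integer(n_perm)),
    class = "blt_slope_test"
  )
}

#' @export
print.blt_slope_test <- function(x, ...) {
  cat(sprintf(
    "<slope permutation test> slopes %.4f vs %.4f, diff %.4f, p = %.4g (%d permutations)\n",
    x$slope_a, x$slope_b, x$observed, x$p_value, x$n_perm
  ))
  invisible(x)
}

#' @method tidy blt_slope_test
#' @export
tidy.blt_slope_test <- function(x, ...) {
  tibble::tibble(slope_a = x$slope_a, slope_b = x$slope_b,
                 estimate = x$observed, p.value = x$p_value,
                 n_perm = x$n_perm)
}

#' @method autoplot blt_slope_test
#' @export
autoplot.blt_slope_test <- function(object, ...) {
  df <- tibble::tibble(null = object$null)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick") +
    ggplot2::labs(
      x = "null slope difference",
      y = "permutations",
      title = sprintf("Observed slope difference %.4f (p = %.3g)",
                      object$observed, object$p_value)
    )
}

#' All pairwise McNemar comparisons within one image set, FDR-controlled
#'
#' Runs McNemar's test (cluster-adjusted when `per_digit = TRUE`) for every
#' pair of models evaluated on the same image set and controls the false
#' discovery rate at `q` across the family with the Benjamini-Hochberg
#' procedure.
#'
#' @param evals named list of `blt_eval` objects over one image set.
#' @param per_digit use per-digit records with images as clusters.
#' @param q FDR level.
#' @return A tibble with one row per pair: `model_a`, `model_b`, `statistic`,
#'   `p.value`, `significant`.
#' @export
pairwise_model_tests <- function(evals, per_digit = FALSE, q = 0.05) {
  stopifnot(length(evals) >= 2, !is.null(names(evals)))
  pairs <- utils::combn(names(evals), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    tab <- prediction_table(evals[[a]], evals[[b]], per_digit = per_digit)
    res <- if (per_digit) {
      clustered_mcnemar(tab)
    } else {
      mcnemar(tab$correct_a, tab$correct_b)
    }
    tibble::tibble(model_a = a, model_b = b,
                   statistic = res$statistic, p.value = res$p_value)
  })
  out <- dplyr::bind_rows(rows)
  out$significant <- bh_fdr(out$p.value, q)$reject
  out
}
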