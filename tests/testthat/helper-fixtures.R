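# Small fixtures shared across the test files. Everything is generated in
# code; nothing is read from disk.

# A miniature recurrent spec that exercises every pathway cheaply.
tiny_spec <- function(lateral = TRUE, top_down = TRUE, features = 2L,
                      n_timesteps = 4L, input_side = 4L) {
  arch_spec(NULL, lateral = lateral, top_down = top_down,
            features = features, bu_kernel = 3L,
            n_timesteps = if (lateral || top_down) n_timesteps else 1L,
            input_side = input_side)
}

# Deterministic batch of random normalized images as an (npix x B) matrix.
random_images <- function(side, n, seed = 1) {
  set.seed(seed)
  matrix(rnorm(side^2 * n), side^2, n)
}

# Paired binary correctness vectors with prescribed discordant counts.
paired_correctness <- function(b, c, both_right = 20, both_wrong = 5) {
  a <- c(rep(1, both_right), rep(0, both_wrong), rep(1, b), rep(0, c))
  bb <- c(rep(1, both_right), rep(0, both_wrong), rep(0, b), rep(1, c))
  list(a = a, b = bb)
}

# A stacked per-image correctness table across difficulty levels for the
# slope permutation test, with per-level marginal accuracies p_a, p_b.
slope_table <- function(n_per_level, p_a, p_b, seed = 1) {
  set.seed(seed)
  K <- length(p_a)
  dplyr::bind_rows(lapply(seq_len(K), function(l) {
    tibble::tibble(
      image = seq_len(n_per_level),
      level = l,
      correct_a = rbinom(n_per_level, 1, p_a[l]),
      correct_b = rbinom(n_per_level, 1, p_b[l])
    )
  }))
}

# Exhaustive-enumeration oracle for the slope permutation test on tiny
# tables: iterates over all 2^n_images swap patterns, recomputing error
# rates and OLS slopes from scratch, and also asserts that every swap
# pattern conserves the pooled per-level performance.
exhaustive_slope_test <- function(table) {
  levels_ord <- sort(unique(table$level))
  slope_of <- function(correct) {
    err <- vapply(levels_ord, function(l) {
      1 - mean(correct[table$level == l])
    }, 0)
    fit_error_slope(err, seq_along(levels_ord))
  }
  observed <- slope_of(table$correct_a) - slope_of(table$correct_b)
  imgs <- unique(paste(table$level, table$image))
  key <- paste(table$level, table$image)
  n <- length(imgs)
  pooled0 <- table$correct_a + table$correct_b
  null <- numeric(2^n)
  for (m in seq_len(2^n) - 1) {
    flip <- as.logical(bitwAnd(m, 2^(seq_len(n) - 1)))
    swap <- flip[match(key, imgs)]
    a <- ifelse(swap, table$correct_b, table$correct_a)
    b <- ifelse(swap, table$correct_a, table$correct_b)
    stopifnot(all(a + b == pooled0)) # pooled performance is conserved
    null[m + 1] <- slope_of(a) - slope_of(b)
  }
  list(observed = observed,
       p = mean(abs(null) >= abs(observed)),
       null = null)
}
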