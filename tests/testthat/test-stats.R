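test_that("McNemar's test matches hand values and the base-R implementation", {
  # b = 15, c = 5: chi2 = (|15-5|-1)^2 / 20 = 81/20 = 4.05
  p15 <- paired_correctness(15, 5)
  r <- mcnemar(p15$a, p15$b)
  expect_equal(r$statistic, 4.05)
  # cross-check statistic and p against stats::mcnemar.test
  mt <- stats::mcnemar.test(table(p15$a, p15$b), correct = TRUE)
  expect_equal(r$statistic, unname(mt$statistic))
  expect_equal(r$p_value, mt$p.value)

  # b = 10, c = 0: chi2 = 81/10 = 8.1
  p10 <- paired_correctness(10, 0)
  expect_equal(mcnemar(p10$a, p10$b)$statistic, 8.1)

  # identical vectors: no discordance, p = 1
  same <- mcnemar(p15$a, p15$a)
  expect_equal(same$p_value, 1)

  # exact variant agrees with the binomial sign test
  ex <- mcnemar(p15$a, p15$b, exact = TRUE)
  expect_equal(ex$p_value, binom.test(15, 20, 0.5)$p.value)

  expect_error(mcnemar(1:3, 1:4), "equal length")
})

test_that("clustered McNemar reduces to the plain statistic for singleton clusters", {
  set.seed(8)
  for (i in 1:10) {
    n <- 60
    a <- rbinom(n, 1, 0.7)
    b <- rbinom(n, 1, 0.6)
    tab <- tibble::tibble(cluster = seq_len(n), correct_a = a, correct_b = b)
    got <- clustered_mcnemar(tab)
    bb <- sum(a == 1 & b == 0); cc <- sum(a == 0 & b == 1)
    if (bb + cc > 0) {
      # uncorrected McNemar (no continuity correction)
      expect_equal(got$statistic, (bb - cc)^2 / (bb + cc))
    } else {
      expect_equal(got$p_value, 1)
    }
  }
})

test_that("clustered McNemar is stable under within-cluster duplication", {
  set.seed(12)
  n <- 40
  tab <- tibble::tibble(cluster = rep(1:20, each = 2),
                        correct_a = rbinom(n, 1, 0.75),
                        correct_b = rbinom(n, 1, 0.55))
  base <- clustered_mcnemar(tab)
  doubled <- dplyr::bind_rows(tab, tab)
  dup <- clustered_mcnemar(doubled)
  # duplicating every cluster's rows leaves the adjusted statistic unchanged,
  # whereas the naive statistic would double
  expect_equal(dup$statistic, base$statistic)
  naive <- function(t) {
    b <- sum(t$correct_a == 1 & t$correct_b == 0)
    c <- sum(t$correct_a == 0 & t$correct_b == 1)
    (b - c)^2 / (b + c)
  }
  expect_equal(naive(doubled), 2 * naive(tab))

  # identical predictions: p = 1
  same <- tibble::tibble(cluster = 1:10, correct_a = rep(1, 10),
                         correct_b = rep(1, 10))
  expect_equal(clustered_mcnemar(same)$p_value, 1)
  expect_error(clustered_mcnemar(tab[0, ]), "empty")
})

test_that("BH FDR control matches the brute-force step-up rule", {
  # worked example: all four rejected (p_(4) = 0.04 <= 4/4 * 0.05)
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r$reject))
  expect_equal(r$threshold, 0.04)
  expect_false(any(bh_fdr(rep(1, 6))$reject))
  expect_true(bh_fdr(0.04, q = 0.05)$reject)

  brute <- function(p, q) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    k <- which(ps <= (seq_len(m) / m) * q)
    if (length(k) == 0) return(rep(FALSE, m))
    p <= ps[max(k)]
  }
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))^sample(1:3, 1)
    expect_identical(bh_fdr(p, 0.05)$reject, brute(p, 0.05))
  }
  expect_error(bh_fdr(c(0.5, 2)), "0, 1")
})

test_that("robustness slopes come from ordinary least squares", {
  expect_equal(fit_error_slope(c(0.10, 0.20, 0.30)), 0.10)
  expect_equal(fit_error_slope(c(0.2, 0.2, 0.2)), 0)
  # label reversal negates the slope
  e <- c(0.05, 0.22, 0.41)
  expect_equal(fit_error_slope(e, 3:1), -fit_error_slope(e, 1:3))
  # unequally spaced levels agree with lm()
  expect_equal(fit_error_slope(e, c(1, 2, 5)),
               unname(coef(lm(e ~ c(1, 2, 5)))[2]))
  expect_error(fit_error_slope(c(0.1, 0.2), c(2, 2)), "constant")
  expect_error(fit_error_slope(0.1), "two")
})

test_that("slope permutation test: identical models give p = 1", {
  tab <- slope_table(30, c(0.9, 0.7, 0.5), c(0.9, 0.7, 0.5), seed = 2)
  tab$correct_b <- tab$correct_a
  r <- slope_permutation_test(tab, n_perm = 200, seed = 3)
  expect_equal(r$observed, 0)
  expect_equal(r$p_value, 1)
  expect_length(r$null, 200)
})

test_that("Monte-Carlo permutation p agrees with exhaustive enumeration", {
  # 4 images per level at 2 levels: 2^8 = 256 swap patterns enumerable
  set.seed(6)
  tab <- tibble::tibble(
    image = rep(1:4, 2),
    level = rep(1:2, each = 4),
    correct_a = c(1, 1, 1, 0, 1, 1, 0, 0),
    correct_b = c(1, 0, 1, 1, 0, 0, 0, 1)
  )
  oracle <- exhaustive_slope_test(tab)
  mc <- slope_permutation_test(tab, n_perm = 4000, seed = 9)
  expect_equal(mc$observed, oracle$observed)
  # the MC estimate must sit inside the 99% binomial envelope of the exact p
  env <- qbinom(c(0.005, 0.995), 4000, oracle$p) / 4000
  raw_p <- (mc$p_value * (1 + 4000) - 1) / 4000 # undo the add-one rule
  expect_gte(raw_p, env[1])
  expect_lte(raw_p, env[2])
})

test_that("the permutation null is symmetric for exchangeable models", {
  tab <- slope_table(60, c(0.85, 0.7, 0.55), c(0.85, 0.7, 0.55), seed = 13)
  r <- slope_permutation_test(tab, n_perm = 2000, seed = 4)
  expect_lt(abs(mean(r$null)), 3 * sd(r$null) / sqrt(2000) + 1e-3)
  expect_error(slope_permutation_test(tab, n_perm = 0), "at least 1")
})

test_that("per-digit rows of one image swap as a unit", {
  # two records per image; flipping must keep them aligned, so a table whose
  # two models differ identically in every record of an image has a null
  # distribution identical to the per-image (collapsed) table's null
  set.seed(21)
  base <- slope_table(12, c(0.8, 0.5), c(0.95, 0.75), seed = 5)
  per_digit <- dplyr::bind_rows(base, base) |> dplyr::arrange(level, image)
  r1 <- slope_permutation_test(base, n_perm = 500, seed = 11)
  r2 <- slope_permutation_test(per_digit, n_perm = 500, seed = 11)
  expect_equal(r1$observed, r2$observed)
  expect_equal(r1$null, r2$null)
})
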