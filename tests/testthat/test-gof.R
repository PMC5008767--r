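test_that("K-S statistic matches a brute-force ECDF supremum", {
  brute_D <- function(a, b) {
    g <- sort(unique(c(a, b)))
    max(abs(vapply(g, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
  }
  expect_equal(ks_two_sample(c(1, 3), c(2, 4))$statistic, 0.5)
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$statistic, 1)
  set.seed(81)
  for (i in 1:10) {
    a <- stats::rnorm(30 + i); b <- stats::rt(40, df = 3)
    expect_equal(ks_two_sample(a, b)$statistic, brute_D(a, b),
                 tolerance = 1e-12)
  }
  ident <- stats::rnorm(20)
  r <- ks_two_sample(ident, ident)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(ks_two_sample(numeric(0), 1:3), "nonempty")
})

test_that("A-D statistic matches an independent loop implementation", {
  # direct double-loop evaluation of the midrank form
  brute_ad <- function(a, b) {
    N <- length(a) + length(b)
    Z <- sort(c(a, b)); Zstar <- unique(Z)
    A2 <- 0
    for (s in list(a, b)) {
      ni <- length(s)
      inner <- 0
      for (j in seq_along(Zstar)) {
        lj <- sum(Z == Zstar[j])
        fij <- sum(s == Zstar[j])
        Maij <- sum(s <= Zstar[j]) - fij / 2
        Bj <- sum(Z <= Zstar[j]) - lj / 2
        inner <- inner + lj / N * (N * Maij - Bj * ni)^2 /
          (Bj * (N - Bj) - N * lj / 4)
      }
      A2 <- A2 + inner / ni
    }
    A2 * (N - 1) / N
  }
  set.seed(82)
  a <- stats::rnorm(25); b <- stats::rnorm(35, 0.5)
  # recover the unstandardised A2 from the standardised statistic
  N <- 60; k <- 2
  H <- 1 / 25 + 1 / 35
  h <- sum(1 / seq_len(N - 1))
  i <- seq_len(N - 2)
  tailsum <- rev(cumsum(rev(1 / seq.int(2, N - 1))))
  g <- sum(tailsum / (N - i))
  aa <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * H
  bb <- (2 * g - 4) * k^2 + 8 * h * k + (2 * g - 14 * h - 4) * H - 8 * h + 4 * g - 6
  cc <- (6 * h + 2 * g - 2) * k^2 + (4 * h - 6 * g + 6) * k + (2 * h - 6) * H + 4 * h
  dd <- (2 * h + 6) * k^2 - 4 * h * k
  sig <- sqrt((aa * N^3 + bb * N^2 + cc * N + dd) / ((N - 1) * (N - 2) * (N - 3)))
  T_expected <- (brute_ad(a, b) - 1) / sig
  expect_equal(ad_two_sample(a, b)$statistic, T_expected, tolerance = 1e-10)
})

test_that("A-D behaves correctly under null and gross alternatives", {
  x <- stats::rnorm(30)
  r0 <- ad_two_sample(x, x)
  expect_lt(r0$statistic, 0)
  expect_gt(r0$p_value, 0.9)
  p <- stable_params(1.5, 0, 1, 0)
  a <- stable_sample(500, p, seed = 83)
  b <- stable_sample(500, p, seed = 84)
  expect_gt(ad_two_sample(a, b)$p_value, 0.05)
  heavy <- stable_sample(500, stable_params(1.2, 0, 1, 0), seed = 85)
  gauss <- local({ set.seed(86); stats::rnorm(500, 0, sqrt(2)) })
  expect_lt(ad_two_sample(heavy, gauss)$p_value, 0.05)
  expect_lt(ks_two_sample(heavy, gauss)$p_value, 0.05)
})

test_that("permutation p-values agree with asymptotic ones for moderate n", {
  a <- stats::rnorm(60); b <- stats::rnorm(60, 0.4)
  set.seed(87)
  ks_a <- ks_two_sample(a, b)$p_value
  ks_p <- ks_two_sample(a, b, exact_permutation = TRUE, n_perm = 1000,
                        seed = 88)$p_value
  expect_lt(abs(ks_a - ks_p), 0.1)
  ad_a <- ad_two_sample(a, b)$p_value
  ad_p <- ad_two_sample(a, b, exact_permutation = TRUE, n_perm = 1000,
                        seed = 89)$p_value
  expect_lt(abs(ad_a - ad_p), 0.1)
})

test_that("gof_assess accepts a well-specified fit and rejects a wrong one", {
  noise <- stable_params(1.5, 0, 1, 0)
  ts <- simulate_langevin(drift_model(0.4, 0), noise, 1e4, seed = 91)
  model <- fit_linear_drift(estimate_drift_curve(ts))
  rs <- extract_residuals(ts, model)
  fit <- estimate_stable_params(rs)
  g1 <- gof_assess(rs, fit, seed = 92)
  expect_false(g1$ks_reject); expect_false(g1$ad_reject)
  expect_identical(g1$n_model_draws, length(rs$xi))
  # deliberately wrong law: Gaussian against alpha = 1.2 residuals
  ts2 <- simulate_langevin(drift_model(0.4, 0), stable_params(1.2, 0, 1, 0),
                           5e3, seed = 93)
  rs2 <- extract_residuals(ts2, drift_model(0.4, 0))
  g2 <- gof_assess(rs2, stable_params(2, 0, 1, 0), seed = 94)
  expect_true(g2$ks_reject); expect_true(g2$ad_reject)
})

test_that("both tests hold their nominal size", {
  p <- stable_params(1.5, 0, 1, 0)
  pw <- mc_power(p, p, n = 500, reps = 1000, level = 0.05, seed = 95)
  expect_lte(abs(pw$power[pw$test == "ks"] - 0.05), 0.02)
  expect_lte(abs(pw$power[pw$test == "ad"] - 0.05), 0.02)
})

test_that("power grows with sample size and saturates for gross separation", {
  null_p <- stable_params(1.5, 0, 1, 0)
  alt_p <- stable_params(1.3, 0, 1, 0)
  pows <- vapply(c(200, 500, 1000), function(n)
    mc_power(null_p, alt_p, n = n, reps = 500, seed = 96)$power,
    numeric(2))
  # non-decreasing up to twice the binomial Monte Carlo standard error
  mc_se <- 2 * sqrt(0.1 * 0.9 / 500)
  expect_true(all(diff(pows[1, ]) >= -mc_se))  # ks
  expect_true(all(diff(pows[2, ]) >= -mc_se))  # ad
  expect_gt(pows[1, 3], pows[1, 1] - mc_se)
  expect_gt(pows[2, 3], pows[2, 1])
  gross <- mc_power(stable_params(2, 0, 1, 0), stable_params(1, 0, 1, 0),
                    n = 1000, reps = 200, seed = 97)
  expect_gte(min(gross$power), 0.99)
})

test_that("A-D is at least as powerful as K-S for tail-weighted alternatives", {
  # same alpha, different skew: the discrepancy lives in one tail
  null_p <- stable_params(1.5, 0, 1, 0)
  alt_p <- stable_params(1.5, 0.8, 1, 0)
  pw <- mc_power(null_p, alt_p, n = 500, reps = 500, seed = 98)
  expect_gte(pw$power[pw$test == "ad"], pw$power[pw$test == "ks"] - 0.02)
  expect_error(mc_power(null_p, alt_p, reps = 50), "at least 100")
})
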