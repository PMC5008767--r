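test_that("pdf and ccdf match the analytic special cases", {
  expect_equal(stable_pdf(0, std_cauchy), 1 / pi, tolerance = 1e-10)
  expect_equal(stable_pdf(0, std_gauss), 1 / (2 * sqrt(pi)),
               tolerance = 1e-10)
  expect_equal(stable_ccdf(1, std_cauchy), 0.25, tolerance = 1e-10)
  # symmetric law: survival at the location is 1/2
  for (a in c(0.6, 1, 1.3, 1.7, 2)) {
    p <- stable_params(a, 0, 1.5, 0.8)
    expect_equal(stable_ccdf(0.8, p), 0.5, tolerance = 1e-7)
  }
  # Levy special case against its closed form
  expect_equal(stable_cdf(1, std_levy), 2 * stats::pnorm(-1),
               tolerance = 1e-12)
})

test_that("numeric inversion agrees with closed forms where both paths exist", {
  # evaluate the Cauchy and Gaussian laws through the generic quadrature
  # path by perturbing alpha infinitesimally away from the special values
  x <- c(-5, -1, 0, 0.5, 2, 8)
  near_gauss <- stable_params(2 - 1e-9, 0, 1, 0)
  expect_equal(stable_pdf(x, near_gauss), stats::dnorm(x, 0, sqrt(2)),
               tolerance = 1e-6)
  expect_equal(stable_cdf(x, near_gauss), stats::pnorm(x, 0, sqrt(2)),
               tolerance = 1e-6)
  near_cauchy <- stable_params(1 + 2e-3, 0, 1, 0)
  expect_equal(stable_cdf(x, near_cauchy), stats::pcauchy(x),
               tolerance = 5e-3)
})

test_that("the density integrates to 1 across the parameter grid", {
  xs <- c(seq(-50, -10, by = 0.5), seq(-10, 10, by = 0.1),
          seq(10, 50, by = 0.5))
  xs <- sort(unique(xs))
  for (i in seq_len(nrow(param_grid))) {
    p <- stable_params(param_grid$alpha[i], param_grid$beta[i], 1, 0)
    f <- stable_pdf(xs, p)
    trap <- sum(diff(xs) * (utils::head(f, -1) + utils::tail(f, -1)) / 2)
    total <- trap + stable_ccdf(50, p) + stable_cdf(-50, p)
    expect_equal(total, 1, tolerance = 1e-3,
                 label = sprintf("mass at alpha=%g beta=%g",
                                 p$alpha, p$beta))
  }
})

test_that("ccdf is monotone and follows the x^-alpha tail law", {
  p <- stable_params(1.5, 0, 1, 0)
  x <- c(0.5, 1, 2, 5, 10, 20, 40, 80, 160)
  cc <- stable_ccdf(x, p)
  expect_true(all(diff(cc) < 0))
  expect_true(all(cc >= 0 & cc <= 1))
  # doubling x far in the tail multiplies the survival by 2^-alpha
  for (x0 in c(50, 100))
    expect_equal(stable_ccdf(2 * x0, p) / stable_ccdf(x0, p), 2^-1.5,
                 tolerance = 1e-3)
})

test_that("samples agree with the distribution function across the grid", {
  # one-sample Kolmogorov check at level 0.01 (critical value 1.628/sqrt(n))
  n <- 500
  for (i in seq_len(nrow(param_grid))) {
    p <- stable_params(param_grid$alpha[i], param_grid$beta[i], 1, 0)
    x <- sort(stable_sample(n, p, seed = 6000 + i))
    D <- ks_stat_vs_cdf(x, stable_cdf(x, p))
    expect_lt(D, 1.628 / sqrt(n))
  }
})
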