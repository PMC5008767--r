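test_that("residual extraction inverts the discrete Langevin identity", {
  dm <- drift_model(0.4, 1)
  # noise-free: residuals are identically zero
  ts <- simulate_langevin(dm, NULL, 100, x0 = 7, burn_in = 0)
  expect_equal(extract_residuals(ts, dm)$xi, rep(0, 99), tolerance = 1e-12)
  # with the true model, residuals equal the injected draws exactly
  noise <- stable_params(1.3, 0, 1, 0)
  ts2 <- simulate_langevin(dm, noise, 500, x0 = 0, seed = 5, burn_in = 0)
  rs <- extract_residuals(ts2, dm)
  expect_length(rs$xi, 499)
  expect_identical(rs$magnitudes, abs(rs$xi))
  v <- ts2$values
  expect_equal(rs$xi, diff(v) + 0.4 * (v[-500] - 1), tolerance = 1e-12)
})

test_that("residuals recovered with a fitted drift match the injected law", {
  noise <- stable_params(1.5, 0, 1, 0)
  ts <- simulate_langevin(drift_model(0.5, 2), noise, 1e4, seed = 61)
  model <- fit_linear_drift(estimate_drift_curve(ts))
  xi <- extract_residuals(ts, model)
  fresh <- stable_sample(length(xi$xi), noise, seed = 62)
  expect_gt(ks_two_sample(xi$xi, fresh)$p_value, 0.05)
})

test_that("empirical survival follows the i/n convention with ties sharing the higher value", {
  sc <- empirical_ccdf(c(1, 2, 3, 4))
  expect_equal(sc$magnitudes, 1:4)
  expect_equal(sc$survival, c(1, 0.75, 0.5, 0.25))
  # all-equal input: a single step at survival 1
  sc2 <- empirical_ccdf(rep(2, 5))
  expect_equal(unique(sc2$survival), 1)
  sc3 <- empirical_ccdf(c(1, 2, 2, 3))
  expect_equal(sc3$survival, c(1, 0.75, 0.75, 0.25))
  expect_true(all(sc3$survival > 0))
  expect_error(empirical_ccdf(c(-1, 2)), "non-negative")
  expect_error(empirical_ccdf(numeric(0)), "empty")
})

test_that("tail slope is exact on an exact power-law grid", {
  # construct magnitudes whose empirical survival is exactly m^-1.5
  n <- 1000
  m <- ((n:1) / n)^(-1 / 1.5)
  tf <- tail_slope(empirical_ccdf(m), tail_fraction = 0.2)
  expect_equal(tf$alpha_tail, 1.5, tolerance = 1e-9)
  expect_equal(tf$alpha_hill, 1.5, tolerance = 0.1)
  expect_gt(tf$r_squared, 0.999)
  expect_true(tf$power_law_ok)
})

test_that("tail slope estimates alpha for stable magnitudes", {
  x <- stable_sample(1e5, stable_params(1.3, 0, 1, 0), seed = 71)
  tf <- tail_slope(empirical_ccdf(abs(x)), tail_fraction = 0.1)
  expect_equal(tf$alpha_tail, 1.3, tolerance = 0.15)
  expect_equal(tf$alpha_hill, 1.3, tolerance = 0.2)
  # rescaling the magnitudes does not move the tail exponent
  tf2 <- tail_slope(empirical_ccdf(abs(37 * x)), tail_fraction = 0.1)
  expect_equal(tf2$alpha_tail, tf$alpha_tail, tolerance = 1e-9)
})

test_that("a Gaussian tail is flagged as inconsistent with a power law", {
  x <- local({ set.seed(72); stats::rnorm(1e5) })
  tf <- tail_slope(empirical_ccdf(abs(x)), tail_fraction = 0.1)
  expect_gt(tf$alpha_tail, 2)
  expect_false(tf$power_law_ok)
})

test_that("tail fitting refuses too-small tails", {
  expect_error(tail_slope(empirical_ccdf(1:100), tail_fraction = 0.1),
               "tail points")
  expect_error(tail_slope(empirical_ccdf(1:100), tail_fraction = 0.7),
               "tail_fraction")
})

test_that("pooled residual sets keep labels and magnitudes aligned", {
  r1 <- residual_set(c(-1, 2), subject_id = "a", network_id = "n")
  r2 <- residual_set(c(3), subject_id = "b", network_id = "n")
  rp <- pool_residuals(list(r1, r2))
  expect_equal(rp$xi, c(-1, 2, 3))
  expect_equal(rp$magnitudes, c(1, 2, 3))
  expect_equal(rp$subject_id, c("a", "a", "b"))
})

test_that("survival curves export as two-column CSV", {
  path <- file.path(tempdir(), "surv.csv")
  write_survival_csv(empirical_ccdf(c(1, 2, 3)), path)
  df <- utils::read.csv(path)
  expect_identical(names(df), c("magnitude", "survival"))
  expect_equal(df$survival, c(1, 2 / 3, 1 / 3))
  unlink(path)
})
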