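test_that("a noise-free linear map is recovered exactly", {
  # pairs (x, -0.5 x) exactly on the line g(x) = -0.5 x
  xs <- seq(-5, 5, length.out = 400)
  sers <- lapply(xs, function(x) time_series(c(x, 0.5 * x)))
  curve <- estimate_drift_curve(sers, n_bins = 10, min_count = 5,
                                trim = c(0, 1))
  expect_equal(curve$conditional_means, -0.5 * curve$bin_centers,
               tolerance = 1e-12)
  model <- fit_linear_drift(curve)
  expect_equal(model$k, 0.5, tolerance = 1e-10)
  expect_equal(model$x_star, 0, tolerance = 1e-10)
  expect_false(model$non_relaxing)
  expect_equal(model$tau, 2, tolerance = 1e-9)
})

test_that("an i.i.d. sequence yields unit relaxation (slope -1)", {
  # x(t) = xi(t) independent: E[x(t+1) | x(t)] = 0, so E[dx | x] = -x
  ts <- time_series(local({ set.seed(12); stats::rnorm(2e4) }))
  model <- fit_linear_drift(estimate_drift_curve(ts))
  expect_equal(model$k, 1, tolerance = 0.05)
  expect_equal(model$x_star, 0, tolerance = 0.05)
})

test_that("drift parameters are recovered from a noisy simulation", {
  dm <- drift_model(0.5, 2)
  ts <- simulate_langevin(dm, std_gauss, 1e5, seed = 21)
  model <- fit_linear_drift(estimate_drift_curve(ts))
  expect_equal(model$k, 0.5, tolerance = 0.05)
  expect_equal(model$x_star, 2, tolerance = 0.2)
  expect_gt(model$r_squared, 0.9)
})

test_that("median-aggregated bins recover the drift under heavy-tailed noise", {
  dm <- drift_model(0.5, 2)
  ts <- simulate_langevin(dm, stable_params(1.1, 0, 1, 0), 1e5, seed = 22)
  model <- fit_linear_drift(estimate_drift_curve(ts, aggregator = "median"))
  expect_equal(model$k, 0.5, tolerance = 0.05)
  expect_equal(model$x_star, 2, tolerance = 0.2)
})

test_that("drift recovery is equivariant under affine rescaling of activity", {
  ts <- simulate_langevin(drift_model(0.4, 1), std_gauss, 2e4, seed = 23)
  m1 <- fit_linear_drift(estimate_drift_curve(ts))
  ts2 <- time_series(3 * ts$values - 5, dt = ts$dt)
  m2 <- fit_linear_drift(estimate_drift_curve(ts2))
  expect_equal(m2$k, m1$k, tolerance = 1e-8)
  expect_equal(m2$x_star, 3 * m1$x_star - 5, tolerance = 1e-6)
})

test_that("recovery error of the relaxation rate shrinks with series length", {
  rmse <- vapply(c(1e3, 1e4, 1e5), function(n) {
    errs <- vapply(1:20, function(s) {
      ts <- simulate_langevin(drift_model(0.5, 2), std_gauss, n,
                              seed = 900 + s)
      fit_linear_drift(estimate_drift_curve(ts))$k - 0.5
    }, numeric(1))
    sqrt(mean(errs^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("degenerate drift curves are flagged, not fatal", {
  flat <- structure(list(bin_centers = 1:5,
                         conditional_means = rep(0, 5),
                         bin_counts = rep(10L, 5), aggregator = "mean"),
                    class = "drift_curve")
  model <- fit_linear_drift(flat)
  expect_equal(model$k, 0)
  expect_true(model$non_relaxing)
  expect_equal(model$x_star, 3)  # falls back to the weighted mean state
  expect_error(estimate_drift_curve(time_series(c(1, 2)), n_bins = 10,
                                    min_count = 20),
               "bin")
})

test_that("the deterministic solution evaluates the exponential decay", {
  dm <- drift_model(0.5, 2)
  expect_equal(deterministic_solution(dm, 10, 0), 10)
  expect_equal(deterministic_solution(dm, 10, 1e6), 2)
  expect_equal(deterministic_solution(dm, 10, 2), 2 + 8 * exp(-1),
               tolerance = 1e-12)
  expect_error(deterministic_solution(drift_model(0, 1), 5, 1), "k > 0")
})
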