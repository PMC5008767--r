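test_that("noise-free simulation follows the discrete relaxation exactly", {
  # k = 0 and no noise: constant trajectory
  ts <- simulate_langevin(drift_model(0, 5), NULL, 10, x0 = 5, burn_in = 0)
  expect_equal(ts$values, rep(5, 10))
  # general (k, x*, x0): x(t) = x* + (x0 - x*) (1 - k)^t, the discrete
  # analogue of the exponential relaxation with tau ~ 1/k
  for (case in list(c(0.5, 0, 10), c(0.3, 2, -4), c(0.05, 1, 8))) {
    k <- case[1]; xs <- case[2]; x0 <- case[3]
    ts <- simulate_langevin(drift_model(k, xs), NULL, 50, x0 = x0,
                            burn_in = 0)
    expect_equal(ts$values, xs + (x0 - xs) * (1 - k)^(0:49),
                 tolerance = 1e-12)
  }
  # for small k the discrete decay matches the continuous exp(-t/tau) form
  ts <- simulate_langevin(drift_model(0.05, 1), NULL, 21, x0 = 8,
                          burn_in = 0)
  expect_equal(ts$values,
               deterministic_solution(drift_model(0.05, 1), 8, 0:20),
               tolerance = 0.03)
})

test_that("the recursive-filter integrator matches an explicit loop", {
  dm <- drift_model(0.4, 1.5)
  noise <- stable_params(1.5, 0.3, 0.8, 0)
  ts <- simulate_langevin(dm, noise, 200, x0 = 2, seed = 77, burn_in = 0)
  n0 <- as_s0(noise)
  xi <- levyflux:::local_seed(77, {
    stable_sample(200, stable_params(n0$alpha, n0$beta, n0$gamma, 0,
                                     parameterization = "S0"))
  })
  x <- numeric(200); x[1] <- 2
  for (t in 2:200) x[t] <- x[t - 1] - 0.4 * (x[t - 1] - 1.5) + xi[t - 1]
  expect_equal(ts$values, x, tolerance = 1e-12)
})

test_that("simulated increments minus drift reproduce the injected stable law", {
  dm <- drift_model(0.5, 2)
  noise <- stable_params(1.5, 0, 1, 0)
  ts <- simulate_langevin(dm, noise, 1e4, seed = 31)
  xi <- extract_residuals(ts, dm)$xi
  fresh <- stable_sample(1e4, noise, seed = 32)
  expect_gt(ks_two_sample(xi, fresh)$p_value, 0.01)
})

test_that("the Gaussian-noise trajectory time-averages to its equilibrium", {
  ts <- simulate_langevin(drift_model(0.5, 2), stable_params(2, 0, 1, 0),
                          1e5, seed = 33)
  expect_equal(mean(ts$values), 2, tolerance = 0.02 * 2)
})

test_that("unstable drift rates are warned about", {
  expect_warning(simulate_langevin(drift_model(2.5, 0), NULL, 10, x0 = 1),
                 "oscillatory")
})

test_that("cohorts have one series per subject-network cell and are reproducible", {
  fix <- make_cohort(c(1.3, 1.7), n_subjects = 2, n_timepoints = 50)
  expect_length(fix$cohort, 4)
  ids <- vapply(fix$cohort, function(ts)
    paste(ts$subject_id, ts$network_id), "")
  expect_identical(anyDuplicated(ids), 0L)
  # all series distinct
  expect_gt(min(stats::dist(do.call(rbind, lapply(fix$cohort,
                                                  `[[`, "values")))), 0)
  again <- generate_cohort(fix$spec, seed = 1)
  expect_identical(fix$cohort, again)
  other <- generate_cohort(fix$spec, seed = 2)
  expect_false(identical(fix$cohort, other))
})

test_that("duplicate network ids are rejected", {
  dm <- drift_model(0.3, 0); no <- stable_params(1.5, 0, 1, 0)
  expect_error(cohort_spec(list(
    list(network_id = "a", drift = dm, noise = no),
    list(network_id = "a", drift = dm, noise = no)), 2, 100),
    "duplicate")
})

test_that("pooled residual tails get lighter as alpha rises", {
  # excess kurtosis of the injected noise decreases with alpha
  kurt <- vapply(c(1.1, 1.5, 2.0), function(a) {
    spec <- cohort_spec(list(list(network_id = "n", drift = drift_model(0.3, 0),
                                  noise = stable_params(a, 0, 1, 0))),
                        n_subjects = 12, n_timepoints = 850)
    cohort <- generate_cohort(spec, seed = 8)
    xi <- unlist(lapply(cohort, function(ts)
      extract_residuals(ts, drift_model(0.3, 0))$xi))
    mean((xi - mean(xi))^4) / stats::var(xi)^2
  }, numeric(1))
  expect_true(all(diff(kurt) < 0))
})

test_that("cohort CSV round-trips through the reader with truth sidecar", {
  fix <- make_cohort(c(1.4), n_subjects = 2, n_timepoints = 60)
  path <- file.path(tempdir(), "cohort.csv")
  write_cohort_csv(fix$cohort, path, spec = fix$spec)
  truth <- yaml::read_yaml(paste0(path, ".truth.yaml"))
  expect_equal(truth$networks[[1]]$alpha, 1.4)
  back <- read_series_table(path)
  expect_length(back, 2)
  orig <- fix$cohort[[1]]
  match_back <- Filter(function(ts) ts$subject_id == orig$subject_id, back)[[1]]
  expect_equal(match_back$values, orig$values, tolerance = 1e-10)
  unlink(c(path, paste0(path, ".truth.yaml")))
})
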