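# shared fixtures: small parameter sets and simulated cohorts built in code

std_gauss <- stable_params(2, 0, 1, 0)
std_cauchy <- stable_params(1, 0, 1, 0)
std_levy <- stable_params(0.5, 1, 1, 0)

# grid used for the distribution-level property checks
param_grid <- expand.grid(alpha = c(0.6, 1.0, 1.3, 1.7, 2.0),
                          beta = c(-0.5, 0, 1))

make_cohort <- function(alphas, k = 0.3, n_subjects = 10, n_timepoints = 850,
                        seed = 1) {
  spec <- cohort_spec(lapply(seq_along(alphas), function(i)
    list(network_id = sprintf("net%d", i),
         drift = drift_model(k, x_star = i),
         noise = stable_params(alphas[i], 0, 1, 0))),
    n_subjects = n_subjects, n_timepoints = n_timepoints)
  list(spec = spec, cohort = generate_cohort(spec, seed = seed))
}

# one-sample Kolmogorov statistic against an exact CDF evaluated pointwise
ks_stat_vs_cdf <- function(x, cdf_vals_sorted) {
  n <- length(x)
  i <- seq_len(n)
  max(pmax(abs(i / n - cdf_vals_sorted), abs((i - 1) / n - cdf_vals_sorted)))
}
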