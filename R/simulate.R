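#' Activity time series
#'
#' One subject-by-network activity trace with its sampling interval.
#'
#' @param values numeric vector of activity readings (length at least 2,
#'   all finite).
#' @param dt sampling interval in seconds (default 2, a typical fMRI TR).
#' @param subject_id,network_id labels.
#' @return An object of class `time_series`.
#' @export
time_series <- function(values, dt = 2, subject_id = "s1", network_id = "n1") {
  values <- as.numeric(values)
  if (length(values) < 2) stop("a time series needs at least 2 samples")
  if (any(!is.finite(values))) stop("activity values must be finite")
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be positive")
  structure(list(values = values, dt = dt,
                 subject_id = as.character(subject_id),
                 network_id = as.character(network_id)),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("time_series: subject %s, network %s, %d samples, dt = %g s\n",
              x$subject_id, x$network_id, length(x$values), x$dt))
  invisible(x)
}

#' Simulate a Langevin trajectory with alpha-stable noise
#'
#' Integrates the discrete (Euler-Maruyama, unit-step) Langevin equation
#' `x(t+1) = x(t) + g(x(t)) + xi(t)` with linear relaxation drift
#' `g(x) = -k (x - x*)` and i.i.d. alpha-stable increments. The noise is
#' re-centred so that its S0 location is zero (for `alpha <= 1` the mean
#' does not exist, so median-type centring keeps the drift identifiable
#' across the whole stable range); `gamma` and the shape parameters of
#' `noise` are used as given.
#'
#' @param drift a [drift_model] (fields `k`, `x_star`).
#' @param noise a [stable_params] object, or `NULL` for the noise-free
#'   (zero-scale) limit.
#' @param n_steps number of retained samples (at least 1).
#' @param x0 initial activity. Default: `x_star` plus one noise draw
#'   (near-stationary start); `x_star` when noise is `NULL`.
#' @param seed optional integer seed for reproducibility.
#' @param burn_in steps discarded before recording (default 100; 0 makes
#'   the first retained value equal `x0`).
#' @param dt,subject_id,network_id metadata passed to [time_series()].
#' @return A [time_series] of length `n_steps`.
#' @details The linear recurrence `x(t+1) = (1-k) x(t) + k x* + xi(t)` is
#'   evaluated with a recursive linear filter, so long trajectories are
#'   cheap. `k >= 2` makes the deterministic map oscillatory/divergent and
#'   triggers a warning.
#' @examples
#' dm <- drift_model(k = 0.3, x_star = 2)
#' ts <- simulate_langevin(dm, stable_params(1.5, 0, 1, 0), 500, seed = 1)
#' @export
simulate_langevin <- function(drift, noise, n_steps, x0 = NULL, seed = NULL,
                              burn_in = 100, dt = 2,
                              subject_id = "sim", network_id = "sim") {
  stopifnot(inherits(drift, "drift_model"))
  if (length(n_steps) != 1L || is.na(n_steps) || n_steps < 1)
    stop("'n_steps' must be at least 1")
  n_steps <- as.integer(n_steps); burn_in <- as.integer(burn_in)
  k <- drift$k; xs <- drift$x_star
  if (k >= 2)
    warning("k >= 2: the unit-step linear map is oscillatory/divergent")
  if (!is.null(noise)) {
    .check_params(noise)
    p0 <- as_s0(noise)
    noise <- stable_params(p0$alpha, p0$beta, p0$gamma, 0,
                           parameterization = "S0")
  }
  local_seed(seed, {
    ntot <- burn_in + n_steps
    xi <- if (is.null(noise)) numeric(ntot) else stable_sample(ntot, noise)
    if (is.null(x0)) x0 <- xs + if (is.null(noise)) 0 else xi[ntot]
    # x_t = (1-k) x_{t-1} + k x* + xi_{t-1}; first retained value after
    # burn_in is the state reached by `burn_in` updates from x0
    upd <- k * xs + c(xi[seq_len(ntot - 1)])
    states <- c(x0, stats::filter(upd, 1 - k, method = "recursive",
                                  init = x0))
    time_series(states[(burn_in + 1):ntot], dt = dt,
                subject_id = subject_id, network_id = network_id)
  })
}

#' Specification of a synthetic multi-subject cohort
#'
#' Ground-truth description of a simulated study: a set of networks, each
#' with its own drift and stable-noise parameters, observed in
#' `n_subjects` subjects for `n_timepoints` samples.
#'
#' @param networks list; each element a list with fields `network_id`,
#'   `drift` (a [drift_model]) and `noise` (a [stable_params]).
#' @param n_subjects number of subjects (at least 1; the emulated study
#'   acquired 25).
#' @param n_timepoints samples per series (at least 10; the emulated runs
#'   had 850 and 450 volumes).
#' @param dt sampling interval in seconds (default 2).
#' @param burn_in burn-in steps passed to [simulate_langevin()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(networks, n_subjects = 25, n_timepoints = 850,
                        dt = 2, burn_in = 100) {
  if (n_subjects < 1) stop("'n_subjects' must be at least 1")
  if (n_timepoints < 10) stop("'n_timepoints' must be at least 10")
  ids <- vapply(networks, function(nw) as.character(nw$network_id), "")
  if (anyDuplicated(ids)) stop("duplicate network ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (nw in networks) {
    stopifnot(inherits(nw$drift, "drift_model"))
    .check_params(nw$noise)
  }
  structure(list(networks = networks, n_subjects = as.integer(n_subjects),
                 n_timepoints = as.integer(n_timepoints), dt = dt,
                 burn_in = as.integer(burn_in)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Simulates `n_subjects x n_networks` independent Langevin trajectories,
#' one per (subject, network), each with a sub-seed derived
#' deterministically from `(seed, subject, network)` so the cohort is
#' reproducible and any single series can be regenerated in isolation.
#'
#' @param spec a [cohort_spec].
#' @param seed integer seed for the whole cohort.
#' @return A list of [time_series], subjects varying fastest.
#' @examples
#' spec <- cohort_spec(list(
#'   list(network_id = "a", drift = drift_model(0.3, 0),
#'        noise = stable_params(1.5, 0, 1, 0))),
#'   n_subjects = 2, n_timepoints = 100)
#' cohort <- generate_cohort(spec, seed = 1)
#' @export
generate_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- list()
  for (nw in spec$networks) {
    for (s in seq_len(spec$n_subjects)) {
      sid <- sprintf("s%02d", s)
      out[[length(out) + 1L]] <- simulate_langevin(
        nw$drift, nw$noise, spec$n_timepoints,
        seed = derive_seed(seed, sid, nw$network_id),
        burn_in = spec$burn_in, dt = spec$dt,
        subject_id = sid, network_id = as.character(nw$network_id))
    }
  }
  out
}

#' Write a cohort as long-format CSV (plus optional ground-truth sidecar)
#'
#' Columns: `subject`, `network`, `t` (sample index, 1-based), `x`. When a
#' [cohort_spec] is supplied its true parameters are written next to the
#' CSV as a YAML sidecar (`<path>.truth.yaml`).
#'
#' @param cohort list of [time_series].
#' @param path output CSV path.
#' @param spec optional [cohort_spec] with the ground truth.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, spec = NULL) {
  df <- do.call(rbind, lapply(cohort, function(ts)
    data.frame(subject = ts$subject_id, network = ts$network_id,
               t = seq_along(ts$values), x = ts$values)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(spec)) {
    truth <- list(
      dt = spec$dt, n_subjects = spec$n_subjects,
      n_timepoints = spec$n_timepoints,
      networks = lapply(spec$networks, function(nw) list(
        network_id = as.character(nw$network_id),
        k = nw$drift$k, x_star = nw$drift$x_star,
        alpha = nw$noise$alpha, beta = nw$noise$beta,
        gamma = nw$noise$gamma, delta = nw$noise$delta,
        parameterization = nw$noise$parameterization)))
    yaml::write_yaml(truth, paste0(path, ".truth.yaml"))
  }
  invisible(path)
}
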