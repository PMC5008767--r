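#' Extract stochastic residuals from a series given its drift model
#'
#' Inverts the discrete Langevin equation: once the drift is known, the
#' noise realisations are `xi(t) = dx(t) - g(x(t)) = dx(t) + k (x(t) - x*)`
#' for `t = 1 .. n-1` (one fewer residual than samples).
#'
#' @param series a [time_series] (or numeric vector).
#' @param model a [drift_model] fitted on compatible data.
#' @return An object of class `residual_set`: signed residuals `xi`, their
#'   `magnitudes`, and source labels.
#' @export
extract_residuals <- function(series, model) {
  stopifnot(inherits(model, "drift_model"))
  if (is.numeric(series)) series <- time_series(series)
  stopifnot(inherits(series, "time_series"))
  v <- series$values
  if (length(v) < 2) stop("series shorter than 2 samples")
  x <- v[-length(v)]
  xi <- diff(v) - drift_g(model, x)
  residual_set(xi, subject_id = series$subject_id,
               network_id = series$network_id)
}

#' @rdname extract_residuals
#' @param xi signed residuals.
#' @param subject_id,network_id source labels (recycled to `length(xi)`).
#' @export
residual_set <- function(xi, subject_id = "s1", network_id = "n1") {
  xi <- as.numeric(xi)
  if (any(!is.finite(xi))) stop("residuals must be finite")
  structure(list(xi = xi, magnitudes = abs(xi),
                 subject_id = rep_len(as.character(subject_id), length(xi)),
                 network_id = rep_len(as.character(network_id), length(xi))),
            class = "residual_set")
}

#' Pool residual sets (e.g. all subjects of one network)
#' @param ... [residual_set] objects or a single list of them.
#' @return A combined [residual_set].
#' @export
pool_residuals <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "residual_set"))
    sets <- sets[[1]]
  residual_set(unlist(lapply(sets, `[[`, "xi")),
               subject_id = unlist(lapply(sets, `[[`, "subject_id")),
               network_id = unlist(lapply(sets, `[[`, "network_id")))
}

#' @export
print.residual_set <- function(x, ...) {
  cat(sprintf("residual_set: %d residuals from %d subject(s), %d network(s)\n",
              length(x$xi), length(unique(x$subject_id)),
              length(unique(x$network_id))))
  invisible(x)
}

#' Empirical survival function of residual magnitudes
#'
#' Complementary CDF on the observed points: the i-th largest magnitude
#' gets survival `i/n`, so the smallest magnitude has survival 1 and every
#' value is strictly positive (log-log plots of the tail are always
#' defined). Tied magnitudes share the higher survival value.
#'
#' @param magnitudes non-negative numeric vector (a `residual_set` is also
#'   accepted; its `magnitudes` field is used).
#' @return An object of class `survival_curve`: `magnitudes` (sorted
#'   increasing) and `survival`.
#' @examples
#' empirical_ccdf(c(1, 2, 3, 4))$survival  # 1, 0.75, 0.5, 0.25
#' @export
empirical_ccdf <- function(magnitudes) {
  if (inherits(magnitudes, "residual_set")) magnitudes <- magnitudes$magnitudes
  m <- as.numeric(magnitudes)
  if (length(m) == 0) stop("empty magnitude vector")
  if (any(!is.finite(m)) || any(m < 0))
    stop("magnitudes must be finite and non-negative")
  n <- length(m)
  ms <- sort(m)
  surv <- (n - seq_len(n) + 1) / n
  # ties share the higher (first-in-group) survival value
  surv <- stats::ave(surv, match(ms, ms), FUN = max)
  structure(list(magnitudes = ms, survival = surv),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("survival_curve: %d points, magnitude range [%.4g, %.4g]\n",
              length(x$magnitudes), min(x$magnitudes), max(x$magnitudes)))
  invisible(x)
}

#' Write a survival curve as a two-column CSV (magnitude, survival)
#' @param curve a [survival_curve].
#' @param path output path.
#' @export
write_survival_csv <- function(curve, path) {
  stopifnot(inherits(curve, "survival_curve"))
  utils::write.csv(data.frame(magnitude = curve$magnitudes,
                              survival = curve$survival),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tail exponent of the survival function
#'
#' For an alpha-stable law the log survival function of the magnitudes has
#' a linear upper tail with slope `-alpha`. This fits an ordinary least
#' squares line to `log(survival)` versus `log(magnitude)` over the top
#' `tail_fraction` of magnitudes and reports `alpha_tail = -slope`,
#' together with a Hill maximum-likelihood estimate on the same tail as a
#' cross-check and simple linearity diagnostics. An estimate above 2, or a
#' visibly curved tail, is flagged as inconsistent with a power law (a
#' Gaussian tail, for instance, steepens without bound).
#'
#' @param curve a [survival_curve] (or a `residual_set`, converted via
#'   [empirical_ccdf()]).
#' @param tail_fraction proportion of points in the fitted tail, in
#'   (0, 0.5] (default 0.1).
#' @param min_points minimum number of tail points (default 50).
#' @return A list of class `tail_fit`: `alpha_tail`, `slope_se`,
#'   `alpha_hill`, `r_squared`, `tail_threshold` (the smallest magnitude
#'   in the fitted tail), `n_tail`, `power_law_ok`.
#' @export
tail_slope <- function(curve, tail_fraction = 0.1, min_points = 50) {
  if (inherits(curve, "residual_set")) curve <- empirical_ccdf(curve)
  stopifnot(inherits(curve, "survival_curve"))
  if (tail_fraction <= 0 || tail_fraction > 0.5)
    stop("'tail_fraction' must lie in (0, 0.5]")
  pos <- curve$magnitudes > 0
  m <- curve$magnitudes[pos]; s <- curve$survival[pos]
  n <- length(m)
  n_tail <- ceiling(tail_fraction * n)
  if (n_tail < min_points)
    stop("only ", n_tail, " tail points; need at least ", min_points)
  idx <- seq.int(n - n_tail + 1L, n)
  lx <- log(m[idx]); ly <- log(s[idx])
  fit <- stats::lm(ly ~ lx)
  sm <- suppressWarnings(summary(fit))  # exact power laws fit perfectly
  slope <- unname(stats::coef(fit)[2])
  alpha_tail <- -slope
  # Hill estimator over the same tail, threshold at the entry order stat
  thr <- m[n - n_tail + 1L]
  hill_terms <- log(m[idx][m[idx] > thr] / thr)
  alpha_hill <- if (length(hill_terms) > 0) 1 / mean(hill_terms) else NA_real_
  structure(list(alpha_tail = alpha_tail,
                 slope_se = sm$coefficients[2, 2],
                 alpha_hill = alpha_hill,
                 r_squared = sm$r.squared,
                 tail_threshold = thr,
                 n_tail = n_tail,
                 power_law_ok = alpha_tail <= 2 && sm$r.squared >= 0.98),
            class = "tail_fit")
}

#' @export
print.tail_fit <- function(x, ...) {
  cat(sprintf("tail fit: alpha = %.3f (se %.3f), Hill alpha = %.3f, R2 = %.4f%s\n",
              x$alpha_tail, x$slope_se, x$alpha_hill, x$r_squared,
              if (!x$power_law_ok) " [tail not consistent with a power law]" else ""))
  invisible(x)
}
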