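#' Linear relaxation drift model
#'
#' Deterministic component `g(x) = -k (x - x*)`: activity relaxes
#' exponentially towards the equilibrium `x*` with characteristic time
#' `tau = 1/k` (in sample steps).
#'
#' @param k relaxation rate per unit step.
#' @param x_star equilibrium activity (signal units).
#' @param slope_se standard error of the fitted slope (optional
#'   diagnostic).
#' @param r_squared weighted R-squared of the fit (optional diagnostic).
#' @param non_relaxing flag set when the fitted slope was non-negative
#'   (no mean reversion).
#' @return An object of class `drift_model` with fields `k`, `x_star`,
#'   `tau` (`1/k`, `Inf` when `k = 0`), and the diagnostics.
#' @export
drift_model <- function(k, x_star, slope_se = NA_real_, r_squared = NA_real_,
                        non_relaxing = FALSE) {
  stopifnot(is.finite(k), is.finite(x_star))
  structure(list(k = as.numeric(k), x_star = as.numeric(x_star),
                 tau = if (k > 0) 1 / k else Inf,
                 slope_se = slope_se, r_squared = r_squared,
                 non_relaxing = isTRUE(non_relaxing)),
            class = "drift_model")
}

#' @export
print.drift_model <- function(x, ...) {
  cat(sprintf("drift model: g(x) = -%.4g (x - %.4g), tau = %.4g steps%s\n",
              x$k, x$x_star, x$tau,
              if (x$non_relaxing) " [non-relaxing]" else ""))
  invisible(x)
}

# evaluate g(x)
drift_g <- function(model, x) -model$k * (x - model$x_star)

# (x_t, dx_t) pairs from one series or a list of series (pooled)
.increment_pairs <- function(series) {
  if (inherits(series, "time_series")) series <- list(series)
  if (is.numeric(series)) series <- list(time_series(series))
  xs <- dxs <- list()
  for (ts in series) {
    v <- if (inherits(ts, "time_series")) ts$values else as.numeric(ts)
    n <- length(v)
    xs[[length(xs) + 1L]] <- v[-n]
    dxs[[length(dxs) + 1L]] <- diff(v)
  }
  list(x = unlist(xs), dx = unlist(dxs))
}

#' Estimate the drift curve as a binned conditional mean of increments
#'
#' Recovers the deterministic component `g(x)` from data: the activity
#' variation `dx(t) = x(t+1) - x(t)` is binned by the current activity
#' `x(t)` and averaged within bins, since the conditional expectation of
#' the increment given the state equals the drift. Bins are
#' equal-occupancy by default (robust to heavy-tailed marginals), bins
#' with fewer than `min_count` points are dropped, and states beyond the
#' 1st/99th percentile are excluded to avoid leverage from rare
#' excursions.
#'
#' @param series a [time_series], a numeric vector, or a list of series
#'   whose increment pairs are pooled (e.g. all subjects of one network).
#' @param n_bins target number of bins (default 50).
#' @param min_count minimum points per retained bin (default 20).
#' @param aggregator `"mean"` (conditional mean, the default) or
#'   `"median"` (robust alternative for very heavy-tailed noise, where
#'   the increment mean may not exist).
#' @param trim quantile range of `x` retained before binning.
#' @return An object of class `drift_curve`: `bin_centers`,
#'   `conditional_means`, `bin_counts`, plus the aggregator used.
#' @export
estimate_drift_curve <- function(series, n_bins = 50, min_count = 20,
                                 aggregator = c("mean", "median"),
                                 trim = c(0.01, 0.99)) {
  aggregator <- match.arg(aggregator)
  pr <- .increment_pairs(series)
  x <- pr$x; dx <- pr$dx
  if (diff(range(x)) <= 1e-10 * max(1, abs(mean(x))))
    stop("constant (degenerate) activity: no state variation to bin")
  qs <- stats::quantile(x, trim, names = FALSE)
  keep <- x >= qs[1] & x <= qs[2]
  x <- x[keep]; dx <- dx[keep]
  n_bins <- max(3L, min(as.integer(n_bins), floor(length(x) / min_count)))
  # equal-occupancy bin edges
  edges <- unique(stats::quantile(x, seq(0, 1, length.out = n_bins + 1),
                                  names = FALSE))
  if (length(edges) < 4) stop("too few distinct activity values to bin")
  bin <- cut(x, edges, include.lowest = TRUE, labels = FALSE)
  agg <- if (aggregator == "mean") mean else stats::median
  centers <- tapply(x, bin, mean)
  means <- tapply(dx, bin, agg)
  counts <- tapply(dx, bin, length)
  keep_bin <- counts >= min_count
  if (sum(keep_bin) < 3)
    stop("fewer than 3 bins with at least ", min_count,
         " points; cannot estimate a drift curve")
  ord <- order(centers[keep_bin])
  structure(list(bin_centers = as.numeric(centers[keep_bin])[ord],
                 conditional_means = as.numeric(means[keep_bin])[ord],
                 bin_counts = as.integer(counts[keep_bin])[ord],
                 aggregator = aggregator),
            class = "drift_curve")
}

#' Fit the linear relaxation line to a drift curve
#'
#' Weighted least squares of the conditional increment means on the bin
#' centers, weights equal to bin occupancies. The slope gives `-k` and the
#' zero crossing gives the equilibrium `x*`.
#'
#' @param curve a [drift_curve].
#' @return A [drift_model]. A non-negative slope (no relaxation) sets the
#'   `non_relaxing` flag instead of failing; a flat curve reports `k = 0`
#'   with `x_star` equal to the occupancy-weighted mean activity.
#' @export
fit_linear_drift <- function(curve) {
  stopifnot(inherits(curve, "drift_curve"))
  if (length(curve$bin_centers) < 3)
    stop("need at least 3 drift-curve bins to fit a line")
  w <- curve$bin_counts
  fit <- stats::lm(conditional_means ~ bin_centers,
                   data = data.frame(bin_centers = curve$bin_centers,
                                     conditional_means = curve$conditional_means),
                   weights = w)
  co <- stats::coef(fit)
  sm <- summary(fit)
  slope <- unname(co[2]); icpt <- unname(co[1])
  slope_se <- sm$coefficients[2, 2]
  k <- -slope
  if (abs(slope) < 1e-12) {
    return(drift_model(0, stats::weighted.mean(curve$bin_centers, w),
                       slope_se = slope_se, r_squared = sm$r.squared,
                       non_relaxing = TRUE))
  }
  drift_model(k, x_star = icpt / k, slope_se = slope_se,
              r_squared = sm$r.squared, non_relaxing = slope >= 0)
}

#' Noise-free solution of the linear relaxation drift
#'
#' Expected activity under the drift alone: exponential decay towards the
#' equilibrium, `x* + (x0 - x*) exp(-t / tau)` with `tau = 1/k`.
#'
#' @param model a [drift_model] with `k > 0`.
#' @param x0 initial activity.
#' @param t time in sample steps (vectorised).
#' @return Numeric vector of expected activities.
#' @examples
#' deterministic_solution(drift_model(0.5, 2), x0 = 10, t = 2)  # 2 + 8/e
#' @export
deterministic_solution <- function(model, x0, t) {
  stopifnot(inherits(model, "drift_model"))
  if (model$k <= 0) stop("deterministic solution requires k > 0")
  model$x_star + (x0 - model$x_star) * exp(-t / model$tau)
}
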