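#' Two-sample Kolmogorov-Smirnov test
#'
#' Supremum distance between the two empirical CDFs with the asymptotic
#' two-sample p-value (via [stats::ks.test()]), or an exact permutation
#' p-value for small samples.
#'
#' @param a,b numeric samples (nonempty).
#' @param exact_permutation if `TRUE`, the p-value is computed by random
#'   permutation of the pooled sample (recommended for n < 100).
#' @param n_perm number of permutations.
#' @param seed optional seed for the permutation p-value.
#' @return List with `statistic` (D) and `p_value`.
#' @examples
#' ks_two_sample(c(1, 3), c(2, 4))$statistic  # 0.5
#' @export
ks_two_sample <- function(a, b, exact_permutation = FALSE, n_perm = 2000,
                          seed = NULL) {
  .check_samples(a, b)
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  D <- unname(kt$statistic)
  if (!exact_permutation)
    return(list(statistic = D, p_value = unname(kt$p.value)))
  pooled <- c(a, b); na <- length(a)
  p <- local_seed(seed, {
    exceed <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), na)
      d <- suppressWarnings(stats::ks.test(pooled[idx], pooled[-idx],
                                           exact = FALSE)$statistic)
      unname(d) >= D - 1e-12
    }, logical(1))
    (sum(exceed) + 1) / (n_perm + 1)
  })
  list(statistic = D, p_value = p)
}

#' Two-sample Anderson-Darling test
#'
#' Rank-based two-sample Anderson-Darling statistic in the
#' Scholz-Stephens form (midrank version, robust to ties), standardised by
#' its exact finite-sample mean and variance, with the published
#' interpolation of the percentile table for the p-value. Compared with
#' the Kolmogorov-Smirnov test it weights discrepancies in the tails more
#' heavily, which matters when comparing heavy-tailed stable laws.
#'
#' @inheritParams ks_two_sample
#' @return List with `statistic` (the standardised statistic) and
#'   `p_value`.
#' @export
ad_two_sample <- function(a, b, exact_permutation = FALSE, n_perm = 2000,
                          seed = NULL) {
  .check_samples(a, b)
  T0 <- .ad_standardized(a, b)
  if (!exact_permutation)
    return(list(statistic = T0, p_value = .ad_pvalue(T0)))
  pooled <- c(a, b); na <- length(a)
  p <- local_seed(seed, {
    exceed <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), na)
      .ad_standardized(pooled[idx], pooled[-idx]) >= T0 - 1e-12
    }, logical(1))
    (sum(exceed) + 1) / (n_perm + 1)
  })
  list(statistic = T0, p_value = p)
}

.check_samples <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("samples must be nonempty")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("samples must be finite")
}

# standardised (A2 - mean) / sd statistic, k = 2 samples, midrank form
.ad_standardized <- function(a, b) {
  samples <- list(sort(a), sort(b))
  k <- 2L
  n <- lengths(samples)
  N <- sum(n)
  Z <- sort(c(a, b))
  Zstar <- unique(Z)
  lj <- tabulate(match(Z, Zstar), nbins = length(Zstar))
  Bj <- cumsum(lj) - lj / 2
  A2 <- 0
  for (i in seq_len(k)) {
    s <- samples[[i]]
    Mright <- findInterval(Zstar, s)                 # count s <= Zstar_j
    fij <- Mright - findInterval(Zstar, s, left.open = TRUE)
    Mij <- Mright - fij / 2
    inner <- lj / N * (N * Mij - Bj * n[i])^2 / (Bj * (N - Bj) - N * lj / 4)
    A2 <- A2 + sum(inner) / n[i]
  }
  A2 <- A2 * (N - 1) / N
  # exact mean (k - 1) and variance of A2 under H0 (Scholz-Stephens)
  H <- sum(1 / n)
  h <- sum(1 / seq_len(N - 1))
  # g = sum_{i=1}^{N-2} 1/(N-i) * sum_{j=i+1}^{N-1} 1/j
  i <- seq_len(N - 2)
  tailsum <- rev(cumsum(rev(1 / seq.int(2, N - 1))))  # sum_{j=i+1}^{N-1} 1/j
  g <- sum(tailsum / (N - i))
  aa <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * H
  bb <- (2 * g - 4) * k^2 + 8 * h * k + (2 * g - 14 * h - 4) * H - 8 * h + 4 * g - 6
  cc <- (6 * h + 2 * g - 2) * k^2 + (4 * h - 6 * g + 6) * k + (2 * h - 6) * H + 4 * h
  dd <- (2 * h + 6) * k^2 - 4 * h * k
  sigsq <- (aa * N^3 + bb * N^2 + cc * N + dd) /
    ((N - 1) * (N - 2) * (N - 3))
  (A2 - (k - 1)) / sqrt(sigsq)
}

# p-value from the Scholz-Stephens percentile table (m = k - 1 = 1),
# quadratic interpolation of log p inside the tabulated range, linear
# continuation of log p outside it (so p -> 1 for strongly negative
# statistics instead of saturating at the largest tabulated level)
.ad_pvalue <- function(tstat) {
  m <- 1
  b0 <- c(0.675, 1.281, 1.645, 1.960, 2.326, 2.573, 3.085)
  b1 <- c(-0.245, 0.250, 0.678, 1.149, 1.822, 2.364, 3.615)
  b2 <- c(-0.105, -0.305, -0.362, -0.391, -0.396, -0.345, -0.154)
  crit <- b0 + b1 / sqrt(m) + b2 / m
  lp <- log(c(0.25, 0.10, 0.05, 0.025, 0.01, 0.005, 0.001))
  pf <- stats::lm(lp ~ stats::poly(crit, 2, raw = TRUE))
  co <- stats::coef(pf)
  evalq2 <- function(t) co[1] + co[2] * t + co[3] * t^2
  dq2 <- function(t) co[2] + 2 * co[3] * t
  t1 <- crit[1]; t2 <- crit[length(crit)]
  lpv <- if (tstat < t1) evalq2(t1) + dq2(t1) * (tstat - t1)
         else if (tstat > t2) evalq2(t2) + dq2(t2) * (tstat - t2)
         else evalq2(tstat)
  unname(min(max(exp(lpv), 0), 1))
}

#' Goodness of fit of a stable law to residuals
#'
#' Draws `n_draws` samples from the fitted stable law and compares them
#' with the residuals using both the two-sample Kolmogorov-Smirnov and
#' Anderson-Darling tests. The null hypothesis is that residuals and model
#' draws come from the same distribution; failing to reject supports the
#' stable fit.
#'
#' @param residuals a [residual_set] or numeric vector.
#' @param params fitted [stable_params].
#' @param n_draws number of model draws (default: the residual count,
#'   keeping the comparison in the standard matched two-sample regime).
#' @param level significance level (default 0.05).
#' @param seed integer seed for the model draws.
#' @return An object of class `gof_result` with both statistics, p-values,
#'   reject decisions, `n_model_draws`, `level` and `seed`.
#' @export
gof_assess <- function(residuals, params, n_draws = NULL, level = 0.05,
                       seed = NULL) {
  xi <- if (inherits(residuals, "residual_set")) residuals$xi
        else as.numeric(residuals)
  .check_params(params)
  n_draws <- n_draws %||% length(xi)
  if (n_draws < length(xi))
    stop("'n_draws' must be at least the residual sample size")
  draws <- stable_sample(n_draws, params, seed = seed)
  ks <- ks_two_sample(xi, draws)
  ad <- ad_two_sample(xi, draws)
  structure(list(ks_statistic = ks$statistic, ks_pvalue = ks$p_value,
                 ad_statistic = ad$statistic, ad_pvalue = ad$p_value,
                 level = level,
                 ks_reject = ks$p_value < level,
                 ad_reject = ad$p_value < level,
                 n_model_draws = as.integer(n_draws),
                 seed = seed),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("goodness of fit (level %.3g):\n  K-S D = %.4f, p = %.4f -> %s\n  A-D T = %.4f, p = %.4f -> %s\n",
              x$level, x$ks_statistic, x$ks_pvalue,
              if (x$ks_reject) "reject" else "not rejected",
              x$ad_statistic, x$ad_pvalue,
              if (x$ad_reject) "reject" else "not rejected"))
  invisible(x)
}

#' Monte Carlo power / size of the two-sample tests
#'
#' Repeatedly draws one sample from `null_params` and one from
#' `alt_params` and records the rejection fraction of each test. With
#' `alt_params = null_params` the result is the empirical type-I error,
#' which should match the nominal level; with nearby alternatives it
#' measures the power to detect small changes in the stable parameters.
#'
#' @param null_params,alt_params [stable_params] objects.
#' @param n per-sample size.
#' @param reps number of replicates (at least 100).
#' @param level significance level.
#' @param seed integer seed (one sub-seed per replicate).
#' @return A data.frame with one row per test (`test`, `n`, `reps`,
#'   `power`).
#' @export
mc_power <- function(null_params, alt_params, n = 500, reps = 1000,
                     level = 0.05, seed = 1) {
  .check_params(null_params); .check_params(alt_params)
  if (reps < 100) stop("'reps' must be at least 100")
  rej_ks <- rej_ad <- logical(reps)
  for (r in seq_len(reps)) {
    a <- stable_sample(n, null_params, seed = derive_seed(seed, "null", r))
    b <- stable_sample(n, alt_params, seed = derive_seed(seed, "alt", r))
    rej_ks[r] <- ks_two_sample(a, b)$p_value < level
    rej_ad[r] <- ad_two_sample(a, b)$p_value < level
  }
  data.frame(test = c("ks", "ad"), n = n,
             delta_alpha = alt_params$alpha - null_params$alpha,
             reps = reps, power = c(mean(rej_ks), mean(rej_ad)))
}
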