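#' Density, distribution and survival function of an alpha-stable law
#'
#' The stable family has no closed-form density in general; these functions
#' evaluate it by numerical inversion of the characteristic function
#' (Gil-Pelaez quadrature on the S0 form, which is continuous in all
#' parameters), switching to the first-order Pareto asymptotic series for
#' `|x - delta| > tail_threshold * gamma` when `alpha < 2`. Closed forms are
#' used where they exist: `alpha = 2` (normal with variance `2 gamma^2`),
#' `alpha = 1, beta = 0` (Cauchy) and `alpha = 0.5, |beta| = 1` (Levy).
#'
#' @param x numeric vector of evaluation points.
#' @param params a [stable_params] object.
#' @param tail_threshold multiple of `gamma` beyond which the power-law
#'   asymptotic branch replaces quadrature (default 25).
#' @return `stable_pdf`: non-negative densities. `stable_cdf`: probabilities
#'   in \[0, 1\], nondecreasing in `x`. `stable_ccdf`: survival
#'   probabilities `1 - F(x)`, nonincreasing in `x` and asymptotically
#'   proportional to `x^-alpha` for `alpha < 2`.
#' @examples
#' stable_pdf(0, stable_params(1, 0, 1, 0))   # Cauchy: 1/pi
#' stable_ccdf(1, stable_params(1, 0, 1, 0))  # Cauchy: 0.25
#' @export
stable_pdf <- function(x, params, tail_threshold = 25) {
  .stable_eval(x, params, tail_threshold, what = "pdf")
}

#' @rdname stable_pdf
#' @export
stable_cdf <- function(x, params, tail_threshold = 25) {
  .stable_eval(x, params, tail_threshold, what = "cdf")
}

#' @rdname stable_pdf
#' @export
stable_ccdf <- function(x, params, tail_threshold = 25) {
  .stable_eval(x, params, tail_threshold, what = "ccdf")
}

# Pareto tail constant: P(X > x) ~ C_alpha (1 + beta) gamma^alpha x^-alpha
.tail_const <- function(alpha) sin(pi * alpha / 2) * gamma(alpha) / pi

.stable_eval <- function(x, params, tail_threshold, what) {
  .check_params(params)
  stopifnot(is.numeric(x))
  p1 <- as_s1(params)
  a <- p1$alpha; b <- p1$beta; g <- p1$gamma; d1 <- p1$delta

  # closed forms
  if (a == 2) {
    s <- sqrt(2) * g
    return(switch(what,
                  pdf = stats::dnorm(x, d1, s),
                  cdf = stats::pnorm(x, d1, s),
                  ccdf = stats::pnorm(x, d1, s, lower.tail = FALSE)))
  }
  if (.is_alpha_one(a) && b == 0) {
    return(switch(what,
                  pdf = stats::dcauchy(x, d1, g),
                  cdf = stats::pcauchy(x, d1, g),
                  ccdf = stats::pcauchy(x, d1, g, lower.tail = FALSE)))
  }
  if (a == 0.5 && abs(b) == 1) {
    z <- if (b == 1) (x - d1) / g else (d1 - x) / g  # Levy, possibly mirrored
    pdf <- ifelse(z > 0, sqrt(1 / (2 * pi)) * z^-1.5 * exp(-1 / (2 * z)) / g, 0)
    Fz <- ifelse(z > 0, 2 * stats::pnorm(-1 / sqrt(z)), 0)  # Levy CDF
    return(switch(what,
                  pdf = pdf,
                  cdf = if (b == 1) Fz else 1 - Fz,
                  ccdf = if (b == 1) 1 - Fz else Fz))
  }

  z1 <- (x - d1) / g
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    zi <- z1[i]
    if (a < 1 && abs(b) == 1 && ((b == 1 && zi <= 0) || (b == -1 && zi >= 0))) {
      # one-sided support boundary
      out[i] <- switch(what, pdf = 0,
                       cdf = if (b == 1) 0 else 1,
                       ccdf = if (b == 1) 1 else 0)
    } else if (abs(zi) > tail_threshold && a <= 1 + .ALPHA1_TOL) {
      # for alpha <= 1 the Zolotarev-Nolan integral representation stays
      # smooth arbitrarily far in the tail (the transformed exponent
      # vanishes as |x| grows), so it replaces the truncated Pareto series;
      # its natural coordinate is the S0-standardized one
      z0 <- zi - .s0_shift(a, b, 1)
      out[i] <- .stable_nolan(z0, a, b, what) / (if (what == "pdf") g else 1)
    } else if (zi > tail_threshold && (1 + b) > 0) {
      Fbar <- min(1, .tail_const(a) * (1 + b) * zi^-a)
      out[i] <- switch(what,
                       pdf = a * .tail_const(a) * (1 + b) * zi^(-a - 1) / g,
                       cdf = 1 - Fbar, ccdf = Fbar)
    } else if (zi < -tail_threshold && (1 - b) > 0) {
      Flo <- min(1, .tail_const(a) * (1 - b) * abs(zi)^-a)
      out[i] <- switch(what,
                       pdf = a * .tail_const(a) * (1 - b) * abs(zi)^(-a - 1) / g,
                       cdf = Flo, ccdf = 1 - Flo)
    } else if (abs(zi) > tail_threshold) {
      # light side of a maximally skewed law with alpha >= 1: the power-law
      # series does not apply; the probability beyond here is negligible
      out[i] <- switch(what, pdf = 0,
                       cdf = if (zi > 0) 1 else 0,
                       ccdf = if (zi > 0) 0 else 1)
    } else {
      out[i] <- .stable_invert(zi, p1, what)
    }
  }
  out
}

# Zolotarev-Nolan integral representation of the standardized S1 law
# (coordinate z1), used for the tails at alpha <= 1 where the integrand is
# smooth. alpha = 1 requires beta != 0 here (beta = 0 is closed-form Cauchy).
.stable_nolan <- function(z1, a, b, what) {
  if (.is_alpha_one(a)) {
    if (b < 0)
      return(switch(what, pdf = .stable_nolan(-z1, a, -b, "pdf"),
                    cdf = 1 - .stable_nolan(-z1, a, -b, "cdf"),
                    ccdf = .stable_nolan(-z1, a, -b, "cdf")))
    logV1 <- function(th) log(2 / pi) + log((pi / 2 + b * th) / cos(th)) +
      (1 / b) * (pi / 2 + b * th) * tan(th)
    lh <- -pi * z1 / (2 * b)
    lg <- function(th) lh + logV1(th)
    fF <- function(th) exp(-exp(pmin(lg(th), 700)))
    ff <- function(th) { v <- lg(th); ifelse(v > 700, 0, exp(v - exp(v))) }
    if (what == "pdf")
      return(.integrate_peak(ff, -pi / 2, pi / 2, lg) / (2 * b))
    Fx <- .integrate_peak(fF, -pi / 2, pi / 2, lg) / pi
    return(if (what == "cdf") Fx else 1 - Fx)
  }
  zeta <- -b * tan(pi * a / 2)
  if (z1 < zeta)
    return(switch(what, pdf = .stable_nolan(-z1, a, -b, "pdf"),
                  cdf = 1 - .stable_nolan(-z1, a, -b, "cdf"),
                  ccdf = .stable_nolan(-z1, a, -b, "cdf")))
  th0 <- atan(b * tan(pi * a / 2)) / a
  if (abs(z1 - zeta) < 1e-9) {
    Fz <- 0.5 - th0 / pi
    return(switch(what,
                  pdf = gamma(1 + 1 / a) * cos(th0) /
                    (pi * (1 + zeta^2)^(1 / (2 * a))),
                  cdf = Fz, ccdf = 1 - Fz))
  }
  logV <- function(th) {
    (1 / (a - 1)) * log(cos(a * th0)) +
      (a / (a - 1)) * log(cos(th) / sin(a * (th0 + th))) +
      log(cos(a * th0 + (a - 1) * th) / cos(th))
  }
  ls <- (a / (a - 1)) * log(z1 - zeta)
  lg <- function(th) ls + logV(th)
  fF <- function(th) { v <- lg(th)
    ifelse(is.nan(v), 0, exp(-exp(pmin(v, 700)))) }
  ff <- function(th) { v <- lg(th)
    ifelse(is.nan(v) | v > 700, 0, exp(v - exp(v))) }
  if (what == "pdf")
    return(a / (pi * abs(1 - a) * (z1 - zeta)) *
             .integrate_peak(ff, -th0, pi / 2, lg))
  Fx <- (0.5 - th0 / pi) +
    sign(1 - a) / pi * .integrate_peak(fF, -th0, pi / 2, lg)
  Fx <- min(max(Fx, 0), 1)
  if (what == "cdf") Fx else 1 - Fx
}

# Integrate f over (lo, hi) splitting at the point where the transformed
# exponent g = exp(lg) crosses 1: the integrands peak (or switch between
# their 0 and 1 plateaus) in a possibly very narrow layer around it, which
# plain adaptive quadrature can miss when the layer hugs an endpoint.
.integrate_peak <- function(f, lo, hi, lg) {
  eps <- (hi - lo) * 1e-9
  th <- seq(lo + eps, hi - eps, length.out = 201)
  v <- suppressWarnings(lg(th))
  v[!is.finite(v)] <- NA_real_
  split <- NULL
  s <- sign(v)
  cross <- which(!is.na(v[-1]) & !is.na(v[-length(v)]) &
                   s[-1] * s[-length(s)] < 0)
  if (length(cross)) {
    j <- cross[1]
    r <- tryCatch(stats::uniroot(function(x) lg(x), c(th[j], th[j + 1]),
                                 tol = 1e-13)$root, error = function(e) NULL)
    star <- r %||% th[j]
    # bracket the boundary layer: its width scales as 1/|d lg / d theta|
    h <- (hi - lo) * 1e-7
    dlg <- abs(lg(star + h) - lg(star - h)) / (2 * h)
    w <- if (is.finite(dlg) && dlg > 0) min(30 / dlg, (hi - lo) / 4)
         else (hi - lo) / 100
    split <- c(star - w, star, star + w)
  }
  pts <- sort(unique(pmin(pmax(c(lo, split, hi), lo), hi)))
  total <- 0
  for (k in seq_len(length(pts) - 1)) {
    r <- tryCatch(stats::integrate(f, pts[k], pts[k + 1], rel.tol = 1e-10,
                                   abs.tol = 1e-13, subdivisions = 1000L),
                  error = function(e) e)
    if (inherits(r, "error"))
      stop("stable tail quadrature failed: ", conditionMessage(r))
    total <- total + r$value
  }
  total
}

# CF inversion at a single point, in the standardized S0 frame.
# x is expressed in S1-standardized units; shift into S0 units here.
.stable_invert <- function(z1, p1, what) {
  a <- p1$alpha; b <- p1$beta
  z0 <- z1 - .s0_shift(a, b, 1)  # S0-standardized coordinate
  alpha1 <- .is_alpha_one(a)
  # modulus and phase of the standardized S0 characteristic function, t > 0
  phase <- if (alpha1) function(t) -b * (2 / pi) * t * log(t)
           else function(t) -b * tan(pi * a / 2) * (t - t^a)
  integrand <- if (what == "pdf") {
    function(t) exp(-t^a) * cos(phase(t) - t * z0)
  } else {
    function(t) {
      v <- exp(-t^a) * sin(phase(t) - t * z0) / t
      v[t == 0] <- 0
      v
    }
  }
  val <- .integrate_cf(integrand, a)
  if (what == "pdf") return(max(val / pi, 0))
  Fx <- min(max(0.5 - val / pi, 0), 1)
  if (what == "cdf") Fx else 1 - Fx
}

.integrate_cf <- function(f, alpha) {
  r <- tryCatch(
    stats::integrate(f, 0, Inf, rel.tol = 1e-10, abs.tol = 1e-12,
                     subdivisions = 2000L, stop.on.error = TRUE),
    error = function(e) e)
  if (!inherits(r, "error")) return(r$value)
  # fall back to a finite window where the CF modulus has decayed below 1e-14
  upper <- (14 * log(10))^(1 / alpha)
  r2 <- tryCatch(
    stats::integrate(f, 0, upper, rel.tol = 1e-9, abs.tol = 1e-12,
                     subdivisions = 5000L, stop.on.error = TRUE),
    error = function(e) e)
  if (inherits(r2, "error"))
    stop("characteristic-function quadrature failed to converge (alpha = ",
         alpha, "): ", conditionMessage(r2))
  r2$value
}
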