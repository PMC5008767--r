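#' Alpha-stable parameter set
#'
#' Container for the four parameters of an alpha-stable law together with an
#' explicit parameterization tag. Two conventions are supported: `"S1"`, the
#' classical Samorodnitsky--Taqqu form in which the characteristic function
#' is written with the `tan(pi * alpha / 2)` skew term (the form used for
#' reporting), and `"S0"`, Nolan's location-shifted form which is jointly
#' continuous in all parameters and is used internally for estimation and
#' numerical evaluation.
#'
#' @param alpha characteristic exponent, in (0, 2]. Controls tail heaviness:
#'   `alpha = 2` is the Gaussian case, `alpha < 2` gives power-law tails
#'   (Levy regime).
#' @param beta skewness, in \[-1, 1\].
#' @param gamma scale (same units as the signal), strictly positive.
#' @param delta location (signal units), finite.
#' @param parameterization `"S1"` (default) or `"S0"`.
#'
#' @return An object of class `stable_params`: a list with fields `alpha`,
#'   `beta`, `gamma`, `delta`, `parameterization`.
#'
#' @details When `alpha = 2` the skew term vanishes (`tan(pi) = 0`), so the
#'   law does not depend on `beta`; `beta` is stored as given but has no
#'   effect. Values of `alpha` within `1e-3` of 1 are treated as exactly 1
#'   by all numerical routines (the S1 form is discontinuous in `alpha`
#'   at 1).
#'
#' @examples
#' p <- stable_params(1.5, 0, 1, 0)
#' p0 <- as_s0(p)
#' as_s1(p0)  # round-trips
#' @export
stable_params <- function(alpha, beta = 0, gamma = 1, delta = 0,
                          parameterization = c("S1", "S0")) {
  parameterization <- match.arg(parameterization)
  stopifnot(length(alpha) == 1L, length(beta) == 1L,
            length(gamma) == 1L, length(delta) == 1L)
  if (!is.finite(alpha) || alpha <= 0 || alpha > 2)
    stop("'alpha' must lie in (0, 2], got ", alpha)
  if (!is.finite(beta) || beta < -1 || beta > 1)
    stop("'beta' must lie in [-1, 1], got ", beta)
  if (!is.finite(gamma) || gamma <= 0)
    stop("'gamma' must be positive and finite, got ", gamma)
  if (!is.finite(delta))
    stop("'delta' must be finite")
  structure(
    list(alpha = as.numeric(alpha), beta = as.numeric(beta),
         gamma = as.numeric(gamma), delta = as.numeric(delta),
         parameterization = parameterization),
    class = "stable_params"
  )
}

#' @export
print.stable_params <- function(x, ...) {
  cat(sprintf("alpha-stable law [%s]: alpha = %.4g, beta = %.4g, gamma = %.4g, delta = %.4g\n",
              x$parameterization, x$alpha, x$beta, x$gamma, x$delta))
  invisible(x)
}

# guard band around alpha = 1: the S1 characteristic function switches branch
.ALPHA1_TOL <- 1e-3

.is_alpha_one <- function(alpha) abs(alpha - 1) < .ALPHA1_TOL

# S0 location = S1 location + shift(alpha, beta, gamma)
.s0_shift <- function(alpha, beta, gamma) {
  if (.is_alpha_one(alpha)) beta * (2 / pi) * gamma * log(gamma)
  else beta * gamma * tan(pi * alpha / 2)
}

#' Convert between stable parameterizations
#'
#' `as_s0()` and `as_s1()` re-express a [stable_params] object in Nolan's S0
#' form or the classical S1 form. Only the location `delta` differs between
#' the two; the conversion is an involution.
#'
#' @param params a [stable_params] object.
#' @return A [stable_params] object in the requested parameterization.
#' @export
as_s0 <- function(params) {
  .check_params(params)
  if (params$parameterization == "S0") return(params)
  stable_params(params$alpha, params$beta, params$gamma,
                params$delta + .s0_shift(params$alpha, params$beta, params$gamma),
                parameterization = "S0")
}

#' @rdname as_s0
#' @export
as_s1 <- function(params) {
  .check_params(params)
  if (params$parameterization == "S1") return(params)
  stable_params(params$alpha, params$beta, params$gamma,
                params$delta - .s0_shift(params$alpha, params$beta, params$gamma),
                parameterization = "S1")
}

.check_params <- function(params) {
  if (!inherits(params, "stable_params"))
    stop("expected a 'stable_params' object")
  invisible(params)
}
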