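#' Characteristic function of an alpha-stable law
#'
#' Evaluates `E[exp(i t X)]` for `X` alpha-stable, using the classical two-
#' branch S1 form: for `alpha != 1`
#' \deqn{\exp\{i\delta t - |\gamma t|^\alpha [1 - i\beta \mathrm{sign}(t)
#'   \tan(\pi\alpha/2)]\}}
#' and for `alpha = 1`
#' \deqn{\exp\{i\delta t - |\gamma t| [1 + i\beta (2/\pi) \mathrm{sign}(t)
#'   \ln|t|]\}.}
#' S0 input is converted internally.
#'
#' @param t numeric vector of frequencies.
#' @param params a [stable_params] object.
#' @return Complex vector of the same length as `t`; modulus is at most 1 and
#'   `stable_cf(-t, p) == Conj(stable_cf(t, p))`.
#' @examples
#' stable_cf(1, stable_params(2, 0, 1, 0))  # exp(-1)
#' @export
stable_cf <- function(t, params) {
  .check_params(params)
  if (any(!is.finite(t))) stop("'t' must be finite")
  p <- as_s1(params)
  a <- p$alpha; b <- p$beta; g <- p$gamma; d <- p$delta
  at <- abs(t)
  if (.is_alpha_one(a)) {
    # |t| log|t| -> 0 as t -> 0
    lt <- ifelse(at > 0, log(at), 0)
    ex <- -g * at * (1 + 1i * b * (2 / pi) * sign(t) * lt) + 1i * d * t
  } else {
    ex <- -(g * at)^a * (1 - 1i * b * sign(t) * tan(pi * a / 2)) + 1i * d * t
  }
  exp(ex)
}

#' Draw alpha-stable random variates
#'
#' Chambers--Mallows--Stuck transformation of a uniform and an exponential
#' variate, with the dedicated `alpha = 1` branch. Output follows the S1
#' parameterization of `params` (S0 input is converted).
#'
#' @param n number of draws (non-negative integer).
#' @param params a [stable_params] object.
#' @param seed optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return Numeric vector of length `n`.
#' @examples
#' x <- stable_sample(1000, stable_params(1.5, 0, 1, 0), seed = 1)
#' @export
stable_sample <- function(n, params, seed = NULL) {
  .check_params(params)
  if (length(n) != 1L || is.na(n) || n < 0) stop("'n' must be a non-negative count")
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  p <- as_s1(params)
  local_seed(seed, {
    V <- stats::runif(n, -pi / 2, pi / 2)
    W <- stats::rexp(n)
    .cms_standard(p$alpha, p$beta, V, W) * p$gamma + .cms_location(p)
  })
}

# standardized S1(alpha, beta, 1, 0) variate from V ~ U(-pi/2, pi/2), W ~ Exp(1)
.cms_standard <- function(alpha, beta, V, W) {
  if (.is_alpha_one(alpha)) {
    h <- pi / 2 + beta * V
    (2 / pi) * (h * tan(V) - beta * log((pi / 2) * W * cos(V) / h))
  } else {
    tb <- beta * tan(pi * alpha / 2)
    B <- atan(tb) / alpha
    S <- (1 + tb^2)^(1 / (2 * alpha))
    S * sin(alpha * (V + B)) / cos(V)^(1 / alpha) *
      (cos(V - alpha * (V + B)) / W)^((1 - alpha) / alpha)
  }
}

# S1 location term: for alpha = 1 scaling introduces (2/pi) beta gamma log gamma
.cms_location <- function(p) {
  if (.is_alpha_one(p$alpha)) p$delta + (2 / pi) * p$beta * p$gamma * log(p$gamma)
  else p$delta
}
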