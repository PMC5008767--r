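# Regenerates R/stable-tables.R: standardized-quantile lookup tables used by
# the quantile initializer of the ECF stable fit. For each (alpha, beta) on a
# grid, the 5/25/50/75/95% quantiles of the standardized S0 law are obtained
# by root-finding on the package's numerical CDF, and summarised as the
# quantile spread ratio nu_alpha, the asymmetry ratio nu_beta, the
# interquartile range and the median. Run from the package root:
#   Rscript data-raw/make_quantile_tables.R
for (f in list.files("R", full.names = TRUE)) source(f)

agrid <- seq(0.5, 2.0, by = 0.1)
bgrid <- c(0, 0.25, 0.5, 0.75, 1)
probs <- c(0.05, 0.25, 0.5, 0.75, 0.95)

qstable_s0 <- function(p, alpha, beta) {
  par <- stable_params(alpha, beta, 1, 0, parameterization = "S0")
  f <- function(x) stable_cdf(x, par) - p
  lo <- -2; hi <- 2
  while (f(lo) > 0 && lo > -1e6) lo <- lo * 2
  while (f(hi) < 0 && hi < 1e6) hi <- hi * 2
  uniroot(f, c(lo, hi), tol = 1e-9)$root
}

nu_a <- nu_b <- iqr <- med <- matrix(NA_real_, length(agrid), length(bgrid),
                                     dimnames = list(agrid, bgrid))
for (i in seq_along(agrid)) for (j in seq_along(bgrid)) {
  q <- vapply(probs, qstable_s0, numeric(1), alpha = agrid[i], beta = bgrid[j])
  nu_a[i, j] <- (q[5] - q[1]) / (q[4] - q[2])
  nu_b[i, j] <- (q[5] + q[1] - 2 * q[3]) / (q[5] - q[1])
  iqr[i, j]  <- q[4] - q[2]
  med[i, j]  <- q[3]
  cat(sprintf("alpha=%.1f beta=%.2f nu_a=%.4f nu_b=%.4f\n",
              agrid[i], bgrid[j], nu_a[i, j], nu_b[i, j]))
}

fmt <- function(m, name) {
  vals <- paste(sprintf("%.6f", t(m)), collapse = ", ")
  sprintf("%s <- matrix(c(%s),\n  nrow = %d, byrow = TRUE, dimnames = list(.qtab_alpha, .qtab_beta))",
          name, vals, nrow(m))
}
out <- c(
  "# Standardized-quantile lookup tables for the stable quantile initializer.",
  "# Generated from the package's own numerical stable CDF by",
  "# data-raw/make_quantile_tables.R; do not edit by hand.",
  sprintf(".qtab_alpha <- c(%s)", paste(agrid, collapse = ", ")),
  sprintf(".qtab_beta <- c(%s)", paste(bgrid, collapse = ", ")),
  fmt(nu_a, ".qtab_nu_alpha"), fmt(nu_b, ".qtab_nu_beta"),
  fmt(iqr, ".qtab_iqr"), fmt(med, ".qtab_median"))
writeLines(out, "R/stable-tables.R")
cat("wrote R/stable-tables.R\n")
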