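#' Write pipeline reports to disk
#'
#' Emits, under `out_dir`: one JSON report per network
#' (`network_<id>.json`), a summary CSV (`summary.csv`: network, k, x*,
#' alpha, beta, gamma, delta, tail alpha, K-S p, A-D p, rank), plot-ready
#' CSVs of the drift curves and survival curves when the corresponding
#' dataset is supplied, and a run manifest (`manifest.json`) recording the
#' configuration, every seed used and the package version. Output is
#' deterministic for a fixed configuration and seed.
#'
#' @param reports list of `network_report` objects from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @param dataset optional list of [time_series]; when given, per-network
#'   drift-curve and survival-curve CSVs are recomputed and written.
#' @param config the [pipeline_config] used (recorded in the manifest).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(reports, out_dir, dataset = NULL, config = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ writeLines("", probe); TRUE }, error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) stop("output directory is not writable: ", out_dir)
  unlink(probe)

  rows <- list()
  for (r in reports) {
    jpath <- file.path(out_dir, paste0("network_", .safe_name(r$network_id),
                                       ".json"))
    jsonlite::write_json(.report_to_list(r), jpath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    rows[[length(rows) + 1L]] <- if (identical(r$status, "ok")) {
      data.frame(network = r$network_id, k = r$drift$k,
                 x_star = r$drift$x_star, alpha = r$stable$alpha,
                 beta = r$stable$beta, gamma = r$stable$gamma,
                 delta = r$stable$delta,
                 tail_alpha = if (is.null(r$tail)) NA_real_
                              else r$tail$alpha_tail,
                 ks_p = r$gof$ks_pvalue, ad_p = r$gof$ad_pvalue,
                 alpha_rank = r$alpha_rank, status = "ok")
    } else {
      data.frame(network = r$network_id, k = NA_real_, x_star = NA_real_,
                 alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
                 delta = NA_real_, tail_alpha = NA_real_, ks_p = NA_real_,
                 ad_p = NA_real_, alpha_rank = NA_integer_,
                 status = "failed")
    }
  }
  summary_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(network = character(0), k = numeric(0), x_star = numeric(0),
               alpha = numeric(0), beta = numeric(0), gamma = numeric(0),
               delta = numeric(0), tail_alpha = numeric(0),
               ks_p = numeric(0), ad_p = numeric(0),
               alpha_rank = integer(0), status = character(0))
  utils::write.csv(summary_df, file.path(out_dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)

  if (!is.null(dataset)) .write_curves(reports, dataset, out_dir,
                                       config %||% pipeline_config())

  manifest <- list(
    package = "levyflux",
    version = as.character(utils::packageVersion("levyflux")),
    config = if (is.null(config)) NULL else unclass(config),
    seeds = lapply(reports, function(r)
      list(network = r$network_id, pipeline_seed = r$seed,
           gof_seed = if (identical(r$status, "ok")) r$gof$seed else NULL)),
    networks = vapply(reports, `[[`, "", "network_id"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}

.safe_name <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

.report_to_list <- function(r) {
  if (!identical(r$status, "ok"))
    return(list(network_id = r$network_id, status = r$status,
                reason = r$reason))
  list(network_id = r$network_id, status = r$status,
       n_subjects = r$n_subjects, n_points = r$n_points,
       n_residuals = r$n_residuals,
       drift = list(k = r$drift$k, x_star = r$drift$x_star,
                    tau_steps = r$drift$tau,
                    slope_se = r$drift$slope_se,
                    r_squared = r$drift$r_squared,
                    non_relaxing = r$drift$non_relaxing),
       stable = list(alpha = r$stable$alpha, beta = r$stable$beta,
                     gamma = r$stable$gamma, delta = r$stable$delta,
                     parameterization = r$stable$parameterization),
       stable_ci = r$stable_ci,
       per_subject_alpha = r$per_subject_alpha,
       tail = if (is.null(r$tail)) NULL else unclass(r$tail),
       tail_sweep = r$tail_sweep,
       gof = unclass(r$gof),
       alpha_rank = r$alpha_rank,
       notes = r$notes,
       seed = r$seed)
}

.write_curves <- function(reports, dataset, out_dir, config) {
  nets <- vapply(dataset, `[[`, "", "network_id")
  for (r in reports) {
    if (!identical(r$status, "ok")) next
    det <- lapply(dataset[nets == r$network_id], detrend,
                  method = config$detrend)
    curve <- tryCatch(estimate_drift_curve(det, n_bins = config$n_bins,
                                           min_count = config$min_count),
                      error = function(e) NULL)
    if (!is.null(curve))
      utils::write.csv(data.frame(bin_center = curve$bin_centers,
                                  conditional_mean = curve$conditional_means,
                                  count = curve$bin_counts),
                       file.path(out_dir, paste0("drift_",
                                                 .safe_name(r$network_id),
                                                 ".csv")),
                       row.names = FALSE, quote = FALSE)
    resid <- pool_residuals(lapply(det, extract_residuals, model = r$drift))
    write_survival_csv(empirical_ccdf(resid),
                       file.path(out_dir, paste0("survival_",
                                                 .safe_name(r$network_id),
                                                 ".csv")))
  }
}
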