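#' Full evaluation report for a cohort of patient series
#'
#' Runs the rolling-origin evaluation for every patient, then aggregates:
#' per-patient metric quadruples and alert counts; per-group pooled metrics
#' and gamma error calibrations (absolute errors at `abs_threshold` kg,
#' relative errors at `rel_threshold`); and, when at least two groups have
#' two or more patients, a one-way ANOVA across groups on per-patient MAE
#' together with Holm-adjusted pairwise t-tests against the first group.
#'
#' @param series_list A `patient_series` or list of them.
#' @param k,n,tau,ema_mode,kernel_mode,trim_rate,warmup See
#'   [rolling_evaluate()].
#' @param abs_threshold,rel_threshold Clinical deviation thresholds, see
#'   [deviation_alert()].
#' @return A nested list of class `cohort_report` with elements `config`,
#'   `patients`, `groups` and (when applicable) `comparison`.
#' @export
cohort_report <- function(series_list, k = 5, n = 5, tau = 1.0,
                          ema_mode = "normalized",
                          kernel_mode = "sample_weight",
                          warmup = 30, trim_rate = 0.10,
                          abs_threshold = 0.5, rel_threshold = 0.01) {
  if (inherits(series_list, "patient_series")) series_list <- list(series_list)
  patients <- list()
  rows_by_patient <- list()
  for (ps in series_list) {
    res <- rolling_evaluate(ps, k = k, n = n, tau = tau, ema_mode = ema_mode,
                            kernel_mode = kernel_mode, warmup = warmup,
                            trim_rate = trim_rate)
    scored <- res[!is.na(res$post_actual), , drop = FALSE]
    q <- metric_quad(scored$post_actual, scored$post_pred)
    alerts <- deviation_alert(res, abs_threshold, rel_threshold)
    patients[[ps$patient_id]] <- list(
      group = ps$group, n_predictions = nrow(res), n_scored = nrow(scored),
      mae = q$mae, mape = q$mape, mse = q$mse, r2 = q$r2,
      n_alerts = nrow(alerts))
    rows_by_patient[[ps$patient_id]] <- cbind(
      data.frame(patient_id = ps$patient_id, group = ps$group), scored)
  }
  all_rows <- do.call(rbind, rows_by_patient)

  groups <- list()
  for (g in unique(all_rows$group)) {
    gr <- all_rows[all_rows$group == g, , drop = FALSE]
    q <- metric_quad(gr$post_actual, gr$post_pred)
    ga <- error_cdf(gr$abs_error, abs_threshold)
    gre <- error_cdf(gr$rel_error, rel_threshold)
    groups[[g]] <- list(
      n_patients = length(unique(gr$patient_id)), n_scored = nrow(gr),
      mae = q$mae, mape = q$mape, mse = q$mse, r2 = q$r2,
      gamma_abs = list(shape = ga$shape, scale = ga$scale,
                       threshold = abs_threshold,
                       cdf = ga$cdf_at_threshold),
      gamma_rel = list(shape = gre$shape, scale = gre$scale,
                       threshold = rel_threshold,
                       cdf = gre$cdf_at_threshold))
  }

  out <- list(
    config = list(k = k, n = n, tau = tau, ema_mode = ema_mode,
                  kernel_mode = kernel_mode, warmup = warmup,
                  trim_rate = trim_rate, abs_threshold = abs_threshold,
                  rel_threshold = rel_threshold),
    patients = patients, groups = groups)

  mae_by_group <- lapply(split(
    vapply(patients, function(p) p$mae, numeric(1)),
    vapply(patients, function(p) p$group, character(1))), unname)
  # canonical clinical order; the stabilized group is the natural reference
  canon <- intersect(c("stabilized", "intolerant", "near_death", "unknown"),
                     names(mae_by_group))
  mae_by_group <- mae_by_group[canon]
  mae_by_group <- mae_by_group[lengths(mae_by_group) >= 2]
  if (length(mae_by_group) >= 2) {
    av <- anova_oneway(mae_by_group)
    ref_name <- names(mae_by_group)[1]
    ht <- holm_ttests(mae_by_group[[1]], mae_by_group[-1], paired = FALSE)
    out$comparison <- list(metric = "mae", anova = av,
                           reference = ref_name, holm = ht)
  }
  class(out) <- "cohort_report"
  out
}

#' Write a cohort report as JSON
#'
#' @param report A [cohort_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Flatten a cohort report to one row per patient x method x metric
#'
#' @param report A [cohort_report()].
#' @return A data frame with columns `patient_id`, `group`, `method`,
#'   `metric`, `value`.
#' @export
flatten_report <- function(report) {
  metrics <- c("mae", "mape", "mse", "r2")
  rows <- lapply(names(report$patients), function(id) {
    p <- report$patients[[id]]
    data.frame(patient_id = id, group = p$group, method = "emd",
               metric = metrics,
               value = unlist(p[metrics], use.names = FALSE))
  })
  do.call(rbind, rows)
}
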