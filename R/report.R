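#' Write a cohort metrics report
#'
#' Serializes a list of plan comparisons as a long-format table (one row
#' per plan, structure and metric) with a cohort summary (mean and SD per
#' structure/metric), as CSV for humans and JSON for exact round-trips.
#'
#' @param comparisons Non-empty list of `plan_comparison`.
#' @param path Output directory (created if needed).
#' @return Invisibly, a list with `detail` and `summary` data.frames.
#' @export
write_metrics_report <- function(comparisons, path) {
  if (length(comparisons) == 0) stop("empty comparison list", call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  detail <- do.call(rbind, lapply(comparisons, function(cmp) {
    rows <- rbind(
      data.frame(plan_id = cmp$plan_id, structure = "ptv",
                 metric = paste0("delta_", cmp$ptv$metric, "_pct"),
                 predicted = cmp$ptv$pred_Gy, reference = cmp$ptv$ref_Gy,
                 delta = cmp$ptv$delta_pct),
      if (!is.null(cmp$oar) && nrow(cmp$oar) > 0) rbind(
        data.frame(plan_id = cmp$plan_id, structure = cmp$oar$structure,
                   metric = "delta_dmean_Gy",
                   predicted = cmp$oar$dmean_pred_Gy, reference = cmp$oar$dmean_ref_Gy,
                   delta = cmp$oar$delta_dmean_Gy),
        data.frame(plan_id = cmp$plan_id, structure = cmp$oar$structure,
                   metric = "delta_dmax_Gy",
                   predicted = cmp$oar$dmax_pred_Gy, reference = cmp$oar$dmax_ref_Gy,
                   delta = cmp$oar$delta_dmax_Gy)
      ),
      data.frame(plan_id = cmp$plan_id, structure = "body",
                 metric = "voxel_mean_diff_Gy",
                 predicted = NA_real_, reference = NA_real_,
                 delta = cmp$voxel_mean_diff_Gy)
    )
    rows
  }))
  agg <- stats::aggregate(delta ~ structure + metric, detail,
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  summary <- data.frame(structure = agg$structure, metric = agg$metric,
                        mean = agg$delta[, "mean"], sd = agg$delta[, "sd"])
  utils::write.csv(detail, file.path(path, "metrics_detail.csv"), row.names = FALSE)
  utils::write.csv(summary, file.path(path, "metrics_summary.csv"), row.names = FALSE)
  jsonlite::write_json(list(detail = detail, summary = summary),
                       file.path(path, "metrics.json"), digits = I(17), na = "null")
  invisible(list(detail = detail, summary = summary))
}
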