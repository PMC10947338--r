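#' Cumulative dose-volume histogram
#'
#' Fraction of a structure's volume receiving at least each dose level,
#' on a regular grid of bin edges from 0 to beyond the maximum dose.
#'
#' @param dose Dose [volume_grid()] (or 3D array) in Gy.
#' @param mask Non-empty [structure_mask()] (or 0/1 array).
#' @param bin_width_Gy Dose bin width (> 0), default 0.1 Gy.
#' @param name Structure name for labelling.
#' @return An object of class `dvh_curve` with `dose_Gy` (bin edges) and
#'   `volume_fraction` (monotone non-increasing, 1 at dose 0).
#' @export
compute_dvh <- function(dose, mask, bin_width_Gy = 0.1,
                        name = if (inherits(mask, "structure_mask")) mask$name else "structure") {
  if (inherits(dose, "volume_grid")) dose <- dose$values
  if (inherits(mask, "volume_grid")) mask <- mask$values
  if (bin_width_Gy <= 0) stop("bin width must be > 0", call. = FALSE)
  vals <- dose[mask != 0]
  if (length(vals) == 0) stop("empty mask", call. = FALSE)
  edges <- seq(0, ceiling(max(vals) / bin_width_Gy + 1) * bin_width_Gy, by = bin_width_Gy)
  frac <- vapply(edges, function(e) mean(vals >= e), numeric(1))
  structure(list(structure = name, dose_Gy = edges, volume_fraction = frac),
            class = "dvh_curve")
}

#' @export
plot.dvh_curve <- function(x, add = FALSE, col = 1, lty = 1, ...) {
  if (add) {
    graphics::lines(x$dose_Gy, 100 * x$volume_fraction, col = col, lty = lty, ...)
  } else {
    graphics::plot(x$dose_Gy, 100 * x$volume_fraction, type = "l", col = col, lty = lty,
                   xlab = "Dose (Gy)", ylab = "Volume (%)",
                   main = x$structure, ylim = c(0, 100), ...)
  }
  invisible(x)
}

#' Conformity index (CI)
#'
#' Ratio of the PTV volume covered by the reference isodose to the total
#' reference-isodose volume, `CI = TV_RI / V_RI` (voxel counting). The
#' routine reference isodose is 95% of the prescription (42.75 Gy for a
#' 45 Gy plan).
#'
#' @param dose Dose [volume_grid()] (or array).
#' @param ptv PTV [structure_mask()] (or 0/1 array).
#' @param reference_isodose_Gy Reference isodose level (> 0).
#' @return CI in \[0, 1\].
#' @export
conformity_index <- function(dose, ptv, reference_isodose_Gy) {
  if (inherits(dose, "volume_grid")) dose <- dose$values
  if (inherits(ptv, "volume_grid")) ptv <- ptv$values
  if (reference_isodose_Gy <= 0) stop("isodose level must be > 0", call. = FALSE)
  ri <- dose >= reference_isodose_Gy
  v_ri <- sum(ri)
  if (v_ri == 0)
    stop("no voxel reaches the reference isodose; CI is undefined", call. = FALSE)
  sum(ri & ptv != 0) / v_ri
}

#' Homogeneity index (HI)
#'
#' `HI = D5% / D95%` of the PTV; 1 means a perfectly homogeneous target
#' dose, and HI >= 1 always (percentile monotonicity).
#'
#' @inheritParams conformity_index
#' @return HI >= 1.
#' @export
homogeneity_index <- function(dose, ptv) {
  d95 <- dose_percentile(dose, ptv, 95)
  if (d95 <= 0) stop("D95% must be positive for HI", call. = FALSE)
  dose_percentile(dose, ptv, 5) / d95
}

#' Scalar dose metrics for one structure
#'
#' @param dose Dose [volume_grid()] (or array).
#' @param mask Non-empty mask.
#' @param vx_levels_Gy Dose levels for `V_x` (volume fraction >= x Gy).
#' @return List with `Dmean`, `Dmax`, `D1`, `D5`, `D50`, `D95`, `D98`
#'   (Gy) and `V_<x>Gy` fractions.
#' @export
dose_metrics <- function(dose, mask, vx_levels_Gy = c(40)) {
  if (inherits(dose, "volume_grid")) dose <- dose$values
  if (inherits(mask, "volume_grid")) mask <- mask$values
  vals <- dose[mask != 0]
  if (length(vals) == 0) stop("empty mask", call. = FALSE)
  out <- list(Dmean = mean(vals), Dmax = max(vals),
              D1 = dose_percentile(dose, mask, 1),
              D5 = dose_percentile(dose, mask, 5),
              D50 = dose_percentile(dose, mask, 50),
              D95 = dose_percentile(dose, mask, 95),
              D98 = dose_percentile(dose, mask, 98))
  for (x in vx_levels_Gy) out[[sprintf("V_%gGy", x)]] <- mean(vals >= x)
  out
}

#' Predicted-vs-reference plan comparison
#'
#' Computes the target percentage dose differences
#' `dD_V%(%) = (D_V%(pred) - D_V%(ref)) / D_V%(ref) * 100` for D1%, D95%
#' and D98%, the organ-at-risk differences in mean and maximum dose (Gy),
#' and the voxel-wise mean dose difference over the body.
#'
#' @param pred,reference Predicted and reference dose [volume_grid()].
#' @param structures Named list of [structure_mask()] including `ptv`;
#'   `body` (if present) defines the voxel-wise comparison region and is
#'   excluded from the OAR table.
#' @param plan_id Optional identifier carried into reports.
#' @return An object of class `plan_comparison` with elements `ptv`
#'   (data.frame of percentage deltas), `oar` (data.frame of Gy deltas
#'   plus predicted metrics), `voxel_mean_diff_Gy`, `plan_id`.
#' @export
plan_dose_deltas <- function(pred, reference, structures, plan_id = "plan") {
  stop_if_geometry_mismatch(pred, reference, "prediction and reference")
  if (is.null(structures[["ptv"]])) stop("structures must include 'ptv'", call. = FALSE)
  ptv <- structures[["ptv"]]
  ptv_rows <- do.call(rbind, lapply(c(1, 95, 98), function(V) {
    dp <- dose_percentile(pred, ptv, V)
    dr <- dose_percentile(reference, ptv, V)
    data.frame(metric = sprintf("D%d%%", V), pred_Gy = dp, ref_Gy = dr,
               delta_pct = (dp - dr) / dr * 100)
  }))
  oar_names <- setdiff(names(structures), c("ptv", "body"))
  oar_names <- oar_names[vapply(oar_names, function(nm) sum(structures[[nm]]$values) > 0,
                                logical(1))]
  oar <- do.call(rbind, lapply(oar_names, function(nm) {
    mp <- dose_metrics(pred, structures[[nm]])
    mr <- dose_metrics(reference, structures[[nm]])
    data.frame(structure = nm,
               dmean_pred_Gy = mp$Dmean, dmean_ref_Gy = mr$Dmean,
               delta_dmean_Gy = mp$Dmean - mr$Dmean,
               dmax_pred_Gy = mp$Dmax, dmax_ref_Gy = mr$Dmax,
               delta_dmax_Gy = mp$Dmax - mr$Dmax,
               d50_pred_Gy = mp$D50)
  }))
  region <- if (!is.null(structures[["body"]])) structures[["body"]]$values != 0
            else array(TRUE, dim(pred$values))
  structure(
    list(plan_id = plan_id, ptv = ptv_rows, oar = oar,
         voxel_mean_diff_Gy = mean(pred$values[region] - reference$values[region])),
    class = "plan_comparison"
  )
}

#' Paired two one-sided t-test (TOST) for dose equivalence
#'
#' Tests whether the mean paired difference `pred - ref` lies within
#' `(-bound, +bound)`: one-sided t-tests of mean > -bound and
#' mean < +bound, each at level `alpha`. The verdict is "equivalent" iff
#' both reject, i.e. `max(p_lower, p_upper) < alpha`. With zero variance
#' the t statistic is undefined and the verdict falls back to
#' `|mean| < bound`.
#'
#' @param pred,ref Paired numeric vectors (>= 3 pairs).
#' @param bound_Gy Equivalence bound (> 0), default 1 Gy.
#' @param alpha Test level, default 0.05.
#' @return An object of class `equivalence_result` with the mean
#'   difference, its standard error, both t statistics and p-values, the
#'   bound, and the logical `equivalent`.
#' @export
tost_equivalence <- function(pred, ref, bound_Gy = 1.0, alpha = 0.05) {
  if (length(pred) != length(ref)) stop("pred and ref must be paired", call. = FALSE)
  n <- length(pred)
  if (n < 3) stop("at least 3 pairs are required", call. = FALSE)
  if (bound_Gy <= 0) stop("equivalence bound must be > 0", call. = FALSE)
  d <- pred - ref
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    eq <- abs(m) < bound_Gy
    res <- list(mean_diff_Gy = m, se_Gy = 0,
                t_lower = if (m > -bound_Gy) Inf else -Inf,
                t_upper = if (m < bound_Gy) -Inf else Inf,
                p_lower = as.numeric(m <= -bound_Gy),
                p_upper = as.numeric(m >= bound_Gy),
                bound_Gy = bound_Gy, alpha = alpha, n = n, equivalent = eq)
    return(structure(res, class = "equivalence_result"))
  }
  lo <- stats::t.test(d, mu = -bound_Gy, alternative = "greater")
  hi <- stats::t.test(d, mu = bound_Gy, alternative = "less")
  structure(
    list(mean_diff_Gy = m, se_Gy = s / sqrt(n),
         t_lower = unname(lo$statistic), t_upper = unname(hi$statistic),
         p_lower = lo$p.value, p_upper = hi$p.value,
         bound_Gy = bound_Gy, alpha = alpha, n = n,
         equivalent = max(lo$p.value, hi$p.value) < alpha),
    class = "equivalence_result"
  )
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf("TOST: mean diff %.3f Gy (se %.3f, n %d), bound %.2f Gy: %s (p = %.3g)\n",
              x$mean_diff_Gy, x$se_Gy, x$n, x$bound_Gy,
              if (x$equivalent) "equivalent" else "not equivalent",
              max(x$p_lower, x$p_upper)))
  invisible(x)
}

#' Isodose volume
#'
#' Mask of voxels receiving at least `level_Gy`; may be empty.
#'
#' @param dose Dose [volume_grid()].
#' @param level_Gy Dose level (> 0).
#' @return A [structure_mask()] named `isodose_<level>`.
#' @export
isodose_volume <- function(dose, level_Gy) {
  if (level_Gy <= 0) stop("isodose level must be > 0", call. = FALSE)
  structure_mask(sprintf("isodose_%g", level_Gy), (dose$values >= level_Gy) * 1,
                 dose$spacing, dose$origin)
}

#' Flag an improvable plan and extract replanning objectives
#'
#' A plan is flagged when the prediction indicates meaningfully better
#' organ-at-risk sparing than the reference plan: any OAR with
#' `dDmean <= -theta_mean` or `dDmax <= -theta_max`. For each flagged OAR
#' a max-dose point objective (at the predicted maximum dose) and a
#' max-DVH point objective (at the predicted median dose, volume 50%) are
#' emitted, optionally scaled by a push factor <= 1 to push slightly
#' beyond the prediction. In addition, dose fall-off planning structures
#' `body - isodose_volume(pred, L)` are created for each configured level
#' `L` with a max-dose objective of `L` on the structure.
#'
#' @param comparison A `plan_comparison` from [plan_dose_deltas()].
#' @param pred_dose Predicted dose [volume_grid()].
#' @param body Body [structure_mask()].
#' @param thresholds List with `theta_mean_Gy` (default 2), `theta_max_Gy`
#'   (default 3), `push` (scale factor <= 1, default 1),
#'   `falloff_levels_Gy` (default `c(40, 30, 20)`),
#'   `max_dvh_volume` (default 0.5).
#' @return List with logical `flag` and `objectives`, a list of
#'   `replan_objective` entries (`kind`, `structure`, `dose_Gy`,
#'   `volume_fraction`, and for fall-off structures the derived `mask`).
#' @export
flag_and_extract_objectives <- function(comparison, pred_dose, body,
                                        thresholds = list()) {
  th <- utils::modifyList(
    list(theta_mean_Gy = 2, theta_max_Gy = 3, push = 1.0,
         falloff_levels_Gy = c(40, 30, 20), max_dvh_volume = 0.5),
    thresholds
  )
  stopifnot(th$push > 0, th$push <= 1)
  oar <- comparison$oar
  flagged <- oar[oar$delta_dmean_Gy <= -th$theta_mean_Gy |
                 oar$delta_dmax_Gy <= -th$theta_max_Gy, , drop = FALSE]
  objectives <- list()
  for (i in seq_len(nrow(flagged))) {
    o <- flagged[i, ]
    objectives[[length(objectives) + 1L]] <- structure(
      list(kind = "max_dose", structure = o$structure,
           dose_Gy = th$push * o$dmax_pred_Gy, volume_fraction = NA_real_),
      class = "replan_objective")
    objectives[[length(objectives) + 1L]] <- structure(
      list(kind = "max_dvh", structure = o$structure,
           dose_Gy = th$push * o$d50_pred_Gy, volume_fraction = th$max_dvh_volume),
      class = "replan_objective")
  }
  flag <- nrow(flagged) > 0
  if (flag) {
    for (L in th$falloff_levels_Gy) {
      iso <- isodose_volume(pred_dose, L)
      falloff <- structure_mask(sprintf("body_minus_isodose_%g", L),
                                pmax(body$values - iso$values, 0),
                                body$spacing, body$origin)
      objectives[[length(objectives) + 1L]] <- structure(
        list(kind = "dose_falloff_structure", structure = falloff$name,
             dose_Gy = L, volume_fraction = NA_real_, mask = falloff),
        class = "replan_objective")
    }
  }
  list(flag = flag, objectives = objectives)
}
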