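#' Dose percentile D_V% of a structure
#'
#' `D_V%` is the minimum dose received by the hottest V% of a structure's
#' volume: the `ceil(V * N / 100)`-th largest dose among the N masked
#' voxels. `D1%` is a near-maximum metric; `D95%`/`D98%` measure target
#' coverage. The estimator is exact (sort-based), not binned.
#'
#' @param dose Dose [volume_grid()] (or 3D array) in Gy.
#' @param mask [structure_mask()] (or 0/1 array), non-empty.
#' @param V Volume percentage in (0, 100].
#' @return Dose in Gy.
#' @export
dose_percentile <- function(dose, mask, V) {
  if (inherits(dose, "volume_grid")) dose <- dose$values
  if (inherits(mask, "volume_grid")) mask <- mask$values
  if (V <= 0 || V > 100) stop("V must lie in (0, 100]", call. = FALSE)
  vals <- dose[mask != 0]
  n <- length(vals)
  if (n == 0) stop("empty mask", call. = FALSE)
  k <- ceiling(V * n / 100)
  sort(vals, decreasing = TRUE)[k]
}

#' Loss configuration
#'
#' Weights of the combined mean-squared-error plus target-DVH training
#' loss: `MSE + dvh_weight * sum_V |D_V%(pred) - D_V%(ref)|` over the PTV
#' percentiles `target_percentiles`.
#'
#' @param dvh_weight Non-negative weight of the DVH term (default 0.25).
#' @param target_percentiles Percentiles (in (0, 100)) entering the DVH
#'   term; default D1%, D95%, D98%.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(dvh_weight = 0.25, target_percentiles = c(1, 95, 98)) {
  if (dvh_weight < 0) stop("dvh_weight must be >= 0", call. = FALSE)
  if (any(target_percentiles <= 0 | target_percentiles >= 100))
    stop("target percentiles must lie in (0, 100)", call. = FALSE)
  structure(list(dvh_weight = dvh_weight, target_percentiles = target_percentiles),
            class = "loss_config")
}

#' Combined MSE + target-DVH loss
#'
#' The training objective: mean squared voxel error over the compared
#' region plus the weighted sum of absolute differences in the PTV
#' percentile metrics. The percentile terms use the exact sort-based
#' `D_V%`; their subgradient flows to the selected voxel, which makes the
#' loss usable as a training objective. Patches containing no PTV voxel
#' contribute the MSE term only.
#'
#' @param pred,reference Predicted and reference dose ([volume_grid()] or
#'   arrays) sharing one geometry.
#' @param ptv PTV [structure_mask()] (or 0/1 array) on the same grid.
#' @param cfg A [loss_config()].
#' @param gradient If `TRUE`, also return the gradient with respect to
#'   `pred`.
#' @return The scalar loss, or (with `gradient = TRUE`) a list with
#'   `loss` and `grad`.
#' @export
combined_loss <- function(pred, reference, ptv, cfg = loss_config(), gradient = FALSE) {
  if (inherits(pred, "volume_grid") && inherits(reference, "volume_grid"))
    stop_if_geometry_mismatch(pred, reference, "prediction and reference")
  p <- if (inherits(pred, "volume_grid")) pred$values else pred
  r <- if (inherits(reference, "volume_grid")) reference$values else reference
  m <- if (inherits(ptv, "volume_grid")) ptv$values else ptv
  if (!identical(dim(p), dim(r))) stop("geometry mismatch", call. = FALSE)
  n <- length(p)
  diffs <- p - r
  loss <- mean(diffs^2)
  grad <- if (gradient) 2 * diffs / n else NULL

  idx <- which(m != 0)
  if (length(idx) > 0 && cfg$dvh_weight > 0) {
    pm <- p[idx]
    rm <- r[idx]
    ord <- order(pm, decreasing = TRUE)
    rs <- sort(rm, decreasing = TRUE)
    for (V in cfg$target_percentiles) {
      k <- ceiling(V * length(idx) / 100)
      dv <- pm[ord[k]] - rs[k]
      loss <- loss + cfg$dvh_weight * abs(dv)
      if (gradient) {
        i <- idx[ord[k]]
        grad[i] <- grad[i] + cfg$dvh_weight * sign(dv)
      }
    }
  }
  if (gradient) list(loss = loss, grad = grad) else loss
}
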