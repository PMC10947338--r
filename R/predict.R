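#' Overlapping-patch specification
#'
#' Inference tiles each plan into overlapping cubic patches (stride 16 by
#' default); every voxel's prediction is the arithmetic mean over all
#' covering (model, patch) predictions.
#'
#' @param size Patch edge length in voxels.
#' @param stride Offset between consecutive patches, in `[1, size]`.
#' @param aggregation Aggregation of overlapping predictions (`"mean"`).
#' @return An object of class `patch_spec`.
#' @export
patch_spec <- function(size = 64L, stride = 16L, aggregation = "mean") {
  size <- as.integer(size); stride <- as.integer(stride)
  if (stride < 1L || stride > size)
    stop("stride must lie in [1, size]", call. = FALSE)
  aggregation <- match.arg(aggregation, "mean")
  structure(list(size = size, stride = stride, aggregation = aggregation),
            class = "patch_spec")
}

#' Enumerate overlapping patch offsets
#'
#' Per-axis offsets are `0, stride, 2 * stride, ...` with the final offset
#' clamped to `axis_len - size` so the last patch abuts the grid boundary
#' (no padding); every voxel is covered by at least one patch and offsets
#' are unique.
#'
#' @param grid_shape Integer grid shape (length 3).
#' @param spec A [patch_spec()].
#' @return Integer matrix of 0-based offsets, one row per patch.
#' @export
tile_patches <- function(grid_shape, spec = patch_spec()) {
  grid_shape <- rep_len(as.integer(grid_shape), 3L)
  if (any(spec$size > grid_shape))
    stop("patch size exceeds grid shape", call. = FALSE)
  axis_offsets <- lapply(grid_shape, function(n) {
    last <- n - spec$size
    unique(c(seq.int(0L, last, by = spec$stride), last))
  })
  g <- expand.grid(x = axis_offsets[[1]], y = axis_offsets[[2]], z = axis_offsets[[3]],
                   KEEP.OUT.ATTRS = FALSE)
  as.matrix(g)
}

#' Predict a full dose volume with an ensemble of models
#'
#' Runs every overlapping patch through every model and averages all
#' predictions voxel-wise (mean over models and covering patches). The
#' output is non-negative by construction of the network head.
#'
#' @param models A `dose_net` or list of `dose_net` (>= 1).
#' @param sample A `plan_sample` whose channels conform to the training
#'   layout.
#' @param spec A [patch_spec()].
#' @return Predicted dose [volume_grid()] in Gy.
#' @export
predict_volume <- function(models, sample, spec = patch_spec()) {
  if (inherits(models, "dose_net")) models <- list(models)
  if (length(models) == 0) stop("at least one model is required", call. = FALSE)
  x <- channel_stack(sample)
  d <- dim(x)[1:3]
  offs <- tile_patches(d, spec)
  acc <- array(0, d)
  cnt <- array(0, d)
  for (m in models) {
    for (r in seq_len(nrow(offs))) {
      o <- offs[r, ]
      ix <- o[1] + seq_len(spec$size); iy <- o[2] + seq_len(spec$size)
      iz <- o[3] + seq_len(spec$size)
      patch <- x[ix, iy, iz, , drop = FALSE]
      pred <- net_predict_array(m, patch)
      acc[ix, iy, iz] <- acc[ix, iy, iz] + pred
      cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
    }
  }
  volume_grid(acc / cnt, sample$reference_dose$spacing, sample$reference_dose$origin)
}

#' Renormalize a predicted dose to the reference D95
#'
#' Scales the whole predicted volume by `D95(reference) / D95(pred)` over
#' the PTV, so the prediction achieves the same 95% target coverage as
#' the reference plan.
#'
#' @param pred Predicted dose [volume_grid()].
#' @param reference Reference dose [volume_grid()] on the same grid.
#' @param ptv PTV [structure_mask()].
#' @return The renormalized dose [volume_grid()].
#' @export
normalize_to_reference_d95 <- function(pred, reference, ptv) {
  stop_if_geometry_mismatch(pred, reference, "prediction and reference")
  d95_pred <- dose_percentile(pred, ptv, 95)
  if (d95_pred <= 0) stop("predicted D95 is zero; cannot renormalize", call. = FALSE)
  d95_ref <- dose_percentile(reference, ptv, 95)
  volume_grid(pred$values * (d95_ref / d95_pred), pred$spacing, pred$origin)
}
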