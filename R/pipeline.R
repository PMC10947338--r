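#' Normalize a CT volume to [0, 1]
#'
#' Crops voxel intensities to \[-1000, 1000\] HU and rescales linearly to
#' \[0, 1\]: `out = (clip(x, -1000, 1000) + 1000) / 2000`.
#'
#' @param ct A [volume_grid()] in Hounsfield units.
#' @return A [volume_grid()] with values in \[0, 1\].
#' @export
normalize_ct <- function(ct) {
  x <- ct$values
  if (any(is.na(x)) || any(!is.finite(x)))
    stop("CT contains NaN or non-finite values", call. = FALSE)
  volume_grid((pmin(pmax(x, -1000), 1000) + 1000) / 2000, ct$spacing, ct$origin)
}

#' Build the target input channel
#'
#' The target array is the PTV mask carrying the prescription dose: voxels
#' inside the PTV take the prescription value (Gy), all others 0.
#'
#' @param ptv PTV [structure_mask()] (non-empty).
#' @param prescription_Gy Prescription dose (> 0).
#' @return A [volume_grid()].
#' @export
build_target_channel <- function(ptv, prescription_Gy) {
  if (sum(ptv$values) == 0) stop("empty PTV", call. = FALSE)
  if (prescription_Gy <= 0) stop("prescription must be > 0", call. = FALSE)
  volume_grid(ptv$values * prescription_Gy, ptv$spacing, ptv$origin)
}

#' Resample a volume or mask to a new voxel spacing
#'
#' Continuous volumes (CT, dose) are resampled with trilinear
#' interpolation; label masks with nearest-neighbour interpolation, which
#' preserves binarity. The new grid covers the same physical extent
#' (within one voxel) and is centre-aligned with the old grid.
#'
#' @param v A [volume_grid()] or [structure_mask()].
#' @param target_spacing_mm New per-axis spacing (length 1 or 3, > 0).
#' @param mode `"continuous"` (trilinear) or `"label"` (nearest-neighbour);
#'   defaults to `"label"` for `structure_mask` inputs.
#' @return Object of the same class as `v` on the new grid.
#' @export
resample_volume <- function(v, target_spacing_mm,
                            mode = if (inherits(v, "structure_mask")) "label" else "continuous") {
  mode <- match.arg(mode, c("continuous", "label"))
  new_sp <- rep_len(as.numeric(target_spacing_mm), 3L)
  if (any(new_sp <= 0)) stop("target spacing must be > 0", call. = FALSE)
  old_sp <- v$spacing
  n_old <- dim(v$values)
  extent <- n_old * old_sp
  n_new <- pmax(1L, as.integer(round(extent / new_sp)))
  # centre alignment: voxel-centre grids share their midpoint
  shift <- ((n_old - 1) * old_sp - (n_new - 1) * new_sp) / 2
  new_origin <- v$origin + shift

  src <- lapply(1:3, function(a) {
    w <- (seq_len(n_new[a]) - 1) * new_sp[a] + shift[a]
    pmin(pmax(w / old_sp[a], 0), n_old[a] - 1)  # fractional 0-based source index
  })

  if (mode == "label") {
    ix <- round(src[[1]]) + 1L; iy <- round(src[[2]]) + 1L; iz <- round(src[[3]]) + 1L
    out <- v$values[ix, iy, iz, drop = FALSE]
    dim(out) <- n_new
  } else {
    interp1 <- function(arr, t, axis) {
      lo <- floor(t); fr <- t - lo
      i0 <- as.integer(lo) + 1L
      i1 <- pmin(i0 + 1L, dim(arr)[axis])
      take <- function(i) {
        idx <- list(quote(expr =), quote(expr =), quote(expr =))
        idx[[axis]] <- i
        do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
      }
      a0 <- take(i0); a1 <- take(i1)
      w <- array(rep(fr, each = prod(dim(a0)[seq_len(axis - 1)])), dim = dim(a0))
      a0 * (1 - w) + a1 * w
    }
    out <- interp1(v$values, src[[1]], 1L)
    out <- interp1(out, src[[2]], 2L)
    out <- interp1(out, src[[3]], 3L)
    dim(out) <- n_new
  }
  if (inherits(v, "structure_mask")) structure_mask(v$name, out, new_sp, new_origin)
  else volume_grid(out, new_sp, new_origin)
}

#' Assemble the 16-channel model input for one plan
#'
#' Stacks the normalized CT, the target array and the 14 structure masks
#' (in the fixed [channel_order()]) together with the reference dose grid.
#' A structure missing from `masks` is replaced by an all-zero mask with a
#' warning; a name outside the vocabulary is an error.
#'
#' @param ct Normalized CT [volume_grid()] (values in \[0, 1\]).
#' @param ptv PTV [structure_mask()].
#' @param masks Named list of [structure_mask()] covering
#'   [structure_vocabulary()] (must include `body`).
#' @param prescription_Gy Prescription dose (> 0).
#' @param dose Reference dose [volume_grid()] in Gy.
#' @param plan_id Optional plan identifier.
#' @return An object of class `plan_sample` with fields `plan_id`,
#'   `prescription_Gy`, `channels` (named list of 16 [volume_grid()]),
#'   `reference_dose`, `ptv_mask`, `body_mask`.
#' @export
assemble_inputs <- function(ct, ptv, masks, prescription_Gy, dose, plan_id = "plan") {
  if (any(ct$values < 0 | ct$values > 1))
    stop("CT channel must be normalized to [0, 1]", call. = FALSE)
  unknown <- setdiff(names(masks), structure_vocabulary())
  if (length(unknown))
    stop(sprintf("unknown structure name(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  if (is.null(masks[["body"]])) stop("a body mask is required", call. = FALSE)
  stop_if_geometry_mismatch(ct, ptv, "CT and PTV")
  stop_if_geometry_mismatch(ct, dose, "CT and dose")
  for (nm in names(masks)) stop_if_geometry_mismatch(ct, masks[[nm]], paste("CT and", nm))

  channels <- list(ct = ct, target = build_target_channel(ptv, prescription_Gy))
  for (nm in structure_vocabulary()) {
    m <- masks[[nm]]
    if (is.null(m)) {
      warning(sprintf("structure '%s' missing; using an all-zero mask", nm), call. = FALSE)
      m <- structure_mask(nm, array(0, dim(ct$values)), ct$spacing, ct$origin)
    }
    channels[[nm]] <- volume_grid(m$values, m$spacing, m$origin)
  }
  stopifnot(identical(names(channels), channel_order()))
  structure(
    list(plan_id = plan_id, prescription_Gy = prescription_Gy,
         channels = channels, reference_dose = dose,
         ptv_mask = ptv, body_mask = masks[["body"]]),
    class = "plan_sample"
  )
}

#' @export
print.plan_sample <- function(x, ...) {
  cat(sprintf("<plan_sample '%s'> %d channels, %s voxels, Rx %.4g Gy, PTV %d voxels\n",
              x$plan_id, length(x$channels),
              paste(dim(x$reference_dose$values), collapse = "x"),
              x$prescription_Gy, sum(x$ptv_mask$values)))
  invisible(x)
}

# Stack the 16 channels into a (x, y, z, 16) array for the network.
channel_stack <- function(sample) {
  d <- dim(sample$channels[[1]]$values)
  out <- array(0, c(d, length(sample$channels)))
  for (i in seq_along(sample$channels)) out[, , , i] <- sample$channels[[i]]$values
  out
}

#' Write / read a plan sample as NIfTI volumes plus a JSON manifest
#'
#' Each channel and the reference dose are written as one `.nii.gz` per
#' volume; the manifest records plan id, prescription and channel order.
#'
#' @param sample A `plan_sample`.
#' @param dir Output directory (one subdirectory per plan).
#' @return The plan directory (`write_plan_sample`) or the re-read
#'   `plan_sample` (`read_plan_sample`).
#' @export
write_plan_sample <- function(sample, dir) {
  pdir <- file.path(dir, sample$plan_id)
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(sample$channels))
    write_volume(sample$channels[[nm]], file.path(pdir, paste0(nm, ".nii.gz")))
  write_volume(sample$reference_dose, file.path(pdir, "dose.nii.gz"))
  write_volume(sample$ptv_mask, file.path(pdir, "ptv.nii.gz"))
  manifest <- list(plan_id = sample$plan_id,
                   prescription_Gy = sample$prescription_Gy,
                   channel_order = channel_order(),
                   spacing_mm = sample$reference_dose$spacing,
                   origin_mm = sample$reference_dose$origin)
  jsonlite::write_json(manifest, file.path(pdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(pdir)
}

#' @rdname write_plan_sample
#' @param plan_dir Directory written by `write_plan_sample`.
#' @export
read_plan_sample <- function(plan_dir) {
  man <- jsonlite::read_json(file.path(plan_dir, "manifest.json"), simplifyVector = TRUE)
  origin <- as.numeric(man$origin_mm)
  rd <- function(nm, mask = FALSE) {
    read_volume(file.path(plan_dir, paste0(nm, ".nii.gz")),
                mask_name = if (mask) nm else NULL, origin = origin)
  }
  ct <- rd("ct")
  ptv <- rd("ptv", mask = TRUE)
  ptv$name <- "ptv"
  masks <- lapply(structure_vocabulary(), function(nm) rd(nm, mask = TRUE))
  names(masks) <- structure_vocabulary()
  dose <- rd("dose")
  assemble_inputs(ct, ptv, masks, man$prescription_Gy, dose, plan_id = man$plan_id)
}
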