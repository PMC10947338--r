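#' Create a 3D scalar volume on a regular grid
#'
#' A `volume_grid` is the basic spatial container of the package: a 3D array
#' of scalar values (CT intensities, normalized units, or dose in Gy) with
#' per-axis voxel spacing and a world origin. Voxel indices are 0-based for
#' world-coordinate purposes: the centre of voxel `(i, j, k)` (0-based) lies
#' at `origin + c(i, j, k) * spacing` (mm).
#'
#' @param values 3D numeric array.
#' @param spacing Per-axis voxel spacing in mm (length 1 or 3, all > 0).
#' @param origin World coordinate (mm) of the first voxel centre (length 3).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing = 3, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be positive and finite on every axis", call. = FALSE)
  if (any(!is.finite(values)))
    stop("`values` must be finite everywhere", call. = FALSE)
  structure(
    list(values = values, spacing = spacing, origin = rep_len(as.numeric(origin), 3L)),
    class = "volume_grid"
  )
}

#' Create a named binary structure mask
#'
#' A `structure_mask` shares the geometry of its companion [volume_grid()]
#' and stores a 0/1 indicator of structure membership (PTV, an organ at
#' risk, a bony structure, or the body contour).
#'
#' @param name Structure name (one of [structure_vocabulary()] or `"ptv"`).
#' @param values 3D array with values in \{0, 1\}.
#' @inheritParams volume_grid
#' @return An object of class `structure_mask` (also a `volume_grid`).
#' @export
structure_mask <- function(name, values, spacing = 3, origin = c(0, 0, 0)) {
  if (!all(values %in% c(0, 1)))
    stop("mask values must be 0 or 1", call. = FALSE)
  v <- volume_grid(values, spacing, origin)
  v$name <- as.character(name)
  class(v) <- c("structure_mask", "volume_grid")
  v
}

#' @export
print.volume_grid <- function(x, ...) {
  kind <- if (inherits(x, "structure_mask")) sprintf("structure_mask '%s'", x$name)
          else "volume_grid"
  cat(sprintf("<%s> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              kind, paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Test whether two volumes share one grid geometry
#'
#' @param a,b `volume_grid` objects.
#' @param tol Absolute tolerance on spacing and origin (mm).
#' @return `TRUE` or `FALSE`.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_geometry_mismatch <- function(a, b, what = "volumes") {
  if (!same_geometry(a, b))
    stop(sprintf("geometry mismatch: %s must share grid, spacing and origin", what),
         call. = FALSE)
  invisible(TRUE)
}

mask_indices <- function(mask) which(mask$values != 0)

#' Write a volume to a NIfTI file
#'
#' Spacing is stored in the NIfTI pixdim; the origin in the sform/qform
#' translation.
#'
#' @param v A `volume_grid` or `structure_mask`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  img <- RNifti::asNifti(v$values)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from a NIfTI file
#'
#' @param path Input path.
#' @param mask_name If non-`NULL`, return a [structure_mask()] with this name
#'   (values are binarized at 0.5).
#' @param origin World origin (mm); NIfTI offsets are not interpreted.
#' @return A `volume_grid` or `structure_mask`.
#' @export
read_volume <- function(path, mask_name = NULL, origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  arr <- array(as.numeric(img), dim = dim(img)[seq_len(3)])
  if (is.null(mask_name)) volume_grid(arr, spacing, origin)
  else structure_mask(mask_name, (arr > 0.5) * 1, spacing, origin)
}
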