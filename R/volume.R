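#' CT attenuation volume
#'
#' A minimal container for a 3-D CT attenuation grid in Hounsfield units (HU)
#' together with its voxel spacing and a reconstruction label. Voxel centres
#' are placed on a regular grid with the centre of voxel `[1, 1, 1]` at
#' physical position (0, 0, 0) mm; axis 3 is the axial (z, feet-to-head)
#' direction, so increasing slice index is more superior.
#'
#' @param values 3-D numeric array of attenuation values (HU). All values
#'   must be finite.
#' @param spacing_mm Numeric length-3 vector of voxel spacing in mm
#'   (in-plane x, in-plane y, axial z). All entries must be positive.
#' @param recon_label Character label for the reconstruction that produced
#'   the volume, e.g. `"FBP"`, `"IR"` or `"clean"` for a noise-free phantom.
#'
#' @return An object of class `ct_volume`: a list with elements `values`,
#'   `spacing_mm` and `recon_label`.
#' @export
#' @examples
#' vol <- ct_volume(array(-900, c(8, 8, 4)), spacing_mm = c(0.7, 0.7, 1))
#' vol
ct_volume <- function(values, spacing_mm, recon_label = "clean") {
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("`values` must be a 3-D array.", class = "lungqct_parameter_error")
  }
  if (!all(is.finite(values))) {
    abort("`values` must be finite.", class = "lungqct_parameter_error")
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    abort("`spacing_mm` must be 3 positive numbers.", class = "lungqct_parameter_error")
  }
  structure(
    list(values = values, spacing_mm = spacing_mm,
         recon_label = as.character(recon_label)[1]),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, recon '%s'\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
              x$recon_label))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$values)

#' Extract an axial slice from a CT volume
#'
#' Returns the 2-D in-plane image at a given slice index, keeping the in-plane
#' voxel spacing so downstream measurements work in physical mm.
#'
#' @param vol A [ct_volume()].
#' @param k Axial slice index (1-based).
#' @return An object of class `ct_slice`: a list with `values` (matrix),
#'   `spacing_mm` (length 2) and `z_mm` (physical slice position).
#' @export
axial_slice <- function(vol, k) {
  stopifnot(inherits(vol, "ct_volume"))
  d <- dim(vol$values)
  k <- as.integer(k)
  if (k < 1L || k > d[3]) {
    abort("Slice index out of range.", class = "lungqct_parameter_error")
  }
  structure(
    list(values = vol$values[, , k], spacing_mm = vol$spacing_mm[1:2],
         z_mm = (k - 1) * vol$spacing_mm[3]),
    class = "ct_slice"
  )
}

#' @export
print.ct_slice <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ct_slice> %d x %d pixels, spacing %.3g x %.3g mm, z = %.2f mm\n",
              d[1], d[2], x$spacing_mm[1], x$spacing_mm[2], x$z_mm))
  invisible(x)
}

# Bilinear interpolation of a slice at physical (x, y) mm positions.
# Positions beyond the voxel-centre grid are clamped to the border value.
interp_bilinear <- function(slice, x_mm, y_mm) {
  mat <- slice$values
  sx <- slice$spacing_mm[1]
  sy <- slice$spacing_mm[2]
  nx <- nrow(mat)
  ny <- ncol(mat)
  fx <- pmin(pmax(x_mm / sx + 1, 1), nx)
  fy <- pmin(pmax(y_mm / sy + 1, 1), ny)
  ix <- pmin(floor(fx), nx - 1L)
  iy <- pmin(floor(fy), ny - 1L)
  wx <- fx - ix
  wy <- fy - iy
  v00 <- mat[cbind(ix, iy)]
  v10 <- mat[cbind(ix + 1, iy)]
  v01 <- mat[cbind(ix, iy + 1)]
  v11 <- mat[cbind(ix + 1, iy + 1)]
  v00 * (1 - wx) * (1 - wy) + v10 * wx * (1 - wy) +
    v01 * (1 - wx) * wy + v11 * wx * wy
}

#' Read and write CT volumes as NIfTI
#'
#' Volumes are stored as NIfTI with the voxel spacing in the header. The
#' reconstruction label has no NIfTI header field, so it travels in an
#' optional JSON sidecar written next to the image (same path with a
#' `.json` extension).
#'
#' @param vol A [ct_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param sidecar Write the JSON sidecar carrying `recon_label` and
#'   `spacing_mm`? Default `TRUE`.
#' @return `write_ct_volume()` returns `path` invisibly; `read_ct_volume()`
#'   returns a [ct_volume()].
#' @export
write_ct_volume <- function(vol, path, sidecar = TRUE) {
  stopifnot(inherits(vol, "ct_volume"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing_mm
  RNifti::writeNifti(img, path)
  if (isTRUE(sidecar)) {
    jsonlite::write_json(
      list(recon_label = vol$recon_label, spacing_mm = vol$spacing_mm),
      sidecar_path(path), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' @rdname write_ct_volume
#' @param recon_label Reconstruction label to use when no sidecar is present.
#' @export
read_ct_volume <- function(path, recon_label = NULL) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  side <- sidecar_path(path)
  if (is.null(recon_label)) {
    recon_label <- if (file.exists(side)) {
      jsonlite::read_json(side)$recon_label %||% "unknown"
    } else "unknown"
  }
  ct_volume(array(as.numeric(img), dim = dim(img)[1:3]), spacing, recon_label)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write a binary mask as NIfTI
#'
#' @param mask Logical 3-D array.
#' @param spacing_mm Voxel spacing in mm.
#' @param path Output path.
#' @return `path`, invisibly. `read_mask()` returns a logical array with a
#'   `spacing_mm` attribute.
#' @export
write_mask <- function(mask, spacing_mm, path) {
  img <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)))
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img) != 0, dim = dim(img)[1:3])
  attr(out, "spacing_mm") <- RNifti::pixdim(img)[1:3]
  out
}
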