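#' Segment the lungs from a CT volume
#'
#' Threshold-and-components lung segmentation: air-like voxels (at or below
#' `air_threshold_hu`) are labeled into 26-connected 3-D components; components
#' touching the grid boundary are discarded as ambient air outside the body;
#' the airway is removed by taking the component that reaches most superior
#' (largest axial index) among the remaining air components, provided it is
#' small enough to be an airway (`airway_cap_ml`); when noise has bridged
#' the airway wall and fused lumen with lung, the airway is instead regrown
#' geodesically from the most superior air voxel at progressively stricter
#' thresholds until the region is airway-sized; the remaining large
#' components form the lungs, with small in-plane holes closed
#' morphologically.
#'
#' Failure — no lung-like component, or a lung volume outside the
#' plausibility bounds — is signaled as a typed condition of class
#' `lungqct_segmentation_failure`, so a cohort pipeline can record the subject
#' as excluded rather than silently producing an empty mask.
#'
#' @param vol A [ct_volume()] in HU.
#' @param air_threshold_hu Initial air threshold (HU); default -320.
#' @param min_component_ml Components smaller than this are ignored (ml).
#' @param airway_cap_ml Upper volume bound for the removed airway component
#'   (ml); the most-superior component is kept as lung if it exceeds this.
#' @param min_volume_ml,max_volume_ml Plausibility bounds for total lung
#'   volume (ml). Defaults span small phantoms through large human lungs;
#'   a clinical pipeline would narrow them (e.g. 2000-9000 ml).
#' @param close_holes Apply a 3x3 in-plane morphological closing? Default
#'   `TRUE`.
#' @return An object of class `lung_mask`: list with `mask` (logical array),
#'   `n_voxels`, `volume_ml` and `spacing_mm`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_params(grid_shape = c(48, 48, 48)))
#' m <- segment_lungs(ph$insp)
#' m$volume_ml
segment_lungs <- function(vol,
                          air_threshold_hu = -320,
                          min_component_ml = 1,
                          airway_cap_ml = 100,
                          min_volume_ml = 5,
                          max_volume_ml = 9000,
                          close_holes = TRUE) {
  stopifnot(inherits(vol, "ct_volume"))
  d <- dim(vol$values)
  voxvol_ml <- prod(vol$spacing_mm) / 1000
  air <- vol$values <= air_threshold_hu
  if (!any(air)) {
    seg_fail("No air-like voxels at the threshold; volume contains no lung.")
  }
  lab <- label_components_3d(air)

  border_labels <- unique(c(
    lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]
  ))
  border_labels <- border_labels[border_labels > 0L]
  sizes <- component_sizes(lab)
  # interior components: not ambient air, not sub-speck noise
  speck_voxels <- max(10, 0.05 / voxvol_ml)
  interior <- setdiff(which(sizes >= speck_voxels), border_labels)
  if (length(interior) == 0L) {
    seg_fail("No interior air component found; volume contains no lung.")
  }
  keep <- interior[sizes[interior] * voxvol_ml >= min_component_ml]
  if (length(keep) == 0L) {
    seg_fail("No interior air component large enough to be lung.")
  }

  # The component reaching most superior among all interior air components
  # is the airway candidate (an airway lumen is typically far smaller than
  # min_component_ml, so the search must not be restricted to lung-sized
  # components). If it is airway-sized, drop it; if it instead exceeds the
  # cap, the airway has fused with the lung (noise bridged the wall) and is
  # regrown geodesically from the component's most superior voxel.
  top_k <- component_top_slice(lab)[interior]
  airway_label <- interior[which.max(top_k)]
  airway_voxels <- NULL
  is_small <- sizes[airway_label] * voxvol_ml <= airway_cap_ml
  others <- setdiff(keep, airway_label)
  if (is_small && length(others) > 0L) {
    keep <- others
  } else if (!is_small || airway_label %in% keep) {
    # Either the airway fused with the lung into one component larger than
    # the cap, or the only lung-sized component itself reaches most
    # superior (a small lung with a noise-bridged lumen): carve the airway
    # out geodesically instead of discarding the component.
    airway_voxels <- grow_airway(
      vol$values, lab == airway_label,
      cap_voxels = min(airway_cap_ml / voxvol_ml, 0.5 * sizes[airway_label])
    )
  }
  if (length(keep) == 0L) {
    seg_fail("Only an airway-sized air component found; no lung.")
  }

  mask <- array(lab %in% keep, d)
  if (!is.null(airway_voxels)) mask[airway_voxels] <- FALSE
  if (isTRUE(close_holes)) {
    brush <- EBImage::makeBrush(3, shape = "box")
    for (k in seq_len(d[3])) {
      if (!any(mask[, , k])) next
      mask[, , k] <- EBImage::closing(mask[, , k] * 1, brush) > 0
    }
  }

  volume_ml <- sum(mask) * voxvol_ml
  if (volume_ml < min_volume_ml || volume_ml > max_volume_ml) {
    seg_fail(sprintf(
      "Segmented lung volume %.1f ml outside plausibility bounds [%g, %g] ml.",
      volume_ml, min_volume_ml, max_volume_ml))
  }
  new_lung_mask(mask, vol$spacing_mm)
}

new_lung_mask <- function(mask, spacing_mm) {
  structure(
    list(mask = mask, n_voxels = sum(mask),
         volume_ml = sum(mask) * prod(spacing_mm) / 1000,
         spacing_mm = spacing_mm),
    class = "lung_mask"
  )
}

#' Construct a lung mask from a logical array
#'
#' Wraps a known-good mask (for example a phantom truth mask) in the same
#' container [segment_lungs()] returns, so densitometry can be run against
#' ground truth.
#'
#' @param mask Logical 3-D array.
#' @param spacing_mm Voxel spacing (mm).
#' @return A `lung_mask`.
#' @export
as_lung_mask <- function(mask, spacing_mm) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  new_lung_mask(array(as.logical(mask), dim(mask)), as.numeric(spacing_mm))
}

#' @export
print.lung_mask <- function(x, ...) {
  cat(sprintf("<lung_mask> %d voxels, %.1f ml\n", x$n_voxels, x$volume_ml))
  invisible(x)
}

seg_fail <- function(msg) {
  abort(msg, class = "lungqct_segmentation_failure")
}

# Geodesic region growing of the airway lumen. Seeded at the most superior
# voxel of the fused air component, grown 26-connected over voxels at or
# below each threshold of a descending ladder; the first threshold whose
# region stays within `cap_voxels` wins. Returns linear voxel indices, or
# NULL when no threshold isolates an airway-sized region.
grow_airway <- function(values, component,
                        thresholds = c(-500, -650, -800),
                        cap_voxels = Inf) {
  d <- dim(values)
  comp_idx <- which(component)
  ci <- arrayInd(comp_idx, d)
  seed_row <- which.max(ci[, 3])
  seed <- ci[seed_row, , drop = FALSE]
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (thr in thresholds) {
    if (values[seed] > thr) next
    visited <- array(FALSE, d)
    visited[seed] <- TRUE
    frontier <- seed
    n_region <- 1L
    repeat {
      cand <- frontier[rep(seq_len(nrow(frontier)), each = nrow(offs)), , drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), times = nrow(frontier)), ]
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
        cand[, 2] >= 1 & cand[, 2] <= d[2] &
        cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      lin <- cand[, 1] + (cand[, 2] - 1L) * d[1] + (cand[, 3] - 1L) * d[1] * d[2]
      lin <- unique(lin[!visited[lin] & values[lin] <= thr])
      if (length(lin) == 0L) break
      visited[lin] <- TRUE
      n_region <- n_region + length(lin)
      if (n_region > cap_voxels) break
      frontier <- arrayInd(lin, d)
    }
    if (n_region <= cap_voxels) return(which(visited))
  }
  NULL
}

#' Automated quality check of a lung segmentation
#'
#' A surrogate for the visual check a reader would perform: the mask must be
#' non-empty, its volume must lie within plausibility bounds, and it must
#' not lean on the grid boundary (a mask touching the image border suggests
#' the field of view clipped the lungs or segmentation leaked into ambient
#' air).
#'
#' @param mask A `lung_mask`.
#' @param vol The [ct_volume()] the mask belongs to.
#' @param min_volume_ml,max_volume_ml Plausible lung volume bounds (ml).
#' @param max_border_fraction Maximum tolerated fraction of mask voxels lying
#'   on a grid boundary face.
#' @return A one-row tibble with `pass` (logical) and `reason` (`NA` when
#'   passing), plus the measured `volume_ml` and `border_fraction`.
#' @export
check_segmentation <- function(mask, vol,
                               min_volume_ml = 5,
                               max_volume_ml = 9000,
                               max_border_fraction = 0.01) {
  stopifnot(inherits(mask, "lung_mask"), inherits(vol, "ct_volume"))
  d <- dim(vol$values)
  if (!identical(dim(mask$mask), d)) {
    abort("Mask and volume dimensions differ.", class = "lungqct_parameter_error")
  }
  m <- mask$mask
  n <- sum(m)
  border <- sum(m[c(1, d[1]), , ]) + sum(m[, c(1, d[2]), ]) + sum(m[, , c(1, d[3])])
  border_fraction <- if (n > 0) border / n else 0
  reason <- NA_character_
  if (n == 0L) {
    reason <- "empty mask"
  } else if (mask$volume_ml < min_volume_ml || mask$volume_ml > max_volume_ml) {
    reason <- sprintf("volume %.1f ml outside [%g, %g] ml",
                      mask$volume_ml, min_volume_ml, max_volume_ml)
  } else if (border_fraction > max_border_fraction) {
    reason <- sprintf("%.1f%% of mask on grid boundary", 100 * border_fraction)
  }
  tibble(
    pass = is.na(reason),
    reason = reason,
    volume_ml = mask$volume_ml,
    border_fraction = border_fraction
  )
}

#' Dice overlap between two binary masks
#'
#' @param a,b Logical arrays of identical shape.
#' @return Dice coefficient 2|A n B| / (|A| + |B|).
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
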