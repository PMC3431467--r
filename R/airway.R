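#' Refine an airway seed point to the lumen centre
#'
#' Starting from a manually placed (or phantom-supplied) seed inside the
#' lumen, finds the connected lumen region (pixels below `lumen_threshold_hu`)
#' containing the seed in the axial slice and moves the seed to its centroid,
#' iterating until the centre is stable. For a symmetric lumen this converges
#' to the tube axis in one step.
#'
#' @param slice A `ct_slice` (see [axial_slice()]).
#' @param seed_xy_mm Length-2 physical position (mm) of the seed in the
#'   slice.
#' @param lumen_threshold_hu Pixels below this are lumen-like air;
#'   default -700 HU.
#' @param max_iter,tol_mm Iteration cap and convergence tolerance.
#' @return Length-2 refined centre (mm).
#' @export
refine_center <- function(slice, seed_xy_mm, lumen_threshold_hu = -700,
                          max_iter = 10, tol_mm = 1e-6) {
  stopifnot(inherits(slice, "ct_slice"))
  centre <- as.numeric(seed_xy_mm)
  if (interp_bilinear(slice, centre[1], centre[2]) >= lumen_threshold_hu) {
    abort("Seed is not inside an air-filled lumen.",
          class = "lungqct_parameter_error")
  }
  air <- slice$values < lumen_threshold_hu
  lab <- EBImage::bwlabel(air * 1)
  lab <- matrix(as.integer(lab), nrow(air), ncol(air))
  sp <- slice$spacing_mm
  for (it in seq_len(max_iter)) {
    px <- pmin(pmax(round(centre / sp) + 1L, 1L), dim(air))
    l <- lab[px[1], px[2]]
    if (l == 0L) break
    idx <- which(lab == l, arr.ind = TRUE)
    new_centre <- c(mean(idx[, 1] - 1) * sp[1], mean(idx[, 2] - 1) * sp[2])
    if (sqrt(sum((new_centre - centre)^2)) < tol_mm) {
      centre <- new_centre
      break
    }
    centre <- new_centre
  }
  centre
}

#' Cast radial attenuation profiles from the lumen centre
#'
#' Samples the attenuation along `n_rays` equally spaced rays from the
#' centre outward, by bilinear interpolation at `step_mm` increments, and
#' records per-ray lumen minimum and wall peak.
#'
#' @param slice A `ct_slice`.
#' @param center_xy_mm Ray origin (mm), normally the refined lumen centre.
#' @param n_rays Number of rays (>= 8); default 128.
#' @param step_mm Radial sampling step (mm); default 0.1.
#' @param max_radius_mm Maximum sampled radius (mm); default 10.
#' @return A list of `ray_profile` objects, each with `angle` (radians),
#'   `r_mm`, `hu`, `lumen_min_hu` and `wall_peak_hu`.
#' @export
cast_rays <- function(slice, center_xy_mm, n_rays = 128,
                      step_mm = 0.1, max_radius_mm = 10) {
  stopifnot(inherits(slice, "ct_slice"))
  if (n_rays < 8) {
    abort("`n_rays` must be at least 8.", class = "lungqct_parameter_error")
  }
  centre <- as.numeric(center_xy_mm)
  d <- dim(slice$values)
  extent <- (d - 1) * slice$spacing_mm
  if (any(centre < 0) || any(centre > extent)) {
    abort("Ray origin lies outside the image.", class = "lungqct_parameter_error")
  }
  angles <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  r <- seq(0, max_radius_mm, by = step_mm)
  lapply(angles, function(a) {
    x <- centre[1] + r * cos(a)
    y <- centre[2] + r * sin(a)
    hu <- interp_bilinear(slice, x, y)
    pk <- first_wall_peak(hu)
    structure(
      list(angle = a, r_mm = r, hu = hu,
           lumen_min_hu = if (is.na(pk$peak_idx)) min(hu) else
             hu[pk$lumen_min_idx],
           wall_peak_hu = if (is.na(pk$peak_idx)) max(hu) else
             hu[pk$peak_idx]),
      class = "ray_profile"
    )
  })
}

# Locate the first wall maximum beyond the lumen minimum: the profile must
# rise at least `min_contrast` above its running minimum (leaving the
# lumen), and the peak window closes once it has dropped `min_contrast`
# below the running maximum (entering the parenchyma). This keeps the
# boundary search on the airway wall even when the ray later crosses
# brighter structures (chest wall, vessels, mediastinum).
first_wall_peak <- function(hu, min_contrast = 250) {
  n <- length(hu)
  run_min <- cummin(hu)
  rise <- which(hu - run_min >= min_contrast)
  none <- list(peak_idx = NA_integer_, lumen_min_idx = NA_integer_)
  if (length(rise) == 0L) return(none)
  i0 <- rise[1]
  seg <- hu[i0:n]
  run_max <- cummax(seg)
  drop <- which(run_max - seg >= min_contrast)
  i1 <- if (length(drop) == 0L) n else i0 + drop[1] - 1L
  peak_idx <- i0 - 1L + which.max(hu[i0:i1])
  list(peak_idx = peak_idx,
       lumen_min_idx = which.min(hu[seq_len(peak_idx)]))
}

#' Full-width-at-half-maximum wall boundaries of a radial profile
#'
#' Places the inner wall boundary at the first crossing of the level halfway
#' between the lumen minimum and the wall peak (on the lumen side of the
#' peak), and the outer boundary at the first crossing of the level halfway
#' between the wall peak and the parenchymal minimum beyond it. Crossing
#' positions are refined by linear interpolation between samples.
#'
#' @param profile A `ray_profile` from [cast_rays()].
#' @param min_contrast_hu Minimum prominence (HU) for a rise to count as
#'   entering the wall and for a fall to count as leaving it. The default of
#'   250 HU sits far below the ~900 HU lumen-to-wall contrast of an
#'   air-filled airway but above plausible noise excursions, so noise bumps
#'   inside the lumen are not mistaken for the wall.
#' @return A list with `inner_radius_mm`, `outer_radius_mm` and `valid`.
#'   Rays without a usable wall peak (e.g. monotone profiles, or the peak at
#'   the sampling boundary) are flagged `valid = FALSE` with `NA` radii.
#' @export
fwhm_boundaries <- function(profile, min_contrast_hu = 250) {
  stopifnot(inherits(profile, "ray_profile"))
  hu <- profile$hu
  r <- profile$r_mm
  n <- length(hu)
  invalid <- list(inner_radius_mm = NA_real_, outer_radius_mm = NA_real_,
                  valid = FALSE)
  pk <- first_wall_peak(hu, min_contrast_hu)
  peak_idx <- pk$peak_idx
  if (is.na(peak_idx) || peak_idx == n || peak_idx == 1L) return(invalid)
  lumen_idx <- pk$lumen_min_idx
  if (hu[peak_idx] - hu[lumen_idx] < min_contrast_hu) return(invalid)

  cross_up <- function(i0, i1, level) {
    seg <- hu[i0:i1]
    j <- which(seg >= level)[1]
    if (is.na(j)) return(NA_real_)
    i <- i0 + j - 1L
    if (i == i0) return(r[i])
    frac <- (level - hu[i - 1]) / (hu[i] - hu[i - 1])
    r[i - 1] + frac * (r[i] - r[i - 1])
  }
  cross_down <- function(i0, i1, level) {
    seg <- hu[i0:i1]
    j <- which(seg <= level)[1]
    if (is.na(j)) return(NA_real_)
    i <- i0 + j - 1L
    if (i == i0) return(r[i])
    frac <- (hu[i - 1] - level) / (hu[i - 1] - hu[i])
    r[i - 1] + frac * (r[i] - r[i - 1])
  }

  half_in <- (hu[lumen_idx] + hu[peak_idx]) / 2
  inner <- cross_up(lumen_idx, peak_idx, half_in)

  par_min <- min(hu[peak_idx:n])
  if (hu[peak_idx] - par_min < min_contrast_hu) return(invalid)
  half_out <- (hu[peak_idx] + par_min) / 2
  outer <- cross_down(peak_idx, n, half_out)

  if (is.na(inner) || is.na(outer) || !(inner < outer)) return(invalid)
  list(inner_radius_mm = inner, outer_radius_mm = outer, valid = TRUE)
}

#' Measure airway dimensions by the FWHM ray-casting method
#'
#' Refines the seed to the lumen centre, casts radial attenuation profiles,
#' places inner/outer wall boundaries at the half-maximum levels on each
#' ray, rejects outlier rays (inner or outer radius more than
#' `outlier_mad_factor` scaled median-absolute-deviations from the angular
#' median — e.g. rays contaminated by an adjacent vessel), fills rejected or
#' invalid rays by circular interpolation of the neighbouring radii, and
#' assembles the boundary polygons.
#'
#' Outputs: lumen area `LA_mm2` (shoelace area of the inner polygon), wall
#' area `WA_mm2` (outer minus inner polygon area), wall-area percentage
#' `WA_pct = 100 * WA / (WA + LA)` and internal perimeter `Pi_mm` (inner
#' polygon perimeter).
#'
#' @param slice A `ct_slice`.
#' @param seed_xy_mm Seed position in the lumen (mm).
#' @param n_rays,step_mm,max_radius_mm Ray-casting settings, see
#'   [cast_rays()].
#' @param min_valid_fraction Minimum fraction of rays that must survive
#'   validity checks and outlier rejection; below this a condition of class
#'   `lungqct_measurement_failure` is raised.
#' @param outlier_mad_factor Rejection threshold in scaled MADs.
#' @param smooth_window Odd width of the circular moving average applied to
#'   the per-ray radii before the contours are assembled. Half-maximum
#'   crossings carry sub-voxel sampling jitter that is nearly unbiased for
#'   the enclosed area but inflates a jagged polygon's perimeter; averaging
#'   a few neighbouring rays removes the jitter while hardly biasing a
#'   smooth contour. `1` disables smoothing.
#' @param min_contrast_hu Wall-prominence threshold, see [fwhm_boundaries()].
#' @param lumen_threshold_hu Passed to [refine_center()].
#' @return An object of class `airway_measurement`; use [tidy()] for a
#'   one-row tibble.
#' @export
#' @examples
#' sl <- generate_annulus_slice()
#' m <- measure_airway(sl, attr(sl, "center_xy_mm"))
#' tidy(m)
measure_airway <- function(slice, seed_xy_mm,
                           n_rays = 128, step_mm = 0.1, max_radius_mm = 10,
                           min_valid_fraction = 0.75,
                           outlier_mad_factor = 3,
                           smooth_window = 5,
                           min_contrast_hu = 250,
                           lumen_threshold_hu = -700) {
  centre <- refine_center(slice, seed_xy_mm,
                          lumen_threshold_hu = lumen_threshold_hu)
  rays <- cast_rays(slice, centre, n_rays = n_rays, step_mm = step_mm,
                    max_radius_mm = max_radius_mm)
  bounds <- lapply(rays, fwhm_boundaries, min_contrast_hu = min_contrast_hu)
  inner <- vapply(bounds, `[[`, numeric(1), "inner_radius_mm")
  outer <- vapply(bounds, `[[`, numeric(1), "outer_radius_mm")
  valid <- vapply(bounds, `[[`, logical(1), "valid")

  # Outlier rejection against the angular median, both boundaries.
  if (sum(valid) >= 3L) {
    for (v in list(inner, outer)) {
      med <- median(v[valid])
      s <- mad(v[valid])
      if (is.finite(s) && s > 0) {
        valid <- valid & !is.na(v) & abs(v - med) <= outlier_mad_factor * s
      }
    }
  }
  n_valid <- sum(valid)
  if (n_valid < min_valid_fraction * n_rays) {
    abort(sprintf("Only %d of %d rays usable; airway measurement failed.",
                  n_valid, n_rays),
          class = "lungqct_measurement_failure")
  }
  inner <- smooth_circular(fill_circular(inner, valid), smooth_window)
  outer <- smooth_circular(fill_circular(outer, valid), smooth_window)

  angles <- vapply(rays, `[[`, numeric(1), "angle")
  inner_xy <- cbind(centre[1] + inner * cos(angles),
                    centre[2] + inner * sin(angles))
  outer_xy <- cbind(centre[1] + outer * cos(angles),
                    centre[2] + outer * sin(angles))
  la <- polygon_area(inner_xy)
  outer_area <- polygon_area(outer_xy)
  wa <- outer_area - la
  structure(
    list(
      LA_mm2 = la,
      WA_mm2 = wa,
      WA_pct = 100 * wa / (wa + la),
      Pi_mm = polygon_perimeter(inner_xy),
      inner_contour_mm = inner_xy,
      outer_contour_mm = outer_xy,
      center_xy_mm = centre,
      seed_xy_mm = as.numeric(seed_xy_mm),
      n_rays = n_rays,
      n_rays_used = n_valid
    ),
    class = "airway_measurement"
  )
}

#' @export
print.airway_measurement <- function(x, ...) {
  cat(sprintf(
    "<airway_measurement> LA %.2f mm^2, WA %.2f mm^2, WA%% %.1f, Pi %.2f mm (%d/%d rays)\n",
    x$LA_mm2, x$WA_mm2, x$WA_pct, x$Pi_mm, x$n_rays_used, x$n_rays))
  invisible(x)
}

# Replace invalid entries of a periodic radius sequence by linear
# interpolation between the nearest valid neighbours around the circle.
fill_circular <- function(v, valid) {
  n <- length(v)
  if (all(valid)) return(v)
  idx_valid <- which(valid)
  out <- v
  for (i in which(!valid)) {
    before <- idx_valid[which.min((i - idx_valid) %% n)]
    after <- idx_valid[which.min((idx_valid - i) %% n)]
    gap <- (after - before) %% n
    if (gap == 0) {
      out[i] <- v[before]
    } else {
      w <- ((i - before) %% n) / gap
      out[i] <- (1 - w) * v[before] + w * v[after]
    }
  }
  out
}

# Circular moving average over the angular neighbours of each ray.
smooth_circular <- function(v, window) {
  window <- as.integer(window)
  if (window <= 1L) return(v)
  if (window %% 2L == 0L) {
    abort("`smooth_window` must be odd.", class = "lungqct_parameter_error")
  }
  n <- length(v)
  h <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (off in -h:h) {
    out <- out + v[((seq_len(n) - 1L + off) %% n) + 1L]
  }
  out / window
}

polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

polygon_perimeter <- function(xy) {
  dx <- diff(c(xy[, 1], xy[1, 1]))
  dy <- diff(c(xy[, 2], xy[1, 2]))
  sum(sqrt(dx^2 + dy^2))
}
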