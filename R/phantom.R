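#' Phantom generation parameters
#'
#' Bundles the knobs of the synthetic thoracic phantom: grid geometry, target
#' pathology burden, per-tissue mean attenuation and the embedded airway
#' geometry. Defaults emulate a screening-population chest CT at desk scale:
#' a 128^3 grid at 0.7 mm in-plane / 1.0 mm axial spacing, normal lung around
#' -850 HU at inspiration rising to -750 HU at expiration, emphysema at
#' -980 HU (below the -950 HU density-mask threshold) and gas-trapping lung
#' that stays near -890 HU at expiration.
#'
#' @param grid_shape Integer length-3, voxels per axis.
#' @param voxel_spacing_mm Numeric length-3 voxel spacing (mm); axis 3 axial.
#' @param emphysema_fraction Target fraction of lung voxels inside emphysema
#'   clusters (0-1).
#' @param trapping_fraction Target fraction of lung voxels inside
#'   air-trapping regions (0-1).
#' @param hu_normal_insp,hu_normal_exp Mean attenuation (HU) of normal lung
#'   at inspiration / expiration.
#' @param hu_emphysema Mean attenuation (HU) of emphysematous lung (must lie
#'   below -950 HU so the density mask is exercised).
#' @param hu_trapped_exp Mean attenuation (HU) of air-trapping lung at
#'   expiration (at inspiration these regions look like normal lung).
#' @param airway_inner_radius_mm,airway_outer_radius_mm Lumen and outer wall
#'   radius of the embedded airway tube (mm).
#' @param airway_wall_hu Mean attenuation of the airway wall (HU).
#' @param texture_sd_hu Per-voxel Gaussian texture SD (HU) applied around the
#'   class means before any reconstruction noise, giving realistic unimodal
#'   attenuation histograms.
#' @param seed Integer RNG seed; identical parameters and seed reproduce the
#'   phantom bit for bit.
#'
#' @return A validated list of class `phantom_params`.
#' @export
#' @examples
#' p <- phantom_params(grid_shape = c(48, 48, 48), seed = 7)
phantom_params <- function(grid_shape = c(128, 128, 128),
                           voxel_spacing_mm = c(0.7, 0.7, 1.0),
                           emphysema_fraction = 0.10,
                           trapping_fraction = 0.15,
                           hu_normal_insp = -850,
                           hu_normal_exp = -750,
                           hu_emphysema = -980,
                           hu_trapped_exp = -890,
                           airway_inner_radius_mm = 1.8,
                           airway_outer_radius_mm = 3.8,
                           airway_wall_hu = -100,
                           texture_sd_hu = 30,
                           seed = 1L) {
  p <- list(
    grid_shape = as.integer(grid_shape),
    voxel_spacing_mm = as.numeric(voxel_spacing_mm),
    emphysema_fraction = emphysema_fraction,
    trapping_fraction = trapping_fraction,
    hu_normal_insp = hu_normal_insp,
    hu_normal_exp = hu_normal_exp,
    hu_emphysema = hu_emphysema,
    hu_trapped_exp = hu_trapped_exp,
    airway_inner_radius_mm = airway_inner_radius_mm,
    airway_outer_radius_mm = airway_outer_radius_mm,
    airway_wall_hu = airway_wall_hu,
    texture_sd_hu = texture_sd_hu,
    seed = as.integer(seed)
  )
  if (length(p$grid_shape) != 3L || any(p$grid_shape < 24L)) {
    abort("`grid_shape` must be 3 integers, each at least 24.",
          class = "lungqct_parameter_error")
  }
  if (length(p$voxel_spacing_mm) != 3L || any(p$voxel_spacing_mm <= 0)) {
    abort("`voxel_spacing_mm` must be 3 positive numbers.",
          class = "lungqct_parameter_error")
  }
  for (f in c("emphysema_fraction", "trapping_fraction")) {
    if (p[[f]] < 0 || p[[f]] > 1) {
      abort(sprintf("`%s` must lie in [0, 1].", f),
            class = "lungqct_parameter_error")
    }
  }
  if (p$emphysema_fraction + p$trapping_fraction > 1) {
    abort("emphysema_fraction + trapping_fraction must not exceed 1.",
          class = "lungqct_parameter_error")
  }
  if (!(p$airway_outer_radius_mm > p$airway_inner_radius_mm &&
          p$airway_inner_radius_mm > 0)) {
    abort("Require airway_outer_radius_mm > airway_inner_radius_mm > 0.",
          class = "lungqct_parameter_error")
  }
  if (!(p$hu_emphysema < -950 && -950 < p$hu_normal_insp)) {
    abort("Require hu_emphysema < -950 < hu_normal_insp.",
          class = "lungqct_parameter_error")
  }
  if (p$texture_sd_hu < 0) {
    abort("`texture_sd_hu` must be non-negative.",
          class = "lungqct_parameter_error")
  }
  structure(p, class = "phantom_params")
}

#' Reconstruction noise parameters
#'
#' Image noise is modeled as additive zero-mean Gaussian noise per voxel.
#' An iterative reconstruction (IR) is modeled purely as a fractional noise
#' reduction relative to filtered back-projection (FBP) — 45 % by default —
#' with no change to the underlying image, mirroring a hybrid IR algorithm
#' that denoises without altering image characteristics.
#'
#' @param label `"FBP"` or `"IR"`.
#' @param noise_sigma_hu Noise SD of the FBP reference rendering (HU). The
#'   default of 80 HU is an expiratory-protocol-like level at which
#'   threshold densitometry visibly responds to the reconstruction choice.
#' @param noise_reduction Fractional noise reduction relative to FBP
#'   (0 for FBP; default 0.45 for IR).
#' @return A validated list of class `recon_params`.
#' @export
#' @examples
#' recon_params("IR")$noise_reduction
recon_params <- function(label = c("FBP", "IR"),
                         noise_sigma_hu = 80,
                         noise_reduction = NULL) {
  label <- match.arg(label)
  if (is.null(noise_reduction)) {
    noise_reduction <- if (label == "FBP") 0 else 0.45
  }
  if (!is.finite(noise_sigma_hu) || noise_sigma_hu < 0) {
    abort("`noise_sigma_hu` must be non-negative.",
          class = "lungqct_parameter_error")
  }
  if (!is.finite(noise_reduction) || noise_reduction < 0 || noise_reduction >= 1) {
    abort("`noise_reduction` must lie in [0, 1).",
          class = "lungqct_parameter_error")
  }
  structure(list(label = label, noise_sigma_hu = noise_sigma_hu,
                 noise_reduction = noise_reduction),
            class = "recon_params")
}

# Tissue class codes used while painting the phantom.
.CLS <- c(background = 0L, soft_tissue = 1L, lung = 2L, emphysema = 3L,
          trapping = 4L, airway_wall = 5L, airway_lumen = 6L)

#' Generate a paired inspiratory/expiratory thoracic phantom
#'
#' Builds a soft-tissue thorax containing a smooth ellipsoidal lung, random
#' spherical emphysema clusters and air-trapping regions occupying the
#' requested fractions of the lung, and a straight airway tube of known
#' annular geometry running along the axial axis (through the lung and into
#' the mediastinum above it). The same tissue geometry is rendered twice:
#' at inspiration (normal lung at `hu_normal_insp`) and at expiration
#' (normal lung rises to `hu_normal_exp` while air-trapping regions stay
#' near `hu_trapped_exp` and emphysema stays emphysematous). Per-voxel
#' Gaussian texture is added around the class means; reconstruction noise is
#' applied separately by [apply_reconstruction()].
#'
#' @param params A [phantom_params()].
#' @return A list with elements `insp` and `exp` (clean [ct_volume()]s,
#'   `recon_label = "clean"`) and `truth`, a `phantom_truth` object holding
#'   the lung / emphysema / trapping masks, the airway geometry (centre,
#'   measurement slice, radii) and the analytic airway truths
#'   `true_LA_mm2 = pi * r_i^2`, `true_WA_mm2 = pi * (r_o^2 - r_i^2)`,
#'   `true_Pi_mm = 2 * pi * r_i`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_params(grid_shape = c(48, 48, 48)))
#' mean(ph$truth$emphysema_mask) / mean(ph$truth$lung_mask)
generate_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  withr::with_seed(params$seed, generate_phantom_impl(params))
}

generate_phantom_impl <- function(p) {
  d <- p$grid_shape
  sp <- p$voxel_spacing_mm
  ext <- d * sp                      # physical extent per axis, mm
  x <- (seq_len(d[1]) - 1) * sp[1]
  y <- (seq_len(d[2]) - 1) * sp[2]
  z <- (seq_len(d[3]) - 1) * sp[3]

  ellipsoid <- function(centre, semi) {
    tx <- ((x - centre[1]) / semi[1])^2
    ty <- ((y - centre[2]) / semi[2])^2
    tz <- ((z - centre[3]) / semi[3])^2
    outer(outer(tx, ty, "+"), tz, "+") <= 1
  }

  body <- ellipsoid(centre = 0.5 * ext, semi = c(0.46, 0.46, 0.48) * ext)
  lung <- ellipsoid(centre = c(0.5, 0.5, 0.45) * ext,
                    semi = c(0.30, 0.30, 0.32) * ext)

  cls <- array(.CLS[["background"]], d)
  cls[body] <- .CLS[["soft_tissue"]]
  cls[lung] <- .CLS[["lung"]]

  # Airway tube along z: through the lung and upward into the mediastinum.
  acx <- 0.58 * ext[1]
  acy <- 0.50 * ext[2]
  if (acx + p$airway_outer_radius_mm >= 0.8 * ext[1]) {
    abort("Airway tube does not fit inside the lung; enlarge the grid.",
          class = "lungqct_parameter_error")
  }
  r2 <- outer((x - acx)^2, (y - acy)^2, "+")
  in_wall <- r2 <= p$airway_outer_radius_mm^2
  in_lumen <- r2 <= p$airway_inner_radius_mm^2
  kz <- which(z >= 0.25 * ext[3] & z <= 0.88 * ext[3])
  for (k in kz) {
    sl <- cls[, , k]
    sl[in_wall] <- .CLS[["airway_wall"]]
    # the tube's inferior end is capped with wall (two slices, so the lumen
    # stays 26-disconnected from the surrounding lung air)
    if (k > kz[2]) sl[in_lumen] <- .CLS[["airway_lumen"]]
    cls[, , k] <- sl
  }

  lung_idx <- which(cls == .CLS[["lung"]])
  n_lung <- length(lung_idx)
  voxvol <- prod(sp)

  cls <- place_spheres(cls, lung_idx, .CLS[["emphysema"]],
                       target = round(p$emphysema_fraction * n_lung),
                       radius_range_mm = c(1.5, 3.5), sp = sp, d = d)
  cls <- place_spheres(cls, lung_idx, .CLS[["trapping"]],
                       target = round(p$trapping_fraction * n_lung),
                       radius_range_mm = c(3.0, 6.0), sp = sp, d = d)

  means_insp <- c(-1000, 40, p$hu_normal_insp, p$hu_emphysema,
                  p$hu_normal_insp, p$airway_wall_hu, -1000)
  means_exp <- c(-1000, 40, p$hu_normal_exp, p$hu_emphysema,
                 p$hu_trapped_exp, p$airway_wall_hu, -1000)
  nvox <- prod(d)
  insp <- array(means_insp[cls + 1L] + rnorm(nvox, 0, p$texture_sd_hu), d)
  expv <- array(means_exp[cls + 1L] + rnorm(nvox, 0, p$texture_sd_hu), d)

  lung_mask <- array(cls %in% .CLS[c("lung", "emphysema", "trapping")], d)
  truth <- structure(list(
    lung_mask = lung_mask,
    emphysema_mask = array(cls == .CLS[["emphysema"]], d),
    trapping_mask = array(cls == .CLS[["trapping"]], d),
    airway_lumen_mask = array(cls == .CLS[["airway_lumen"]], d),
    airway_center_xy_mm = c(acx, acy),
    airway_slice_index = which.min(abs(z - 0.45 * ext[3])),
    airway_axis = 3L,
    airway_inner_radius_mm = p$airway_inner_radius_mm,
    airway_outer_radius_mm = p$airway_outer_radius_mm,
    true_LA_mm2 = pi * p$airway_inner_radius_mm^2,
    true_WA_mm2 = pi * (p$airway_outer_radius_mm^2 - p$airway_inner_radius_mm^2),
    true_Pi_mm = 2 * pi * p$airway_inner_radius_mm,
    lung_volume_ml = sum(lung_mask) * voxvol / 1000,
    params = p
  ), class = "phantom_truth")

  list(
    insp = ct_volume(insp, sp, "clean"),
    exp = ct_volume(expv, sp, "clean"),
    truth = truth
  )
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "<phantom_truth> lung %.0f ml; emphysema %.1f%%, trapping %.1f%% of lung\n",
    x$lung_volume_ml,
    100 * sum(x$emphysema_mask) / sum(x$lung_mask),
    100 * sum(x$trapping_mask) / sum(x$lung_mask)))
  cat(sprintf("  airway r_i %.2f mm, r_o %.2f mm (LA %.2f mm^2, WA %.2f mm^2, Pi %.2f mm)\n",
              x$airway_inner_radius_mm, x$airway_outer_radius_mm,
              x$true_LA_mm2, x$true_WA_mm2, x$true_Pi_mm))
  invisible(x)
}

# Stamp random spheres of class `code` into available normal-lung voxels
# until `target` voxels are claimed (to within a few voxels). Errors when the
# lung cannot host the requested burden.
place_spheres <- function(cls, lung_idx, code, target, radius_range_mm, sp, d) {
  if (target <= 0) return(cls)
  count <- 0L
  nx <- d[1]; ny <- d[2]
  min_r <- max(sp) # at least one voxel across
  for (iter in seq_len(5000L)) {
    remaining <- target - count
    if (remaining <= 3L) break
    r <- runif(1, radius_range_mm[1], radius_range_mm[2])
    r_needed <- (3 * remaining * prod(sp) / (4 * pi))^(1 / 3)
    r <- max(min(r, r_needed), min_r)
    ctr <- lung_idx[sample.int(length(lung_idx), 1L)]
    ci <- arrayInd(ctr, d)
    ii <- max(1L, ci[1] - ceiling(r / sp[1])):min(nx, ci[1] + ceiling(r / sp[1]))
    jj <- max(1L, ci[2] - ceiling(r / sp[2])):min(ny, ci[2] + ceiling(r / sp[2]))
    kk <- max(1L, ci[3] - ceiling(r / sp[3])):min(d[3], ci[3] + ceiling(r / sp[3]))
    dx2 <- ((ii - ci[1]) * sp[1])^2
    dy2 <- ((jj - ci[2]) * sp[2])^2
    dz2 <- ((kk - ci[3]) * sp[3])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
    sub <- cls[ii, jj, kk]
    claim <- inside & sub == .CLS[["lung"]]
    n_new <- sum(claim)
    if (n_new == 0L) next
    if (count + n_new > target + 3L && n_new > remaining) {
      # keep the sphere but only up to the remaining budget, nearest first
      ord <- order(outer(outer(dx2, dy2, "+"), dz2, "+")[claim])
      keep <- which(claim)[ord[seq_len(remaining)]]
      claim[] <- FALSE
      claim[keep] <- TRUE
      n_new <- remaining
    }
    sub[claim] <- code
    cls[ii, jj, kk] <- sub
    count <- count + n_new
  }
  if (abs(count - target) > max(3, 0.01 * max(target, 1)) && count < target) {
    abort("Requested pathology fraction exceeds the capacity of the lung region.",
          class = "lungqct_parameter_error")
  }
  cls
}

#' Apply reconstruction noise to a clean volume
#'
#' Adds independent zero-mean Gaussian noise with standard deviation
#' `noise_sigma_hu * (1 - noise_reduction)` to every voxel and stamps the
#' reconstruction label. Under a fixed `seed` the underlying standard-normal
#' field is reproducible, so rendering the same clean volume under FBP and
#' IR with the same seed yields the correlated noise expected of two
#' reconstructions of one raw acquisition (the IR field is the FBP field
#' scaled down).
#'
#' @param clean A [ct_volume()].
#' @param recon A [recon_params()].
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return A [ct_volume()] with noise applied and `recon_label` set.
#' @export
#' @examples
#' vol <- ct_volume(array(-880, c(16, 16, 16)), c(1, 1, 1))
#' noisy <- apply_reconstruction(vol, recon_params("FBP"), seed = 1)
#' sd(noisy$values)
apply_reconstruction <- function(clean, recon, seed = NULL) {
  stopifnot(inherits(clean, "ct_volume"), inherits(recon, "recon_params"))
  sigma <- recon$noise_sigma_hu * (1 - recon$noise_reduction)
  out <- clean
  out$recon_label <- recon$label
  if (sigma > 0) {
    draw <- function() {
      array(rnorm(length(clean$values)) * sigma, dim(clean$values))
    }
    noise <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    out$values <- clean$values + noise
  }
  out
}

#' Default cohort severity ranges
#'
#' Per-subject phantom parameters are drawn uniformly from these ranges,
#' emulating the between-subject spread of a smoking screening cohort:
#' emphysema burden from trace to moderate, air trapping up to a quarter of
#' the lung, segmental-airway lumen radii around 1.4-2.6 mm and normal-lung
#' attenuation varying tens of HU between subjects.
#'
#' @return Named list of length-2 numeric ranges; entries named after
#'   [phantom_params()] fields, plus `airway_wall_thickness_mm` which sets
#'   the outer radius as inner radius + thickness.
#' @export
cohort_severity_ranges <- function() {
  list(
    emphysema_fraction = c(0.02, 0.20),
    trapping_fraction = c(0.05, 0.25),
    airway_inner_radius_mm = c(1.4, 2.6),
    airway_wall_thickness_mm = c(1.2, 2.2),
    hu_normal_insp = c(-870, -830),
    hu_normal_exp = c(-780, -720)
  )
}

#' Draw per-subject phantom parameters for a cohort
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param severity_ranges Named list of uniform ranges, see
#'   [cohort_severity_ranges()]. A degenerate range (min = max) pins the
#'   parameter for every subject.
#' @param seed Integer master seed; per-subject seeds are derived from it
#'   deterministically.
#' @param base_params A [phantom_params()] supplying every field not covered
#'   by `severity_ranges`.
#' @return A tibble with columns `subject` and `params` (list-column of
#'   [phantom_params()]).
#' @export
draw_cohort_params <- function(n_subjects,
                               severity_ranges = cohort_severity_ranges(),
                               seed = 1L,
                               base_params = phantom_params()) {
  if (n_subjects < 1) {
    abort("`n_subjects` must be at least 1.", class = "lungqct_parameter_error")
  }
  known <- c(names(phantom_params()), "airway_wall_thickness_mm")
  bad <- setdiff(names(severity_ranges), known)
  if (length(bad) > 0) {
    abort(paste0("Unknown severity range(s): ", paste(bad, collapse = ", ")),
          class = "lungqct_parameter_error")
  }
  withr::with_seed(seed, {
    subject_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
    draws <- lapply(severity_ranges, function(rg) {
      runif(n_subjects, rg[1], rg[2])
    })
    params <- lapply(seq_len(n_subjects), function(i) {
      p <- unclass(base_params)
      for (nm in names(draws)) {
        if (nm == "airway_wall_thickness_mm") next
        p[[nm]] <- draws[[nm]][i]
      }
      if ("airway_wall_thickness_mm" %in% names(draws)) {
        inner <- p$airway_inner_radius_mm
        p$airway_outer_radius_mm <- inner + draws$airway_wall_thickness_mm[i]
      }
      p$seed <- subject_seeds[i]
      do.call(phantom_params, p)
    })
    tibble(subject = sprintf("S%03d", seq_len(n_subjects)), params = params)
  })
}

#' Generate a phantom cohort
#'
#' Draws per-subject parameters with [draw_cohort_params()] and materialises
#' each subject's paired clean volumes and ground truth. For large cohorts
#' prefer [run_study()], which generates and processes subjects one at a
#' time instead of holding every volume in memory.
#'
#' @inheritParams draw_cohort_params
#' @return A tibble with columns `subject`, `params`, `insp`, `exp`
#'   (list-columns of [ct_volume()]) and `truth`.
#' @export
generate_cohort <- function(n_subjects,
                            severity_ranges = cohort_severity_ranges(),
                            seed = 1L,
                            base_params = phantom_params()) {
  cohort <- draw_cohort_params(n_subjects, severity_ranges, seed, base_params)
  built <- lapply(cohort$params, generate_phantom)
  cohort$insp <- lapply(built, `[[`, "insp")
  cohort$exp <- lapply(built, `[[`, "exp")
  cohort$truth <- lapply(built, `[[`, "truth")
  cohort
}

#' Generate an ideal annular airway cross-section
#'
#' Builds a single axial slice containing a circular airway: lumen inside
#' `r_inner_mm`, wall between the radii, parenchyma outside. Useful as an
#' analytic fixture for the ray-casting morphometry, whose truth values are
#' `pi * r_inner^2`, `pi * (r_outer^2 - r_inner^2)` and `2 * pi * r_inner`.
#'
#' @param r_inner_mm,r_outer_mm Annulus radii (mm).
#' @param spacing_mm In-plane voxel spacing (mm), isotropic.
#' @param half_extent_mm Half-width of the square image (mm).
#' @param lumen_hu,wall_hu,parenchyma_hu Attenuation of the three regions.
#' @param center_offset_mm Length-2 sub-voxel offset of the annulus centre
#'   from the image centre (mm), for sampling-sensitivity studies.
#' @param noise_sd_hu Optional additive Gaussian noise SD (HU).
#' @param seed Optional seed for the noise.
#' @return A `ct_slice` with attribute `center_xy_mm`, the annulus centre in
#'   physical slice coordinates.
#' @export
#' @examples
#' sl <- generate_annulus_slice()
#' attr(sl, "center_xy_mm")
generate_annulus_slice <- function(r_inner_mm = 1.8, r_outer_mm = 3.8,
                                   spacing_mm = 0.25, half_extent_mm = 12,
                                   lumen_hu = -1000, wall_hu = 0,
                                   parenchyma_hu = -880,
                                   center_offset_mm = c(0, 0),
                                   noise_sd_hu = 0, seed = NULL) {
  if (!(r_outer_mm > r_inner_mm && r_inner_mm > 0)) {
    abort("Require r_outer_mm > r_inner_mm > 0.",
          class = "lungqct_parameter_error")
  }
  n <- 2L * ceiling(half_extent_mm / spacing_mm) + 1L
  ctr <- (n - 1) / 2 * spacing_mm + center_offset_mm
  x <- (seq_len(n) - 1) * spacing_mm
  r2 <- outer((x - ctr[1])^2, (x - ctr[2])^2, "+")
  img <- matrix(parenchyma_hu, n, n)
  img[r2 <= r_outer_mm^2] <- wall_hu
  img[r2 <= r_inner_mm^2] <- lumen_hu
  if (noise_sd_hu > 0) {
    draw <- function() matrix(rnorm(n * n, 0, noise_sd_hu), n, n)
    img <- img + if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  out <- structure(
    list(values = img, spacing_mm = c(spacing_mm, spacing_mm), z_mm = 0),
    class = "ct_slice"
  )
  attr(out, "center_xy_mm") <- ctr
  out
}
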