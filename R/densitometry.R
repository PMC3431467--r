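#' Histogram densitometry of masked lung volumes
#'
#' The five histogram-based emphysema and air-trapping indices computed from
#' the attenuation distribution of the segmented lung:
#'
#' * `compute_in950()` — emphysema index IN-950: percentage of inspiratory
#'   lung voxels strictly below -950 HU (density mask).
#' * `compute_perc15()` — emphysema index Perc15: HU value at the 15th
#'   percentile of the inspiratory lung histogram.
#' * `compute_exp856()` — air-trapping index EXP-856: percentage of
#'   expiratory lung voxels strictly below -856 HU.
#' * `compute_rvc()` — air-trapping index RVC-860 to -950: change
#'   (expiration minus inspiration) in the percentage of lung voxels with
#'   attenuation in the band \[-950, -860\] HU, in percentage points.
#' * `compute_ei_ratio()` — air-trapping index E/I-ratio MLD:
#'   `100 * MLD_exp / MLD_insp`, the expiratory-to-inspiratory ratio of mean
#'   lung density.
#'
#' Conventions: "below" thresholds are strict (`<`); the RVC band is
#' inclusive at both ends and excludes voxels below -950 HU; percentiles use
#' linear interpolation between order statistics at position `(n - 1) * p`
#' (the default convention of [stats::quantile()], type 7). HU values are
#' treated as real numbers throughout.
#'
#' @param insp,exp [ct_volume()]s of the inspiratory / expiratory series.
#' @param mask,insp_mask,exp_mask `lung_mask` objects aligned to the
#'   corresponding volume.
#' @return A scalar for the single-index functions; [compute_densitometry()]
#'   returns a one-row tibble with all indices plus `mld_insp_hu`,
#'   `mld_exp_hu`, `lung_volume_insp_ml` and `lung_volume_exp_ml`.
#' @name densitometry
NULL

masked_values <- function(vol, mask) {
  stopifnot(inherits(vol, "ct_volume"), inherits(mask, "lung_mask"))
  if (!identical(dim(vol$values), dim(mask$mask))) {
    abort("Mask and volume dimensions differ.", class = "lungqct_parameter_error")
  }
  v <- vol$values[mask$mask]
  if (length(v) == 0L) {
    abort("Empty lung mask.", class = "lungqct_parameter_error")
  }
  v
}

pct_below <- function(v, threshold_hu) {
  100 * mean(v < threshold_hu)
}

#' @rdname densitometry
#' @export
compute_in950 <- function(insp, mask) {
  pct_below(masked_values(insp, mask), -950)
}

#' @rdname densitometry
#' @param p Percentile in (0, 1) for [compute_percentile()]; Perc15 is
#'   `p = 0.15`.
#' @export
compute_perc15 <- function(insp, mask) {
  compute_percentile(insp, mask, 0.15)
}

#' @rdname densitometry
#' @export
compute_percentile <- function(insp, mask, p) {
  if (p <= 0 || p >= 1) {
    abort("`p` must lie in (0, 1).", class = "lungqct_parameter_error")
  }
  unname(quantile(masked_values(insp, mask), p, type = 7, names = FALSE))
}

#' @rdname densitometry
#' @export
compute_exp856 <- function(exp, mask) {
  pct_below(masked_values(exp, mask), -856)
}

band_share_pct <- function(v) {
  100 * mean(v >= -950 & v <= -860)
}

#' @rdname densitometry
#' @export
compute_rvc <- function(insp, insp_mask, exp, exp_mask) {
  band_share_pct(masked_values(exp, exp_mask)) -
    band_share_pct(masked_values(insp, insp_mask))
}

#' @rdname densitometry
#' @export
compute_ei_ratio <- function(insp, insp_mask, exp, exp_mask) {
  mld_insp <- mean(masked_values(insp, insp_mask))
  if (mld_insp == 0) {
    abort("Inspiratory mean lung density is zero; E/I ratio undefined.",
          class = "lungqct_parameter_error")
  }
  100 * mean(masked_values(exp, exp_mask)) / mld_insp
}

#' @rdname densitometry
#' @export
#' @examples
#' ph <- generate_phantom(phantom_params(grid_shape = c(48, 48, 48)))
#' m <- as_lung_mask(ph$truth$lung_mask, ph$insp$spacing_mm)
#' compute_densitometry(ph$insp, ph$exp, m, m)
compute_densitometry <- function(insp, exp, insp_mask, exp_mask) {
  vi <- masked_values(insp, insp_mask)
  ve <- masked_values(exp, exp_mask)
  mld_insp <- mean(vi)
  if (mld_insp == 0) {
    abort("Inspiratory mean lung density is zero; E/I ratio undefined.",
          class = "lungqct_parameter_error")
  }
  tibble(
    in950_pct = pct_below(vi, -950),
    perc15_hu = unname(quantile(vi, 0.15, type = 7, names = FALSE)),
    exp856_pct = pct_below(ve, -856),
    rvc_pct = band_share_pct(ve) - band_share_pct(vi),
    ei_ratio_pct = 100 * mean(ve) / mld_insp,
    mld_insp_hu = mld_insp,
    mld_exp_hu = mean(ve),
    lung_volume_insp_ml = insp_mask$volume_ml,
    lung_volume_exp_ml = exp_mask$volume_ml
  )
}
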