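#' Tidy an airway measurement
#'
#' @param x An `airway_measurement` from [measure_airway()].
#' @param ... Unused.
#' @return One-row tibble with `la_mm2`, `wa_mm2`, `wa_pct`, `pi_mm`, the
#'   refined centre and the ray bookkeeping.
#' @method tidy airway_measurement
#' @export
tidy.airway_measurement <- function(x, ...) {
  tibble(
    la_mm2 = x$LA_mm2,
    wa_mm2 = x$WA_mm2,
    wa_pct = x$WA_pct,
    pi_mm = x$Pi_mm,
    center_x_mm = x$center_xy_mm[1],
    center_y_mm = x$center_xy_mm[2],
    n_rays_used = x$n_rays_used,
    n_rays = x$n_rays
  )
}

#' Tidy an agreement result
#'
#' @param x An `agreement_result` from [agreement_test()].
#' @param ... Unused.
#' @return One-row tibble with the concordance, its descriptive class, the
#'   signed-rank test and the median/IQR summaries (algorithm A/B suffixes,
#'   `abs_diff_` for the absolute within-subject differences).
#' @method tidy agreement_result
#' @export
tidy.agreement_result <- function(x, ...) {
  tibble(
    measure = x$measure,
    n = x$n,
    pc = x$pc,
    agreement_class = x$agreement_class,
    wilcoxon_stat = x$wilcoxon_stat,
    wilcoxon_p = x$wilcoxon_p,
    wilcoxon_method = x$wilcoxon_method,
    degenerate = x$degenerate,
    median_a = x$median_iqr_A[["median"]],
    q1_a = x$median_iqr_A[["q1"]],
    q3_a = x$median_iqr_A[["q3"]],
    median_b = x$median_iqr_B[["median"]],
    q1_b = x$median_iqr_B[["q1"]],
    q3_b = x$median_iqr_B[["q3"]],
    abs_diff_median = x$abs_diff_median_iqr[["median"]],
    abs_diff_q1 = x$abs_diff_median_iqr[["q1"]],
    abs_diff_q3 = x$abs_diff_median_iqr[["q3"]]
  )
}

#' @rdname tidy.agreement_result
#' @method glance agreement_result
#' @export
glance.agreement_result <- function(x, ...) {
  tibble(n = x$n, pc = x$pc, agreement_class = x$agreement_class,
         wilcoxon_p = x$wilcoxon_p)
}

#' Tidy a cohort study result
#'
#' @param x A `lung_study` from [run_study()].
#' @param ... Unused.
#' @return `tidy()` returns the long per-subject measure table; `glance()`
#'   a one-row summary of cohort size and exclusions.
#' @method tidy lung_study
#' @export
tidy.lung_study <- function(x, ...) {
  x$measures
}

#' @rdname tidy.lung_study
#' @method glance lung_study
#' @export
glance.lung_study <- function(x, ...) {
  tibble(
    n_subjects = x$config$n_subjects,
    n_included = x$n_included,
    n_excluded = x$config$n_subjects - x$n_included,
    n_measures = length(unique(x$measures$measure))
  )
}
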