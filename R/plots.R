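#' Scatter plots of paired measures with the identity line
#'
#' One panel per measure, algorithm A against algorithm B, with the line of
#' identity drawn — departures from it are what the concordance correlation
#' penalizes.
#'
#' @param data Long per-subject measure table with columns `subject`,
#'   `measure`, `algorithm`, `value` (e.g. `run_study(...)$measures`).
#' @param algorithm_a,algorithm_b Algorithm labels; A on the x axis.
#' @return A ggplot object.
#' @export
plot_agreement_scatter <- function(data, algorithm_a = "FBP",
                                   algorithm_b = "IR") {
  wide <- tidyr::pivot_wider(
    dplyr::select(data, "subject", "measure", "algorithm", "value"),
    names_from = "algorithm", values_from = "value"
  )
  ggplot(wide, aes(x = .data[[algorithm_a]], y = .data[[algorithm_b]])) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey50") +
    geom_point(alpha = 0.7) +
    facet_wrap(~measure, scales = "free") +
    labs(x = algorithm_a, y = algorithm_b) +
    theme_bw()
}

#' @method autoplot agreement_table
#' @export
autoplot.agreement_table <- function(object, ...) {
  lab <- function(v) sprintf("%s\npc = %.3f (%s)", object$measure,
                             object$pc, object$agreement_class)
  df <- dplyr::mutate(object, panel = lab(object))
  ggplot(df, aes(x = .data$median_a, y = .data$median_b)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey50") +
    geom_point() +
    geom_errorbar(aes(ymin = .data$q1_b, ymax = .data$q3_b), width = 0) +
    geom_errorbarh(aes(xmin = .data$q1_a, xmax = .data$q3_a), height = 0) +
    labs(x = "algorithm A (median, IQR)", y = "algorithm B (median, IQR)",
         title = "Agreement of paired reconstruction algorithms") +
    theme_bw()
}

#' @method autoplot lung_study
#' @export
autoplot.lung_study <- function(object, ...) {
  plot_agreement_scatter(object$measures, ...)
}

#' Attenuation histogram of a masked lung
#'
#' Histogram of lung attenuation with the density-mask thresholds marked,
#' the raw material of every densitometry index.
#'
#' @param vol A [ct_volume()].
#' @param mask A `lung_mask`.
#' @param binwidth Histogram bin width in HU.
#' @return A ggplot object.
#' @export
plot_lung_histogram <- function(vol, mask, binwidth = 10) {
  df <- tibble(hu = masked_values(vol, mask))
  ggplot(df, aes(x = .data$hu)) +
    geom_histogram(binwidth = binwidth, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = c(-950, -856), linetype = "dashed",
               colour = c("firebrick", "steelblue")) +
    labs(x = "attenuation (HU)", y = "voxels",
         subtitle = "dashed: -950 HU (emphysema), -856 HU (air trapping)") +
    theme_bw()
}
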