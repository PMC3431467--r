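#' Configuration for an end-to-end reconstruction-sensitivity study
#'
#' Validates and bundles everything [run_study()] needs: cohort size and
#' master seed, phantom parameter ranges, the two reconstruction noise
#' levels, segmentation settings and airway-measurement settings. The
#' configuration is serialized alongside outputs so a run can be reproduced
#' exactly.
#'
#' @param n_subjects Cohort size (>= 1); default 30.
#' @param seed Master RNG seed; every downstream random draw derives from
#'   it.
#' @param base_params A [phantom_params()] giving the fields not varied
#'   across subjects.
#' @param severity_ranges Per-subject uniform ranges, see
#'   [cohort_severity_ranges()].
#' @param sigma_fbp_hu FBP noise SD (HU).
#' @param ir_noise_reduction Fractional IR noise reduction relative to FBP.
#' @param segmentation Named list of [segment_lungs()] /
#'   [check_segmentation()] settings (partial lists are completed with
#'   defaults).
#' @param airway Named list of [measure_airway()] settings (partial lists
#'   completed with defaults).
#' @param outdir Optional output directory for tables and the serialized
#'   config; `NULL` keeps everything in memory.
#' @param write_volumes Also write every rendered volume as NIfTI under
#'   `outdir` (large; default `FALSE`).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(n_subjects = 30,
                       seed = 1L,
                       base_params = phantom_params(),
                       severity_ranges = cohort_severity_ranges(),
                       sigma_fbp_hu = 80,
                       ir_noise_reduction = 0.45,
                       segmentation = list(),
                       airway = list(),
                       outdir = NULL,
                       write_volumes = FALSE) {
  if (n_subjects < 1) {
    abort("`n_subjects` must be at least 1.", class = "lungqct_parameter_error")
  }
  stopifnot(inherits(base_params, "phantom_params"))
  seg_defaults <- list(air_threshold_hu = -320, min_component_ml = 1,
                       airway_cap_ml = 100, min_volume_ml = 5,
                       max_volume_ml = 9000, max_border_fraction = 0.01)
  air_defaults <- list(n_rays = 128, step_mm = 0.1, max_radius_mm = 10,
                       min_valid_fraction = 0.75, outlier_mad_factor = 3,
                       lumen_threshold_hu = -700)
  bad_seg <- setdiff(names(segmentation), names(seg_defaults))
  bad_air <- setdiff(names(airway), names(air_defaults))
  if (length(bad_seg) || length(bad_air)) {
    abort(paste0("Unknown config entries: ",
                 paste(c(bad_seg, bad_air), collapse = ", ")),
          class = "lungqct_parameter_error")
  }
  # validate the recon settings eagerly
  recon_params("FBP", sigma_fbp_hu, 0)
  recon_params("IR", sigma_fbp_hu, ir_noise_reduction)
  structure(list(
    n_subjects = as.integer(n_subjects),
    seed = as.integer(seed),
    base_params = base_params,
    severity_ranges = severity_ranges,
    sigma_fbp_hu = sigma_fbp_hu,
    ir_noise_reduction = ir_noise_reduction,
    segmentation = modifyList(seg_defaults, segmentation),
    airway = modifyList(air_defaults, airway),
    outdir = outdir,
    write_volumes = isTRUE(write_volumes)
  ), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %d subjects, seed %d, grid %s, sigma_FBP %g HU, IR reduction %g\n",
              x$n_subjects, x$seed,
              paste(x$base_params$grid_shape, collapse = "x"),
              x$sigma_fbp_hu, x$ir_noise_reduction))
  invisible(x)
}

# Measure labels in reporting order (densitometry then airway).
measure_levels <- function() {
  c("in950", "perc15", "exp856", "rvc", "ei_ratio", "la", "wa", "wa_pct", "pi")
}

#' Run the full simulate-reconstruct-segment-measure-compare study
#'
#' For every subject, generates a paired inspiratory/expiratory phantom,
#' renders both phases under FBP and IR (same noise seed per phase, so the
#' two reconstructions share the raw acquisition), segments the lungs of
#' every rendering, computes the five densitometry indices per
#' reconstruction and measures the embedded airway on the inspiratory slice
#' — at the identical seed point for both reconstructions — and finally
#' compares FBP against IR across subjects for all nine measures. Any stage
#' failure excludes the subject (logged with stage and reason) without
#' aborting the cohort; reruns with the same config are identical.
#'
#' @param config A [run_config()].
#' @param verbose Emit per-subject progress messages? Default `FALSE`.
#' @return An object of class `lung_study`: list with `densitometry` and
#'   `airway` (wide per-subject tibbles), `measures` (long tibble),
#'   `agreement` (the nine-row [compare_algorithms()] table), `truth`
#'   (per-subject ground-truth summary), `exclusions` (tibble with
#'   `subject`, `stage`, `reason`), `n_included` and `config`.
#' @export
#' @examples
#' \donttest{
#' cfg <- run_config(n_subjects = 3,
#'                   base_params = phantom_params(grid_shape = c(48, 48, 48)))
#' study <- run_study(cfg)
#' study$agreement
#' }
run_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  cohort <- draw_cohort_params(config$n_subjects, config$severity_ranges,
                               config$seed, config$base_params)
  recons <- list(
    FBP = recon_params("FBP", config$sigma_fbp_hu, 0),
    IR = recon_params("IR", config$sigma_fbp_hu, config$ir_noise_reduction)
  )
  seg <- config$segmentation
  air <- config$airway

  dens_rows <- list()
  airway_rows <- list()
  truth_rows <- list()
  exclusions <- list()

  for (i in seq_len(nrow(cohort))) {
    id <- cohort$subject[i]
    params <- cohort$params[[i]]
    if (verbose) inform(sprintf("[%s] generating phantom", id))
    ph <- generate_phantom(params)
    phase_seeds <- withr::with_seed(
      params$seed,
      sample.int(.Machine$integer.max - 1L, 2L)
    )

    subject_dens <- list()
    subject_air <- list()
    failure <- NULL
    for (lab in names(recons)) {
      rendered <- list(
        insp = apply_reconstruction(ph$insp, recons[[lab]], seed = phase_seeds[1]),
        exp = apply_reconstruction(ph$exp, recons[[lab]], seed = phase_seeds[2])
      )
      if (config$write_volumes && !is.null(config$outdir)) {
        vd <- file.path(config$outdir, "volumes")
        dir.create(vd, recursive = TRUE, showWarnings = FALSE)
        for (phase in c("insp", "exp")) {
          write_ct_volume(rendered[[phase]],
                          file.path(vd, sprintf("%s_%s_%s.nii.gz", id, phase, lab)))
        }
      }
      masks <- list()
      for (phase in c("insp", "exp")) {
        m <- tryCatch(
          segment_lungs(rendered[[phase]],
                        air_threshold_hu = seg$air_threshold_hu,
                        min_component_ml = seg$min_component_ml,
                        airway_cap_ml = seg$airway_cap_ml,
                        min_volume_ml = seg$min_volume_ml,
                        max_volume_ml = seg$max_volume_ml),
          lungqct_segmentation_failure = function(e) e
        )
        if (inherits(m, "condition")) {
          failure <- list(stage = sprintf("segmentation %s %s", phase, lab),
                          reason = conditionMessage(m))
          break
        }
        qc <- check_segmentation(m, rendered[[phase]],
                                 min_volume_ml = seg$min_volume_ml,
                                 max_volume_ml = seg$max_volume_ml,
                                 max_border_fraction = seg$max_border_fraction)
        if (!qc$pass) {
          failure <- list(stage = sprintf("segmentation QC %s %s", phase, lab),
                          reason = qc$reason)
          break
        }
        masks[[phase]] <- m
      }
      if (!is.null(failure)) break

      subject_dens[[lab]] <- dplyr::mutate(
        compute_densitometry(rendered$insp, rendered$exp,
                             masks$insp, masks$exp),
        subject = id, algorithm = lab, .before = 1
      )

      # airway: inspiratory series, identical seed for both reconstructions
      sl <- axial_slice(rendered$insp, ph$truth$airway_slice_index)
      am <- tryCatch(
        measure_airway(sl, ph$truth$airway_center_xy_mm,
                       n_rays = air$n_rays, step_mm = air$step_mm,
                       max_radius_mm = air$max_radius_mm,
                       min_valid_fraction = air$min_valid_fraction,
                       outlier_mad_factor = air$outlier_mad_factor,
                       lumen_threshold_hu = air$lumen_threshold_hu),
        lungqct_measurement_failure = function(e) e,
        lungqct_parameter_error = function(e) e
      )
      if (inherits(am, "condition")) {
        failure <- list(stage = sprintf("airway %s", lab),
                        reason = conditionMessage(am))
        break
      }
      subject_air[[lab]] <- dplyr::mutate(tidy(am), subject = id,
                                          algorithm = lab, .before = 1)
    }

    if (!is.null(failure)) {
      warn(sprintf("Excluding %s at stage '%s': %s",
                   id, failure$stage, failure$reason))
      exclusions[[length(exclusions) + 1L]] <-
        tibble(subject = id, stage = failure$stage, reason = failure$reason)
      next
    }
    dens_rows[[id]] <- dplyr::bind_rows(subject_dens)
    airway_rows[[id]] <- dplyr::bind_rows(subject_air)
    truth_rows[[id]] <- tibble(
      subject = id,
      emphysema_fraction = sum(ph$truth$emphysema_mask) / sum(ph$truth$lung_mask),
      trapping_fraction = sum(ph$truth$trapping_mask) / sum(ph$truth$lung_mask),
      true_LA_mm2 = ph$truth$true_LA_mm2,
      true_WA_mm2 = ph$truth$true_WA_mm2,
      true_Pi_mm = ph$truth$true_Pi_mm,
      lung_volume_ml = ph$truth$lung_volume_ml
    )
  }

  empty_subjects <- tibble(subject = character(), algorithm = character())
  densitometry <- if (length(dens_rows)) dplyr::bind_rows(dens_rows) else
    empty_subjects
  airway_tbl <- if (length(airway_rows)) dplyr::bind_rows(airway_rows) else
    empty_subjects
  exclusions <- if (length(exclusions)) dplyr::bind_rows(exclusions) else
    tibble(subject = character(), stage = character(), reason = character())

  measures <- if (nrow(densitometry) > 0) {
    dens_long <- tidyr::pivot_longer(
      dplyr::select(densitometry, "subject", "algorithm",
                    in950 = "in950_pct", perc15 = "perc15_hu",
                    exp856 = "exp856_pct", rvc = "rvc_pct",
                    ei_ratio = "ei_ratio_pct"),
      cols = -c("subject", "algorithm"),
      names_to = "measure", values_to = "value"
    )
    air_long <- tidyr::pivot_longer(
      dplyr::select(airway_tbl, "subject", "algorithm",
                    la = "la_mm2", wa = "wa_mm2", wa_pct = "wa_pct",
                    pi = "pi_mm"),
      cols = -c("subject", "algorithm"),
      names_to = "measure", values_to = "value"
    )
    out <- dplyr::bind_rows(dens_long, air_long)
    out$measure <- factor(out$measure, levels = measure_levels())
    dplyr::arrange(out, .data$measure, .data$subject)
  } else {
    tibble(subject = character(), algorithm = character(),
           measure = factor(character(), levels = measure_levels()),
           value = numeric())
  }

  agreement <- if (nrow(measures) > 0) {
    m2 <- dplyr::mutate(measures, measure = as.character(.data$measure))
    compare_algorithms(m2, "FBP", "IR")
  } else {
    tibble()
  }

  study <- structure(list(
    densitometry = densitometry,
    airway = airway_tbl,
    measures = measures,
    agreement = agreement,
    truth = if (length(truth_rows)) dplyr::bind_rows(truth_rows) else
      tibble(subject = character()),
    exclusions = exclusions,
    n_included = length(dens_rows),
    config = config
  ), class = "lung_study")

  if (!is.null(config$outdir)) write_study(study, config$outdir)
  study
}

#' @export
print.lung_study <- function(x, ...) {
  cat(sprintf("<lung_study> %d/%d subjects included (%d excluded)\n",
              x$n_included, x$config$n_subjects, nrow(x$exclusions)))
  if (nrow(x$agreement) > 0) {
    print(dplyr::select(as_tibble(x$agreement), "measure", "n", "pc",
                        "agreement_class", "wilcoxon_p"))
  }
  invisible(x)
}

# Write the study tables, exclusion log and config next to each other.
write_study <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$densitometry, file.path(outdir, "densitometry.csv"),
                   row.names = FALSE)
  utils::write.csv(study$airway, file.path(outdir, "airway.csv"),
                   row.names = FALSE)
  utils::write.csv(study$measures, file.path(outdir, "measures.csv"),
                   row.names = FALSE)
  utils::write.csv(study$agreement, file.path(outdir, "agreement.csv"),
                   row.names = FALSE)
  utils::write.csv(study$exclusions, file.path(outdir, "exclusions.csv"),
                   row.names = FALSE)
  cfg <- study$config
  cfg$base_params <- unclass(cfg$base_params)
  jsonlite::write_json(unclass(cfg), file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}
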