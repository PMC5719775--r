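# End-to-end study driver: extraction of all volumes, B0 averaging,
# registration and cleaning, field estimation (first-order and iterative),
# correction, and residual validation by re-running the pipeline on the
# corrected volumes.

#' Extract, register and measure one orientation's displacement samples
#'
#' Runs extraction on the forward (and, if given, reverse) MR volume,
#' averages the polarities to cancel B0, registers the (rotated) CT
#' reference, cleans artifacts with the per-sheet polynomial fit, matches
#' correspondences and computes per-axis displacements.
#'
#' @param ct_points transverse CT `control_points`.
#' @param fwd,rev MR [mr_volume]s (reverse may be `NULL`; B0 then stays in).
#' @param params a [detection_params()].
#' @param clean_tol_mm,match_radius_mm registration settings.
#' @return `displacement_samples` for this orientation, with a `counts`
#'   attribute recording points in/out at each stage.
#' @export
measure_orientation <- function(ct_points, fwd, rev = NULL,
                                params = detection_params(),
                                clean_tol_mm = 3, match_radius_mm = 7.5) {
  orientation <- orientation_from_axes(fwd$axes)
  p_f <- extract_control_points(fwd, params, polarity = "forward")
  counts <- list(extracted_forward = nrow(p_f))
  if (!is.null(rev)) {
    p_r <- extract_control_points(rev, params, polarity = "reverse")
    counts$extracted_reverse <- nrow(p_r)
    mr <- average_forward_reverse(p_f, p_r, match_radius_mm)
  } else {
    mr <- p_f
  }
  counts$after_b0_average <- nrow(mr)
  ct_ref <- permute_ct_reference(ct_points, orientation)
  shift <- register_ct_to_mr(ct_ref, mr)
  ct_shifted <- apply_shift(ct_ref, shift)
  mr_clean <- clean_with_polynomial(mr, ct_shifted, tol_mm = clean_tol_mm)
  counts$removed_artifacts <- attr(mr_clean, "removed_artifacts")
  pairs <- match_correspondences(ct_shifted, mr_clean, match_radius_mm)
  counts$matched <- nrow(pairs)
  counts$unmatched_ct <- attr(pairs, "unmatched_ct")
  samples <- per_axis_displacement(pairs)
  attr(samples, "counts") <- counts
  attr(samples, "shift") <- shift
  samples
}

#' Run the full distortion-mapping study
#'
#' The complete flow: control-point extraction from the CT volume and all MR
#' volumes, forward/reverse averaging, registration, cleaning, matching,
#' first-order and iterative field estimation, spline distortion maps,
#' statistics, and (optionally) correction of the MR volumes plus residual
#' validation — for both the iterative and the first-order maps.
#'
#' @param study list with `ct` ([mr_volume]) and `mr` (named list of
#'   [mr_volume]s, names `orientation_polarity`), as from [simulate_study()].
#' @param params a [detection_params()].
#' @param config an [iteration_config()].
#' @param clean_tol_mm,match_radius_mm registration settings.
#' @param correct run correction + residual validation?
#' @param interp intensity interpolation for correction.
#' @param voi_half_mm half extents of the analysis volume of interest for
#'   the summary statistics (the sampled field extends slightly beyond it,
#'   but sites there depend on extrapolated cross-orientation lookups).
#' @return A `study_report` list: per-orientation samples, `first_order`
#'   and `fit` estimates, `map`, `stats`, `profile`, residual stats, and
#'   stage counts.
#' @export
run_study <- function(study, params = detection_params(),
                      config = iteration_config(),
                      clean_tol_mm = 3, match_radius_mm = 7.5,
                      correct = TRUE, interp = "cubic",
                      voi_half_mm = c(130, 130, 120)) {
  ct_points <- extract_control_points(study$ct, params)
  report <- list(n_ct_points = nrow(ct_points))
  samples <- list()
  for (o in c("transverse", "sagittal", "coronal")) {
    fwd <- study$mr[[paste0(o, "_forward")]]
    rev <- study$mr[[paste0(o, "_reverse")]]
    if (is.null(fwd)) next
    samples[[o]] <- measure_orientation(ct_points, fwd, rev, params,
                                        clean_tol_mm, match_radius_mm)
  }
  if (length(samples) == 0) stop("run_study(): no MR volumes", call. = FALSE)
  report$samples <- samples
  first <- screen_field_outliers(first_order_estimate(
    samples$transverse, samples$sagittal, samples$coronal))
  fit <- iterate_field(samples$transverse, samples$sagittal,
                       samples$coronal, init = first, config = config)
  fit$samples <- screen_field_outliers(fit$samples)
  report$first_order <- first
  report$fit <- fit
  report$map <- build_map(fit$samples)
  report$map_first_order <- build_map(first)
  report$stats <- field_statistics(fit$samples, voi_half_mm)
  report$stats_first_order <- field_statistics(first, voi_half_mm)
  report$profile <- slice_max_profile(fit$samples)
  if (correct) {
    report$residual <- residual_validation(study, report$map, ct_points,
                                           params, config, clean_tol_mm,
                                           match_radius_mm, interp,
                                           voi_half_mm)
    report$residual_first_order <- residual_validation(
      study, report$map_first_order, ct_points, params, config,
      clean_tol_mm, match_radius_mm, interp, voi_half_mm
    )
  }
  class(report) <- "study_report"
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  CT points: %d; orientations: %s\n", x$n_ct_points,
              paste(names(x$samples), collapse = ", ")))
  cat(sprintf("  iterations: %d (%s)\n", x$fit$iterations,
              if (x$fit$converged) "converged" else "not converged"))
  cat("  distortion found (iterative):\n")
  print(as.data.frame(x$stats), digits = 3)
  if (!is.null(x$residual)) {
    cat("  residual after correction (iterative):\n")
    print(as.data.frame(x$residual$stats), digits = 3)
  }
  invisible(x)
}

#' Residual distortion after correcting with a map
#'
#' Corrects every MR volume of the study with the given map and re-runs the
#' whole mapping pipeline (extraction, B0 averaging, registration, cleaning,
#' matching, first-order + iterative estimation) on the rectified volumes.
#' The resulting displacement statistics are the residual distortion — the
#' method's validation surface.
#'
#' @param study as in [run_study()].
#' @param map `distortion_map` used for correction.
#' @param ct_points transverse CT `control_points` (reused).
#' @param params,config,clean_tol_mm,match_radius_mm as in [run_study()].
#' @param interp intensity interpolation for correction.
#' @param voi_half_mm analysis volume of interest for the statistics.
#' @return List with `fit` (residual `distortion_fit`), `stats`,
#'   `profile`.
#' @export
residual_validation <- function(study, map, ct_points,
                                params = detection_params(),
                                config = iteration_config(),
                                clean_tol_mm = 3, match_radius_mm = 7.5,
                                interp = "cubic",
                                voi_half_mm = c(130, 130, 120)) {
  samples <- list()
  for (o in c("transverse", "sagittal", "coronal")) {
    fwd <- study$mr[[paste0(o, "_forward")]]
    rev <- study$mr[[paste0(o, "_reverse")]]
    if (is.null(fwd)) next
    cfwd <- correct_volume(fwd, map, interp = interp)
    crev <- if (!is.null(rev)) correct_volume(rev, map, interp = interp)
    samples[[o]] <- measure_orientation(ct_points, cfwd, crev, params,
                                        clean_tol_mm, match_radius_mm)
  }
  first <- screen_field_outliers(first_order_estimate(
    samples$transverse, samples$sagittal, samples$coronal))
  fit <- iterate_field(samples$transverse, samples$sagittal,
                       samples$coronal, init = first, config = config)
  fit$samples <- screen_field_outliers(fit$samples)
  list(fit = fit, stats = field_statistics(fit$samples, voi_half_mm),
       profile = slice_max_profile(fit$samples))
}
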