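# Readers and writers: NIfTI-1 volumes (world geometry round-tripped through
# the sform), control-point / correspondence / displacement CSVs with JSON
# sidecars, ground-truth exports, and YAML study configuration.

#' Write a volume as NIfTI-1
#'
#' The voxel spacing, world origin and axis permutation are encoded in the
#' sform so that [read_volume()] round-trips the grid and geometry exactly.
#' Modality is carried in the NIfTI description field.
#'
#' @param volume an [mr_volume].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  perm <- match(c("x", "y", "z"), volume$axes)
  sform <- matrix(0, 4, 4)
  for (a in 1:3) {
    # world axis a runs along array dim perm[a]
    sform[a, perm[a]] <- volume$voxel_mm[perm[a]]
    sform[a, 4] <- volume$origin_mm[perm[a]]
  }
  sform[4, 4] <- 1
  img <- RNifti::asNifti(volume$data)
  img <- RNifti::`sform<-`(img, structure(sform, code = 2L))
  img$descrip <- volume$modality
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Accepts axis-aligned volumes (the sform may permute axes but not rotate
#' obliquely); the axis labels, spacing and origin are reconstructed from
#' the sform.
#'
#' @param path NIfTI file.
#' @param modality override the modality (otherwise taken from the
#'   description field, defaulting to MR).
#' @return An [mr_volume].
#' @export
read_volume <- function(path, modality = NULL) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  sform <- rbind(hdr$srow_x, hdr$srow_y, hdr$srow_z)
  dat <- array(as.numeric(img), dim = dim(img))
  if (length(dim(dat)) != 3) {
    stop("read_volume(): expected a 3D volume in ", path, call. = FALSE)
  }
  R <- sform[, 1:3]
  axes <- character(3)
  voxel <- numeric(3)
  origin <- numeric(3)
  for (dim_i in 1:3) {
    nz <- which(abs(R[, dim_i]) > 1e-6)
    if (length(nz) != 1) {
      stop("read_volume(): oblique orientation in ", path,
           " is not supported (sform must be an axis permutation)",
           call. = FALSE)
    }
    if (R[nz, dim_i] < 0) {
      stop("read_volume(): negative axis direction in ", path,
           " is not supported", call. = FALSE)
    }
    axes[dim_i] <- c("x", "y", "z")[nz]
    voxel[dim_i] <- R[nz, dim_i]
    origin[dim_i] <- sform[nz, 4]
  }
  mod <- modality %||% if (identical(hdr$descrip, "CT")) "CT" else "MR"
  mr_volume(dat, voxel, origin, axes, mod)
}

#' Write control points as CSV with a JSON sidecar
#'
#' @param points a `control_points` tibble.
#' @param path CSV path; the sidecar is written next to it as `.json`.
#' @return `path`, invisibly.
#' @export
write_control_points <- function(points, path) {
  utils::write.csv(as.data.frame(points), path, row.names = FALSE)
  meta <- list(
    modality = attr(points, "modality"),
    orientation = attr(points, "orientation"),
    polarity = attr(points, "polarity"),
    n_points = nrow(points)
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Read control points written by [write_control_points()]
#'
#' @param path CSV path.
#' @return A `control_points` tibble.
#' @export
read_control_points <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  meta <- if (file.exists(sidecar_path(path))) {
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  } else {
    list(modality = "MR", orientation = "transverse", polarity = "forward")
  }
  attr(df, "modality") <- meta$modality
  attr(df, "orientation") <- meta$orientation
  attr(df, "polarity") <- meta$polarity
  class(df) <- c("control_points", class(df))
  df
}

#' Write displacement samples (or correspondences) as CSV
#'
#' @param samples a `displacement_samples` or `correspondences` tibble.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(as.data.frame(samples), path, row.names = FALSE)
  invisible(path)
}

#' Export simulator ground truth
#'
#' Writes per-point true displacements as CSV
#' (`x_mm,y_mm,z_mm,dx_mm,dy_mm,dz_mm,dr_mm`) and the model coefficients as
#' JSON.
#'
#' @param geometry a [phantom_geometry].
#' @param model a [distortion_model].
#' @param csv_path,json_path output paths.
#' @return `csv_path`, invisibly.
#' @export
write_ground_truth <- function(geometry, model, csv_path, json_path) {
  nom <- nominal_lattice(geometry)
  tr <- true_displacement(model, nom)
  utils::write.csv(cbind(as.data.frame(nom), as.data.frame(tr)),
                   csv_path, row.names = FALSE)
  coefs <- list(
    scale_mm = model$scale_mm,
    dx = poly_to_list(model$comps$dx),
    dy = poly_to_list(model$comps$dy),
    dz = poly_to_list(model$comps$dz),
    b0 = if (is.null(model$b0)) NULL else poly_to_list(model$b0)
  )
  jsonlite::write_json(coefs, json_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(csv_path)
}

poly_to_list <- function(pmat) {
  lapply(seq_len(nrow(pmat)), function(r) {
    list(px = pmat[r, 1], py = pmat[r, 2], pz = pmat[r, 3],
         coef = pmat[r, 4])
  })
}

#' Read a study configuration from YAML
#'
#' Recognised top-level keys: `volumes` (paths: `ct`,
#' `<orientation>_<polarity>`), `detection`, `iteration`, `registration`
#' (`clean_tol_mm`, `match_radius_mm`), `seed`, `output_dir`. Missing
#' sections fall back to package defaults.
#'
#' @param path YAML file.
#' @return A list with `volumes`, `params`, `config`, `registration`,
#'   `seed`, `output_dir`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  params <- do.call(detection_params, y$detection %||% list())
  config <- do.call(iteration_config, y$iteration %||% list())
  list(
    volumes = y$volumes %||% list(),
    params = params,
    config = config,
    registration = list(
      clean_tol_mm = y$registration$clean_tol_mm %||% 3,
      match_radius_mm = y$registration$match_radius_mm %||% 7.5
    ),
    seed = y$seed %||% 1L,
    output_dir = y$output_dir %||% "."
  )
}

#' Write a study report to a directory
#'
#' Emits the per-orientation sample CSVs, field sample CSVs, a JSON stats
#' report (summary statistics, per-slice maxima, iteration diagnostics,
#' stage counts) and, when present, the residual statistics.
#'
#' @param report a `study_report` from [run_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (o in names(report$samples)) {
    write_samples(report$samples[[o]],
                  file.path(dir, paste0("samples_", o, ".csv")))
  }
  write_samples(report$fit$samples, file.path(dir, "field_iterative.csv"))
  write_samples(report$first_order, file.path(dir, "field_first_order.csv"))
  js <- list(
    n_ct_points = report$n_ct_points,
    counts = lapply(report$samples, function(s) attr(s, "counts")),
    iterations = report$fit$iterations,
    converged = report$fit$converged,
    gap_trace_mm = report$fit$gap_trace,
    stats = as.data.frame(report$stats),
    stats_first_order = as.data.frame(report$stats_first_order),
    profile = as.data.frame(report$profile)
  )
  if (!is.null(report$residual)) {
    js$residual_stats <- as.data.frame(report$residual$stats)
    js$residual_stats_first_order <-
      as.data.frame(report$residual_first_order$stats)
  }
  jsonlite::write_json(js, file.path(dir, "report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
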