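# Shared fixtures. Small phantoms keep unit tests fast; the heavyweight
# acceptance fixtures (full-resolution detection volume, complete half-
# resolution study) are computed lazily once and cached for the acceptance
# tests that share them.

small_geometry <- function() {
  phantom_geometry(n_sheets = 3L, points_per_row = 5L,
                   box_inner_mm = c(110, 110, 80))
}

small_fov <- c(100.8, 100.8, 72)

# a gentle degree-3 field, |delta| <= ~2 mm over the small phantom
small_model <- function() {
  distortion_model(
    dx = c(x3 = 0.4, x = 0.3, z = -0.5),
    dy = c(y3 = 0.4, y = 0.2, z = 0.4),
    dz = c(z3 = 0.5, z = 0.3),
    scale_mm = 40
  )
}

nearest_errors <- function(points, lattice) {
  n <- nrow(points)
  err <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    d2 <- (lattice$x_mm - points$x_mm[i])^2 +
      (lattice$y_mm - points$y_mm[i])^2 +
      (lattice$z_mm - points$z_mm[i])^2
    j <- which.min(d2)
    err[i, ] <- c(points$x_mm[i] - lattice$x_mm[j],
                  points$y_mm[i] - lattice$y_mm[j],
                  points$z_mm[i] - lattice$z_mm[j])
  }
  err
}

.acc_cache <- new.env(parent = emptyenv())

acc_fixture <- function(name, build) {
  if (!exists(name, envir = .acc_cache)) {
    assign(name, build(), envir = .acc_cache)
  }
  get(name, envir = .acc_cache)
}

# full default-resolution MR volume under the study artifact conditions
# (30 % bias, 5 % noise, 10 bubbles), no distortion
acc_fullres_detection <- function() {
  acc_fixture("fullres", function() {
    geom <- phantom_geometry()
    vol <- simulate_mr_volume(
      geom, zero_model(),
      acquisition_config(voxel_mm = c(0.9, 0.9, 1.0), seed = 11L)
    )
    list(points = extract_control_points(vol), geometry = geom)
  })
}

# complete half-resolution study: simulate + full pipeline with correction
# and residual validation for both the iterative and first-order maps
acc_study <- function() {
  acc_fixture("study", function() {
    geom <- phantom_geometry()
    model <- default_study_model()
    study <- simulate_study(geom, model, seed = 7L)
    report <- run_study(study, correct = TRUE)
    list(study = study, report = report, geometry = geom, model = model)
  })
}
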