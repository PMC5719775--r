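# Image rectification and the isocenter-offset handling.

test_that("isocenter shift follows the header arithmetic", {
  expect_equal(unname(isocenter_shift(450, 225, 225)), c(0, 0))
  expect_equal(unname(isocenter_shift(450, 200, 225)), c(25, 0))
  expect_equal(unname(isocenter_shift(c(450, 400), 225, 180)), c(0, 20))
  expect_error(isocenter_shift(NULL, 1, 2), "explicit shift")
})

test_that("a zero map leaves the volume unchanged within tolerance", {
  geom <- small_geometry()
  vol <- rasterize_phantom(geom, c(1.8, 1.8, 2), "MR", small_fov)
  nom <- nominal_lattice(geom)
  zs <- tibble::tibble(
    x_mm = nom$x_mm, y_mm = nom$y_mm, z_mm = nom$z_mm,
    dx_mm = 0, dy_mm = 0, dz_mm = 0, dr_mm = 0
  )
  class(zs) <- c("displacement_samples", class(zs))
  out <- correct_volume(vol, build_map(zs))
  expect_lt(max(abs(out$data - vol$data)) / diff(range(vol$data)), 0.01)
})

test_that("correction undoes the forward warp (round trip on centroids)", {
  geom <- small_geometry()
  m <- small_model()
  cfg <- acquisition_config(voxel_mm = c(1.8, 1.8, 2), fov_mm = small_fov,
                            bias_amplitude = 0, noise_sigma = 0,
                            bubble_count = 0)
  warped <- simulate_mr_volume(geom, m, cfg)
  nom <- nominal_lattice(geom)
  d <- fixed_point_displacement(m, nom)
  truth <- tibble::tibble(
    x_mm = nom$x_mm, y_mm = nom$y_mm, z_mm = nom$z_mm,
    dx_mm = d$dx_mm, dy_mm = d$dy_mm, dz_mm = d$dz_mm, dr_mm = d$dr_mm
  )
  class(truth) <- c("displacement_samples", class(truth))
  corrected <- correct_volume(warped, build_map(truth))
  pts <- extract_control_points(corrected)
  expect_equal(nrow(pts), nrow(nom))
  err <- nearest_errors(pts, nom)
  expect_lt(max(abs(err[, 1])) / 1.8, 0.5)
  expect_lt(max(abs(err[, 2])) / 1.8, 0.5)
  expect_lt(max(abs(err[, 3])) / 2.0, 0.5)
})

test_that("the in-plane isocenter shift relocates the map lookup", {
  geom <- small_geometry()
  m <- small_model()
  cfg <- acquisition_config(voxel_mm = c(1.8, 1.8, 2), fov_mm = small_fov,
                            bias_amplitude = 0, noise_sigma = 0,
                            bubble_count = 0)
  warped <- simulate_mr_volume(geom, m, cfg)
  nom <- nominal_lattice(geom)
  d <- fixed_point_displacement(m, nom)
  truth <- tibble::tibble(
    x_mm = nom$x_mm, y_mm = nom$y_mm, z_mm = nom$z_mm,
    dx_mm = d$dx_mm, dy_mm = d$dy_mm, dz_mm = d$dz_mm, dr_mm = d$dr_mm
  )
  class(truth) <- c("displacement_samples", class(truth))
  # shifting the frame one way and the map sites the other cancels exactly
  off <- c(12, -8)
  truth_shifted <- truth
  truth_shifted$x_mm <- truth$x_mm + off[1]
  truth_shifted$y_mm <- truth$y_mm + off[2]
  class(truth_shifted) <- class(truth)
  corr <- correct_volume(warped, build_map(truth_shifted), shift = off)
  pts <- extract_control_points(corr)
  err <- nearest_errors(pts, nom)
  expect_lt(max(abs(err)), 1.0)
})

test_that("difference volumes are antisymmetric and grid-checked", {
  geom <- small_geometry()
  a <- rasterize_phantom(geom, c(1.8, 1.8, 2), "MR", small_fov)
  b <- a
  b$data <- a$data + 5
  d1 <- difference_volume(a, b)
  d2 <- difference_volume(b, a)
  expect_equal(d1$data, -d2$data)
  expect_equal(unique(as.numeric(d1$data)), -5)
  small <- rasterize_phantom(geom, c(2, 2, 2), "MR", small_fov)
  expect_error(difference_volume(a, small), "identical grids")
})
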