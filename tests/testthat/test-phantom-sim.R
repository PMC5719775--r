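# Synthetic phantom and scanner simulator.

test_that("phantom geometry defaults and lattice arithmetic", {
  geom <- phantom_geometry()
  expect_equal(geom$n_sheets, 17L)
  expect_equal(geom$points_per_row, 17L)
  expect_equal(geom$point_pitch_mm, 15)
  expect_equal(geom$sheet_thickness_mm, 7.6)
  expect_equal(geom$gap_mm, 9)
  nom <- nominal_lattice(geom)
  expect_equal(nrow(nom), 17^3)
  # in-plane span is 16 pitches = 240 mm, centered on the isocenter
  expect_equal(max(nom$x_mm) - min(nom$x_mm), 240)
  expect_equal(max(nom$y_mm) - min(nom$y_mm), 240)
  expect_equal(mean(nom$z_mm), 0)
  # one-sheet phantom has exactly points_per_row^2 crossings in one slab
  g1 <- phantom_geometry(n_sheets = 1L, points_per_row = 5L)
  n1 <- nominal_lattice(g1)
  expect_equal(nrow(n1), 25)
  expect_equal(unique(n1$z_mm), 0)
  expect_error(phantom_geometry(n_sheets = 0), "n_sheets")
})

test_that("rasterized centroids sit on the nominal lattice", {
  geom <- small_geometry()
  nom <- nominal_lattice(geom)
  for (modality in c("MR", "CT")) {
    vol <- rasterize_phantom(geom, c(1.8, 1.8, 2), modality, small_fov)
    pts <- extract_control_points(vol)
    expect_equal(nrow(pts), nrow(nom))
    err <- nearest_errors(pts, nom)
    # within half a voxel of the nominal lattice
    expect_lt(max(abs(err[, 1])) / 1.8, 0.5)
    expect_lt(max(abs(err[, 2])) / 1.8, 0.5)
    expect_lt(max(abs(err[, 3])) / 2.0, 0.5)
  }
})

test_that("rasterize_phantom rejects a matrix too small for the lattice", {
  expect_error(
    rasterize_phantom(phantom_geometry(), c(2, 2, 2), "MR", c(100, 100, 100)),
    "does not fit"
  )
})

test_that("true_displacement: zero model, B0 symmetry, closed forms", {
  pts <- matrix(c(100, 0, 0, 0, 50, -80), 2, 3, byrow = TRUE)
  expect_equal(as.matrix(true_displacement(zero_model(), pts)[, 1:3]),
               matrix(0, 2, 3), ignore_attr = TRUE)
  # cubic closed form: dx = 1e-6 * x^3 (scale folded into the coefficient)
  m <- distortion_model(dx = c(x3 = 1), scale_mm = 100)
  expect_equal(true_displacement(m, matrix(c(100, 0, 0), 1))$dx_mm, 1)
  # pure-B0 model: forward and reverse displacements are equal and opposite,
  # and their mean vanishes
  mb <- distortion_model(b0 = c(x2 = 1.5, y = 0.7), scale_mm = 100)
  fw <- true_displacement(mb, pts, "forward", read_axis = "x")
  rv <- true_displacement(mb, pts, "reverse", read_axis = "x")
  expect_equal(fw$dx_mm, -rv$dx_mm)
  expect_equal(fw$dx_mm + rv$dx_mm, c(0, 0))
  expect_equal(fw$dy_mm, c(0, 0))
})

test_that("default study model is negligible at the isocenter and realistic in magnitude", {
  m <- default_study_model()
  d0 <- true_displacement(m, matrix(0, 1, 3))
  expect_lt(d0$dr_mm, 0.1)
  mx <- model_max_displacement(m, c(120, 120, 120))
  expect_gt(mx, 4)
  expect_lt(mx, 6.5)
})

test_that("warp moves detected centroids by the modelled displacement", {
  geom <- small_geometry()
  ideal <- rasterize_phantom(geom, c(1.8, 1.8, 2), "MR", small_fov)
  shift <- distortion_model(dx = c("1" = 3.6))  # rigid 2-voxel shift
  cfg <- acquisition_config(voxel_mm = c(1.8, 1.8, 2), fov_mm = small_fov,
                            bias_amplitude = 0, noise_sigma = 0,
                            bubble_count = 0)
  warped <- warp_volume(ideal, shift, cfg)
  p0 <- extract_control_points(ideal)
  p1 <- extract_control_points(warped)
  expect_equal(nrow(p1), nrow(p0))
  expect_equal(mean(p1$x_mm) - mean(p0$x_mm), 3.6, tolerance = 0.05)
  expect_lt(abs(mean(p1$y_mm) - mean(p0$y_mm)), 0.1)
  # zero model: warp is the identity up to interpolation tolerance
  same <- warp_volume(ideal, zero_model(), cfg)
  expect_lt(max(abs(same$data - ideal$data)) / diff(range(ideal$data)), 0.01)
})

test_that("forward and reverse warps of a pure B0 model mirror each other", {
  geom <- small_geometry()
  mb <- distortion_model(b0 = c(x = 4, z2 = 2), scale_mm = 50)
  mk <- function(pol) {
    simulate_mr_volume(geom, mb, acquisition_config(
      polarity = pol, voxel_mm = c(1.8, 1.8, 2), fov_mm = small_fov,
      bias_amplitude = 0, noise_sigma = 0, bubble_count = 0
    ))
  }
  pf <- extract_control_points(mk("forward"))
  pr <- extract_control_points(mk("reverse"))
  nom <- nominal_lattice(geom)
  ef <- nearest_errors(pf, nom)
  er <- nearest_errors(pr, nom)
  # displacements equal in magnitude, opposite in sign (read axis x),
  # up to the small phantom's detection floor (~0.1 mm)
  expect_equal(mean(ef[, 1]), -mean(er[, 1]), tolerance = 0.25)
  expect_gt(mean(abs(ef[, 1])), 0.4)
  avg <- average_forward_reverse(pf, pr)
  ea <- nearest_errors(avg, nom)
  # averaging cancels the B0 shift down to the detection floor
  expect_lt(mean(abs(ea[, 1])), 0.3 * mean(abs(ef[, 1])))
})

test_that("bias field preserves the mean and is removed by unsharp masking", {
  geom <- small_geometry()
  vol <- rasterize_phantom(geom, c(1.8, 1.8, 2), "MR", small_fov)
  expect_identical(apply_bias_field(vol, 0)$data, vol$data)
  b <- apply_bias_field(vol, 0.3, seed = 5)
  expect_lt(abs(mean(b$data) - mean(vol$data)) / mean(vol$data), 0.02)
  # per-slice medians really do vary under the bias
  med <- apply(b$data, 3, stats::median)
  expect_gt(diff(range(med)) / stats::median(med), 0.1)
  # the unsharp operator suppresses a bias much broader than its sigma to
  # a few percent (away from the boundary-window region)
  broad <- apply_bias_field(vol, 0.3, scale_mm = 240, seed = 5)
  field <- broad$data[, , 10] / vol$data[, , 10]
  resid <- unsharp_mask(field, 15, c(1.8, 1.8))
  interior <- 15:42
  expect_lt(max(abs(resid[interior, interior])) /
              (max(field) - min(field)), 0.05)
})

test_that("noise and bubbles are seeded and reproducible", {
  geom <- small_geometry()
  vol <- rasterize_phantom(geom, c(1.8, 1.8, 2), "MR", small_fov)
  expect_identical(add_noise_and_bubbles(vol, 0, 0L)$data, vol$data)
  a <- add_noise_and_bubbles(vol, 30, 5L, seed = 42)
  b <- add_noise_and_bubbles(vol, 30, 5L, seed = 42)
  expect_identical(a$data, b$data)
  c2 <- add_noise_and_bubbles(vol, 30, 5L, seed = 43)
  expect_false(identical(a$data, c2$data))
  # bubbles leave the detected point set unchanged (guarded placement)
  nb <- add_noise_and_bubbles(vol, 0, 8L, seed = 9,
                              avoid_points = as.matrix(nominal_lattice(geom)))
  pts <- extract_control_points(nb)
  expect_equal(nrow(pts), nrow(nominal_lattice(geom)))
})

test_that("fixed_point_displacement reduces to the plain field when uncoupled", {
  m <- distortion_model(dx = c(x3 = 1, x = 0.5), dy = c(y2 = 0.8),
                        dz = c(z3 = 0.6), scale_mm = 100)
  pts <- matrix(stats::runif(30, -90, 90), 10, 3)
  fp <- fixed_point_displacement(m, pts)
  pl <- true_displacement(m, pts)
  expect_equal(fp$dx_mm, pl$dx_mm, tolerance = 1e-6)
  expect_equal(fp$dz_mm, pl$dz_mm, tolerance = 1e-6)
})
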