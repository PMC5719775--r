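# Per-slice detection pipeline and control-point extraction.

test_that("invert_if_mr flips MR only and is an involution up to a constant", {
  geom <- small_geometry()
  mr <- rasterize_phantom(geom, c(1.8, 1.8, 2), "MR", small_fov)
  ct <- rasterize_phantom(geom, c(1.8, 1.8, 2), "CT", small_fov)
  expect_identical(invert_if_mr(ct)$data, ct$data)
  inv <- invert_if_mr(mr)
  expect_equal(inv$data, max(mr$data) - mr$data)
  twice <- invert_if_mr(inv)
  expect_equal(twice$data, mr$data - min(mr$data), tolerance = 1e-12)
})

test_that("unsharp masking zeroes constants and suppresses smooth bias", {
  const <- matrix(7, 40, 40)
  expect_equal(max(abs(unsharp_mask(const, 20, c(1, 1)))), 0,
               tolerance = 1e-10)
  xs <- seq(-50, 50, length.out = 101)
  bias <- outer(1 + 0.3 * sin(xs / 60), 1 + 0.2 * cos(xs / 80))
  resid <- unsharp_mask(bias, 15, c(1, 1))
  interior <- 31:71   # away from the boundary-window region
  expect_lt(max(abs(resid[interior, interior])),
            0.05 * diff(range(bias)))
})

test_that("adaptive threshold is scale invariant and keeps the grid", {
  set.seed(1)
  img <- matrix(-0.1 + 0.05 * rnorm(3600), 60, 60)
  img[, c(15, 45)] <- img[, c(15, 45)] + 1
  img[c(20, 40), ] <- img[c(20, 40), ] + 1
  m1 <- adaptive_threshold(img)
  m2 <- adaptive_threshold(img * 2)
  expect_identical(m1, m2)
  # the full grid support survives, background is mostly removed
  expect_true(all(m1[c(20, 40), c(15, 45)] == 1))
  expect_lt(mean(m1[-c(20, 40), -c(15, 45)]), 0.05)
  expect_warning(adaptive_threshold(matrix(1, 5, 5)), "dynamic range")
})

test_that("line-intersection mask isolates crossings and rejects blobs", {
  img <- matrix(0, 80, 80)
  img[, 40] <- 1      # line along dim 1
  img[40, ] <- 1      # line along dim 2
  img[disc <- as.matrix(expand.grid(18:22, 18:22))] <- 1  # compact blob
  d <- line_intersection_mask(img, 5, c(1, 1), cross_sigma_mm = 2)
  lab <- separate_and_filter_dots(d, detection_params(expected_dot_px = 40),
                                  c(1, 1))
  expect_equal(max(lab), 1L)  # single dot at the crossing; blob rejected
  sel <- which(lab > 0L)
  ci <- mean((sel - 1) %% 80 + 1)
  cj <- mean((sel - 1) %/% 80 + 1)
  expect_equal(ci, 40, tolerance = 1)
  expect_equal(cj, 40, tolerance = 1)
})

test_that("a full synthetic grid slice yields one dot per crossing", {
  geom <- phantom_geometry(n_sheets = 1L)
  vol <- rasterize_phantom(geom, c(0.9, 0.9, 1), "MR",
                           fov_mm = c(280.8, 280.8, 12))
  pts <- extract_control_points(vol)
  expect_equal(nrow(pts), 289)
})

test_that("dot centroids are sub-voxel accurate (moment oracle)", {
  # symmetric Gaussian dot centred between pixels
  img <- outer(stats::dnorm(1:21, 10.5, 2), stats::dnorm(1:21, 12.25, 2))
  lab <- matrix(0L, 21, 21)
  lab[img > 0.002] <- 1L
  cen <- dot_centroids(lab, img, c(0, 0), c(1, 1))
  sel <- which(lab > 0)
  i <- (sel - 1) %% 21 + 1
  j <- (sel - 1) %/% 21 + 1
  expect_equal(cen$u_mm, sum(img[sel] * i) / sum(img[sel]) - 1,
               tolerance = 1e-10)
  expect_equal(cen$v_mm, sum(img[sel] * j) / sum(img[sel]) - 1,
               tolerance = 1e-10)
  expect_equal(cen$u_mm + 1, 10.5, tolerance = 0.05)
})

test_that("extraction is invariant to intensity scaling and deterministic", {
  geom <- small_geometry()
  vol <- simulate_mr_volume(geom, small_model(), acquisition_config(
    voxel_mm = c(1.8, 1.8, 2), fov_mm = small_fov, seed = 3
  ))
  p1 <- extract_control_points(vol)
  v2 <- vol; v2$data <- vol$data * 2.5
  p2 <- extract_control_points(v2)
  expect_equal(nrow(p1), nrow(p2))
  expect_equal(p1$x_mm, p2$x_mm, tolerance = 1e-8)
  p3 <- extract_control_points(vol)
  expect_identical(p1$x_mm, p3$x_mm)
})

test_that("bias, noise and bubbles do not change the point count", {
  geom <- small_geometry()
  nom <- nominal_lattice(geom)
  clean <- rasterize_phantom(geom, c(1.8, 1.8, 2), "MR", small_fov)
  dirty <- simulate_mr_volume(geom, zero_model(), acquisition_config(
    voxel_mm = c(1.8, 1.8, 2), fov_mm = small_fov,
    bias_amplitude = 0.3, noise_sigma = 50, bubble_count = 5L, seed = 21
  ))
  pc <- extract_control_points(clean)
  pd <- extract_control_points(dirty)
  expect_equal(nrow(pc), nrow(nom))
  expect_equal(nrow(pd), nrow(nom))
  ec <- nearest_errors(pc, nom)
  ed <- nearest_errors(pd, nom)
  expect_lt(max(abs(ed)), 1.0)
  # retained centroids move only slightly under the artifacts
  expect_lt(sqrt(mean((ed - ec)^2)), 0.35)
})

test_that("an oil-only volume yields an empty set with a warning", {
  geom <- small_geometry()
  vol <- rasterize_phantom(geom, c(1.8, 1.8, 2), "MR", small_fov)
  vol$data[] <- 1000
  vol$data[1] <- 999   # non-degenerate range
  expect_warning(pts <- extract_control_points(vol), "no dots")
  expect_equal(nrow(pts), 0)
})

test_that("a long streak is removed by the area filter on CT slices", {
  geom <- phantom_geometry(n_sheets = 1L)
  vol <- rasterize_phantom(geom, c(0.9, 0.9, 1), "CT",
                           fov_mm = c(280.8, 280.8, 12))
  vol$data[, 30, ] <- 1000   # couch-like streak across all slices
  pts <- extract_control_points(vol)
  expect_equal(nrow(pts), 289)
})
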