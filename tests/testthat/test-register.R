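# Registration, cleaning and correspondence matching.

make_points <- function(xyz, orientation = "transverse") {
  out <- tibble::tibble(
    x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3],
    slice = seq_len(nrow(xyz)), area_px = 10, intensity = 1
  )
  attr(out, "modality") <- "MR"
  attr(out, "orientation") <- orientation
  attr(out, "polarity") <- "forward"
  class(out) <- c("control_points", class(out))
  out
}

lattice_points <- function(geometry = phantom_geometry(),
                           orientation = "transverse") {
  make_points(as.matrix(nominal_lattice(geometry, orientation)), orientation)
}

test_that("registration recovers applied translations", {
  ct <- lattice_points()
  mr <- ct
  expect_equal(unname(register_ct_to_mr(ct, mr)), c(0, 0, 0),
               tolerance = 1e-10)
  tr <- c(3.2, -1.1, 2.0)
  ct2 <- ct
  ct2$x_mm <- ct$x_mm + tr[1]
  ct2$y_mm <- ct$y_mm + tr[2]
  ct2$z_mm <- ct$z_mm + tr[3]
  sh <- register_ct_to_mr(ct2, mr)
  expect_equal(unname(sh), tr, tolerance = 0.1)
  expect_equal(apply_shift(ct2, sh)$x_mm, ct$x_mm, tolerance = 0.1)
})

test_that("registration tolerates edge distortion when the center is clean", {
  geom <- phantom_geometry()
  ct <- lattice_points(geom)
  m <- default_study_model()
  d <- true_displacement(m, ct)
  mr <- ct
  mr$x_mm <- ct$x_mm + d$dx_mm
  mr$y_mm <- ct$y_mm + d$dy_mm
  mr$z_mm <- ct$z_mm + d$dz_mm
  sh <- register_ct_to_mr(ct, mr)
  expect_lt(max(abs(sh)), 0.2)
})

test_that("registration errors without a point near the isocenter", {
  ct <- lattice_points()
  far <- ct[sqrt(ct$x_mm^2 + ct$y_mm^2 + ct$z_mm^2) > 40, ]
  class(far) <- class(ct)
  expect_error(register_ct_to_mr(ct, far), "isocenter")
})

test_that("CT reformatting is the exact axis permutation of the rotation", {
  geom <- phantom_geometry()
  ct <- lattice_points(geom)
  for (o in c("sagittal", "coronal")) {
    ref <- permute_ct_reference(ct, o)
    expect_equal(
      as.matrix(ref[, c("x_mm", "y_mm", "z_mm")]),
      as.matrix(nominal_lattice(geom, o)),
      ignore_attr = TRUE
    )
  }
})

test_that("polynomial cleaning removes planted artifacts and keeps truth", {
  geom <- phantom_geometry()
  ct <- lattice_points(geom)
  m <- default_study_model()
  d <- true_displacement(m, ct)
  mr <- ct
  mr$x_mm <- ct$x_mm + d$dx_mm
  mr$y_mm <- ct$y_mm + d$dy_mm
  mr$z_mm <- ct$z_mm + d$dz_mm
  expect_equal(nrow(clean_with_polynomial(mr, ct)), nrow(mr))
  # plant 20 false points midway between grid sites (surviving bubbles)
  set.seed(4)
  fake_idx <- sample(nrow(ct), 20)
  fake <- mr[fake_idx, ]
  fake$x_mm <- fake$x_mm + 7.5
  fake$y_mm <- fake$y_mm + 6
  both <- dplyr::bind_rows(mr, fake)
  attr(both, "orientation") <- "transverse"
  class(both) <- class(mr)
  cleaned <- clean_with_polynomial(both, ct, tol_mm = 3)
  expect_equal(attr(cleaned, "removed_artifacts"), 20)
  expect_equal(nrow(cleaned), nrow(mr))
  # none of the genuine points were removed
  expect_true(all(round(cleaned$x_mm, 6) %in% round(mr$x_mm, 6)))
})

test_that("cleaning keeps points whose residual is within tolerance", {
  geom <- phantom_geometry()
  ct <- lattice_points(geom)
  mr <- ct
  # a local wiggle beyond what a cubic can follow, but within tol
  wig <- which(abs(ct$z_mm) < 1 & abs(ct$x_mm) < 40)
  mr$y_mm[wig] <- mr$y_mm[wig] + 2.0 * sin(mr$x_mm[wig] / 5)
  cleaned <- clean_with_polynomial(mr, ct, tol_mm = 3)
  expect_equal(nrow(cleaned), nrow(mr))
})

test_that("matching is a within-radius bijection with greedy resolution", {
  ct <- lattice_points()
  mr <- ct
  pairs <- match_correspondences(ct, mr, 7.5)
  expect_equal(nrow(pairs), nrow(ct))
  expect_equal(max(pairs$dist_mm), 0)
  # displaced by a known smooth field: all matched, vectors equal the field
  m <- default_study_model()
  d <- true_displacement(m, ct)
  mr2 <- ct
  mr2$x_mm <- ct$x_mm + d$dx_mm
  mr2$y_mm <- ct$y_mm + d$dy_mm
  mr2$z_mm <- ct$z_mm + d$dz_mm
  p2 <- match_correspondences(ct, mr2, 7.5)
  expect_equal(nrow(p2), nrow(ct))
  expect_equal(p2$x_mr - p2$x_ct,
               true_displacement(m, tibble::tibble(
                 x_mm = p2$x_ct, y_mm = p2$y_ct, z_mm = p2$z_ct))$dx_mm,
               tolerance = 1e-8)
  expect_true(all(p2$dist_mm <= 7.5))
  expect_equal(anyDuplicated(paste(p2$x_mr, p2$y_mr, p2$z_mr)), 0)
  # deleting one MR point unmatches exactly one CT point
  mr3 <- mr[-100, ]
  class(mr3) <- class(mr)
  p3 <- suppressWarnings(match_correspondences(ct, mr3, 7.5))
  expect_equal(nrow(p3), nrow(ct) - 1)
})

test_that("forward/reverse averaging is the coordinate-wise mean", {
  f <- make_points(matrix(c(10.2, 5, -3), 1))
  r <- make_points(matrix(c(9.8, 5, -3), 1))
  avg <- average_forward_reverse(f, r)
  expect_equal(avg$x_mm, 10.0)
  expect_equal(avg$y_mm, 5)
  expect_identical(attr(avg, "polarity"), "averaged")
  same <- average_forward_reverse(f, f)
  expect_equal(same$x_mm, f$x_mm)
})
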