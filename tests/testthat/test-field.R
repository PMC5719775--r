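# Field estimation: per-axis displacements, first-order and iterative
# estimates, interpolated maps, statistics.

analytic_three <- function(model, geometry = phantom_geometry()) {
  list(
    tra = synthetic_orientation_samples(model, geometry, "transverse"),
    sag = synthetic_orientation_samples(model, geometry, "sagittal"),
    cor = synthetic_orientation_samples(model, geometry, "coronal")
  )
}

test_that("per-axis displacement components and the total norm", {
  pairs <- tibble::tibble(
    x_ct = c(0, 10), y_ct = c(0, 0), z_ct = c(0, 5),
    x_mr = c(3, 10), y_mr = c(4, 0), z_mr = c(-5, 5),
    dist_mm = 0
  )
  attr(pairs, "orientation") <- "transverse"
  class(pairs) <- c("correspondences", class(pairs))
  s <- per_axis_displacement(pairs)
  expect_equal(s$dx_mm, c(3, 0))
  expect_equal(s$dy_mm, c(4, 0))
  expect_equal(s$dz_mm, c(-5, 0))
  expect_equal(s$dr_mm, c(sqrt(3^2 + 4^2 + 5^2), 0))
  # the norm identity holds on every emitted sample of a real set
  m <- default_study_model()
  a <- synthetic_orientation_samples(m)
  expect_equal(a$dr_mm, sqrt(a$dx_mm^2 + a$dy_mm^2 + a$dz_mm^2))
})

test_that("first-order estimate averages the two orientation measurements", {
  m <- default_study_model()
  s <- analytic_three(m)
  first <- first_order_estimate(s$tra, s$sag, s$cor)
  # at a site, dx0 is the mean of the transverse and coronal x measurements
  i <- which(first$x_mm == 0 & first$y_mm == 0 & abs(first$z_mm) < 1)[1]
  site <- first[i, c("x_mm", "y_mm", "z_mm")]
  v_tra <- s$tra$dx_mm[s$tra$x_mm == site$x_mm & s$tra$y_mm == site$y_mm &
                         s$tra$z_mm == site$z_mm]
  expect_equal(first$dx_mm[i], v_tra, tolerance = 0.05)  # cor agrees at center
  expect_false(any(first$single_estimate))
  # a missing orientation flags single estimates
  f1 <- first_order_estimate(s$tra, s$sag, NULL)
  expect_true(all(f1$single_estimate))
})

test_that("first-order is exact without through-plane coupling, biased with it", {
  geom <- phantom_geometry()
  sep <- distortion_model(dx = c(x3 = 1.5, x = 0.5), dy = c(y3 = 1.2),
                          dz = c(z3 = 1.4), scale_mm = 130)
  s <- analytic_three(sep, geom)
  first <- first_order_estimate(s$tra, s$sag, s$cor)
  # restrict to the analysis VOI (|z| <= 120): beyond it the cross-
  # orientation lookups extrapolate past the in-plane lattice
  voi <- abs(first$z_mm) <= 120
  tr <- true_displacement(sep, first)
  expect_lt(max(abs(first$dx_mm - tr$dx_mm)[voi]), 0.02)
  expect_lt(max(abs(first$dz_mm - tr$dz_mm)[voi]), 0.02)
  # strong z-coupling in the in-plane components biases the first order
  cpl <- default_study_model()
  s2 <- analytic_three(cpl, geom)
  f2 <- first_order_estimate(s2$tra, s2$sag, s2$cor)
  tr2 <- true_displacement(cpl, f2)
  expect_gt(max(abs(f2$dx_mm - tr2$dx_mm)), 0.15)
})

test_that("iteration recovers coupled degree-3 fields from noiseless samples", {
  geom <- phantom_geometry()
  set.seed(31)
  for (case in 1:3) {
    m <- distortion_model(
      dx = c(x3 = stats::runif(1, 0.5, 1), x = 0.3,
             z3 = stats::runif(1, 6, 10), z = stats::runif(1, -8, -5)),
      dy = c(y3 = 0.7, y = 0.3, z2 = stats::runif(1, -2, 2)),
      dz = c(z3 = stats::runif(1, 1.5, 2.5), z = 0.3, x2z = 0.5),
      scale_mm = 130
    )
    s <- analytic_three(m, geom)
    fit <- iterate_field(s$tra, s$sag, s$cor)
    expect_true(fit$converged)
    expect_lte(fit$iterations, 4)
    tr <- fixed_point_displacement(m, fit$samples)
    err <- cbind(fit$samples$dx_mm - tr$dx_mm,
                 fit$samples$dy_mm - tr$dy_mm,
                 fit$samples$dz_mm - tr$dz_mm)
    expect_lt(sqrt(mean(err^2)), 0.2)
    # iterated beats first-order against the fixed-point target away from
    # the isocenter
    first <- first_order_estimate(s$tra, s$sag, s$cor)
    e_first <- rowSums(cbind(first$dx_mm - tr$dx_mm,
                             first$dy_mm - tr$dy_mm,
                             first$dz_mm - tr$dz_mm)^2)
    e_fit <- rowSums(err^2)
    far <- abs(fit$samples$z_mm) > 100
    expect_gt(mean(e_fit[far] < e_first[far]), 0.9)
  }
})

test_that("a position-independent field converges in one iteration", {
  m <- distortion_model(dx = c("1" = 2), dy = c("1" = -1), dz = c("1" = 0.5))
  s <- analytic_three(m)
  fit <- iterate_field(s$tra, s$sag, s$cor)
  expect_true(fit$converged)
  expect_equal(fit$iterations, 1L)
  expect_equal(fit$samples$dx_mm, fit$init$dx_mm, tolerance = 1e-8)
})

test_that("axis update order changes converged values by under 2 %", {
  m <- default_study_model()
  s <- analytic_three(m)
  f1 <- iterate_field(s$tra, s$sag, s$cor)
  f2 <- iterate_field(s$tra, s$sag, s$cor,
                      config = iteration_config(axis_order = c("z", "y", "x")))
  num <- abs(cbind(f1$samples$dx_mm - f2$samples$dx_mm,
                   f1$samples$dy_mm - f2$samples$dy_mm,
                   f1$samples$dz_mm - f2$samples$dz_mm))
  den <- pmax(abs(cbind(f1$samples$dx_mm, f1$samples$dy_mm,
                        f1$samples$dz_mm)), 0.5)
  expect_lt(max(num / den), 0.02)
})

test_that("the interpolated map is exact at sites and accurate off-lattice", {
  geom <- phantom_geometry()
  m <- default_study_model()
  nom <- nominal_lattice(geom)
  d <- fixed_point_displacement(m, nom)
  samples <- tibble::tibble(
    x_mm = nom$x_mm, y_mm = nom$y_mm, z_mm = nom$z_mm,
    dx_mm = d$dx_mm, dy_mm = d$dy_mm, dz_mm = d$dz_mm, dr_mm = d$dr_mm
  )
  class(samples) <- c("displacement_samples", class(samples))
  map <- build_map(samples)
  at_sites <- eval_map(map, samples)
  expect_equal(at_sites[, 1], samples$dx_mm, tolerance = 1e-8)
  expect_equal(at_sites[, 3], samples$dz_mm, tolerance = 1e-8)
  set.seed(8)
  q <- cbind(stats::runif(200, -110, 110), stats::runif(200, -110, 110),
             stats::runif(200, -110, 110))
  tr <- fixed_point_displacement(m, q)
  ev <- eval_map(map, q)
  expect_lt(max(abs(ev - as.matrix(tr[, 1:3]))), 0.05)
  # an all-zero sample set gives a zero map everywhere
  z <- samples
  z$dx_mm <- z$dy_mm <- z$dz_mm <- z$dr_mm <- 0
  expect_equal(max(abs(eval_map(build_map(z), q))), 0)
})

test_that("grid evaluation of a map matches scattered evaluation", {
  geom <- phantom_geometry()
  m <- default_study_model()
  nom <- nominal_lattice(geom)
  d <- true_displacement(m, nom)
  samples <- tibble::tibble(
    x_mm = nom$x_mm, y_mm = nom$y_mm, z_mm = nom$z_mm,
    dx_mm = d$dx_mm, dy_mm = d$dy_mm, dz_mm = d$dz_mm, dr_mm = d$dr_mm
  )
  class(samples) <- c("displacement_samples", class(samples))
  map <- build_map(samples)
  gx <- seq(-100, 100, by = 40)
  gy <- seq(-90, 90, by = 45)
  gz <- 17.3
  grid <- mrdistort:::eval_map_grid(map, gx, gy, gz)
  q <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  sc <- eval_map(map, q)
  expect_equal(as.numeric(grid[[1]]), sc[, 1], tolerance = 1e-9)
  expect_equal(as.numeric(grid[[2]]), sc[, 2], tolerance = 1e-9)
  expect_equal(as.numeric(grid[[3]]), sc[, 3], tolerance = 1e-9)
})

test_that("statistics match an independent brute-force pass", {
  set.seed(5)
  n <- 400
  s <- tibble::tibble(
    x_mm = stats::runif(n, -100, 100), y_mm = stats::runif(n, -100, 100),
    z_mm = stats::runif(n, -100, 100),
    dx_mm = stats::rnorm(n), dy_mm = stats::rnorm(n), dz_mm = stats::rnorm(n)
  )
  s$dr_mm <- sqrt(s$dx_mm^2 + s$dy_mm^2 + s$dz_mm^2)
  class(s) <- c("displacement_samples", class(s))
  st <- field_statistics(s)
  expect_equal(st$mean_mm[st$axis == "x"], mean(abs(s$dx_mm)))
  expect_equal(st$sd_mm[st$axis == "y"], stats::sd(abs(s$dy_mm)))
  expect_equal(st$max_mm[st$axis == "r"], max(s$dr_mm))
  one <- s[1, ]
  one$dx_mm <- 3; one$dy_mm <- 4; one$dz_mm <- 0; one$dr_mm <- 5
  class(one) <- class(s)
  st1 <- field_statistics(one)
  expect_equal(st1$mean_mm[st1$axis == "r"], 5)
  expect_equal(st1$max_mm[st1$axis == "r"], 5)
  expect_equal(st1$sd_mm[st1$axis == "r"], 0)
  prof <- slice_max_profile(s)
  z0 <- unique(round(s$z_mm / 2) * 2)[1]
  sel <- round(s$z_mm / 2) * 2 == z0
  expect_equal(prof$max_mm[prof$z_mm == z0 & prof$component == "x"],
               max(abs(s$dx_mm[sel])))
})

test_that("tidy and glance summarise a fit", {
  m <- default_study_model()
  s <- analytic_three(m)
  fit <- iterate_field(s$tra, s$sag, s$cor)
  td <- generics::tidy(fit)
  expect_equal(td$axis, c("x", "y", "z", "r"))
  expect_true(all(td$max_mm >= td$mean_mm))
  gl <- generics::glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
  expect_equal(gl$n_sites, nrow(fit$samples))
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})
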