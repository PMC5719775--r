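#' Acquisition configuration for the simulator
#'
#' One MR acquisition of the phantom: grid-profile orientation, read-gradient
#' polarity, voxel grid, and artifact levels. Defaults follow the study
#' conditions: 0.9 x 0.9 x 1.0 mm voxels, 30 % intensity bias, Gaussian noise
#' with sigma of 5 % of the oil signal, and 10 air bubbles.
#'
#' @param orientation `"transverse"`, `"sagittal"` or `"coronal"`.
#' @param polarity read-gradient polarity, `"forward"` or `"reverse"`.
#' @param voxel_mm length-3 voxel size (in-plane u, v then slice w).
#' @param fov_mm length-3 field of view.
#' @param bias_amplitude multiplicative intensity-inhomogeneity amplitude
#'   (fraction in `[0, 1)`).
#' @param noise_sigma additive Gaussian noise sigma in intensity units
#'   (the oil signal is 1000; the default 50 is 5 %).
#' @param bubble_count number of air bubbles inserted in the oil.
#' @param seed RNG seed for bias, noise and bubbles.
#' @return An `acquisition_config` list.
#' @export
acquisition_config <- function(orientation = "transverse",
                               polarity = c("forward", "reverse"),
                               voxel_mm = c(0.9, 0.9, 1.0),
                               fov_mm = c(280.8, 280.8, 280),
                               bias_amplitude = 0.3,
                               noise_sigma = 50,
                               bubble_count = 10L,
                               seed = 1L) {
  polarity <- match.arg(polarity)
  stopifnot(bias_amplitude >= 0, bias_amplitude < 1, noise_sigma >= 0,
            bubble_count >= 0, all(voxel_mm > 0))
  structure(
    list(
      orientation = orientation, polarity = polarity,
      voxel_mm = voxel_mm, fov_mm = fov_mm,
      bias_amplitude = bias_amplitude, noise_sigma = noise_sigma,
      bubble_count = as.integer(bubble_count), seed = as.integer(seed)
    ),
    class = "acquisition_config"
  )
}

read_axis_for <- function(orientation) {
  switch(orientation, transverse = "x", sagittal = "y", coronal = "x",
         stop("unknown orientation: ", orientation, call. = FALSE))
}

#' Apparent displacement under the slice-stack measurement model
#'
#' Where a structure truly at `points` appears in an acquisition with the
#' given grid orientation: the through-plane coordinate is displaced by the
#' through-plane field component at the true position (slice selection),
#' while the in-plane coordinates are displaced by the in-plane field
#' components evaluated at the *nominal coordinate of the slice where the
#' structure appears* — the coupling that makes a first-order (per-plane)
#' field estimate biased when the field has through-plane gradients. The B0
#' displacement adds along the in-plane read axis with the polarity sign.
#' For fields without through-plane gradients this reduces exactly to the
#' plain displacement `delta(x)`.
#'
#' @param model a [distortion_model].
#' @param points matrix/data frame of true scanner positions (see
#'   [true_displacement()]).
#' @param orientation acquisition orientation.
#' @param polarity `"none"`, `"forward"` or `"reverse"`.
#' @return n x 3 matrix of apparent displacement (mm, scanner x/y/z columns).
#' @export
apparent_displacement <- function(model, points, orientation = "transverse",
                                  polarity = "none") {
  xyz <- as_xyz_matrix(points)
  ax <- orientation_axes(orientation)
  itw <- match(ax[3], c("x", "y", "z"))
  iip <- setdiff(1:3, itw)
  d_true <- eval_system(model, xyz)
  w_app <- xyz[, itw] + d_true[, itw]
  xyz_slice <- xyz
  xyz_slice[, itw] <- w_app
  d_slice <- eval_system(model, xyz_slice)
  out <- matrix(0, nrow(xyz), 3)
  out[, iip] <- d_slice[, iip]
  out[, itw] <- d_true[, itw]
  if (polarity %in% c("forward", "reverse")) {
    b <- eval_b0(model, xyz_slice) * if (polarity == "forward") 1 else -1
    iread <- match(read_axis_for(orientation), c("x", "y", "z"))
    out[, iread] <- out[, iread] + b
  }
  out
}

# Solve apparent(c) = s for the true pre-image c by fixed-point iteration.
# s: n x 3 scanner coords. Returns n x 3.
preimage_positions <- function(model, s, orientation, polarity,
                               tol = 0.01, max_iter = 20L) {
  c_cur <- s
  for (it in seq_len(max_iter)) {
    a <- apparent_displacement(model, c_cur, orientation, polarity)
    c_new <- s - a
    if (max(abs(c_new - c_cur)) < tol) {
      return(c_new)
    }
    c_cur <- c_new
  }
  c_cur
}

#' Simulate one distorted MR acquisition of the phantom
#'
#' Renders the phantom through the forward acquisition model (analytic
#' partial-volume intensity at the pre-image of each voxel), then applies the
#' multiplicative bias field, additive noise and air bubbles as configured.
#'
#' @param geometry a [phantom_geometry].
#' @param model a [distortion_model] (use [zero_model()] for an ideal scan).
#' @param config an [acquisition_config].
#' @return An [mr_volume] (modality MR, axes set from the orientation).
#' @export
simulate_mr_volume <- function(geometry, model, config) {
  vol <- render_phantom_volume(geometry, model, config, modality = "MR")
  if (config$bias_amplitude > 0) {
    vol <- apply_bias_field(vol, config$bias_amplitude, seed = config$seed)
  }
  if (config$noise_sigma > 0 || config$bubble_count > 0) {
    avoid <- apparent_lattice(geometry, model, config)
    vol <- add_noise_and_bubbles(
      vol, config$noise_sigma, config$bubble_count,
      seed = config$seed + 1L, avoid_points = avoid
    )
  }
  vol
}

#' Simulate the CT reference scan of the phantom
#'
#' CT is treated as distortion free; only mild Gaussian noise is added.
#'
#' @param geometry a [phantom_geometry].
#' @param voxel_mm CT voxel size.
#' @param fov_mm CT field of view.
#' @param noise_sigma additive noise sigma (intensity units).
#' @param seed RNG seed.
#' @return An [mr_volume] with modality CT, transverse orientation.
#' @export
simulate_ct_volume <- function(geometry, voxel_mm = c(1, 1, 1),
                               fov_mm = c(280.8, 280.8, 280),
                               noise_sigma = 10, seed = 99L) {
  vol <- rasterize_phantom(geometry, voxel_mm, "CT", fov_mm, "transverse")
  if (noise_sigma > 0) {
    vol <- add_noise_and_bubbles(vol, noise_sigma, 0L, seed = seed)
  }
  vol
}

# apparent positions of all control points in one acquisition (used to keep
# bubbles away from the dots, so the ground-truth point count is unambiguous)
apparent_lattice <- function(geometry, model, config) {
  nom <- nominal_lattice(geometry, config$orientation)
  app <- apparent_displacement(model, nom, config$orientation, config$polarity)
  cbind(nom$x_mm + app[, 1], nom$y_mm + app[, 2], nom$z_mm + app[, 3])
}

render_phantom_volume <- function(geometry, model, config, modality) {
  voxel <- config$voxel_mm
  mat <- pmax(round(config$fov_mm / voxel), 2L)
  origin <- centered_origin(mat, voxel)
  ax <- orientation_axes(config$orientation)
  us <- origin[1] + (seq_len(mat[1]) - 1) * voxel[1]
  vs <- origin[2] + (seq_len(mat[2]) - 1) * voxel[2]
  ws <- origin[3] + (seq_len(mat[3]) - 1) * voxel[3]
  hw3 <- voxel / 2
  uu <- rep(us, times = mat[2])
  vv <- rep(vs, each = mat[1])
  arr <- array(0, dim = mat)
  zero <- length(model$comps$dx[, 1]) == 0 &&
    length(model$comps$dy[, 1]) == 0 && length(model$comps$dz[, 1]) == 0 &&
    is.null(model$b0) && is.null(model$harmonic)
  for (k in seq_len(mat[3])) {
    if (zero) {
      pre_uvw <- cbind(uu, vv, rep(ws[k], length(uu)))
    } else {
      # scanner coords of this slice's voxel centers
      s <- matrix(0, length(uu), 3)
      s[, match(ax[1], c("x", "y", "z"))] <- uu
      s[, match(ax[2], c("x", "y", "z"))] <- vv
      s[, match(ax[3], c("x", "y", "z"))] <- ws[k]
      colnames(s) <- c("x", "y", "z")
      pre <- preimage_positions(s = s, model = model,
                                orientation = config$orientation,
                                polarity = config$polarity)
      pre_uvw <- scanner_to_phantom(pre, config$orientation)
    }
    arr[, , k] <- phantom_intensity(
      geometry, pre_uvw[, 1], pre_uvw[, 2], pre_uvw[, 3], hw3, modality
    )
  }
  mr_volume(arr, voxel, origin, axes = ax, modality = modality)
}

#' Warp an arbitrary volume through the forward acquisition model
#'
#' Resamples `ideal` so that a structure truly at position `x` appears at its
#' apparent position under the distortion model (see
#' [apparent_displacement()]). Voxels whose pre-image falls outside `ideal`
#' are filled with the background value and counted.
#'
#' @param ideal an [mr_volume] on the same grid layout as the output.
#' @param model a [distortion_model].
#' @param config an [acquisition_config] (orientation/polarity used).
#' @param interp intensity interpolation, `"cubic"` or `"linear"`.
#' @param fill fill value for out-of-volume pre-images; default is the oil
#'   signal for MR (volume maximum) and the background minimum for CT.
#' @return An [mr_volume]; attribute `n_filled` counts filled voxels.
#' @export
warp_volume <- function(ideal, model, config, interp = "cubic", fill = NULL) {
  if (is.null(fill)) {
    fill <- if (ideal$modality == "MR") max(ideal$data) else min(ideal$data)
  }
  dm <- dim(ideal$data)
  ax <- ideal$axes
  us <- axis_coords(ideal, 1)
  vs <- axis_coords(ideal, 2)
  ws <- axis_coords(ideal, 3)
  uu <- rep(us, times = dm[2])
  vv <- rep(vs, each = dm[1])
  arr <- array(0, dim = dm)
  bb <- volume_bbox(ideal)
  n_filled <- 0L
  for (k in seq_len(dm[3])) {
    s <- matrix(0, length(uu), 3)
    s[, match(ax[1], c("x", "y", "z"))] <- uu
    s[, match(ax[2], c("x", "y", "z"))] <- vv
    s[, match(ax[3], c("x", "y", "z"))] <- ws[k]
    colnames(s) <- c("x", "y", "z")
    pre <- preimage_positions(s = s, model = model,
                              orientation = config$orientation,
                              polarity = config$polarity)
    outside <- pre[, 1] < bb[1, 1] | pre[, 1] > bb[2, 1] |
      pre[, 2] < bb[1, 2] | pre[, 2] > bb[2, 2] |
      pre[, 3] < bb[1, 3] | pre[, 3] > bb[2, 3]
    vals <- sample_volume(ideal, pre, interp = interp, fill = fill)
    vals[outside] <- fill
    n_filled <- n_filled + sum(outside)
    arr[, , k] <- vals
  }
  out <- mr_volume(arr, ideal$voxel_mm, ideal$origin_mm, ax, ideal$modality)
  attr(out, "n_filled") <- n_filled
  out
}

#' Apply a smooth multiplicative intensity-inhomogeneity field
#'
#' Multiplies the volume by a smooth positive field in
#' `[1 - amplitude, 1 + amplitude]` built from a seeded mixture of broad
#' Gaussians, normalised to zero mean so the overall intensity level is
#' approximately preserved.
#'
#' @param volume an [mr_volume].
#' @param amplitude fraction in `[0, 1)`.
#' @param scale_mm spatial scale of the bias (Gaussian sigma).
#' @param seed RNG seed.
#' @return Biased [mr_volume].
#' @export
apply_bias_field <- function(volume, amplitude, scale_mm = 120, seed = 1L) {
  stopifnot(amplitude >= 0, amplitude < 1)
  if (amplitude == 0) return(volume)
  out <- volume
  out$data <- volume$data * bias_field_array(volume, amplitude, scale_mm, seed)
  out
}

# the bias field itself, as an array matching the volume grid
bias_field_array <- function(volume, amplitude, scale_mm = 120, seed = 1L) {
  dm <- dim(volume$data)
  lo <- volume$origin_mm
  hi <- volume$origin_mm + (dm - 1) * volume$voxel_mm
  comp <- with_seed(seed, {
    k <- 4L
    list(
      centers = cbind(stats::runif(k, lo[1], hi[1]),
                      stats::runif(k, lo[2], hi[2]),
                      stats::runif(k, lo[3], hi[3])),
      weights = stats::runif(k, 0.5, 1) * sample(c(-1, 1), k, replace = TRUE)
    )
  })
  us <- axis_coords(volume, 1)
  vs <- axis_coords(volume, 2)
  ws <- axis_coords(volume, 3)
  g <- array(0, dm)
  for (i in seq_len(nrow(comp$centers))) {
    gu <- exp(-(us - comp$centers[i, 1])^2 / (2 * scale_mm^2))
    gv <- exp(-(vs - comp$centers[i, 2])^2 / (2 * scale_mm^2))
    gw <- exp(-(ws - comp$centers[i, 3])^2 / (2 * scale_mm^2))
    g <- g + comp$weights[i] * (gu %o% gv %o% gw)
  }
  g <- g - mean(g)
  g <- g / max(abs(g))
  1 + amplitude * g
}

#' Add Gaussian noise and air-bubble artifacts
#'
#' Adds seeded Gaussian noise, then inserts `bubble_count` small dark
#' ellipsoids at random positions, kept at least `guard_mm` away from any
#' point in `avoid_points` (the apparent control-point positions), so bubbles
#' never overlap true dots.
#'
#' @param volume an [mr_volume].
#' @param noise_sigma Gaussian noise sigma (intensity units).
#' @param bubble_count number of bubbles.
#' @param seed RNG seed (same seed gives bit-identical output).
#' @param avoid_points optional n x 3 matrix of scanner positions to avoid.
#' @param guard_mm exclusion radius around `avoid_points`.
#' @param radius_mm_range bubble semi-axis range (mm).
#' @return Modified [mr_volume].
#' @export
add_noise_and_bubbles <- function(volume, noise_sigma, bubble_count,
                                  seed = 1L, avoid_points = NULL,
                                  guard_mm = 5, radius_mm_range = c(1.5, 3.5)) {
  stopifnot(noise_sigma >= 0, bubble_count >= 0)
  if (noise_sigma == 0 && bubble_count == 0) return(volume)
  out <- volume
  dm <- dim(out$data)
  with_seed(seed, {
    if (bubble_count > 0) {
      air <- min(out$data)
      bb <- volume_bbox(out)
      span <- bb[2, ] - bb[1, ]
      lo <- bb[1, ] + 0.15 * span
      hi <- bb[2, ] - 0.15 * span
      placed <- 0L
      tries <- 0L
      while (placed < bubble_count && tries < 200L * bubble_count) {
        tries <- tries + 1L
        pos <- stats::runif(3, lo, hi)
        r <- stats::runif(3, radius_mm_range[1], radius_mm_range[2])
        if (!is.null(avoid_points)) {
          d2 <- (avoid_points[, 1] - pos[1])^2 + (avoid_points[, 2] - pos[2])^2 +
            (avoid_points[, 3] - pos[3])^2
          # no part of the bubble may enter the guard zone of a point
          if (min(d2) < (guard_mm + max(r))^2) next
        }
        out$data <- stamp_bubble(out, pos, r, air)
        placed <- placed + 1L
      }
      if (placed < bubble_count) {
        warning("add_noise_and_bubbles(): placed only ", placed, " of ",
                bubble_count, " bubbles", call. = FALSE)
      }
    }
    if (noise_sigma > 0) {
      out$data <- out$data +
        array(stats::rnorm(prod(dm), 0, noise_sigma), dm)
    }
  })
  out
}

# blend an air ellipsoid into the local patch around scanner position `pos`
stamp_bubble <- function(volume, pos, radii, air_value) {
  arr <- volume$data
  dm <- dim(arr)
  dd <- scanner_to_dims(volume, matrix(pos, 1))
  rr <- scanner_to_dims(volume, matrix(radii, 1))
  ctr <- (dd - volume$origin_mm) / volume$voxel_mm + 1
  half <- abs(rr) / volume$voxel_mm + 1.5
  lo <- pmax(floor(ctr - half), 1)
  hi <- pmin(ceiling(ctr + half), dm)
  if (any(lo > hi)) return(arr)
  is <- lo[1]:hi[1]; js <- lo[2]:hi[2]; ks <- lo[3]:hi[3]
  du <- (is - ctr[1]) * volume$voxel_mm[1] / abs(rr[1])
  dv <- (js - ctr[2]) * volume$voxel_mm[2] / abs(rr[2])
  dw <- (ks - ctr[3]) * volume$voxel_mm[3] / abs(rr[3])
  rho <- sqrt(outer(outer(du^2, dv^2, "+"), dw^2, "+"))
  e <- pmin(pmax((1.15 - rho) / 0.3, 0), 1)   # soft ellipsoid edge
  patch <- arr[is, js, ks]
  arr[is, js, ks] <- patch * (1 - e) + air_value * e
  arr
}

# run code with a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Noiseless analytic displacement samples for one orientation
#'
#' The measurement a perfect (noise- and detection-error-free) pipeline
#' would produce for one grid orientation: CT sites at the (rotated)
#' nominal lattice, MR coordinates at the apparent positions under the
#' acquisition model, displacements as their difference. Useful as an
#' independent oracle for the field estimators.
#'
#' @param model a [distortion_model].
#' @param geometry a [phantom_geometry].
#' @param orientation grid orientation.
#' @return A `displacement_samples` tibble (provenance `"analytic"`).
#' @export
synthetic_orientation_samples <- function(model,
                                          geometry = phantom_geometry(),
                                          orientation = "transverse") {
  nom <- nominal_lattice(geometry, orientation)
  ap <- apparent_displacement(model, nom, orientation, "none")
  out <- tibble::tibble(
    x_mm = nom$x_mm, y_mm = nom$y_mm, z_mm = nom$z_mm,
    x_mr = nom$x_mm + ap[, 1],
    y_mr = nom$y_mm + ap[, 2],
    z_mr = nom$z_mm + ap[, 3],
    dx_mm = ap[, 1], dy_mm = ap[, 2], dz_mm = ap[, 3],
    dr_mm = sqrt(rowSums(ap^2))
  )
  attr(out, "orientation") <- orientation
  attr(out, "provenance") <- "analytic"
  class(out) <- c("displacement_samples", class(out))
  out
}

#' Simulate a complete phantom study
#'
#' One CT reference scan plus MR acquisitions of the phantom in up to three
#' grid orientations, each with forward and (optionally) reverse read
#' gradient. All randomness derives from `seed`.
#'
#' @param geometry a [phantom_geometry].
#' @param model a [distortion_model].
#' @param voxel_mm MR voxel size.
#' @param fov_mm field of view (all acquisitions).
#' @param ct_voxel_mm CT voxel size.
#' @param orientations subset of `c("transverse","sagittal","coronal")`.
#' @param reverse include reverse-gradient acquisitions?
#' @param bias_amplitude,noise_sigma,bubble_count artifact levels
#'   (see [acquisition_config()]).
#' @param seed master seed.
#' @return List with elements `ct` ([mr_volume]), `mr` (named list of
#'   [mr_volume]s, names like `"transverse_forward"`), `geometry`, `model`.
#' @export
simulate_study <- function(geometry = phantom_geometry(),
                           model = default_study_model(),
                           voxel_mm = c(1.8, 1.8, 2.0),
                           fov_mm = c(280.8, 280.8, 280),
                           ct_voxel_mm = c(2, 2, 2),
                           orientations = c("transverse", "sagittal", "coronal"),
                           reverse = TRUE,
                           bias_amplitude = 0.3,
                           noise_sigma = 50,
                           bubble_count = 10L,
                           seed = 1L) {
  ct <- simulate_ct_volume(geometry, ct_voxel_mm, fov_mm, seed = seed + 90L)
  pols <- if (reverse) c("forward", "reverse") else "forward"
  mr <- list()
  i <- 0L
  for (o in orientations) {
    for (p in pols) {
      i <- i + 1L
      cfg <- acquisition_config(
        orientation = o, polarity = p, voxel_mm = voxel_mm, fov_mm = fov_mm,
        bias_amplitude = bias_amplitude, noise_sigma = noise_sigma,
        bubble_count = bubble_count, seed = seed + i * 10L
      )
      mr[[paste(o, p, sep = "_")]] <- simulate_mr_volume(geometry, model, cfg)
    }
  }
  list(ct = ct, mr = mr, geometry = geometry, model = model)
}
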