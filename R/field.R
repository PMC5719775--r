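# Estimation of the 3D distortion field from three orthogonal correspondence
# sets: per-axis displacements, first-order (double-estimate) combination,
# iterative refinement with shifted interpolant lookups, spline distortion
# maps, and summary statistics.

#' Iteration settings for the field estimator
#'
#' @param phi_mm convergence cutoff: iteration stops when every per-site
#'   component change is below `phi_mm` simultaneously (0.2 mm default, the
#'   value found to minimise residual distortion).
#' @param max_iter iteration cap (convergence is typically reached in <= 4).
#' @param axis_order order in which the three components are updated within
#'   one iteration; the result is insensitive to it to within ~2 %.
#' @param interpolator `"spline"` (tensor natural splines) or `"linear"`.
#' @return An `iteration_config` list.
#' @export
iteration_config <- function(phi_mm = 0.2, max_iter = 10L,
                             axis_order = c("x", "y", "z"),
                             interpolator = c("spline", "linear")) {
  interpolator <- match.arg(interpolator)
  stopifnot(phi_mm > 0, max_iter >= 1, setequal(axis_order, c("x", "y", "z")))
  structure(
    list(phi_mm = phi_mm, max_iter = as.integer(max_iter),
         axis_order = axis_order, interpolator = interpolator),
    class = "iteration_config"
  )
}

#' Per-axis displacement samples from CT-MR correspondences
#'
#' The local distortion at each control point is the coordinate difference
#' between the matched MR and CT positions; the total displacement is the
#' Euclidean norm of the three components.
#'
#' @param pairs a `correspondences` tibble from [match_correspondences()].
#' @return A `displacement_samples` tibble: CT site coordinates
#'   (`x_mm, y_mm, z_mm`), MR coordinates (`x_mr, y_mr, z_mr`), components
#'   `dx_mm, dy_mm, dz_mm` and total `dr_mm`; attributes `orientation`,
#'   `provenance = "measured"`.
#' @export
per_axis_displacement <- function(pairs) {
  stopifnot(nrow(pairs) > 0)
  out <- tibble::tibble(
    x_mm = pairs$x_ct, y_mm = pairs$y_ct, z_mm = pairs$z_ct,
    x_mr = pairs$x_mr, y_mr = pairs$y_mr, z_mr = pairs$z_mr,
    dx_mm = pairs$x_mr - pairs$x_ct,
    dy_mm = pairs$y_mr - pairs$y_ct,
    dz_mm = pairs$z_mr - pairs$z_ct
  )
  out$dr_mm <- sqrt(out$dx_mm^2 + out$dy_mm^2 + out$dz_mm^2)
  attr(out, "orientation") <- attr(pairs, "orientation")
  attr(out, "provenance") <- "measured"
  class(out) <- c("displacement_samples", class(out))
  out
}

new_displacement_samples <- function(sites, d, provenance,
                                     single_estimate = NULL) {
  out <- tibble::tibble(
    x_mm = sites[, 1], y_mm = sites[, 2], z_mm = sites[, 3],
    dx_mm = d[, 1], dy_mm = d[, 2], dz_mm = d[, 3],
    dr_mm = sqrt(rowSums(d^2))
  )
  if (!is.null(single_estimate)) out$single_estimate <- single_estimate
  attr(out, "provenance") <- provenance
  class(out) <- c("displacement_samples", class(out))
  out
}

# Snap near-regular sample sites to a rectangular lattice. A small number
# of missing nodes is allowed (they are NA-filled later); duplicate claims
# on one node make the set non-griddable. NULL if not lattice-like.
snap_to_lattice <- function(xyz, tol = 6, max_missing_frac = 0.05) {
  knots <- list()
  idx <- matrix(0L, nrow(xyz), 3)
  for (a in 1:3) {
    v <- sort(unique(round(xyz[, a], 6)))
    cl <- cumsum(c(1, diff(v) > tol))
    kn <- as.numeric(tapply(v, cl, mean))
    if (length(kn) < 2) return(NULL)
    knots[[a]] <- kn
    idx[, a] <- findInterval(xyz[, a], c(-Inf, (kn[-1] + kn[-length(kn)]) / 2))
  }
  n <- vapply(knots, length, integer(1))
  if (nrow(xyz) < (1 - max_missing_frac) * prod(n) ||
      nrow(xyz) > prod(n)) {
    return(NULL)
  }
  key <- (idx[, 3] - 1L) * n[1] * n[2] + (idx[, 2] - 1L) * n[1] + idx[, 1]
  if (anyDuplicated(key)) return(NULL)
  list(knots = knots, idx = idx, n = n, key = key,
       n_missing = prod(n) - nrow(xyz))
}

# place values onto the lattice (NA where no sample) and fill missing nodes
# with the mean of their available axis neighbours (iterated)
lattice_array <- function(snap, values) {
  arr <- array(NA_real_, dim = snap$n)
  arr[snap$key] <- values
  fill_lattice_na(arr)
}

fill_lattice_na <- function(arr) {
  for (pass in 1:10) {
    nas <- which(is.na(arr))
    if (length(nas) == 0) break
    dm <- dim(arr)
    acc <- array(0, dm)
    cnt <- array(0, dm)
    for (a in 1:3) {
      for (s in c(-1L, 1L)) {
        src <- shift_array(arr, a, s)
        ok <- !is.na(src)
        acc[ok] <- acc[ok] + src[ok]
        cnt <- cnt + ok
      }
    }
    fill <- nas[cnt[nas] > 0]
    arr[fill] <- acc[fill] / cnt[fill]
  }
  arr
}

# 2D analogue of fill_lattice_na (4-neighbour iterative mean, then median)
fill_plane_na <- function(mat) {
  for (pass in 1:10) {
    nas <- which(is.na(mat))
    if (length(nas) == 0) return(mat)
    dm <- dim(mat)
    acc <- matrix(0, dm[1], dm[2])
    cnt <- matrix(0, dm[1], dm[2])
    shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
    for (s in shifts) {
      src <- matrix(NA_real_, dm[1], dm[2])
      i_dst <- max(1, 1 + s[1]):min(dm[1], dm[1] + s[1])
      j_dst <- max(1, 1 + s[2]):min(dm[2], dm[2] + s[2])
      src[i_dst, j_dst] <- mat[i_dst - s[1], j_dst - s[2]]
      ok <- !is.na(src)
      acc[ok] <- acc[ok] + src[ok]
      cnt <- cnt + ok
    }
    fill <- nas[cnt[nas] > 0]
    mat[fill] <- acc[fill] / cnt[fill]
  }
  mat[is.na(mat)] <- stats::median(mat, na.rm = TRUE)
  mat
}

shift_array <- function(arr, axis, by) {
  dm <- dim(arr)
  out <- array(NA_real_, dm)
  idx_src <- lapply(dm, seq_len)
  idx_dst <- idx_src
  n <- dm[axis]
  if (by > 0) {
    idx_dst[[axis]] <- (1 + by):n
    idx_src[[axis]] <- 1:(n - by)
  } else {
    idx_dst[[axis]] <- 1:(n + by)
    idx_src[[axis]] <- (1 - by):n
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# orientation bookkeeping: in-plane and through-plane axis indices
orientation_axis_idx <- function(orientation) {
  ax <- orientation_axes(orientation)
  list(ip = match(ax[1:2], c("x", "y", "z")),
       tw = match(ax[3], c("x", "y", "z")))
}

# Build the two interpolant views of one orientation's measured samples.
#  - ct-housed: component values on the regular CT lattice (first-order /
#    cross-lattice association);
#  - sheared: same in-plane lattice, but each sample housed at its apparent
#    through-plane coordinate (iteration lookups, Eqs. 5a-5c).
# Components interpolated are the orientation's two in-plane ones.
orientation_interpolants <- function(samples, extrap_mm = 15) {
  orientation <- attr(samples, "orientation")
  oi <- orientation_axis_idx(orientation)
  xyz <- cbind(samples$x_mm, samples$y_mm, samples$z_mm)
  snap <- snap_to_lattice(xyz)
  if (is.null(snap)) {
    stop("orientation_interpolants(): sample sites for the ", orientation,
         " orientation do not form a complete lattice; ",
         nrow(samples), " sites found", call. = FALSE)
  }
  d <- cbind(samples$dx_mm, samples$dy_mm, samples$dz_mm)
  mr <- cbind(samples$x_mr, samples$y_mr, samples$z_mr)
  # samples whose measured through-plane displacement approaches half the
  # sheet pitch would break the monotone apparent-coordinate housing; treat
  # them as missing (artifacts that slipped through cleaning)
  tw_spacing <- min(diff(snap$knots[[oi$tw]]))
  valid <- abs(d[, oi$tw]) <= 0.45 * tw_spacing
  perm <- c(oi$ip, oi$tw)       # reorder axes as (in-plane1, in-plane2, through)
  # array index order is x,y,z; build (NA-filled) arrays then permute
  to_arr <- function(v) {
    v[!valid] <- NA_real_
    aperm(lattice_array(snap, v), perm)
  }
  out <- list(orientation = orientation, oi = oi,
              knots = snap$knots, components = oi$ip)
  # apparent through-plane coordinates: fill missing nodes within their own
  # sheet layer only (cross-layer filling would break monotonicity)
  vw <- mr[, oi$tw]
  vw[!valid] <- NA_real_
  Wraw <- array(NA_real_, dim = snap$n)
  Wraw[snap$key] <- vw
  Wraw <- aperm(Wraw, perm)
  for (k in seq_len(dim(Wraw)[3])) {
    Wraw[, , k] <- fill_plane_na(Wraw[, , k])
  }
  W <- Wraw
  for (comp in oi$ip) {
    VAL <- to_arr(d[, comp])
    out[[paste0("ct_", comp)]] <- build_tensor3(
      snap$knots[[perm[1]]], snap$knots[[perm[2]]], snap$knots[[perm[3]]],
      VAL, extrap = extrap_mm
    )
    out[[paste0("sh_", comp)]] <- build_sheared3(
      snap$knots[[perm[1]]], snap$knots[[perm[2]]], W, VAL,
      extrap = extrap_mm
    )
  }
  out
}

# evaluate one orientation's interpolant for component `comp` at scanner
# coords q (n x 3); view = "ct" or "sh"
eval_orientation <- function(itp, comp, q, view) {
  oi <- itp$oi
  f <- itp[[paste0(view, "_", comp)]]
  if (is.null(f)) return(NULL)
  if (view == "ct") {
    eval_tensor3(f, q[, oi$ip[1]], q[, oi$ip[2]], q[, oi$tw])
  } else {
    eval_sheared3(f, q[, oi$ip[1]], q[, oi$ip[2]], q[, oi$tw])
  }
}

# which orientations measure each component (the double estimate)
component_orientations <- list(
  x = c("transverse", "coronal"),
  y = c("transverse", "sagittal"),
  z = c("sagittal", "coronal")
)

#' First-order estimate of the 3D field (double-estimate average)
#'
#' Each axis is measured in-plane by two of the three orientations; the
#' first-order estimate at each common site is the mean of the two (or the
#' single one available, flagged). Cross-orientation lattices do not
#' coincide (the rotated phantom's sheet pitch differs from the in-plane
#' pitch), so each orientation's contribution is read off its CT-housed
#' interpolant at the common site — exact at the orientation's own sites.
#'
#' @param tra,sag,cor measured `displacement_samples` per orientation (any
#'   may be `NULL` if that scan is missing).
#' @param sites optional n x 3 matrix of common CT sites; defaults to the
#'   transverse set's sites (or the first available set's).
#' @return `displacement_samples` with provenance `"first_order"` and a
#'   `single_estimate` logical column.
#' @export
first_order_estimate <- function(tra, sag, cor, sites = NULL) {
  sets <- list(transverse = tra, sagittal = sag, coronal = cor)
  avail <- names(sets)[!vapply(sets, is.null, logical(1))]
  if (length(avail) == 0) stop("no displacement samples given", call. = FALSE)
  if (is.null(sites)) {
    s0 <- sets[[avail[1]]]
    sites <- cbind(s0$x_mm, s0$y_mm, s0$z_mm)
  }
  itps <- lapply(sets[avail], orientation_interpolants)
  d <- matrix(0, nrow(sites), 3)
  single <- rep(FALSE, nrow(sites))
  for (comp in 1:3) {
    contrib <- intersect(component_orientations[[comp]], avail)
    if (length(contrib) == 0) {
      stop("component ", c("x", "y", "z")[comp],
           " is measured by no available orientation", call. = FALSE)
    }
    vals <- lapply(contrib, function(o) {
      eval_orientation(itps[[o]], comp, sites, "ct")
    })
    d[, comp] <- Reduce(`+`, vals) / length(vals)
    if (length(vals) == 1) single <- single | TRUE
  }
  new_displacement_samples(sites, d, "first_order", single)
}

#' Iterative refinement of the 3D field (shifted-lookup fixed point)
#'
#' Re-evaluates each axis's distortion at coordinates corrected by the other
#' axes' latest estimates: the x component at iteration n is looked up at
#' `(x_i, y_i + dy_(n-1), z_i + dz_(n-1))`, then y at
#' `(x_i + dx_n, y_i, z_i + dz_(n-1))`, then z at
#' `(x_i + dx_n, y_i + dy_n, z_i)` — each still the mean of its two
#' orientation estimates, with the per-orientation samples housed at their
#' apparent through-plane coordinate. Iteration stops when all three
#' per-site changes fall below `phi_mm` simultaneously, or at `max_iter`.
#' A divergence guard returns the initial estimate if the change gap grows
#' instead of shrinking.
#'
#' @param tra,sag,cor measured `displacement_samples` per orientation.
#' @param init initial estimate from [first_order_estimate()].
#' @param config an [iteration_config()].
#' @return A `distortion_fit` object: final `samples`, `init`, `iterations`,
#'   `converged`, `gap_trace` (max per-site component change per iteration).
#' @export
iterate_field <- function(tra, sag, cor, init = NULL,
                          config = iteration_config()) {
  sets <- list(transverse = tra, sagittal = sag, coronal = cor)
  avail <- names(sets)[!vapply(sets, is.null, logical(1))]
  if (is.null(init)) init <- first_order_estimate(tra, sag, cor)
  sites <- cbind(init$x_mm, init$y_mm, init$z_mm)
  itps <- lapply(sets[avail], orientation_interpolants)
  cur <- cbind(init$dx_mm, init$dy_mm, init$dz_mm)
  comp_idx <- match(config$axis_order, c("x", "y", "z"))
  gap_trace <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  for (n in seq_len(config$max_iter)) {
    prev <- cur
    for (comp in comp_idx) {
      q <- sites + cur
      q[, comp] <- sites[, comp]      # own coordinate unshifted
      contrib <- intersect(component_orientations[[comp]], avail)
      vals <- lapply(contrib, function(o) {
        eval_orientation(itps[[o]], comp, q, "sh")
      })
      cur[, comp] <- Reduce(`+`, vals) / length(vals)
    }
    gap <- max(abs(cur - prev))
    gap_trace <- c(gap_trace, gap)
    iterations <- n
    if (gap < config$phi_mm) {
      converged <- TRUE
      break
    }
  }
  if (!converged && length(gap_trace) > 1 &&
      gap_trace[length(gap_trace)] > gap_trace[1]) {
    # divergence guard: fall back to the initial estimate
    samples <- new_displacement_samples(sites, cbind(init$dx_mm, init$dy_mm,
                                                     init$dz_mm),
                                        "iteration_diverged",
                                        init$single_estimate)
    return(structure(
      list(samples = samples, init = init, iterations = iterations,
           converged = FALSE, gap_trace = gap_trace, config = config),
      class = "distortion_fit"
    ))
  }
  samples <- new_displacement_samples(
    sites, cur, paste0("iteration_", iterations), init$single_estimate
  )
  structure(
    list(samples = samples, init = init, iterations = iterations,
         converged = converged, gap_trace = gap_trace, config = config),
    class = "distortion_fit"
  )
}

#' @export
print.distortion_fit <- function(x, ...) {
  cat(sprintf(
    "<distortion_fit> %d sites, %d iteration(s), %s (gap %.3g mm)\n",
    nrow(x$samples), x$iterations,
    if (x$converged) "converged" else "NOT converged",
    utils::tail(x$gap_trace, 1)
  ))
  invisible(x)
}

#' Screen displacement samples against their lattice neighbours
#'
#' The distortion field is smooth on the scale of the control-point pitch,
#' so a per-site component that deviates from the median of its adjacent
#' lattice sites by more than `tol_mm` is a measurement artifact (a
#' detection outlier that slipped past the point-level cleaning); it is
#' replaced by that neighbour median. Sites are left untouched when they
#' agree with their neighbourhood, so genuine local field structure within
#' the tolerance is preserved.
#'
#' @param samples a `displacement_samples` tibble on a (near-)regular
#'   lattice.
#' @param tol_mm per-component disagreement tolerance.
#' @return The screened samples; attribute `n_screened` counts replaced
#'   component values.
#' @export
screen_field_outliers <- function(samples, tol_mm = 1.5) {
  xyz <- cbind(samples$x_mm, samples$y_mm, samples$z_mm)
  snap <- snap_to_lattice(xyz)
  if (is.null(snap)) return(samples)
  n_screened <- 0L
  for (col in c("dx_mm", "dy_mm", "dz_mm")) {
    arr <- lattice_array(snap, samples[[col]])
    nb <- array(NA_real_, dim = c(dim(arr), 6))
    k <- 0L
    for (a in 1:3) for (s in c(-1L, 1L)) {
      k <- k + 1L
      nb[, , , k] <- shift_array(arr, a, s)
    }
    med <- apply(nb, 1:3, stats::median, na.rm = TRUE)
    bad <- abs(arr - med) > tol_mm
    bad[is.na(bad)] <- FALSE
    n_screened <- n_screened + sum(bad[snap$key])
    arr[bad] <- med[bad]
    samples[[col]] <- arr[snap$key]
  }
  samples$dr_mm <- sqrt(samples$dx_mm^2 + samples$dy_mm^2 + samples$dz_mm^2)
  attr(samples, "n_screened") <- n_screened
  samples
}

#' Continuous distortion map from displacement samples
#'
#' Per-component tensor natural-spline interpolant on the (near-regular)
#' sample lattice: exact at the sample sites, smooth in between. Queries
#' beyond the sampled volume extrapolate linearly up to `extrap_mm`, then
#' clamp. Falls back to inverse-distance weighting (with a warning) if the
#' sites are not griddable.
#'
#' @param samples a `displacement_samples` tibble.
#' @param method `"spline"` or `"idw"` (scattered fallback).
#' @param extrap_mm extrapolation limit beyond the lattice (one pitch).
#' @return A `distortion_map` object; evaluate with [eval_map()].
#' @export
build_map <- function(samples, method = c("spline", "idw"), extrap_mm = 15) {
  method <- match.arg(method)
  xyz <- cbind(samples$x_mm, samples$y_mm, samples$z_mm)
  d <- cbind(samples$dx_mm, samples$dy_mm, samples$dz_mm)
  snap <- if (method == "spline") snap_to_lattice(xyz) else NULL
  if (is.null(snap)) {
    if (method == "spline") {
      warning("build_map(): sites are not a complete lattice; ",
              "falling back to scattered inverse-distance weighting",
              call. = FALSE)
    }
    return(structure(
      list(method = "idw", xyz = xyz, d = d,
           bbox = rbind(apply(xyz, 2, min), apply(xyz, 2, max))),
      class = "distortion_map"
    ))
  }
  comp <- lapply(1:3, function(a) {
    build_tensor3(snap$knots[[1]], snap$knots[[2]], snap$knots[[3]],
                  lattice_array(snap, d[, a]), extrap = extrap_mm)
  })
  structure(
    list(method = "spline", comp = comp,
         knots = snap$knots,
         bbox = rbind(vapply(snap$knots, min, numeric(1)),
                      vapply(snap$knots, max, numeric(1)))),
    class = "distortion_map"
  )
}

#' Evaluate a distortion map at scanner coordinates
#'
#' @param map a `distortion_map`.
#' @param xyz n x 3 matrix (or data frame with `x_mm`, `y_mm`, `z_mm`).
#' @return n x 3 matrix of displacement (mm).
#' @export
eval_map <- function(map, xyz) {
  xyz <- as_xyz_matrix(xyz)
  if (map$method == "idw") {
    return(eval_idw(map, xyz))
  }
  cbind(
    eval_tensor3(map$comp[[1]], xyz[, 1], xyz[, 2], xyz[, 3]),
    eval_tensor3(map$comp[[2]], xyz[, 1], xyz[, 2], xyz[, 3]),
    eval_tensor3(map$comp[[3]], xyz[, 1], xyz[, 2], xyz[, 3])
  )
}

# separable grid evaluation: returns list of 3 arrays len(xg) x len(yg) x len(zg)
eval_map_grid <- function(map, xg, yg, zg) {
  if (map$method == "idw") {
    g <- as.matrix(expand.grid(x = xg, y = yg, z = zg))
    d <- eval_idw(map, g)
    return(lapply(1:3, function(a) {
      array(d[, a], dim = c(length(xg), length(yg), length(zg)))
    }))
  }
  lapply(map$comp, function(f) eval_tensor3_grid3(f, xg, yg, zg))
}

eval_tensor3_grid3 <- function(itp, xg, yg, zg) {
  nxq <- length(xg); nyq <- length(yg); nzq <- length(zg)
  # collapse z at each zg: planes nx x ny
  planes <- vapply(zg, function(z) eval_tensor3_chunk_plane(itp, z),
                   numeric(itp$nx * itp$ny))
  planes <- array(planes, dim = c(itp$nx, itp$ny, nzq))
  # collapse x: rows = (y, z) pairs sharing x-knots
  Y <- matrix(aperm(planes, c(2, 3, 1)), itp$ny * nzq, itp$nx)
  out_x <- matrix(0, itp$ny * nzq, nxq)
  Mx <- Y %*% t(itp$Sx)
  for (q in seq_len(nxq)) {
    out_x[, q] <- ns_eval_rows_fixed(itp$xs, Y, Mx, xg[q], itp$extrap)
  }
  # collapse y: out_x rows are (y, z) pairs with y fastest
  res <- array(0, dim = c(nxq, nyq, nzq))
  for (k in seq_len(nzq)) {
    sel <- ((k - 1) * itp$ny + 1):(k * itp$ny)
    Yk <- out_x[sel, , drop = FALSE]              # ny x nxq values
    My <- t(itp$Sy %*% Yk)                        # nxq x ny
    Ykt <- t(Yk)                                  # nxq x ny
    for (q in seq_len(nyq)) {
      res[, q, k] <- ns_eval_rows_fixed(itp$ys, Ykt, My, yg[q], itp$extrap)
    }
  }
  res
}

# evaluate many splines (rows of Y, shared knots) at one scalar t
ns_eval_rows_fixed <- function(x, Y, M, t, extrap = Inf) {
  n <- length(x)
  t <- min(max(t, x[1] - extrap), x[n] + extrap)
  tin <- min(max(t, x[1]), x[n])
  k <- min(max(findInterval(tin, x), 1L), n - 1L)
  h <- x[k + 1] - x[k]
  A <- (x[k + 1] - tin) / h
  B <- 1 - A
  val <- A * Y[, k] + B * Y[, k + 1] +
    ((A^3 - A) * M[, k] + (B^3 - B) * M[, k + 1]) * h^2 / 6
  if (t < x[1]) {
    h1 <- x[2] - x[1]
    val <- val + ((Y[, 2] - Y[, 1]) / h1 - h1 * M[, 2] / 6) * (t - x[1])
  } else if (t > x[n]) {
    hn <- x[n] - x[n - 1]
    val <- val + ((Y[, n] - Y[, n - 1]) / hn + hn * M[, n - 1] / 6) * (t - x[n])
  }
  val
}

eval_idw <- function(map, xyz, k = 8, eps = 1e-9) {
  out <- matrix(0, nrow(xyz), 3)
  for (i in seq_len(nrow(xyz))) {
    d2 <- (map$xyz[, 1] - xyz[i, 1])^2 + (map$xyz[, 2] - xyz[i, 2])^2 +
      (map$xyz[, 3] - xyz[i, 3])^2
    nn <- order(d2)[seq_len(min(k, length(d2)))]
    if (d2[nn[1]] < eps) {
      out[i, ] <- map$d[nn[1], ]
    } else {
      w <- 1 / d2[nn]
      out[i, ] <- colSums(map$d[nn, , drop = FALSE] * w) / sum(w)
    }
  }
  out
}

#' Summary statistics of a displacement sample set
#'
#' Mean, standard deviation and maximum of the absolute per-axis components
#' and of the total displacement, over all sites (optionally restricted to
#' a volume of interest).
#'
#' @param samples a `displacement_samples` tibble.
#' @param voi_half_mm optional length-3 half extents of the volume of
#'   interest; sites outside it are excluded. The through-plane positions
#'   beyond the in-plane lattice of the other orientations rely on
#'   extrapolated lookups, so the standard analysis volume excludes them
#'   (the default VOI in [run_study()] is 260 x 260 x 240 mm).
#' @return A `distortion_stats` tibble with columns `axis` (`x, y, z, r`),
#'   `mean_mm`, `sd_mm`, `max_mm`, `n`.
#' @export
field_statistics <- function(samples, voi_half_mm = NULL) {
  if (!is.null(voi_half_mm)) {
    keep <- abs(samples$x_mm) <= voi_half_mm[1] &
      abs(samples$y_mm) <= voi_half_mm[2] &
      abs(samples$z_mm) <= voi_half_mm[3]
    samples <- samples[keep, ]
  }
  stopifnot(nrow(samples) > 0)
  comp <- list(x = abs(samples$dx_mm), y = abs(samples$dy_mm),
               z = abs(samples$dz_mm), r = samples$dr_mm)
  out <- tibble::tibble(
    axis = names(comp),
    mean_mm = unname(vapply(comp, mean, numeric(1))),
    sd_mm = unname(vapply(comp, stats::sd, numeric(1))),
    max_mm = unname(vapply(comp, max, numeric(1))),
    n = nrow(samples)
  )
  out$sd_mm[is.na(out$sd_mm)] <- 0
  class(out) <- c("distortion_stats", class(out))
  out
}

#' Per-slice maximum displacement profile along z
#'
#' The maximum absolute displacement per component in each control-point
#' plane along the z axis.
#'
#' @param samples a `displacement_samples` tibble.
#' @param round_mm grouping tolerance for the z planes.
#' @return Tibble with `z_mm`, `component` (`x, y, z, r`), `max_mm`.
#' @export
slice_max_profile <- function(samples, round_mm = 2) {
  zg <- round(samples$z_mm / round_mm) * round_mm
  agg <- function(v) unname(tapply(abs(v), zg, max))
  zs <- as.numeric(names(tapply(abs(samples$dx_mm), zg, max)))
  tibble::tibble(
    z_mm = rep(zs, 4),
    component = rep(c("x", "y", "z", "r"), each = length(zs)),
    max_mm = c(agg(samples$dx_mm), agg(samples$dy_mm),
               agg(samples$dz_mm), agg(samples$dr_mm))
  )
}
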