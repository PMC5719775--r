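#' Detection parameters for control-point extraction
#'
#' Tunables of the per-slice detection pipeline. The defaults are expressed
#' relative to the default phantom: the unsharp-masking sigma is three times
#' the grid pitch (strong blur, removes all grid-scale structure), the
#' directional line sigma is a third of the pitch, and the per-slice
#' threshold is the median of the positive unsharp-masked intensities times
#' `threshold_factor`.
#'
#' @param unsharp_sigma_mm Gaussian sigma of the unsharp-mask blur.
#' @param line_sigma_mm sigma of the 1D directional (line) blurs.
#' @param cross_sigma_mm small cross-axis sigma of the directional blurs
#'   (about one bar width; widens crossing dots to a robust support).
#' @param threshold_mode `"median_auto"` (per-slice adaptive, on the
#'   unsharp-masked slice) or `"fixed"` (one global threshold applied to the
#'   raw inverted slice — the non-adaptive baseline).
#' @param threshold_factor scale on the per-slice median (adaptive mode).
#' @param threshold_value global threshold (fixed mode).
#' @param dot_cutoff relative cutoff on the combined directional response:
#'   pixels below `dot_cutoff` times the typical (median) candidate-peak
#'   response are discarded, keeping only areas where both orthogonal line
#'   responses are high (the crossings).
#' @param area_min_px,area_max_px,expected_dot_px dot-area filter in pixels;
#'   `NULL` means derived from the voxel size (about 15 px at 0.9 mm).
#' @param ws_tolerance watershed tolerance (fraction of the dot maximum).
#' @param line_support_frac minimum mean-to-peak ratio of each directional
#'   response along a window through a dot (the line-support test that
#'   rejects compact blobs such as air bubbles).
#' @param support_window_mm half-window of the line-support test.
#' @param border_margin_mm in-plane margin near the slice boundary excluded
#'   from dot detection (directional blur support is truncated there).
#' @param min_contrast minimum relative grid contrast (90th percentile of the
#'   normalised unsharp residual) for a slice to count as containing grid
#'   structure; slices below it (pure oil / noise) are skipped.
#' @param min_sheet_gap_mm through-plane gap that separates two grid sheets
#'   when merging per-slice detections.
#' @param track_radius_mm in-plane radius used to associate detections of the
#'   same physical crossing across slices of one sheet.
#' @param expected_points_per_slice if given, slices yielding fewer than half
#'   this many dots raise a warning and sheets yielding more raise an error.
#' @return A `detection_params` list.
#' @export
detection_params <- function(unsharp_sigma_mm = 45,
                             line_sigma_mm = 5,
                             cross_sigma_mm = 2,
                             threshold_mode = c("median_auto", "fixed"),
                             threshold_factor = 1.0,
                             threshold_value = NULL,
                             dot_cutoff = 0.6,
                             area_min_px = NULL,
                             area_max_px = NULL,
                             expected_dot_px = NULL,
                             ws_tolerance = 0.05,
                             line_support_frac = 0.45,
                             support_window_mm = 12,
                             border_margin_mm = 10,
                             min_contrast = 0.25,
                             min_sheet_gap_mm = 4.5,
                             track_radius_mm = 4.5,
                             expected_points_per_slice = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(unsharp_sigma_mm > 0, line_sigma_mm > 0, dot_cutoff > 0,
            dot_cutoff < 1)
  structure(
    list(
      unsharp_sigma_mm = unsharp_sigma_mm, line_sigma_mm = line_sigma_mm,
      cross_sigma_mm = cross_sigma_mm,
      threshold_mode = threshold_mode, threshold_factor = threshold_factor,
      threshold_value = threshold_value, dot_cutoff = dot_cutoff,
      area_min_px = area_min_px, area_max_px = area_max_px,
      expected_dot_px = expected_dot_px, ws_tolerance = ws_tolerance,
      line_support_frac = line_support_frac,
      support_window_mm = support_window_mm,
      border_margin_mm = border_margin_mm,
      min_contrast = min_contrast,
      min_sheet_gap_mm = min_sheet_gap_mm, track_radius_mm = track_radius_mm,
      expected_points_per_slice = expected_points_per_slice
    ),
    class = "detection_params"
  )
}

# fill in voxel-dependent dot-area defaults: at the default cutoff a dot
# covers roughly (bar width + 2.5 * cross sigma)^2 ~ 50 mm^2
resolve_area_limits <- function(params, voxel_mm) {
  px_area <- voxel_mm[1] * voxel_mm[2]
  expected <- params$expected_dot_px %||% max(4, round(55 / px_area))
  amin <- params$area_min_px %||% max(2, floor(expected / 5))
  amax <- params$area_max_px %||% ceiling(expected * 4)
  list(amin = amin, amax = amax, expected = expected)
}

#' Invert MR intensities so the grid is bright on dark
#'
#' MR shows bright oil and dark grid; CT the opposite. Inverting the MR
#' volume (`v -> max(v) - v`) lets one detection pipeline serve both.
#'
#' @param volume an [mr_volume].
#' @return The volume, inverted if modality is MR; CT volumes pass through.
#' @export
invert_if_mr <- function(volume) {
  if (volume$modality != "MR") return(volume)
  out <- volume
  out$data <- max(volume$data) - volume$data
  out
}

gauss_kernel <- function(sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(seq(-r, r), sd = sigma_px)
  k / sum(k)
}

# 1D Gaussian blur of a matrix along dimension 1 or 2 (zero-padded);
# the kernel is truncated if it would exceed the image extent
blur1d <- function(img, sigma_px, dim) {
  k <- gauss_kernel(sigma_px)
  n <- dim(img)[dim]
  rmax <- (n - 1L) %/% 2L
  r <- (length(k) - 1L) %/% 2L
  if (r > rmax) {
    k <- k[(r - rmax + 1L):(r + rmax + 1L)]
    k <- k / sum(k)
  }
  f <- if (dim == 1L) matrix(k, ncol = 1) else matrix(k, nrow = 1)
  EBImage::filter2(img, f, boundary = 0)
}

# separable 2D Gaussian blur, optionally normalised by the blurred window
# (correct local mean near the image boundary)
smooth2d <- function(img, sigma_px2, norm = NULL) {
  out <- blur1d(blur1d(img, sigma_px2[1], 1L), sigma_px2[2], 2L)
  if (!is.null(norm)) out / norm else out
}

smooth2d_norm <- function(dims, sigma_px2) {
  smooth2d(matrix(1, dims[1], dims[2]), sigma_px2)
}

#' Unsharp masking of one slice
#'
#' Subtracts a strongly Gaussian-blurred copy of the slice, removing smooth
#' intensity inhomogeneity while keeping the grid-scale structure.
#'
#' @param slice_image 2D numeric matrix.
#' @param sigma_mm blur sigma (should be much larger than the grid bars).
#' @param voxel_mm length-2 in-plane voxel size.
#' @return Matrix of the same size, approximately zero-mean.
#' @export
unsharp_mask <- function(slice_image, sigma_mm, voxel_mm) {
  spx <- sigma_mm / voxel_mm[1:2]
  norm <- smooth2d_norm(dim(slice_image), spx)
  slice_image - smooth2d(slice_image, spx, norm)
}

#' Per-slice adaptive threshold
#'
#' Threshold derived from the slice's own histogram: the slice median (the
#' background/oil level of the contrast image) plus `factor * robust_cap`
#' noise standard deviations. The noise scale is estimated from the
#' *negative* deviations only — the grid contributes only positive residual
#' contrast, so the negative half-histogram is pure background — which makes
#' the threshold sit just above the background fluctuations of *this*
#' slice: low enough to keep the entire grid including partial-volume bar
#' pixels, high enough to remove background noise, regardless of the
#' slice's overall intensity level.
#'
#' @param slice_image 2D numeric matrix (unsharp-masked contrast image,
#'   grid positive).
#' @param factor scale on the robust offset (exposed tuning knob).
#' @param robust_cap offset in noise-sigma units.
#' @return Binary matrix (0/1); all-zero with a warning if the slice has no
#'   dynamic range.
#' @export
adaptive_threshold <- function(slice_image, factor = 1.0, robust_cap = 3.0) {
  rng <- range(slice_image)
  if (diff(rng) <= 0) {
    warning("adaptive_threshold(): slice has zero dynamic range; skipped",
            call. = FALSE)
    return(matrix(0, nrow(slice_image), ncol(slice_image)))
  }
  med <- stats::median(slice_image)
  neg <- med - slice_image[slice_image < med]
  sigma <- if (length(neg)) 1.4826 * stats::median(neg) else 0
  thr <- med + factor * robust_cap * sigma
  (slice_image > thr) * 1
}

#' Line-intersection mask: keep only grid crossings
#'
#' Blurs the grid image with a 1D Gaussian along each in-plane axis (plus a
#' small cross-axis sigma) to obtain a horizontal-line and a vertical-line
#' response. Both are normalised by the local grid density (so partial
#' sheet coverage does not scale the responses down) and referenced to the
#' robust bar-parallel level of this slice. Pixels where *both* directional
#' responses exceed `cutoff` times their bar level — the crossings of
#' orthogonal grid lines — keep the geometric-mean response; all others are
#' zeroed. Bar segments respond in only one direction and are suppressed;
#' bright blobs (bubbles) can respond in both and are removed later by the
#' line-support test in [separate_and_filter_dots()].
#'
#' @param binary_image binary mask from [adaptive_threshold()], or the
#'   masked contrast image (mask times positive contrast).
#' @param line_sigma_mm directional blur sigma (along the line direction).
#' @param voxel_mm length-2 in-plane voxel size.
#' @param cutoff per-direction cutoff as a fraction of the bar level.
#' @param cross_sigma_mm small cross-axis sigma (about one bar width) that
#'   widens the crossing dots to a robust few-pixel support.
#' @return Non-negative matrix with isolated dots at the grid crossings;
#'   attributes `bh`, `bv` hold the normalised directional responses.
#' @export
line_intersection_mask <- function(binary_image, line_sigma_mm, voxel_mm,
                                   cutoff = 0.6, cross_sigma_mm = 2) {
  bh <- blur1d(blur1d(binary_image, line_sigma_mm / voxel_mm[1], 1L),
               cross_sigma_mm / voxel_mm[2], 2L)
  bv <- blur1d(blur1d(binary_image, line_sigma_mm / voxel_mm[2], 2L),
               cross_sigma_mm / voxel_mm[1], 1L)
  sup <- binary_image > 0
  if (!any(sup)) {
    out <- bh * 0
    attr(out, "bh") <- bh
    attr(out, "bv") <- bv
    return(out)
  }
  # local grid density (scale ~ one pitch, boundary-corrected): normalises
  # out partial sheet coverage so crossings in weakly covered slice regions
  # keep full response
  dens_spx <- 3 * line_sigma_mm / voxel_mm[1:2]
  dens <- smooth2d(binary_image, dens_spx,
                   smooth2d_norm(dim(binary_image), dens_spx))
  d_med <- stats::median(dens[sup])
  if (d_med > 0) {
    nf <- d_med / pmax(dens, 0.3 * d_med)
    bh <- bh * nf
    bv <- bv * nf
  }
  # robust bar-parallel level per direction: on-bar pixels are roughly half
  # parallel (high) and half perpendicular (low) to each blur direction
  level_h <- stats::quantile(bh[sup], 0.7, names = FALSE)
  level_v <- stats::quantile(bv[sup], 0.7, names = FALSE)
  if (level_h <= 0 || level_v <= 0) {
    out <- bh * 0
  } else {
    keep <- bh >= cutoff * level_h & bv >= cutoff * level_v
    out <- ifelse(keep, sqrt(pmax(bh, 0) * pmax(bv, 0)), 0)
  }
  # directional responses kept for sub-voxel centroiding and line support:
  # bv localises the dim-1 coordinate, bh the dim-2 one
  attr(out, "bh") <- bh
  attr(out, "bv") <- bv
  out
}

#' Separate touching dots and filter artifacts
#'
#' Watershed segmentation of the dot image (splits merged dots at their
#' intensity saddle), then two artifact filters: regions whose pixel count
#' falls outside the expected dot-area limits (streaks, frame fragments,
#' merged clumps), and regions failing the line-support test — a true
#' crossing sits on two long grid lines, so each directional response stays
#' near its peak value along a window through the region; a compact blob
#' (air bubble) responds only over its own extent and is rejected.
#'
#' @param dot_image non-negative matrix from [line_intersection_mask()]
#'   (with `bh`/`bv` attributes for the line-support test).
#' @param params a [detection_params].
#' @param voxel_mm length-2 in-plane voxel size (for area defaults).
#' @return Integer label matrix (0 = background); attribute `n_discarded`
#'   counts removed regions.
#' @export
separate_and_filter_dots <- function(dot_image, params = detection_params(),
                                     voxel_mm = c(1, 1)) {
  lim <- resolve_area_limits(params, voxel_mm)
  mx <- max(dot_image)
  if (mx <= 0) {
    out <- matrix(0L, nrow(dot_image), ncol(dot_image))
    attr(out, "n_discarded") <- 0L
    return(out)
  }
  lab <- EBImage::imageData(
    EBImage::watershed(EBImage::Image(dot_image / mx),
                       tolerance = params$ws_tolerance, ext = 1L)
  )
  storage.mode(lab) <- "integer"
  counts <- tabulate(lab)
  bad <- which(counts < lim$amin | counts > lim$amax)
  bh <- attr(dot_image, "bh")
  bv <- attr(dot_image, "bv")
  if (!is.null(bh) && !is.null(bv) && max(lab) > 0) {
    bad <- union(bad, which_fails_line_support(
      lab, dot_image, bh, bv, voxel_mm,
      params$support_window_mm, params$line_support_frac
    ))
  }
  if (length(bad)) {
    lab[lab %in% bad] <- 0L
    # compact label ids
    keep <- sort(unique(lab[lab > 0L]))
    lab[lab > 0L] <- match(lab[lab > 0L], keep)
  }
  attr(lab, "n_discarded") <- length(bad)
  lab
}

# Line-support test: for each region's peak pixel, each directional
# response sampled a window away *along its line direction* (both sides,
# with a small perpendicular tolerance for tilted lines) must stay a good
# fraction of the central response. A crossing sits on two long lines, so
# both side samples stay at bar level; a compact blob's response collapses
# beyond its own blurred extent.
which_fails_line_support <- function(lab, s, bh, bv, voxel_mm,
                                     window_mm, frac) {
  dm <- dim(lab)
  idx <- which(lab > 0L)
  if (length(idx) == 0) return(integer())
  l <- lab[idx]
  # peak pixel per region
  ord <- order(l, s[idx])
  last <- ord[cumsum(tabulate(l)[sort(unique(l))])]
  peak_idx <- idx[last]
  regs <- l[last]
  wi <- max(2L, round(window_mm / voxel_mm[1]))
  wj <- max(2L, round(window_mm / voxel_mm[2]))
  # perpendicular tolerance ~2 mm for locally tilted lines (kept small so a
  # side sample cannot graze a neighbouring orthogonal line)
  ti <- max(1L, round(2 / voxel_mm[1]))
  tj <- max(1L, round(2 / voxel_mm[2]))
  bad <- logical(length(regs))
  pi <- (peak_idx - 1L) %% dm[1] + 1L
  pj <- (peak_idx - 1L) %/% dm[1] + 1L
  side_max <- function(m, i, j, di, dj) {
    ci <- min(max(i + di, 1L), dm[1])
    cj <- min(max(j + dj, 1L), dm[2])
    ri <- if (di == 0) ti else 0L
    rj <- if (dj == 0) tj else 0L
    ii <- max(1L, ci - ri):min(dm[1], ci + ri)
    jj <- max(1L, cj - rj):min(dm[2], cj + rj)
    max(m[ii, jj])
  }
  for (r in seq_along(regs)) {
    i <- pi[r]; j <- pj[r]
    ch <- bh[i, j]; cv <- bv[i, j]
    if (ch <= 0 || cv <= 0) { bad[r] <- TRUE; next }
    # bh responds to lines running along dim 1: sample along dim 1
    sup_h <- min(side_max(bh, i, j, -wi, 0L), side_max(bh, i, j, wi, 0L)) / ch
    sup_v <- min(side_max(bv, i, j, 0L, -wj), side_max(bv, i, j, 0L, wj)) / cv
    bad[r] <- min(sup_h, sup_v) < frac
  }
  regs[bad]
}

#' Sub-voxel dot centroids of one slice
#'
#' Intensity-weighted center of mass of each labeled dot, using the positive
#' part of the unsharp-masked slice as weights (which carries the sub-voxel
#' partial-volume information), converted to world millimetres.
#'
#' @param labels integer label matrix from [separate_and_filter_dots()].
#' @param weight_image matrix of non-negative weights (same size).
#' @param origin_mm length-2 world coordinate of pixel (1,1).
#' @param voxel_mm length-2 in-plane voxel size.
#' @param dot_image optional dot-response matrix; when given, each centroid
#'   is computed from background-subtracted marginal profiles of the
#'   contrast over a fixed symmetric window (`core_radius_mm`) around the
#'   region's peak response: within the window, the orthogonal bar
#'   contributes a *constant* to each marginal (it crosses the whole
#'   window), so subtracting the marginal's median baseline isolates the
#'   bar that localises that coordinate. The symmetric window means a
#'   lopsided thresholded region (e.g. skewed by a nearby blob's blurred
#'   response) cannot bias the estimate.
#' @param core_radius_mm half-extent of the centroiding window.
#' @return Tibble with `u_mm`, `v_mm` (in-plane world coords), `area_px`,
#'   `intensity` (mean weight) per dot.
#' @export
dot_centroids <- function(labels, weight_image, origin_mm, voxel_mm,
                          dot_image = NULL, core_radius_mm = 3.2) {
  sel <- which(labels > 0L)
  if (length(sel) == 0) {
    return(tibble::tibble(u_mm = numeric(), v_mm = numeric(),
                          area_px = integer(), intensity = numeric()))
  }
  dm <- dim(labels)
  if (!is.null(dot_image)) {
    lab0 <- labels[sel]
    area_full <- tabulate(lab0)
    # peak pixel per region
    ord <- order(lab0, dot_image[sel])
    last <- ord[cumsum(area_full[sort(unique(lab0))])]
    peak_idx <- sel[last]
    regs <- lab0[last]
    nreg <- length(regs)
    ri <- max(2L, round(core_radius_mm / voxel_mm[1]))
    rj <- max(2L, round(core_radius_mm / voxel_mm[2]))
    pi0 <- pmin(pmax((peak_idx - 1L) %% dm[1] + 1L, 1L + ri), dm[1] - ri)
    pj0 <- pmin(pmax((peak_idx - 1L) %/% dm[1] + 1L, 1L + rj), dm[2] - rj)
    w <- pmax(weight_image, 0)
    # window values per region: nreg x (2ri+1) x (2rj+1)
    offs_i <- -ri:ri
    offs_j <- -rj:rj
    V <- array(0, dim = c(nreg, length(offs_i), length(offs_j)))
    for (a in seq_along(offs_i)) {
      for (b in seq_along(offs_j)) {
        V[, a, b] <- w[cbind(pi0 + offs_i[a], pj0 + offs_j[b])]
      }
    }
    marg_centroid <- function(P, offs) {
      base <- apply(P, 1, stats::median)
      Q <- pmax(P - base, 0)
      tot <- rowSums(Q)
      tot[tot <= 0] <- 1
      as.numeric(Q %*% offs) / tot
    }
    du <- marg_centroid(apply(V, c(1, 2), sum), offs_i)
    dv <- marg_centroid(apply(V, c(1, 3), sum), offs_j)
    wmean <- apply(V, 1, mean)
    return(tibble::tibble(
      u_mm = origin_mm[1] + (pi0 + du - 1) * voxel_mm[1],
      v_mm = origin_mm[2] + (pj0 + dv - 1) * voxel_mm[2],
      area_px = as.integer(area_full[regs]),
      intensity = as.numeric(wmean)
    ))
  }
  # plain path: intensity-weighted centroid over the labelled region
  lab <- labels[sel]
  w <- pmax(weight_image[sel], 0)
  wsum0 <- rowsum(w, lab)
  zero <- wsum0[, 1] <= 0
  if (any(zero)) {
    ids <- as.integer(rownames(wsum0))[zero]
    w[lab %in% ids] <- 1
  }
  i <- (sel - 1L) %% dm[1] + 1L
  j <- (sel - 1L) %/% dm[1] + 1L
  wsum <- rowsum(w, lab)
  ui <- rowsum(w * i, lab) / wsum
  vj <- rowsum(w * j, lab) / wsum
  n <- rowsum(rep(1L, length(sel)), lab)
  tibble::tibble(
    u_mm = as.numeric(origin_mm[1] + (ui[, 1] - 1) * voxel_mm[1]),
    v_mm = as.numeric(origin_mm[2] + (vj[, 1] - 1) * voxel_mm[2]),
    area_px = as.integer(n[, 1]),
    intensity = as.numeric(wsum[, 1] / n[, 1])
  )
}

orientation_from_axes <- function(axes) {
  key <- paste(axes, collapse = "")
  switch(key,
    xyz = "transverse", yzx = "sagittal", xzy = "coronal",
    stop("unrecognised axis labels: ", key, call. = FALSE)
  )
}

#' Extract sub-voxel control points from a phantom volume
#'
#' Runs the per-slice pipeline (MR inversion, unsharp masking, per-slice
#' adaptive thresholding, directional line-intersection masking, watershed
#' separation, area filtering, intensity-weighted centroids) over every
#' slice, then merges the per-slice detections that belong to one physical
#' grid sheet — contiguous runs of slices along the through-plane axis,
#' associated in-plane within `track_radius_mm` — into one point per grid
#' crossing, averaging with the per-slice dot intensity as weight (which
#' yields a sub-voxel through-plane coordinate).
#'
#' @param volume an [mr_volume] with the grid profile in the slice plane.
#' @param params a [detection_params].
#' @param polarity read-gradient polarity tag carried into the output.
#' @return A `control_points` tibble: `x_mm`, `y_mm`, `z_mm`, `slice`
#'   (central slice index), `area_px`, `intensity`, with attributes
#'   `modality`, `orientation`, `polarity`, `n_slices_used`.
#' @export
extract_control_points <- function(volume, params = detection_params(),
                                   polarity = "forward") {
  vol <- if (params$threshold_mode == "fixed") invert_if_mr(volume) else volume
  # grid polarity: MR shows the grid dark on bright oil, CT the opposite
  sgn <- if (volume$modality == "MR") -1 else 1
  dm <- dim(vol$data)
  vox2 <- vol$voxel_mm[1:2]
  org2 <- vol$origin_mm[1:2]
  ws <- axis_coords(vol, 3)
  per_slice <- vector("list", dm[3])
  wstack <- vector("list", dm[3])   # contrast stacks for z refinement
  expected <- params$expected_points_per_slice
  spx <- params$unsharp_sigma_mm / vox2
  wnorm <- smooth2d_norm(dm[1:2], spx)
  for (k in seq_len(dm[3])) {
    sl <- vol$data[, , k]
    if (params$threshold_mode == "median_auto") {
      blurred <- smooth2d(sl, spx, wnorm)
      # two views of the unsharp residual, grid made positive:
      #  - resid (absolute): uniform noise level -> noise-referenced mask
      #  - un (relative contrast, residual / local level): a multiplicative
      #    inhomogeneity cancels in the ratio -> uniform bar mass, used for
      #    weighting and responses
      resid <- sgn * (sl - blurred)
      un <- resid / pmax(blurred, 0.1 * max(blurred), 1e-12)
      wstack[[k]] <- pmax(un, 0)
      if (stats::quantile(un, 0.9) < params$min_contrast) next
      mask <- adaptive_threshold(un, params$threshold_factor)
      wimg <- pmax(un, 0)
    } else {
      if (is.null(params$threshold_value)) {
        stop("threshold_mode='fixed' requires threshold_value", call. = FALSE)
      }
      mask <- (sl > params$threshold_value) * 1
      wimg <- pmax(sl - params$threshold_value, 0)
    }
    if (!any(mask > 0)) next
    dots <- line_intersection_mask(mask * wimg, params$line_sigma_mm, vox2,
                                   params$dot_cutoff, params$cross_sigma_mm)
    # blur support is invalid near the slice boundary; exclude a margin
    mi <- max(1L, round(params$border_margin_mm / vox2[1]))
    mj <- max(1L, round(params$border_margin_mm / vox2[2]))
    if (2 * mi < nrow(dots) && 2 * mj < ncol(dots)) {
      dots[c(seq_len(mi), nrow(dots) - seq_len(mi) + 1L), ] <- 0
      dots[, c(seq_len(mj), ncol(dots) - seq_len(mj) + 1L)] <- 0
    }
    labs <- separate_and_filter_dots(dots, params, vox2)
    cents <- dot_centroids(labs, wimg, org2, vox2, dot_image = dots)
    if (nrow(cents) == 0) next
    cents$slice <- k
    cents$w_mm <- ws[k]
    per_slice[[k]] <- cents
    if (!is.null(expected) && nrow(cents) < expected / 2 &&
        nrow(cents) > 0) {
      warning(sprintf(
        "extract_control_points(): slice %d yielded %d of ~%d expected dots",
        k, nrow(cents), expected), call. = FALSE)
    }
  }
  all_pts <- dplyr::bind_rows(per_slice)
  if (nrow(all_pts) == 0) {
    warning("extract_control_points(): no dots detected in any slice",
            call. = FALSE)
    return(empty_control_points(vol, polarity))
  }
  merged <- merge_sheet_detections(all_pts, params)
  if (params$threshold_mode == "median_auto") {
    merged <- refine_track_w(merged, wstack, ws, org2, vox2)
  }
  if (!is.null(expected)) {
    per_sheet <- table(merged$sheet)
    if (any(per_sheet > expected)) {
      stop("extract_control_points(): sheet(s) ",
           paste(names(per_sheet)[per_sheet > expected], collapse = ", "),
           " yielded more than the expected ", expected,
           " merged points (duplicates)", call. = FALSE)
    }
  }
  as_control_points(merged, vol, polarity)
}

empty_control_points <- function(vol, polarity) {
  out <- tibble::tibble(
    x_mm = numeric(), y_mm = numeric(), z_mm = numeric(),
    slice = integer(), area_px = numeric(), intensity = numeric()
  )
  attr(out, "modality") <- vol$modality
  attr(out, "orientation") <- orientation_from_axes(vol$axes)
  attr(out, "polarity") <- polarity
  class(out) <- c("control_points", class(out))
  out
}

# merge per-slice detections into one point per grid crossing per sheet;
# sheets are runs of "core" slices (at least half the maximum per-slice dot
# count); sparse detections in other slices attach to an adjacent sheet or
# are dropped as noise
merge_sheet_detections <- function(pts, params) {
  counts <- table(pts$w_mm)
  ws_found <- as.numeric(names(counts))
  n_slice <- as.integer(counts)
  core <- n_slice >= max(n_slice) / 2
  if (!any(core)) core <- n_slice == max(n_slice)
  wcore <- ws_found[core]
  brk <- which(diff(wcore) > params$min_sheet_gap_mm)
  sheet_of_core <- findInterval(wcore, wcore[brk] + 1e-9) + 1L
  n_sheets <- max(sheet_of_core)
  lo <- tapply(wcore, sheet_of_core, min)
  hi <- tapply(wcore, sheet_of_core, max)
  spacing <- if (length(ws_found) > 1) stats::median(diff(ws_found)) else 1
  attach_mm <- max(params$min_sheet_gap_mm / 2, 1.25 * spacing)
  sheet_of_w <- integer(length(ws_found))
  for (i in seq_along(ws_found)) {
    d_lo <- lo - ws_found[i]
    d_hi <- ws_found[i] - hi
    d <- pmax(d_lo, d_hi, 0)
    s <- which.min(d)
    sheet_of_w[i] <- if (d[s] <= attach_mm) s else NA_integer_
  }
  pts$sheet <- sheet_of_w[match(pts$w_mm, ws_found)]
  pts <- pts[!is.na(pts$sheet), ]
  out <- vector("list", n_sheets)
  for (s in sort(unique(pts$sheet))) {
    sub <- pts[pts$sheet == s, ]
    out[[s]] <- merge_tracks(sub, params$track_radius_mm)
    out[[s]]$sheet <- s
  }
  dplyr::bind_rows(out)
}

# within one sheet, associate detections across slices and average
merge_tracks <- function(sub, radius_mm) {
  slices <- sort(unique(sub$slice))
  centers <- NULL      # n_tracks x 2 running (weighted) means
  acc <- NULL          # list of accumulators
  for (k in slices) {
    p <- sub[sub$slice == k, ]
    pw <- p$intensity * p$area_px        # total dot weight in this slice
    if (is.null(centers)) {
      centers <- cbind(p$u_mm, p$v_mm)
      acc <- list(
        su = p$u_mm * pw, sv = p$v_mm * pw, sw = p$w_mm * pw,
        wt = pw, n = rep(1L, nrow(p)), area = p$area_px,
        slice_lo = rep(k, nrow(p)), slice_hi = rep(k, nrow(p))
      )
      next
    }
    d2 <- outer(p$u_mm, centers[, 1], "-")^2 +
      outer(p$v_mm, centers[, 2], "-")^2
    nearest <- max.col(-d2)
    dist <- sqrt(d2[cbind(seq_len(nrow(p)), nearest)])
    for (r in seq_len(nrow(p))) {
      if (dist[r] <= radius_mm) {
        t <- nearest[r]
        acc$su[t] <- acc$su[t] + p$u_mm[r] * pw[r]
        acc$sv[t] <- acc$sv[t] + p$v_mm[r] * pw[r]
        acc$sw[t] <- acc$sw[t] + p$w_mm[r] * pw[r]
        acc$wt[t] <- acc$wt[t] + pw[r]
        acc$n[t] <- acc$n[t] + 1L
        acc$area[t] <- acc$area[t] + p$area_px[r]
        acc$slice_hi[t] <- k
        centers[t, ] <- c(acc$su[t], acc$sv[t]) / acc$wt[t]
      } else {
        centers <- rbind(centers, c(p$u_mm[r], p$v_mm[r]))
        acc$su <- c(acc$su, p$u_mm[r] * pw[r])
        acc$sv <- c(acc$sv, p$v_mm[r] * pw[r])
        acc$sw <- c(acc$sw, p$w_mm[r] * pw[r])
        acc$wt <- c(acc$wt, pw[r])
        acc$n <- c(acc$n, 1L)
        acc$area <- c(acc$area, p$area_px[r])
        acc$slice_lo <- c(acc$slice_lo, k)
        acc$slice_hi <- c(acc$slice_hi, k)
      }
    }
  }
  res <- tibble::tibble(
    u_mm = acc$su / acc$wt,
    v_mm = acc$sv / acc$wt,
    w_mm = acc$sw / acc$wt,
    slice = as.integer(round((acc$slice_lo + acc$slice_hi) / 2)),
    area_px = acc$area / acc$n,
    intensity = acc$wt / acc$area,
    n_slices = acc$n,
    mass = acc$wt
  )
  # a real crossing is seen in most slices of the sheet and accumulates
  # substantial response mass; isolated single-slice tracks and
  # feeble-mass tracks are residual noise or bubble fragments
  if (length(slices) >= 3) {
    res <- res[res$n_slices >= 2, ]
  }
  if (nrow(res) > 3) {
    res <- res[res$mass >= 0.15 * stats::median(res$mass), ]
  }
  res$n_slices <- NULL
  res$mass <- NULL
  res
}

# Refine each merged point's through-plane coordinate: intensity-weighted
# centroid of the contrast mass inside a fixed in-plane window around the
# point, profiled across the slices of its sheet (plus a margin). This is
# independent of the per-slice segmentation, so edge slices whose dots fell
# below slice-level cutoffs still contribute their partial-volume mass.
refine_track_w <- function(merged, wstack, ws, org2, vox2, window_mm = 2.8,
                           mass_floor = 0.15) {
  have <- which(!vapply(wstack, is.null, logical(1)))
  if (length(have) == 0 || nrow(merged) == 0) return(merged)
  dm2 <- dim(wstack[[have[1]]])
  ru <- max(1L, round(window_mm / vox2[1]))
  rv <- max(1L, round(window_mm / vox2[2]))
  offs <- expand.grid(du = -ru:ru, dv = -rv:rv)
  for (s in unique(merged$sheet)) {
    rows <- which(merged$sheet == s)
    iu <- pmin(pmax(round((merged$u_mm[rows] - org2[1]) / vox2[1]) + 1L,
                    1L + ru), dm2[1] - ru)
    iv <- pmin(pmax(round((merged$v_mm[rows] - org2[2]) / vox2[2]) + 1L,
                    1L + rv), dm2[2] - rv)
    # merged$slice holds track midpoints; extend the profile window to
    # cover the whole sheet thickness plus a margin beyond its edges
    spacing <- if (length(ws) > 1) stats::median(diff(ws)) else 1
    margin <- max(2L, ceiling(6 / spacing))
    krange <- range(merged$slice[rows])
    ks <- intersect(
      max(1L, krange[1] - margin):min(length(ws), krange[2] + margin),
      have
    )
    mass <- matrix(0, length(rows), length(ks))
    for (q in seq_along(ks)) {
      wimg <- wstack[[ks[q]]]
      acc <- numeric(length(rows))
      for (o in seq_len(nrow(offs))) {
        acc <- acc + wimg[cbind(iu + offs$du[o], iv + offs$dv[o])]
      }
      mass[, q] <- acc
    }
    keep <- mass >= mass_floor * apply(mass, 1, max)
    mass_k <- mass * keep
    merged$w_mm[rows] <- as.numeric((mass_k %*% ws[ks]) / rowSums(mass_k))
  }
  merged
}

# convert merged (u,v,w) rows to scanner-axis columns + attributes
as_control_points <- function(merged, vol, polarity) {
  s <- matrix(0, nrow(merged), 3, dimnames = list(NULL, c("x", "y", "z")))
  s[, vol$axes[1]] <- merged$u_mm
  s[, vol$axes[2]] <- merged$v_mm
  s[, vol$axes[3]] <- merged$w_mm
  out <- tibble::tibble(
    x_mm = s[, "x"], y_mm = s[, "y"], z_mm = s[, "z"],
    slice = merged$slice, area_px = merged$area_px,
    intensity = merged$intensity
  )
  attr(out, "modality") <- vol$modality
  attr(out, "orientation") <- orientation_from_axes(vol$axes)
  attr(out, "polarity") <- polarity
  class(out) <- c("control_points", class(out))
  out
}
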