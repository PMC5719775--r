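# CT/MR point-set registration: rigid shift from the isocenter assumption,
# polynomial-fit artifact cleaning, and one-to-one correspondence matching.

#' Reformat the transverse CT reference for another phantom orientation
#'
#' The MR acquisitions rotate the phantom, so the CT reference (scanned once,
#' transverse) must be rotated the same way. For point sets this is a
#' coordinate-axis permutation — exact, with no interpolation loss.
#'
#' @param ct_points `control_points` from the transverse CT scan.
#' @param orientation target grid orientation.
#' @return A `control_points` tibble in the rotated frame.
#' @export
permute_ct_reference <- function(ct_points, orientation) {
  uvw <- scanner_to_phantom(
    cbind(x = ct_points$x_mm, y = ct_points$y_mm, z = ct_points$z_mm),
    "transverse"
  )
  s <- phantom_to_scanner(uvw, orientation)
  out <- ct_points
  out$x_mm <- s[, "x"]
  out$y_mm <- s[, "y"]
  out$z_mm <- s[, "z"]
  attr(out, "orientation") <- orientation
  out
}

#' Rigid CT-to-MR shift from the isocenter assumption
#'
#' Two-step translation estimate. First the through-plane (z) shift aligns
#' the midplane of the CT point set's z extent with the MR isocenter plane
#' (z = 0). Then the residual translation is the mean CT-minus-MR
#' displacement over the control points in a small neighbourhood of the
#' isocenter, where distortion is negligible — and, the neighbourhood being
#' symmetric about the isocenter, the leading (linear) field term averages
#' out, making the estimate far less sensitive to single-point detection
#' noise than a lone center-point pair.
#'
#' @param ct,mr `control_points` sets (CT in the same phantom orientation).
#' @param pitch_mm nominal grid pitch (used for sanity radii).
#' @param neighborhood_mm radius of the isocenter neighbourhood.
#' @return Named numeric `c(dx_mm, dy_mm, dz_mm)`: subtract from the CT
#'   coordinates to bring them into the MR (isocenter) frame.
#' @export
register_ct_to_mr <- function(ct, mr, pitch_mm = 15, neighborhood_mm = 26) {
  stopifnot(nrow(ct) > 0, nrow(mr) > 0)
  dz <- (max(ct$z_mm) + min(ct$z_mm)) / 2
  ct_m <- cbind(ct$x_mm, ct$y_mm, ct$z_mm - dz)
  mr_m <- cbind(mr$x_mm, mr$y_mm, mr$z_mm)
  near <- which(rowSums(mr_m^2) <= neighborhood_mm^2)
  if (length(near) == 0 ||
      min(rowSums(mr_m^2)) > (pitch_mm / 2 + 2)^2 ||
      min(rowSums(ct_m^2)) > (pitch_mm / 2 + 2)^2) {
    stop("register_ct_to_mr(): no control point near the isocenter in one ",
         "of the sets", call. = FALSE)
  }
  pr <- greedy_match(candidate_pairs(mr_m[near, , drop = FALSE], ct_m,
                                     pitch_mm / 2),
                     length(near), nrow(ct_m))
  if (nrow(pr) == 0) {
    stop("register_ct_to_mr(): isocenter neighbourhood points could not be ",
         "paired", call. = FALSE)
  }
  d <- ct_m[pr$j, , drop = FALSE] - mr_m[near[pr$i], , drop = FALSE]
  c(dx_mm = mean(d[, 1]), dy_mm = mean(d[, 2]), dz_mm = mean(d[, 3]) + dz)
}

#' Apply a rigid shift to a control-point set
#'
#' @param points a `control_points` tibble.
#' @param shift shift from [register_ct_to_mr()] (subtracted).
#' @return Shifted `control_points`.
#' @export
apply_shift <- function(points, shift) {
  out <- points
  out$x_mm <- points$x_mm - shift[[1]]
  out$y_mm <- points$y_mm - shift[[2]]
  out$z_mm <- points$z_mm - shift[[3]]
  out
}

# all candidate pairs within `radius` between two point matrices (chunked)
candidate_pairs <- function(a, b, radius, chunk = 512L) {
  res <- list()
  nb <- nrow(b)
  for (s in seq(1L, nrow(a), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(a))
    d2 <- outer(a[s:e, 1], b[, 1], "-")^2 +
      outer(a[s:e, 2], b[, 2], "-")^2 +
      outer(a[s:e, 3], b[, 3], "-")^2
    hit <- which(d2 <= radius^2, arr.ind = TRUE)
    if (nrow(hit)) {
      res[[length(res) + 1L]] <- data.frame(
        i = hit[, 1] + s - 1L, j = hit[, 2], d = sqrt(d2[hit])
      )
    }
  }
  if (length(res) == 0) {
    return(data.frame(i = integer(), j = integer(), d = numeric()))
  }
  do.call(rbind, res)
}

# greedy distance-sorted unique matching ("keep closest, re-queue the loser")
greedy_match <- function(pairs, n_a, n_b) {
  pairs <- pairs[order(pairs$d), ]
  used_a <- logical(n_a)
  used_b <- logical(n_b)
  keep <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    ia <- pairs$i[r]; jb <- pairs$j[r]
    if (!used_a[ia] && !used_b[jb]) {
      keep[r] <- TRUE
      used_a[ia] <- TRUE
      used_b[jb] <- TRUE
    }
  }
  pairs[keep, ]
}

#' Remove artifact points with a per-sheet polynomial fit
#'
#' Per grid sheet, fits a 2D polynomial of degree `order` mapping the CT
#' in-plane coordinates to the detected MR in-plane coordinates, and removes
#' MR points lying farther than `tol_mm` from the polynomial prediction at
#' their provisionally matched CT site — along with MR points that match no
#' CT site at all (e.g. surviving bubbles). The polynomial is used only for
#' outlier rejection, never as the distortion model.
#'
#' @param mr MR `control_points` (isocenter frame).
#' @param ct CT `control_points` in the same orientation and frame.
#' @param order polynomial degree (3 in the reference protocol).
#' @param tol_mm rejection tolerance.
#' @param pitch_mm nominal grid pitch (provisional match radius = pitch / 2).
#' @return Cleaned MR `control_points`; attribute `removed_artifacts` counts
#'   dropped points.
#' @export
clean_with_polynomial <- function(mr, ct, order = 3, tol_mm = 3,
                                  pitch_mm = 15) {
  orientation <- attr(mr, "orientation") %||% "transverse"
  ax <- orientation_axes(orientation)
  iip <- match(ax[1:2], c("x", "y", "z"))
  itw <- match(ax[3], c("x", "y", "z"))
  cols <- c("x_mm", "y_mm", "z_mm")
  mr_m <- cbind(mr$x_mm, mr$y_mm, mr$z_mm)
  ct_m <- cbind(ct$x_mm, ct$y_mm, ct$z_mm)
  pr <- candidate_pairs(mr_m, ct_m, pitch_mm / 2)
  pr <- greedy_match(pr, nrow(mr), nrow(ct))
  keep <- logical(nrow(mr))          # unmatched stay FALSE -> removed
  matched_mr <- pr$i
  matched_ct <- pr$j
  # group matched points by CT sheet: cluster the through-plane coordinate
  # with gaps above half the sheet pitch
  wct <- ct_m[matched_ct, itw]
  ow <- order(wct)
  brk <- cumsum(c(1, diff(wct[ow]) > pitch_mm / 2))
  sheet_id <- integer(length(wct))
  sheet_id[ow] <- brk
  sheets <- split(seq_along(matched_mr), sheet_id)
  n_coef <- (order + 1) * (order + 2) / 2
  for (sh in sheets) {
    a1 <- ct_m[matched_ct[sh], iip[1]]
    a2 <- ct_m[matched_ct[sh], iip[2]]
    if (length(sh) < n_coef + 2) {
      warning("clean_with_polynomial(): sheet with ", length(sh),
              " points passes through unfiltered", call. = FALSE)
      keep[matched_mr[sh]] <- TRUE
      next
    }
    X <- poly2d_design(a1, a2, order)
    r1 <- mr_m[matched_mr[sh], iip[1]] -
      X %*% qr.solve(X, mr_m[matched_mr[sh], iip[1]])
    r2 <- mr_m[matched_mr[sh], iip[2]] -
      X %*% qr.solve(X, mr_m[matched_mr[sh], iip[2]])
    ok <- sqrt(r1^2 + r2^2) <= tol_mm
    keep[matched_mr[sh][ok]] <- TRUE
  }
  out <- mr[keep, ]
  attr(out, "modality") <- attr(mr, "modality")
  attr(out, "orientation") <- orientation
  attr(out, "polarity") <- attr(mr, "polarity")
  attr(out, "removed_artifacts") <- sum(!keep)
  class(out) <- class(mr)
  out
}

poly2d_design <- function(a1, a2, order) {
  s1 <- max(abs(a1), 1); s2 <- max(abs(a2), 1)
  cols <- list()
  for (p in 0:order) for (q in 0:(order - p)) {
    cols[[length(cols) + 1L]] <- (a1 / s1)^p * (a2 / s2)^q
  }
  do.call(cbind, cols)
}

#' One-to-one CT-to-MR correspondences
#'
#' For each CT control point, the nearest MR point within `match_radius_mm`;
#' competing claims are resolved in favour of the smaller distance, with the
#' loser re-queued to its next candidate. The default radius (half the grid
#' pitch) guarantees uniqueness for distortion below half a pitch.
#'
#' @param ct CT `control_points` in the isocenter (MR) frame.
#' @param mr MR `control_points` (cleaned).
#' @param match_radius_mm matching radius.
#' @return A `correspondences` tibble: `x_ct, y_ct, z_ct, x_mr, y_mr, z_mr,
#'   dist_mm`, with attributes `orientation`, `polarity`, `unmatched_ct`.
#' @export
match_correspondences <- function(ct, mr, match_radius_mm = 7.5) {
  ct_m <- cbind(ct$x_mm, ct$y_mm, ct$z_mm)
  mr_m <- cbind(mr$x_mm, mr$y_mm, mr$z_mm)
  pr <- candidate_pairs(ct_m, mr_m, match_radius_mm)
  pr <- greedy_match(pr, nrow(ct), nrow(mr))
  unmatched <- nrow(ct) - nrow(pr)
  if (unmatched > 0.05 * nrow(ct)) {
    warning(sprintf(
      "match_correspondences(): %d of %d CT points unmatched",
      unmatched, nrow(ct)), call. = FALSE)
  }
  out <- tibble::tibble(
    x_ct = ct_m[pr$i, 1], y_ct = ct_m[pr$i, 2], z_ct = ct_m[pr$i, 3],
    x_mr = mr_m[pr$j, 1], y_mr = mr_m[pr$j, 2], z_mr = mr_m[pr$j, 3],
    dist_mm = pr$d
  )
  attr(out, "orientation") <- attr(mr, "orientation")
  attr(out, "polarity") <- attr(mr, "polarity")
  attr(out, "unmatched_ct") <- unmatched
  class(out) <- c("correspondences", class(out))
  out
}

#' Average forward- and reverse-gradient control points (B0 removal)
#'
#' The B0-induced displacement flips sign with the read-gradient polarity;
#' the coordinate-wise mean of each point's location in the forward and
#' reverse acquisitions cancels it, leaving the gradient-nonlinearity
#' (system) component.
#'
#' @param fwd,rev `control_points` from the two polarities.
#' @param match_radius_mm radius for the point-by-point forward/reverse
#'   association.
#' @return `control_points` with averaged coordinates (polarity
#'   `"averaged"`); unmatched points are dropped with a warning.
#' @export
average_forward_reverse <- function(fwd, rev, match_radius_mm = 7.5) {
  f_m <- cbind(fwd$x_mm, fwd$y_mm, fwd$z_mm)
  r_m <- cbind(rev$x_mm, rev$y_mm, rev$z_mm)
  pr <- greedy_match(candidate_pairs(f_m, r_m, match_radius_mm),
                     nrow(fwd), nrow(rev))
  dropped <- nrow(fwd) - nrow(pr)
  if (dropped > 0) {
    warning("average_forward_reverse(): ", dropped,
            " forward points had no reverse partner and were dropped",
            call. = FALSE)
  }
  out <- fwd[pr$i, ]
  out$x_mm <- (f_m[pr$i, 1] + r_m[pr$j, 1]) / 2
  out$y_mm <- (f_m[pr$i, 2] + r_m[pr$j, 2]) / 2
  out$z_mm <- (f_m[pr$i, 3] + r_m[pr$j, 3]) / 2
  attr(out, "modality") <- attr(fwd, "modality")
  attr(out, "orientation") <- attr(fwd, "orientation")
  attr(out, "polarity") <- "averaged"
  class(out) <- class(fwd)
  out
}
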