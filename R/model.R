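#' Analytic ground-truth distortion model
#'
#' A smooth stand-in for the (unknown) scanner distortion field used by the
#' simulator: each displacement component is a trivariate polynomial of total
#' degree <= 3 in scaled coordinates, optionally plus a radial harmonic term,
#' and a separate polynomial models the B0-induced displacement along the
#' read direction (which flips sign under read-gradient reversal).
#'
#' Coefficients are given as named numeric vectors; names are monomials in
#' `x`, `y`, `z` with optional integer powers, e.g. `c(x3 = 0.7, x = 0.3,
#' z3 = 11.2, z = -8.4)` means `0.7 u^3 + 0.3 u + 11.2 w^3 - 8.4 w` with
#' `u = x / scale_mm`, `w = z / scale_mm`. All terms have total degree >= 1,
#' so the displacement vanishes at the isocenter (distortion is negligible
#' there by construction).
#'
#' @param dx,dy,dz named coefficient vectors for the system displacement (mm).
#' @param b0 named coefficient vector for the B0 displacement (mm), or NULL.
#' @param scale_mm coordinate scale for the monomials.
#' @param harmonic optional `list(amp_mm=, period_mm=)` radial term
#'   `amp * sin(2*pi*r/period)` applied along the radial unit vector.
#' @return A `distortion_model` object.
#' @export
distortion_model <- function(dx = numeric(), dy = numeric(), dz = numeric(),
                             b0 = NULL, scale_mm = 130, harmonic = NULL) {
  comps <- list(dx = parse_poly(dx), dy = parse_poly(dy), dz = parse_poly(dz))
  b0p <- if (is.null(b0)) NULL else parse_poly(b0)
  if (!is.null(harmonic)) {
    stopifnot(is.list(harmonic), all(c("amp_mm", "period_mm") %in% names(harmonic)),
              harmonic$period_mm > 0)
  }
  structure(
    list(comps = comps, b0 = b0p, scale_mm = scale_mm, harmonic = harmonic),
    class = "distortion_model"
  )
}

# parse named monomial coefficients into a (terms x 4) matrix: px, py, pz, coef
parse_poly <- function(coefs) {
  if (length(coefs) == 0) {
    return(matrix(numeric(), 0, 4, dimnames = list(NULL, c("px", "py", "pz", "coef"))))
  }
  stopifnot(!is.null(names(coefs)), all(nzchar(names(coefs))))
  out <- t(vapply(names(coefs), function(nm) {
    pows <- c(x = 0, y = 0, z = 0)
    if (nm != "1") {      # "1" denotes a constant (rigid-offset) term
      for (m in regmatches(nm, gregexpr("[xyz][0-9]*", nm))[[1]]) {
        ax <- substr(m, 1, 1)
        p <- if (nchar(m) > 1) as.integer(substr(m, 2, nchar(m))) else 1L
        pows[ax] <- pows[ax] + p
      }
      if (sum(pows) < 1) {
        stop("distortion_model: monomial '", nm, "' not understood",
             call. = FALSE)
      }
    }
    if (sum(pows) > 3) {
      stop("distortion_model: monomial '", nm,
           "' has total degree above 3", call. = FALSE)
    }
    pows
  }, numeric(3)))
  cbind(out, coef = as.numeric(coefs))
}

eval_poly <- function(pmat, u, v, w) {
  out <- numeric(length(u))
  for (r in seq_len(nrow(pmat))) {
    out <- out + pmat[r, 4] *
      (if (pmat[r, 1] > 0) u^pmat[r, 1] else 1) *
      (if (pmat[r, 2] > 0) v^pmat[r, 2] else 1) *
      (if (pmat[r, 3] > 0) w^pmat[r, 3] else 1)
  }
  out
}

# system displacement (no B0) at scanner coords; returns n x 3 matrix (mm)
eval_system <- function(model, xyz) {
  u <- xyz[, 1] / model$scale_mm
  v <- xyz[, 2] / model$scale_mm
  w <- xyz[, 3] / model$scale_mm
  out <- cbind(
    dx = eval_poly(model$comps$dx, u, v, w),
    dy = eval_poly(model$comps$dy, u, v, w),
    dz = eval_poly(model$comps$dz, u, v, w)
  )
  if (!is.null(model$harmonic)) {
    r <- sqrt(xyz[, 1]^2 + xyz[, 2]^2 + xyz[, 3]^2)
    amp <- model$harmonic$amp_mm * sin(2 * pi * r / model$harmonic$period_mm)
    s <- ifelse(r > 0, amp / r, 0)
    out <- out + xyz * s
  }
  out
}

# B0 displacement magnitude at scanner coords (mm); zero if no b0 model
eval_b0 <- function(model, xyz) {
  if (is.null(model$b0)) return(numeric(nrow(xyz)))
  eval_poly(model$b0, xyz[, 1] / model$scale_mm, xyz[, 2] / model$scale_mm,
            xyz[, 3] / model$scale_mm)
}

#' Ground-truth displacement at given points
#'
#' System displacement plus the polarity-signed B0 displacement along the
#' read axis. The mean of forward and reverse displacement equals the system
#' component exactly.
#'
#' @param model a [distortion_model].
#' @param points data frame or matrix with columns `x_mm`, `y_mm`, `z_mm`
#'   (or a plain n x 3 matrix).
#' @param polarity `"none"`, `"forward"` or `"reverse"`.
#' @param read_axis scanner axis the read gradient lies along (`"x"`, `"y"`
#'   or `"z"`).
#' @return Tibble with columns `dx_mm`, `dy_mm`, `dz_mm`, `dr_mm`.
#' @export
true_displacement <- function(model, points,
                              polarity = c("none", "forward", "reverse"),
                              read_axis = "x") {
  polarity <- match.arg(polarity)
  xyz <- as_xyz_matrix(points)
  d <- eval_system(model, xyz)
  if (polarity != "none") {
    b <- eval_b0(model, xyz) * if (polarity == "forward") 1 else -1
    ax <- match(read_axis, c("x", "y", "z"))
    d[, ax] <- d[, ax] + b
  }
  tibble::tibble(
    dx_mm = d[, 1], dy_mm = d[, 2], dz_mm = d[, 3],
    dr_mm = sqrt(rowSums(d^2))
  )
}

as_xyz_matrix <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 3)
    colnames(points) <- c("x", "y", "z")
    return(points)
  }
  cols <- c("x_mm", "y_mm", "z_mm")
  stopifnot(all(cols %in% names(points)))
  cbind(x = points$x_mm, y = points$y_mm, z = points$z_mm)
}

#' Maximum displacement magnitude of a model over a box
#'
#' @param model a [distortion_model].
#' @param half_extent_mm length-3 half extents of the box.
#' @param n grid points per axis used for the scan.
#' @return max |delta r| in mm over the sampled box.
#' @export
model_max_displacement <- function(model, half_extent_mm = c(120, 120, 120),
                                   n = 21) {
  g <- expand.grid(
    x = seq(-half_extent_mm[1], half_extent_mm[1], length.out = n),
    y = seq(-half_extent_mm[2], half_extent_mm[2], length.out = n),
    z = seq(-half_extent_mm[3], half_extent_mm[3], length.out = n)
  )
  d <- eval_system(model, as.matrix(g))
  max(sqrt(rowSums(d^2)))
}

#' Default synthetic study field
#'
#' Degree-3 field with maximum total displacement of about 5 to 6 mm over the
#' control-point volume and deliberate through-plane (z) gradients in the
#' in-plane components — the regime where the iterative estimator is needed —
#' plus a quadratic B0 term of about 2 mm at the edges.
#'
#' @return A [distortion_model].
#' @export
default_study_model <- function() {
  distortion_model(
    dx = c(x3 = 0.7, x = 0.3, z3 = 11.2, z = -8.4),
    dy = c(y3 = 0.7, y = 0.3, z3 = -11.2, z = 8.4),
    dz = c(z3 = 2.6, z = 0.3, x2z = 0.5),
    b0 = c(x2 = 1.2, y = 0.8, z2 = 0.6),
    scale_mm = 130
  )
}

#' Zero distortion model
#' @return A [distortion_model] with no displacement anywhere.
#' @export
zero_model <- function() distortion_model()

#' Analytic fixed point of the shifted-lookup displacement equations
#'
#' The iterative estimator refines each component by evaluating the field at
#' coordinates corrected by the other components' latest estimates; its
#' fixed point satisfies `dx = dx(x, y + dy, z + dz)` (and cyclically).
#' This function solves those equations with the analytic model — the exact
#' quantity the estimator converges to, independent of any measurement.
#' When the field has no cross-axis coupling it equals the plain
#' displacement [true_displacement()].
#'
#' @param model a [distortion_model].
#' @param points data frame or n x 3 matrix of positions.
#' @param tol_mm,max_iter fixed-point stopping parameters.
#' @return Tibble with `dx_mm`, `dy_mm`, `dz_mm`, `dr_mm`.
#' @export
fixed_point_displacement <- function(model, points, tol_mm = 1e-4,
                                     max_iter = 50L) {
  xyz <- as_xyz_matrix(points)
  d <- eval_system(model, xyz)
  for (it in seq_len(max_iter)) {
    prev <- d
    for (comp in 1:3) {
      q <- xyz + d
      q[, comp] <- xyz[, comp]
      d[, comp] <- eval_system(model, q)[, comp]
    }
    if (max(abs(d - prev)) < tol_mm) break
  }
  tibble::tibble(dx_mm = d[, 1], dy_mm = d[, 2], dz_mm = d[, 3],
                 dr_mm = sqrt(rowSums(d^2)))
}
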