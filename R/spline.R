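# Natural cubic spline machinery for distortion-field interpolation.
#
# The displacement samples live on (nearly) regular lattices of a few thousand
# sites; the estimator needs to evaluate per-component interpolants at many
# scattered query points (Eqs-of-motion style shifted lookups during the
# iterative refinement, and dense grids during image correction). Everything
# here is plain natural-spline algebra, vectorised over queries:
#   - ns_operator(x): linear operator S with m = S y giving second derivatives
#     of the natural cubic spline through (x, y);
#   - tensor3: tensor-product spline on a regular x/y/z lattice;
#   - sheared3: tensor spline whose through-plane knots differ per in-plane
#     node (used to house samples at their apparent through-plane coordinate).
# Extrapolation is linear (natural-spline end slope) up to `extrap_mm`, then
# the query coordinate is clamped to that limit.

ns_operator <- function(x) {
  n <- length(x)
  stopifnot(n >= 2, !is.unsorted(x, strictly = TRUE))
  S <- matrix(0, n, n)
  if (n > 2) {
    h <- diff(x)
    A <- matrix(0, n - 2, n - 2)
    R <- matrix(0, n - 2, n)
    for (i in seq_len(n - 2)) {
      A[i, i] <- 2 * (h[i] + h[i + 1])
      if (i > 1) A[i, i - 1] <- h[i]
      if (i < n - 2) A[i, i + 1] <- h[i + 1]
      R[i, i] <- 6 / h[i]
      R[i, i + 1] <- -6 / h[i] - 6 / h[i + 1]
      R[i, i + 2] <- 6 / h[i + 1]
    }
    S[2:(n - 1), ] <- solve(A, R)
  }
  S
}

# Evaluate one natural spline (knots x, values y, second derivs m) at t.
# Linear extrapolation beyond the knot range, clamped `extrap` past the ends.
ns_eval <- function(x, y, m, t, extrap = Inf) {
  n <- length(x)
  lo <- x[1] - extrap
  hi <- x[n] + extrap
  t <- pmin(pmax(t, lo), hi)
  tin <- pmin(pmax(t, x[1]), x[n])
  k <- pmin(pmax(findInterval(tin, x), 1L), n - 1L)
  h <- x[k + 1] - x[k]
  A <- (x[k + 1] - tin) / h
  B <- 1 - A
  val <- A * y[k] + B * y[k + 1] +
    ((A^3 - A) * m[k] + (B^3 - B) * m[k + 1]) * h^2 / 6
  over_lo <- t < x[1]
  over_hi <- t > x[n]
  if (any(over_lo)) {
    h1 <- x[2] - x[1]
    s <- (y[2] - y[1]) / h1 - h1 * m[2] / 6
    val[over_lo] <- val[over_lo] + s * (t[over_lo] - x[1])
  }
  if (any(over_hi)) {
    hn <- x[n] - x[n - 1]
    s <- (y[n] - y[n - 1]) / hn + hn * m[n - 1] / 6
    val[over_hi] <- val[over_hi] + s * (t[over_hi] - x[n])
  }
  val
}

# Evaluate q independent natural splines sharing knots `x`: row i of Y holds
# the values of spline i, which is evaluated at t[i]. S = ns_operator(x).
ns_eval_rows <- function(x, S, Y, t, extrap = Inf) {
  n <- length(x)
  q <- nrow(Y)
  M <- Y %*% t(S)
  lo <- x[1] - extrap
  hi <- x[n] + extrap
  t <- pmin(pmax(t, lo), hi)
  tin <- pmin(pmax(t, x[1]), x[n])
  k <- pmin(pmax(findInterval(tin, x), 1L), n - 1L)
  h <- x[k + 1] - x[k]
  A <- (x[k + 1] - tin) / h
  B <- 1 - A
  rows <- seq_len(q)
  yk <- Y[cbind(rows, k)]
  yk1 <- Y[cbind(rows, k + 1)]
  mk <- M[cbind(rows, k)]
  mk1 <- M[cbind(rows, k + 1)]
  val <- A * yk + B * yk1 + ((A^3 - A) * mk + (B^3 - B) * mk1) * h^2 / 6
  over_lo <- t < x[1]
  over_hi <- t > x[n]
  if (any(over_lo)) {
    h1 <- x[2] - x[1]
    s <- (Y[over_lo, 2] - Y[over_lo, 1]) / h1 - h1 * M[over_lo, 2] / 6
    val[over_lo] <- val[over_lo] + s * (t[over_lo] - x[1])
  }
  if (any(over_hi)) {
    hn <- x[n] - x[n - 1]
    s <- (Y[over_hi, n] - Y[over_hi, n - 1]) / hn + hn * M[over_hi, n - 1] / 6
    val[over_hi] <- val[over_hi] + s * (t[over_hi] - x[n])
  }
  val
}

build_tensor3 <- function(xs, ys, zs, vals, extrap = Inf) {
  stopifnot(identical(dim(vals), c(length(xs), length(ys), length(zs))))
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  Vz <- matrix(aperm(vals, c(3, 1, 2)), nz, nx * ny)  # nz x (nx*ny), i fastest
  Sz <- ns_operator(zs)
  structure(
    list(
      xs = xs, ys = ys, zs = zs,
      Sx = ns_operator(xs), Sy = ns_operator(ys),
      Vz = Vz, Mz = Sz %*% Vz,
      nx = nx, ny = ny, nz = nz, extrap = extrap
    ),
    class = "tensor3"
  )
}

# Scattered evaluation of a tensor3 at (qx, qy, qz); chunked to bound memory.
eval_tensor3 <- function(itp, qx, qy, qz, chunk = 16384L) {
  q <- length(qx)
  out <- numeric(q)
  for (s in seq(1L, q, by = chunk)) {
    e <- min(s + chunk - 1L, q)
    out[s:e] <- eval_tensor3_chunk(itp, qx[s:e], qy[s:e], qz[s:e])
  }
  out
}

eval_tensor3_chunk <- function(itp, qx, qy, qz) {
  zs <- itp$zs; nz <- itp$nz
  q <- length(qz)
  t <- pmin(pmax(qz, zs[1] - itp$extrap), zs[nz] + itp$extrap)
  tin <- pmin(pmax(t, zs[1]), zs[nz])
  k <- pmin(pmax(findInterval(tin, zs), 1L), nz - 1L)
  h <- zs[k + 1] - zs[k]
  A <- (zs[k + 1] - tin) / h
  B <- 1 - A
  C <- (A^3 - A) * h^2 / 6
  D <- (B^3 - B) * h^2 / 6
  # q x (nx*ny) plane of z-collapsed values
  W <- A * itp$Vz[k, , drop = FALSE] + B * itp$Vz[k + 1, , drop = FALSE] +
    C * itp$Mz[k, , drop = FALSE] + D * itp$Mz[k + 1, , drop = FALSE]
  over_lo <- t < zs[1]
  over_hi <- t > zs[nz]
  if (any(over_lo)) {
    h1 <- zs[2] - zs[1]
    s <- (itp$Vz[2, ] - itp$Vz[1, ]) / h1 - h1 * itp$Mz[2, ] / 6
    W[over_lo, ] <- W[over_lo, , drop = FALSE] +
      outer(t[over_lo] - zs[1], s)
  }
  if (any(over_hi)) {
    hn <- zs[nz] - zs[nz - 1]
    s <- (itp$Vz[nz, ] - itp$Vz[nz - 1, ]) / hn + hn * itp$Mz[nz - 1, ] / 6
    W[over_hi, ] <- W[over_hi, , drop = FALSE] +
      outer(t[over_hi] - zs[nz], s)
  }
  # collapse y per x-node, then x
  Vx <- matrix(0, q, itp$nx)
  idx <- seq(0L, (itp$ny - 1L)) * itp$nx
  for (i in seq_len(itp$nx)) {
    Yi <- W[, i + idx, drop = FALSE]
    Vx[, i] <- ns_eval_rows(itp$ys, itp$Sy, Yi, qy, itp$extrap)
  }
  ns_eval_rows(itp$xs, itp$Sx, Vx, qx, itp$extrap)
}

# Fast grid path: evaluate tensor3 on the separable grid gx x gy at a single
# slice coordinate z. Returns a length(gx) x length(gy) matrix.
eval_tensor3_slice <- function(itp, gx, gy, z) {
  zs <- itp$zs; nz <- itp$nz
  plane <- as.numeric(
    eval_tensor3_chunk_plane(itp, z)
  )                                   # nx*ny values at this z
  V <- matrix(plane, itp$nx, itp$ny)
  # x-direction: each y-column is a spline in x evaluated at all gx
  Sx <- itp$Sx
  Vg <- matrix(0, length(gx), itp$ny)
  Mx <- Sx %*% V                      # nx x ny second derivs
  for (j in seq_len(itp$ny)) {
    Vg[, j] <- ns_eval(itp$xs, V[, j], Mx[, j], gx, itp$extrap)
  }
  # y-direction: each gx row is a spline in y evaluated at all gy
  My <- Vg %*% t(itp$Sy)              # gx x ny
  out <- matrix(0, length(gx), length(gy))
  ys <- itp$ys; ny <- itp$ny
  tg <- pmin(pmax(gy, ys[1] - itp$extrap), ys[ny] + itp$extrap)
  tin <- pmin(pmax(tg, ys[1]), ys[ny])
  kv <- pmin(pmax(findInterval(tin, ys), 1L), ny - 1L)
  for (jj in seq_along(gy)) {
    k <- kv[jj]
    h <- ys[k + 1] - ys[k]
    A <- (ys[k + 1] - tin[jj]) / h
    B <- 1 - A
    col <- A * Vg[, k] + B * Vg[, k + 1] +
      ((A^3 - A) * My[, k] + (B^3 - B) * My[, k + 1]) * h^2 / 6
    if (tg[jj] < ys[1]) {
      h1 <- ys[2] - ys[1]
      col <- col + ((Vg[, 2] - Vg[, 1]) / h1 - h1 * My[, 2] / 6) * (tg[jj] - ys[1])
    } else if (tg[jj] > ys[ny]) {
      hn <- ys[ny] - ys[ny - 1]
      col <- col + ((Vg[, ny] - Vg[, ny - 1]) / hn + hn * My[, ny - 1] / 6) * (tg[jj] - ys[ny])
    }
    out[, jj] <- col
  }
  out
}

eval_tensor3_chunk_plane <- function(itp, z) {
  zs <- itp$zs; nz <- itp$nz
  t <- pmin(pmax(z, zs[1] - itp$extrap), zs[nz] + itp$extrap)
  tin <- pmin(pmax(t, zs[1]), zs[nz])
  k <- pmin(pmax(findInterval(tin, zs), 1L), nz - 1L)
  h <- zs[k + 1] - zs[k]
  A <- (zs[k + 1] - tin) / h
  B <- 1 - A
  W <- A * itp$Vz[k, ] + B * itp$Vz[k + 1, ] +
    (A^3 - A) * h^2 / 6 * itp$Mz[k, ] + (B^3 - B) * h^2 / 6 * itp$Mz[k + 1, ]
  if (t < zs[1]) {
    h1 <- zs[2] - zs[1]
    W <- W + ((itp$Vz[2, ] - itp$Vz[1, ]) / h1 - h1 * itp$Mz[2, ] / 6) * (t - zs[1])
  } else if (t > zs[nz]) {
    hn <- zs[nz] - zs[nz - 1]
    W <- W + ((itp$Vz[nz, ] - itp$Vz[nz - 1, ]) / hn + hn * itp$Mz[nz - 1, ] / 6) * (t - zs[nz])
  }
  W
}

# Sheared-grid interpolant: regular in-plane lattice (a_knots x b_knots), but
# each in-plane node has its own through-plane knots (W[a, b, ]) housing the
# values (VAL[a, b, ]). Used to house per-orientation displacement samples at
# their *apparent* through-plane coordinate.
build_sheared3 <- function(a_knots, b_knots, W, VAL, extrap = Inf) {
  na <- length(a_knots); nb <- length(b_knots)
  stopifnot(identical(dim(W), dim(VAL)),
            dim(W)[1] == na, dim(W)[2] == nb)
  nw <- dim(W)[3]
  Wm <- matrix(W, na * nb, nw)
  Vm <- matrix(VAL, na * nb, nw)
  if (any(apply(Wm, 1, is.unsorted, strictly = TRUE))) {
    stop("sheared-grid interpolant: apparent through-plane coordinates are not ",
         "monotone at some in-plane node (distortion exceeds half the sheet pitch?)",
         call. = FALSE)
  }
  # per-node second derivatives (knots differ per node)
  Mm <- matrix(0, na * nb, nw)
  for (r in seq_len(na * nb)) {
    Mm[r, ] <- ns_operator(Wm[r, ]) %*% Vm[r, ]
  }
  structure(
    list(
      a_knots = a_knots, b_knots = b_knots,
      Sa = ns_operator(a_knots), Sb = ns_operator(b_knots),
      Wm = Wm, Vm = Vm, Mm = Mm,
      na = na, nb = nb, nw = nw, extrap = extrap
    ),
    class = "sheared3"
  )
}

# Evaluate sheared3 at scattered (qa, qb, qw).
eval_sheared3 <- function(itp, qa, qb, qw, chunk = 16384L) {
  q <- length(qa)
  out <- numeric(q)
  for (s in seq(1L, q, by = chunk)) {
    e <- min(s + chunk - 1L, q)
    out[s:e] <- eval_sheared3_chunk(itp, qa[s:e], qb[s:e], qw[s:e])
  }
  out
}

eval_sheared3_chunk <- function(itp, qa, qb, qw) {
  q <- length(qw)
  nn <- itp$na * itp$nb
  nw <- itp$nw
  U <- matrix(0, q, nn)
  for (r in seq_len(nn)) {
    U[, r] <- ns_eval(itp$Wm[r, ], itp$Vm[r, ], itp$Mm[r, ], qw, itp$extrap)
  }
  Va <- matrix(0, q, itp$na)
  idx <- seq(0L, (itp$nb - 1L)) * itp$na
  for (i in seq_len(itp$na)) {
    Yi <- U[, i + idx, drop = FALSE]
    Va[, i] <- ns_eval_rows(itp$b_knots, itp$Sb, Yi, qb, itp$extrap)
  }
  ns_eval_rows(itp$a_knots, itp$Sa, Va, qa, itp$extrap)
}
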