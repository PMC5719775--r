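#' 3D image volume with world geometry
#'
#' `mr_volume()` wraps a 3D intensity array together with its voxel spacing,
#' world origin and the mapping from array dimensions to scanner axes.
#' World coordinates are millimetres in the scanner (isocenter-origin) frame,
#' voxel-center convention: the center of voxel `(i, j, k)` (1-based) sits at
#' `origin_mm + (index - 1) * voxel_mm` along the axis named by `axes`.
#'
#' The `axes` labels say which scanner axis each array dimension runs along.
#' A transverse acquisition stores slices along `z` (`axes = c("x","y","z")`);
#' a sagittal one along `x` (`axes = c("y","z","x")`); a coronal one along `y`
#' (`axes = c("x","z","y")`). The third dimension is always the slice
#' (through-plane) direction.
#'
#' @param data 3D numeric array of intensities.
#' @param voxel_mm length-3 positive numeric, spacing along each array dim.
#' @param origin_mm length-3 numeric, world position (mm) of voxel (1,1,1).
#' @param axes character(3), permutation of `c("x","y","z")`.
#' @param modality `"MR"` or `"CT"`.
#' @return An object of class `mr_volume`.
#' @export
mr_volume <- function(data, voxel_mm, origin_mm, axes = c("x", "y", "z"),
                      modality = c("MR", "CT")) {
  modality <- match.arg(modality)
  stopifnot(
    is.array(data), length(dim(data)) == 3L,
    length(voxel_mm) == 3L, all(voxel_mm > 0),
    length(origin_mm) == 3L, all(is.finite(origin_mm)),
    setequal(axes, c("x", "y", "z"))
  )
  structure(
    list(
      data = data,
      voxel_mm = as.numeric(voxel_mm),
      origin_mm = as.numeric(origin_mm),
      axes = as.character(axes),
      modality = modality
    ),
    class = "mr_volume"
  )
}

#' @export
print.mr_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<mr_volume> %s  %d x %d x %d voxels  spacing (%g, %g, %g) mm  axes (%s)\n",
    x$modality, d[1], d[2], d[3],
    x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3],
    paste(x$axes, collapse = ",")
  ))
  cat(sprintf(
    "  origin (%.2f, %.2f, %.2f) mm  intensity [%.3g, %.3g]\n",
    x$origin_mm[1], x$origin_mm[2], x$origin_mm[3],
    min(x$data), max(x$data)
  ))
  invisible(x)
}

#' @export
dim.mr_volume <- function(x) dim(x$data)

#' World coordinates of voxel centers along one array dimension
#'
#' @param volume an [mr_volume].
#' @param dim_index array dimension (1, 2 or 3).
#' @return Numeric vector of world mm coordinates (along `volume$axes[dim_index]`).
#' @export
axis_coords <- function(volume, dim_index) {
  n <- dim(volume$data)[dim_index]
  volume$origin_mm[dim_index] + (seq_len(n) - 1) * volume$voxel_mm[dim_index]
}

#' Centered volume origin for a given matrix size
#'
#' Origin such that the volume's world extent is centered on the isocenter.
#' @keywords internal
centered_origin <- function(matrix_dim, voxel_mm) {
  -(matrix_dim - 1) / 2 * voxel_mm
}

# Map a matrix of scanner-frame (x, y, z) coordinates (n x 3, columns x,y,z)
# to this volume's array dimension order. Returns n x 3 in dim order.
scanner_to_dims <- function(volume, xyz) {
  perm <- match(volume$axes, c("x", "y", "z"))
  xyz[, perm, drop = FALSE]
}

# Inverse: n x 3 matrix in array-dim order -> scanner (x,y,z) columns.
dims_to_scanner <- function(volume, d3) {
  perm <- match(c("x", "y", "z"), volume$axes)
  d3[, perm, drop = FALSE]
}

#' World bounding box of a volume
#'
#' @param volume an [mr_volume].
#' @return A 2 x 3 matrix (rows min/max, columns x, y, z in scanner order).
#' @export
volume_bbox <- function(volume) {
  lo <- volume$origin_mm - volume$voxel_mm / 2
  hi <- volume$origin_mm + (dim(volume$data) - 1 + 0.5) * volume$voxel_mm
  perm <- match(c("x", "y", "z"), volume$axes)
  rbind(min = lo[perm], max = hi[perm])
}

#' Voxelwise difference of two volumes on identical grids
#'
#' Quality-assurance helper: `a - b` voxel by voxel, e.g. corrected minus raw.
#'
#' @param a,b [mr_volume]s on the same grid (dims, spacing, origin, axes).
#' @return An [mr_volume] holding the difference.
#' @export
difference_volume <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)) ||
      !isTRUE(all.equal(a$voxel_mm, b$voxel_mm)) ||
      !isTRUE(all.equal(a$origin_mm, b$origin_mm)) ||
      !identical(a$axes, b$axes)) {
    stop("difference_volume(): volumes are not on identical grids", call. = FALSE)
  }
  out <- a
  out$data <- a$data - b$data
  out
}

#' Sample a volume's intensities at world coordinates
#'
#' Interpolates the volume at arbitrary scanner-frame positions. `"cubic"`
#' uses a separable Catmull-Rom kernel (interpolating, C1), `"linear"`
#' trilinear interpolation. Queries outside the volume are filled with `fill`.
#'
#' @param volume an [mr_volume].
#' @param xyz n x 3 matrix of scanner (x, y, z) mm coordinates.
#' @param interp `"cubic"` or `"linear"`.
#' @param fill value for out-of-volume queries (default: volume minimum).
#' @return Numeric vector of n interpolated intensities.
#' @export
sample_volume <- function(volume, xyz, interp = c("cubic", "linear"),
                          fill = NULL) {
  interp <- match.arg(interp)
  if (is.null(fill)) fill <- min(volume$data)
  dd <- scanner_to_dims(volume, xyz)
  dm <- dim(volume$data)
  # continuous 1-based index along each dim
  u <- sweep(sweep(dd, 2, volume$origin_mm, "-"), 2, volume$voxel_mm, "/") + 1
  if (interp == "linear") {
    interp_trilinear(volume$data, u, dm, fill)
  } else {
    interp_catmullrom(volume$data, u, dm, fill)
  }
}

interp_trilinear <- function(arr, u, dm, fill) {
  n <- nrow(u)
  i0 <- floor(u)
  f <- u - i0
  inside <- u[, 1] >= 1 & u[, 1] <= dm[1] &
    u[, 2] >= 1 & u[, 2] <= dm[2] &
    u[, 3] >= 1 & u[, 3] <= dm[3]
  # clamp so that gathers are valid; outside results overwritten with fill
  i0 <- pmin(pmax(i0, 1), matrix(rep(dm - 1, each = n), n))
  f <- pmin(pmax(u - i0, 0), 1)
  out <- numeric(n)
  for (dz in 0:1) {
    wz <- if (dz == 0) 1 - f[, 3] else f[, 3]
    for (dy in 0:1) {
      wy <- if (dy == 0) 1 - f[, 2] else f[, 2]
      for (dx in 0:1) {
        wx <- if (dx == 0) 1 - f[, 1] else f[, 1]
        idx <- (i0[, 3] + dz - 1) * dm[1] * dm[2] +
          (i0[, 2] + dy - 1) * dm[1] + (i0[, 1] + dx)
        out <- out + wx * wy * wz * arr[idx]
      }
    }
  }
  out[!inside] <- fill
  out
}

catmullrom_weights <- function(t) {
  # weights for samples at offsets -1, 0, 1, 2
  t2 <- t * t; t3 <- t2 * t
  cbind(
    -0.5 * t3 + t2 - 0.5 * t,
    1.5 * t3 - 2.5 * t2 + 1,
    -1.5 * t3 + 2 * t2 + 0.5 * t,
    0.5 * t3 - 0.5 * t2
  )
}

interp_catmullrom <- function(arr, u, dm, fill) {
  n <- nrow(u)
  inside <- u[, 1] >= 1 & u[, 1] <= dm[1] &
    u[, 2] >= 1 & u[, 2] <= dm[2] &
    u[, 3] >= 1 & u[, 3] <= dm[3]
  i0 <- floor(u)
  f <- u - i0
  wx <- catmullrom_weights(f[, 1])
  wy <- catmullrom_weights(f[, 2])
  wz <- catmullrom_weights(f[, 3])
  # clamped neighbour indices (replicate-edge) per axis, offsets -1..2
  ix <- lapply(-1:2, function(o) pmin(pmax(i0[, 1] + o, 1), dm[1]))
  iy <- lapply(-1:2, function(o) pmin(pmax(i0[, 2] + o, 1), dm[2]))
  iz <- lapply(-1:2, function(o) pmin(pmax(i0[, 3] + o, 1), dm[3]))
  out <- numeric(n)
  for (c3 in 1:4) {
    wz3 <- wz[, c3]
    off3 <- (iz[[c3]] - 1) * dm[1] * dm[2]
    for (c2 in 1:4) {
      w23 <- wy[, c2] * wz3
      off23 <- off3 + (iy[[c2]] - 1) * dm[1]
      for (c1 in 1:4) {
        out <- out + wx[, c1] * w23 * arr[off23 + ix[[c1]]]
      }
    }
  }
  out[!inside] <- fill
  out
}
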