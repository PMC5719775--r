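#' Grid-sheet phantom geometry
#'
#' Describes the physical QA phantom: a stack of styrene grid sheets inside an
#' oil-filled box. Each sheet carries a square lattice of grid bars whose
#' crossings are the control points. The default instance is 17 sheets of
#' 17 x 17 points at 15 mm in-plane pitch, 7.6 mm sheet thickness and 9 mm
#' oil gaps inside a 300 mm box.
#'
#' Canonical phantom coordinates are (u, v, w): u, v span the grid plane,
#' w the stacking direction. The control-point lattice is centered on the
#' phantom center.
#'
#' @param n_sheets number of grid sheets (>= 1).
#' @param points_per_row grid points per row/column on a sheet (>= 2).
#' @param point_pitch_mm in-plane spacing of grid crossings.
#' @param sheet_thickness_mm sheet thickness along the stack.
#' @param gap_mm oil gap between sheets.
#' @param grid_bar_width_mm width of the grid bars.
#' @param box_inner_mm inner box extent, length-3.
#' @return A `phantom_geometry` list.
#' @export
phantom_geometry <- function(n_sheets = 17L,
                             points_per_row = 17L,
                             point_pitch_mm = 15,
                             sheet_thickness_mm = 7.6,
                             gap_mm = 9,
                             grid_bar_width_mm = 2,
                             box_inner_mm = c(300, 300, 300)) {
  stopifnot(
    n_sheets >= 1, points_per_row >= 2,
    point_pitch_mm > 0, sheet_thickness_mm > 0, gap_mm > 0,
    grid_bar_width_mm > 0, length(box_inner_mm) == 3, all(box_inner_mm > 0)
  )
  structure(
    list(
      n_sheets = as.integer(n_sheets),
      points_per_row = as.integer(points_per_row),
      point_pitch_mm = point_pitch_mm,
      sheet_thickness_mm = sheet_thickness_mm,
      gap_mm = gap_mm,
      grid_bar_width_mm = grid_bar_width_mm,
      box_inner_mm = box_inner_mm,
      sheet_pitch_mm = sheet_thickness_mm + gap_mm
    ),
    class = "phantom_geometry"
  )
}

#' @export
print.phantom_geometry <- function(x, ...) {
  cat(sprintf(
    "<phantom_geometry> %d sheets of %dx%d points, pitch %g mm, sheet %g mm + gap %g mm\n",
    x$n_sheets, x$points_per_row, x$points_per_row,
    x$point_pitch_mm, x$sheet_thickness_mm, x$gap_mm
  ))
  invisible(x)
}

# centered lattice positions along one axis
lattice_1d <- function(n, pitch) (seq_len(n) - (n + 1) / 2) * pitch

#' Nominal control-point lattice of a phantom
#'
#' World (scanner-frame) coordinates of the undistorted grid crossings for a
#' given phantom orientation in the scanner.
#'
#' @param geometry a [phantom_geometry].
#' @param orientation `"transverse"`, `"sagittal"` or `"coronal"` — the plane
#'   the grid profile lies in.
#' @return Tibble with columns `x_mm`, `y_mm`, `z_mm` (one row per crossing).
#' @export
nominal_lattice <- function(geometry, orientation = "transverse") {
  uv <- lattice_1d(geometry$points_per_row, geometry$point_pitch_mm)
  w <- lattice_1d(geometry$n_sheets, geometry$sheet_pitch_mm)
  g <- expand.grid(u = uv, v = uv, w = w, KEEP.OUT.ATTRS = FALSE)
  s <- phantom_to_scanner(as.matrix(g), orientation)
  tibble::tibble(x_mm = s[, 1], y_mm = s[, 2], z_mm = s[, 3])
}

# scanner axis labels of the phantom's (u, v, w) axes per orientation
orientation_axes <- function(orientation) {
  switch(orientation,
    transverse = c("x", "y", "z"),
    sagittal   = c("y", "z", "x"),
    coronal    = c("x", "z", "y"),
    stop("unknown orientation: ", orientation, call. = FALSE)
  )
}

# map canonical phantom (u,v,w) rows to scanner (x,y,z) columns
phantom_to_scanner <- function(uvw, orientation) {
  ax <- orientation_axes(orientation)
  out <- matrix(0, nrow(uvw), 3, dimnames = list(NULL, c("x", "y", "z")))
  out[, ax[1]] <- uvw[, 1]
  out[, ax[2]] <- uvw[, 2]
  out[, ax[3]] <- uvw[, 3]
  out
}

# inverse mapping
scanner_to_phantom <- function(xyz, orientation) {
  ax <- orientation_axes(orientation)
  cbind(u = xyz[, ax[1]], v = xyz[, ax[2]], w = xyz[, ax[3]])
}

# Fractional coverage of the voxel interval [c - h, c + h] by a periodic set
# of slabs (centers at pitch * m, |m| <= mmax, slab full width `width`).
# Assumes pitch > width + 2h so at most one slab overlaps.
slab_coverage <- function(c, h, pitch, mmax, width) {
  m <- pmin(pmax(round(c / pitch), -mmax), mmax)
  d <- c - m * pitch
  ol <- pmin(d + h, width / 2) - pmax(d - h, -width / 2)
  pmin(pmax(ol, 0), 2 * h) / (2 * h)
}

# Fractional coverage of [c - h, c + h] by the single interval [-L, L].
span_coverage <- function(c, h, L) {
  ol <- pmin(c + h, L) - pmax(c - h, -L)
  pmin(pmax(ol, 0), 2 * h) / (2 * h)
}

# Partial-volume fraction of grid material at canonical points (u, v, w),
# averaged over a voxel footprint of half-extents hw3 = c(hu, hv, hw).
# Exact for the axis-aligned slab geometry (separable overlap integrals).
grid_fraction <- function(geometry, u, v, w, hw3) {
  # bars run the full sheet width (to the box walls); crossings only at the
  # points_per_row line positions
  p <- geometry$point_pitch_mm
  bw <- geometry$grid_bar_width_mm
  mmax_uv <- (geometry$points_per_row - 1) / 2
  fu <- slab_coverage(u, hw3[1], p, mmax_uv, bw)
  fv <- slab_coverage(v, hw3[2], p, mmax_uv, bw)
  fw <- slab_coverage(
    w, hw3[3], geometry$sheet_pitch_mm,
    (geometry$n_sheets - 1) / 2, geometry$sheet_thickness_mm
  )
  fw * (fu + fv - fu * fv)
}

# Oil (in-box) fraction at canonical points, with partial volume at the box edge.
box_fraction <- function(geometry, u, v, w, hw3) {
  b <- geometry$box_inner_mm / 2
  span_coverage(u, hw3[1], b[1]) *
    span_coverage(v, hw3[2], b[2]) *
    span_coverage(w, hw3[3], b[3])
}

# modality intensity levels: two-level rendering
modality_levels <- function(modality) {
  if (modality == "MR") {
    list(air = 0, oil = 1000, grid = 100)   # oil bright, grid dark
  } else {
    list(air = 0, oil = 100, grid = 1000)   # grid bright, oil dark
  }
}

# intensities at scanner-frame canonical coordinates (vectorised)
phantom_intensity <- function(geometry, u, v, w, hw3, modality) {
  lv <- modality_levels(modality)
  occ <- grid_fraction(geometry, u, v, w, hw3)
  inb <- box_fraction(geometry, u, v, w, hw3)
  lv$air + inb * ((lv$oil - lv$air) + (lv$grid - lv$oil) * occ)
}

#' Rasterize an ideal (undistorted) phantom volume
#'
#' Renders the grid-sheet phantom on a voxel grid with exact analytic
#' partial-volume fractions, so that detected dot centroids are sub-voxel
#' accurate against the nominal lattice. MR renders the grid dark on bright
#' oil; CT renders the grid bright on dark oil.
#'
#' @param geometry a [phantom_geometry].
#' @param voxel_mm length-3 voxel size: in-plane (u, v) then slice (w).
#' @param modality `"MR"` or `"CT"`.
#' @param fov_mm length-3 field of view (defaults to 280.8 x 280.8 x 280 mm,
#'   covering the control lattice with margin but excluding the box walls).
#' @param orientation grid-profile orientation in the scanner.
#' @return An [mr_volume]; array dims run along (u, v, w), axis labels set
#'   from the orientation.
#' @export
rasterize_phantom <- function(geometry, voxel_mm = c(0.9, 0.9, 1.0),
                              modality = c("MR", "CT"),
                              fov_mm = c(280.8, 280.8, 280),
                              orientation = "transverse") {
  modality <- match.arg(modality)
  stopifnot(all(voxel_mm > 0), length(fov_mm) == 3)
  mat <- pmax(round(fov_mm / voxel_mm), 2L)
  extent_uv <- (geometry$points_per_row - 1) * geometry$point_pitch_mm
  extent_w <- (geometry$n_sheets - 1) * geometry$sheet_pitch_mm +
    geometry$sheet_thickness_mm
  if (extent_uv > mat[1] * voxel_mm[1] || extent_uv > mat[2] * voxel_mm[2] ||
      extent_w > mat[3] * voxel_mm[3]) {
    stop("rasterize_phantom(): control-point lattice does not fit in the ",
         "requested matrix extent", call. = FALSE)
  }
  origin <- centered_origin(mat, voxel_mm)
  us <- origin[1] + (seq_len(mat[1]) - 1) * voxel_mm[1]
  vs <- origin[2] + (seq_len(mat[2]) - 1) * voxel_mm[2]
  ws <- origin[3] + (seq_len(mat[3]) - 1) * voxel_mm[3]
  hw3 <- voxel_mm / 2
  arr <- array(0, dim = mat)
  uu <- rep(us, times = mat[2])
  vv <- rep(vs, each = mat[1])
  for (k in seq_len(mat[3])) {
    arr[, , k] <- phantom_intensity(
      geometry, uu, vv, rep(ws[k], length(uu)), hw3, modality
    )
  }
  mr_volume(arr, voxel_mm, origin, axes = orientation_axes(orientation),
            modality = modality)
}
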