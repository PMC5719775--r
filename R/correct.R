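# Image rectification: resample the distorted volume at the displaced
# coordinates given by a distortion map, with isocenter-offset handling for
# volumes whose image center is not at the scanner isocenter.

#' In-plane shift between image center and scanner isocenter
#'
#' For volumes not acquired centered at the isocenter, the in-plane offset
#' is derived from the acquisition field of view and the header position
#' values: `shift = FOV/2 - position`.
#'
#' @param fov_mm in-plane field of view (mm); scalar or length-2.
#' @param x_dicom_mm,y_dicom_mm in-plane position values from the header.
#' @return Named numeric `c(x_shift_iso, y_shift_iso)` in mm.
#' @export
isocenter_shift <- function(fov_mm, x_dicom_mm, y_dicom_mm) {
  if (missing(fov_mm) || missing(x_dicom_mm) || missing(y_dicom_mm) ||
      is.null(fov_mm) || is.null(x_dicom_mm) || is.null(y_dicom_mm)) {
    stop("isocenter_shift(): FOV and header position values are required; ",
         "pass an explicit shift instead if they are unavailable",
         call. = FALSE)
  }
  stopifnot(all(fov_mm > 0))
  fov_mm <- rep(fov_mm, length.out = 2)
  c(x_shift_iso = fov_mm[1] / 2 - x_dicom_mm,
    y_shift_iso = fov_mm[2] / 2 - y_dicom_mm)
}

#' Rectify a distorted volume with a distortion map
#'
#' Each output voxel at (isocenter-frame) position `x` takes the input
#' intensity interpolated at `x + delta(x)`, the apparent position of the
#' structure that belongs at `x` — consistent with the displacement samples
#' being MR minus CT at CT sites, so the estimated map drives correction
#' directly without field inversion.
#'
#' @param distorted an [mr_volume].
#' @param map a `distortion_map` from [build_map()].
#' @param shift in-plane isocenter shift `c(x, y)` in mm (from
#'   [isocenter_shift()]); the volume's own coordinates plus `shift` give
#'   isocenter-frame coordinates.
#' @param interp intensity interpolation, `"cubic"` (Catmull-Rom) or
#'   `"linear"`.
#' @return The corrected [mr_volume].
#' @export
correct_volume <- function(distorted, map, shift = c(0, 0),
                           interp = c("cubic", "linear")) {
  interp <- match.arg(interp)
  # out-of-volume queries take the background level: the (bright) oil for
  # MR, the minimum for CT — a dark fill would masquerade as structure
  fill <- if (distorted$modality == "MR") {
    stats::quantile(distorted$data, 0.7, names = FALSE)
  } else {
    min(distorted$data)
  }
  dm <- dim(distorted$data)
  ax <- distorted$axes
  shift3 <- c(x = shift[[1]], y = shift[[2]], z = 0)
  us <- axis_coords(distorted, 1) + shift3[[ax[1]]]
  vs <- axis_coords(distorted, 2) + shift3[[ax[2]]]
  ws <- axis_coords(distorted, 3) + shift3[[ax[3]]]
  arr <- array(0, dim = dm)
  uu <- rep(us, times = dm[2])
  vv <- rep(vs, each = dm[1])
  dimperm <- match(ax, c("x", "y", "z"))  # scanner-axis index of each dim
  for (k in seq_len(dm[3])) {
    slice_coords <- list()
    slice_coords[[ax[1]]] <- us
    slice_coords[[ax[2]]] <- vs
    slice_coords[[ax[3]]] <- ws[k]
    dgrid <- eval_map_grid(map, slice_coords$x, slice_coords$y,
                           slice_coords$z)
    # each dgrid component is an array over (x, y, z) grid axes; rearrange
    # to the volume's (dim1, dim2) layout
    dslice <- lapply(dgrid, function(a) {
      aperm(a, dimperm)[, , 1]
    })
    q <- cbind(
      uu + as.numeric(dslice[[match(ax[1], c("x", "y", "z"))]]),
      vv + as.numeric(dslice[[match(ax[2], c("x", "y", "z"))]]),
      ws[k] + as.numeric(dslice[[match(ax[3], c("x", "y", "z"))]])
    )
    # back to the volume's own frame, in scanner-axis columns
    sq <- matrix(0, nrow(q), 3)
    sq[, match(ax[1], c("x", "y", "z"))] <- q[, 1] - shift3[[ax[1]]]
    sq[, match(ax[2], c("x", "y", "z"))] <- q[, 2] - shift3[[ax[2]]]
    sq[, match(ax[3], c("x", "y", "z"))] <- q[, 3] - shift3[[ax[3]]]
    arr[, , k] <- sample_volume(distorted, sq, interp = interp, fill = fill)
  }
  out <- distorted
  out$data <- arr
  out
}
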