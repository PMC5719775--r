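# ggplot2 visualisations: per-slice maximum profiles (the classic
# distortion-vs-z figure), distortion-map slices, and detection QA overlays.

#' Plot per-slice maximum distortion profiles
#'
#' Maximum absolute displacement per component in each control-point plane
#' along z — optionally comparing the measured field with a residual set.
#'
#' @param profile tibble from [slice_max_profile()].
#' @param residual optional second profile (drawn dashed).
#' @return A ggplot.
#' @export
plot_max_profile <- function(profile, residual = NULL) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$z_mm, y = .data$max_mm,
                                    colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "z (mm)", y = "max |displacement| (mm)",
                  colour = "component") +
    ggplot2::theme_minimal()
  if (!is.null(residual)) {
    p <- p + ggplot2::geom_line(data = residual, linetype = "dashed")
  }
  p
}

#' @method autoplot distortion_fit
#' @export
autoplot.distortion_fit <- function(object, ...) {
  plot_max_profile(slice_max_profile(object$samples)) +
    ggplot2::ggtitle(sprintf(
      "Iterative distortion field (%d iteration%s, %s)",
      object$iterations, if (object$iterations == 1) "" else "s",
      if (object$converged) "converged" else "not converged"
    ))
}

#' @method autoplot distortion_stats
#' @export
autoplot.distortion_stats <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$axis, y = .data$mean_mm)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_mm,
                   ymax = .data$mean_mm + .data$sd_mm), width = 0.25) +
    ggplot2::geom_point(ggplot2::aes(y = .data$max_mm), shape = 4) +
    ggplot2::labs(x = "axis", y = "displacement (mm)",
                  caption = "bars: mean + sd; crosses: max") +
    ggplot2::theme_minimal()
}

#' Map one distortion-map slice as a filled raster
#'
#' @param map a `distortion_map`.
#' @param z_mm slice position.
#' @param component `"x"`, `"y"`, `"z"` or `"r"`.
#' @param n grid resolution.
#' @return A ggplot.
#' @export
plot_distortion_slice <- function(map, z_mm = 0, component = "r", n = 81) {
  lim <- map$bbox
  gx <- seq(lim[1, 1], lim[2, 1], length.out = n)
  gy <- seq(lim[1, 2], lim[2, 2], length.out = n)
  g <- expand.grid(x_mm = gx, y_mm = gy)
  d <- eval_map(map, cbind(g$x_mm, g$y_mm, rep(z_mm, nrow(g))))
  g$value <- switch(component,
    x = d[, 1], y = d[, 2], z = d[, 3],
    r = sqrt(rowSums(d^2)),
    stop("component must be x, y, z or r", call. = FALSE)
  )
  ggplot2::ggplot(g, ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = sprintf("|d%s| (mm)", component)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Distortion map, z = %g mm", z_mm),
                  x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' QA overlay: detected control points on a slice
#'
#' @param volume the [mr_volume] the points came from.
#' @param points a `control_points` tibble.
#' @param slice slice index (array dim 3).
#' @param tol_mm through-plane distance within which points are drawn.
#' @return A ggplot.
#' @export
plot_detection_overlay <- function(volume, points, slice, tol_mm = 5) {
  sl <- volume$data[, , slice]
  us <- axis_coords(volume, 1)
  vs <- axis_coords(volume, 2)
  w <- axis_coords(volume, 3)[slice]
  img <- data.frame(
    u = rep(us, times = length(vs)),
    v = rep(vs, each = length(us)),
    intensity = as.numeric(sl)
  )
  ax <- volume$axes
  pu <- points[[paste0(ax[1], "_mm")]]
  pv <- points[[paste0(ax[2], "_mm")]]
  pw <- points[[paste0(ax[3], "_mm")]]
  sel <- abs(pw - w) <= tol_mm
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = img,
                         ggplot2::aes(x = .data$u, y = .data$v,
                                      fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::geom_point(data = data.frame(u = pu[sel], v = pv[sel]),
                        ggplot2::aes(x = .data$u, y = .data$v),
                        colour = "red", shape = 3, size = 1.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = sprintf("%s (mm)", ax[1]), y = sprintf("%s (mm)", ax[2]),
                  title = sprintf("Slice %d (%s = %g mm)", slice, ax[3], w)) +
    ggplot2::theme_minimal()
}
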