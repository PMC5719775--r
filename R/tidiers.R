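# broom-style tidiers for the iterative field fit.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-axis summary of a distortion fit
#'
#' One row per axis (`x`, `y`, `z`, `r`) with the mean, standard deviation
#' and maximum absolute displacement over all control points.
#'
#' @param x a `distortion_fit` from [iterate_field()].
#' @param ... unused.
#' @return A tibble with columns `axis`, `mean_mm`, `sd_mm`, `max_mm`, `n`.
#' @method tidy distortion_fit
#' @export
tidy.distortion_fit <- function(x, ...) {
  out <- field_statistics(x$samples)
  class(out) <- class(tibble::tibble())
  out
}

#' One-row summary of a distortion fit
#'
#' @param x a `distortion_fit` from [iterate_field()].
#' @param ... unused.
#' @return A one-row tibble: number of sites, iterations used, convergence
#'   flag, final iteration gap, and the mean/max total displacement.
#' @method glance distortion_fit
#' @export
glance.distortion_fit <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x$samples),
    iterations = x$iterations,
    converged = x$converged,
    final_gap_mm = utils::tail(x$gap_trace, 1),
    mean_dr_mm = mean(x$samples$dr_mm),
    max_dr_mm = max(x$samples$dr_mm)
  )
}
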