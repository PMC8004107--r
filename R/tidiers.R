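#' Broom-style accessors and plots for result objects
#'
#' `tidy()` returns the per-observation table, `glance()` a one-row
#' summary; `autoplot()` gives a quick diagnostic ggplot.
#'
#' @param x a `bf_run`, `bf_spots` or `bf_fits` object.
#' @param ... unused.
#' @return A tibble (`tidy`, `glance`) or a ggplot (`autoplot`).
#' @name brainfish-tidiers
NULL

#' @rdname brainfish-tidiers
#' @method tidy bf_run
#' @export
tidy.bf_run <- function(x, ...) x$counts

#' @rdname brainfish-tidiers
#' @method glance bf_run
#' @export
glance.bf_run <- function(x, ...) {
  tibble(
    sample = x$provenance$sample_id,
    n_detected = x$counts$n_detected[1],
    n_kept = x$counts$n_kept[1],
    n_colocalized = sum(x$counts$n_colocalized),
    alpha = x$provenance$detection$alpha,
    seed = x$provenance$seed
  )
}

#' @rdname brainfish-tidiers
#' @method tidy bf_fits
#' @export
tidy.bf_fits <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "bf_fits")
  as_tibble(out)
}

#' @rdname brainfish-tidiers
#' @method glance bf_fits
#' @export
glance.bf_fits <- function(x, ...) {
  tibble(
    n_spots = nrow(x),
    median_photons = stats::median(x$photons),
    median_fwhm = stats::median(x$fwhm),
    median_sbr = stats::median(x$signal_background_ratio),
    prop_converged = mean(x$converged)
  )
}

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_histogram labs coord_fixed
#' @export
ggplot2::autoplot

#' @rdname brainfish-tidiers
#' @param object a `bf_spots` or `bf_fits` tibble.
#' @method autoplot bf_spots
#' @export
autoplot.bf_spots <- function(object, ...) {
  ggplot(object, aes(x = .data$x, y = .data$y, size = .data$glrt_stat)) +
    geom_point(alpha = 0.6) +
    coord_fixed() +
    labs(x = "x (px)", y = "y (px)", size = "GLRT",
         title = sprintf("%d detections", nrow(object)))
}

#' @rdname brainfish-tidiers
#' @method autoplot bf_fits
#' @export
autoplot.bf_fits <- function(object, ...) {
  ggplot(object, aes(x = .data$photons, y = .data$signal_background_ratio)) +
    geom_point(alpha = 0.6) +
    labs(x = "fitted photons", y = "signal / background",
         title = "spot brightness")
}
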