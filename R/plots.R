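#' Plot methods for morphometry results
#'
#' `autoplot()` methods returning ggplot objects: vertical fraction
#' profiles, cumulative thickness distributions, curvature
#' occurrence-ratio curves and REV convergence curves (with the reference
#' +/- sd band).
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name icemorph-autoplot
NULL

#' @rdname icemorph-autoplot
#' @export
autoplot.vertical_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$value * 100, y = .data$z_um)) +
    geom_path() +
    labs(x = paste(attr(object, "fraction"), "(%)"), y = "height (µm)")
}

#' @rdname icemorph-autoplot
#' @export
autoplot.thickness_distribution <- function(object, ...) {
  ggplot(object, aes(x = .data$thickness_um, y = .data$cum_pct)) +
    geom_line() +
    labs(x = "local thickness (µm)", y = "cumulative volume (%)")
}

#' @rdname icemorph-autoplot
#' @export
autoplot.curvature_distribution <- function(object, ...) {
  ggplot(object, aes(x = .data$curvature_mm, y = .data$occurrence_pct)) +
    geom_col(width = object$upper[1] - object$lower[1]) +
    labs(x = expression(paste("mean curvature (", mm^-1, ")")),
         y = "occurrence ratio (%)")
}

#' @rdname icemorph-autoplot
#' @export
autoplot.rev_curve <- function(object, ...) {
  ref <- attr(object, "ref_mean")
  sdv <- attr(object, "ref_sd")
  ggplot(object, aes(x = .data$size_vx, y = .data$mean_fraction)) +
    geom_ribbon(aes(ymin = ref - sdv, ymax = ref + sdv),
                fill = "grey80", alpha = 0.6) +
    geom_hline(yintercept = ref, linetype = "dashed") +
    geom_line() + geom_point() +
    labs(x = "sub-volume edge (voxels)",
         y = paste(attr(object, "phase"), "fraction"))
}

#' Plot a single z-slice of a volume
#'
#' @param volume A [grey_volume()] or [label_volume()].
#' @param z Slice index (default: middle slice).
#' @return A ggplot raster of the slice.
#' @export
plot_slice <- function(volume, z = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$data)
  z <- z %||% (d[3] %/% 2L + 1L)
  sl <- volume$data[, , z]
  df <- tibble(y = rep(seq_len(d[1]), d[2]),
               x = rep(seq_len(d[2]), each = d[1]),
               value = as.vector(sl))
  p <- ggplot(df, aes(.data$x, .data$y)) + labs(x = NULL, y = NULL)
  if (inherits(volume, "label_volume")) {
    ph <- names(phase_codes())[df$value + 1L]
    p + ggplot2::geom_raster(aes(fill = ph)) +
      ggplot2::scale_fill_manual(values = c(air = "grey70",
                                            ice_outside = "lightblue",
                                            ice_inside = "darkblue",
                                            starch = "tan4"), name = NULL)
  } else {
    p + ggplot2::geom_raster(aes(fill = .data$value)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white",
                                   name = "grey")
  }
}
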