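#' Plot a colony plate as a size heatmap
#'
#' @param plates Long plate tibble (one or more plates; faceted by
#'   condition and replicate).
#' @return A ggplot object.
#' @export
plot_plate <- function(plates) {
  ggplot2::ggplot(plates, ggplot2::aes(x = .data$col, y = .data$row,
                                       fill = .data$size)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "colony size (A.U.)") +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$replicate),
      cols = ggplot2::vars(.data$induced),
      labeller = ggplot2::labeller(
        induced = c(`FALSE` = "uninduced", `TRUE` = "induced"))) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot before/after strain fluorescence against the autofluorescence band
#'
#' Scatter of post- versus pre-induction geometric means on log scales,
#' the identity diagonal (where irresponsive strains fall), and the
#' autofluorescence band as dotted lines.
#'
#' @param calls Strain calls from [classify_strain()] /
#'   [adjust_strain_calls()].
#' @param band An [autofluorescence_band()].
#' @return A ggplot object.
#' @export
plot_responsiveness <- function(calls, band) {
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$geo_before,
                                      y = .data$geo_after,
                                      colour = .data$status)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_hline(yintercept = c(band$lower, band$upper),
                        linetype = "dotted") +
    ggplot2::geom_vline(xintercept = c(band$lower, band$upper),
                        linetype = "dotted") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "geometric mean intensity, before induction",
                  y = "geometric mean intensity, after induction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname fit_one_phase_decay
#' @param object A `decay_fit`.
#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, ...) {
  curve <- predict(object)
  lab <- if (object$non_degrading) "non-degrading" else
    sprintf("t50 = %.1f min [%.1f, %.1f]",
            object$t50, object$ci_low, object$ci_high)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time_min, y = .data$signal)) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(y = .data$.fitted), colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$replicate))) +
    ggplot2::labs(x = "time (min)", y = "fraction of initial signal",
                  colour = "replicate", subtitle = lab) +
    ggplot2::theme_minimal()
}

#' @rdname assemble_grid
#' @param object A `montage`.
#' @param ... Unused.
#' @method autoplot montage
#' @export
autoplot.montage <- function(object, ...) {
  df <- tibble(
    row = rep(seq_len(nrow(object$pixels)), times = ncol(object$pixels)),
    col = rep(seq_len(ncol(object$pixels)), each = nrow(object$pixels)),
    value = as.vector(object$pixels)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "intensity") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
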