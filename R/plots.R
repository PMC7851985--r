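#' Bode plot of an impedance spectrum
#'
#' Magnitude and phase against frequency on a logarithmic frequency axis.
#'
#' @param object A `vc_spectrum` from [impedance_spectrum()].
#' @param ... Unused.
#' @return A ggplot object (faceted magnitude / phase panels).
#' @method autoplot vc_spectrum
#' @export
autoplot.vc_spectrum <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(f_Hz = object$f_Hz, value = object$absZ,
                   panel = "|Z| (Ohm)"),
    tibble::tibble(f_Hz = object$f_Hz, value = object$phase_deg,
                   panel = "phase (deg)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f_Hz, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frequency (Hz)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a midplane slice
#'
#' @param object A `vc_slice` from [export_slice()].
#' @param log10_values Plot `log10` of the values (useful for `|J|`, `|S|`,
#'   `|z|`, which span many decades); default `TRUE` except for potential.
#' @param ... Unused.
#' @return A ggplot raster plot with the y and z axes in millimetres.
#' @method autoplot vc_slice
#' @export
autoplot.vc_slice <- function(object,
                              log10_values = object$quantity != "potential",
                              ...) {
  df <- expand.grid(y = object$y * 1e3, z = object$z * 1e3)
  df$value <- as.vector(object$values)
  lab <- paste0(if (log10_values) "log10 ", "|", object$quantity, "| (",
                object$units, ")")
  if (log10_values) df$value <- log10(pmax(df$value, 1e-300))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "z (mm)", y = "y (mm)",
                  title = sprintf("%s at %s Hz", object$quantity,
                                  format(object$frequency, digits = 3))) +
    ggplot2::theme_minimal()
}

#' Bar chart of per-region impedance contributions
#'
#' @param object A `vc_contributions` from [region_contributions()].
#' @param ... Unused.
#' @return A ggplot bar chart comparing the two contribution measures.
#' @method autoplot vc_contributions
#' @export
autoplot.vc_contributions <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(region = object$region, pct = object$z_density_pct,
                   measure = "volume impedance density"),
    tibble::tibble(region = object$region, pct = object$power_loss_pct,
                   measure = "power loss density"))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$region,
                                                      -.data$pct),
                                   y = .data$pct, fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "contribution to measured impedance (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Vein contribution across a configuration sweep
#'
#' @param sweep A `vc_sweep` from [run_configuration_sweep()].
#' @return A ggplot of the vein contribution against electrode count,
#'   faceted by excitation mode and colored by ground radius.
#' @export
plot_vein_contribution <- function(sweep) {
  stopifnot(inherits(sweep, "vc_sweep"))
  df <- tibble::as_tibble(sweep)
  df$r_g <- factor(df$r_ground * 1e3)
  df$r_t <- factor(df$r_terminal * 1e3)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_electrodes,
                                   y = .data$z_density_vein_pct,
                                   color = .data$r_g,
                                   shape = .data$r_t)) +
    ggplot2::geom_point(size = 2) + ggplot2::geom_line() +
    ggplot2::facet_wrap(~mode) +
    ggplot2::labs(x = "number of surface electrodes",
                  y = "vein contribution (%)",
                  color = "r_ground (mm)", shape = "r_terminal (mm)") +
    ggplot2::theme_minimal()
}
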