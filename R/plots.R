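# ggplot2 views of ensembles, sweeps and forecasts.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot observable densities of one or more ensembles
#'
#' Kernel-density overlays of an observable across ensembles (e.g. the
#' same observable at several substrate stiffness values).
#'
#' @param ensembles A named list of `homeostatic_ensemble` objects (or a
#'   single ensemble).
#' @param observable Column to plot.
#' @return A ggplot object.
#' @export
plot_observable_density <- function(ensembles, observable = "F_cyto") {
  if (inherits(ensembles, "homeostatic_ensemble")) {
    ensembles <- list(ensemble = ensembles)
  }
  df <- purrr::imap_dfr(ensembles, function(e, nm) {
    d <- marginal_density(e[[observable]])
    dplyr::mutate(d, condition = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$condition)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = observable, y = "probability density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.homeostatic_ensemble <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object[, c("A_hat", "aspect_ratio", "T_total", "N_b", "F_cyto")],
    dplyr::everything(), names_to = "observable", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey80", colour = "grey30") +
    ggplot2::facet_wrap(~observable, scales = "free") +
    ggplot2::labs(x = NULL, y = "probability density") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sweep_result <- function(object, ...) {
  df <- dplyr::filter(object$forecasts, is.finite(.data$condition))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$p,
                                   colour = .data$lineage)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = if (object$sweep == "stiffness") "substrate stiffness (kPa)"
          else "island area (um^2)",
      y = "differentiation fraction", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fate_forecast <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lineage, y = .data$p)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(0, .data$p - .data$se),
                                        ymax = pmin(1, .data$p + .data$se)),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "probability") +
    ggplot2::theme_minimal()
}

#' Heat map of a joint density
#'
#' @param jd A [joint_density()] object.
#' @param xlab,ylab Axis labels.
#' @return A ggplot object.
#' @export
plot_joint_density <- function(jd, xlab = "x", ylab = "y") {
  df <- expand.grid(x = jd$grid_x, y = jd$grid_y)
  df$z <- as.vector(jd$z)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "density") +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}
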