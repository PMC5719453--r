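#' Plot a simulated trajectory
#'
#' Two stacked panels in the style of the standard figures: biomasses
#' (prey, predator, and optionally the effective prey biomass) on top,
#' traits (defense, offense) below.
#'
#' @param traj A `"coevo_trajectory"`.
#' @param window Restrict the plot to the last `window` time units
#'   (`NULL` = post-transient window).
#' @param effective Add the effective prey biomass as a dashed line.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj, window = NULL, effective = TRUE) {
  win <- analysis_window(traj, last = window)
  if (effective && !"x_eff" %in% names(win)) {
    win <- add_effective_biomass(win)
  }
  long <- tidyr::pivot_longer(tibble::as_tibble(win), -"t",
                              names_to = "series", values_to = "value")
  long$panel <- ifelse(long$series %in% c("u", "v"), "traits", "biomass")
  lvl <- c(x = "prey", y = "predator", x_eff = "effective prey",
           u = "defense", v = "offense")
  long$series <- factor(lvl[long$series], levels = unname(lvl))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$series,
                                     linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::scale_linetype_manual(values = c("solid", "solid", "dashed",
                                              "dashed", "dashed"),
                                   drop = TRUE) +
    ggplot2::labs(x = "time", y = NULL, colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_trajectory
#' @param object,... `autoplot` method arguments.
#' @export
autoplot.coevo_trajectory <- function(object, ...) {
  plot_trajectory(object, ...)
}

#' Plot Geber component series
#'
#' One panel per trophic level showing the four component effects, by
#' default standardized by their absolute maxima so everything lives in
#' \[-1, 1\].
#'
#' @param components A `"coevo_components"` tibble.
#' @param standardize Standardize each component by its absolute maximum.
#' @return A ggplot object.
#' @export
plot_components <- function(components, standardize = TRUE) {
  dat <- if (standardize) standardize_components(components) else components
  long <- tidyr::pivot_longer(tibble::as_tibble(dat),
                              dplyr::all_of(component_names()),
                              names_to = "component", values_to = "value")
  long$panel <- ifelse(grepl("_x$", long$component),
                       "effects on prey fitness",
                       "effects on predator fitness")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1) +
    ggplot2::labs(x = "time", y = if (standardize) "standardized effect" else
      "effect (1/time^2)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_components
#' @param object,... `autoplot` method arguments.
#' @export
autoplot.coevo_components <- function(object, ...) {
  plot_components(object, ...)
}

#' Heatmap of a sweep set
#'
#' Tile map of the focal-parameter grid, coloured by the predator-prey
#' phase lag (non-cycling outcomes shown as labelled grey/white tiles) or
#' by any other cell column.
#'
#' @param sweep A `"coevo_sweep"` tibble.
#' @param fill Name of the column to map to fill (default `"phi_xy"`).
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, fill = "phi_xy") {
  axes <- names(sweep)[1:2]
  dat <- tibble::as_tibble(sweep)
  dat$fill_val <- dat[[fill]]
  gg <- ggplot2::ggplot(dat, ggplot2::aes(x = .data[[axes[1]]],
                                          y = .data[[axes[2]]])) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$fill_val)) +
    ggplot2::labs(fill = fill) +
    ggplot2::theme_minimal()
  if (attr(sweep, "family") == "speed") {
    gg <- gg + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  }
  gg
}

#' @rdname plot_sweep
#' @param object,... `autoplot` method arguments.
#' @export
autoplot.coevo_sweep <- function(object, ...) {
  plot_sweep(object, ...)
}
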