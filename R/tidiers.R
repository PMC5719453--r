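#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a sweep set
#'
#' One row per (cell, component pair): the focal-axis values, outcome,
#' phase lag and label, the pair name and its `r_c`.
#'
#' @param x A `"coevo_sweep"`.
#' @param ... Unused.
#' @return A long tibble.
#' @export
tidy.coevo_sweep <- function(x, ...) {
  axes <- names(x)[1:2]
  dat <- tibble::as_tibble(x)
  long <- tidyr::pivot_longer(dat, dplyr::all_of(rc_col_names()),
                              names_to = "pair", values_to = "r_c")
  map <- stats::setNames(correlation_pairs()$pair, rc_col_names())
  long$pair <- unname(map[long$pair])
  dplyr::select(long, dplyr::all_of(axes), "outcome", "phi_xy", "label",
                "pair", "r_c")
}

#' Glance at a sweep set
#'
#' One-row summary: family, grid size, counts of each outcome and cycle
#' type, and whether the set qualifies for the final association analysis
#' (contains both antiphase and quarter-lag cells).
#'
#' @param x A `"coevo_sweep"`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.coevo_sweep <- function(x, ...) {
  tibble::tibble(
    family = attr(x, "family"),
    n_cells = nrow(x),
    n_cycles = sum(x$outcome == "cycles"),
    n_equilibrium = sum(x$outcome == "equilibrium"),
    n_extinct = sum(x$outcome == "predator_extinct"),
    n_error = sum(x$outcome == "error"),
    n_antiphase = sum(x$label == "antiphase"),
    n_quarter_lag = sum(x$label == "quarter_lag"),
    included = any(x$label == "antiphase") && any(x$label == "quarter_lag")
  )
}

#' Tidy / glance a trajectory
#'
#' `tidy()` returns the state in long form (one row per sample and
#' variable); `glance()` returns the [classify_outcome()] one-row summary.
#'
#' @param x A `"coevo_trajectory"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.coevo_trajectory <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"t",
                      names_to = "variable", values_to = "value")
}

#' @rdname tidy.coevo_trajectory
#' @export
glance.coevo_trajectory <- function(x, ...) {
  classify_outcome(x)
}
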