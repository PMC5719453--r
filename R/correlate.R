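#' Component correlations within one simulation
#'
#' Spearman rank correlations between pairs of Geber component series over
#' the final stretch of the horizon (by default the last 5,000 time
#' units). Of the twelve possible pairs, four are excluded: `Ex_x`-`Ey_x`
#' and `Ex_y`-`Ey_y` merely mirror the predator-prey phase relationship,
#' and the two pairs involving `Ey_y` are meaningless because `Ey_y` is
#' identically zero. That leaves eight correlations per simulation: five
#' on the prey side and three on the predator side.
#'
#' @param components A `"coevo_components"` tibble covering the window.
#' @param window Length of the correlation window in model time units; use
#'   `NULL` to correlate over the whole series supplied.
#' @return A tibble of class `"coevo_correlations"` with columns `comp1`,
#'   `comp2`, `pair` and `r_c`. A component with zero variance over the
#'   window yields `NA` (undefined), never zero.
#' @examples
#' \donttest{
#' std <- standard_params("speed")
#' traj <- simulate_coevolution(std$model, std$adaptation,
#'                              sim_control(t_total = 4000, t_transient = 2000))
#' component_correlations(geber_components(traj), window = 2000)
#' }
#' @export
component_correlations <- function(components, window = 5000) {
  dat <- if (is.null(window)) {
    components
  } else {
    components[components$t >= max(components$t) - window, , drop = FALSE]
  }
  pairs <- correlation_pairs()
  r_c <- purrr::map2_dbl(pairs$comp1, pairs$comp2, function(a, b) {
    xa <- dat[[a]]
    xb <- dat[[b]]
    if (stats::sd(xa) == 0 || stats::sd(xb) == 0) return(NA_real_)
    stats::cor(xa, xb, method = "spearman")
  })
  out <- tibble::tibble(comp1 = pairs$comp1, comp2 = pairs$comp2,
                        pair = pairs$pair, r_c = r_c)
  class(out) <- c("coevo_correlations", class(out))
  out
}

# The eight admissible component pairs (5 prey-side, 3 predator-side).
correlation_pairs <- function() {
  comp1 <- c("Ex_x", "Ex_x", "Ey_x", "Ey_x", "Eu_x", "Ex_y", "Ex_y", "Eu_y")
  comp2 <- c("Eu_x", "Ev_x", "Eu_x", "Ev_x", "Ev_x", "Eu_y", "Ev_y", "Ev_y")
  tibble::tibble(comp1 = comp1, comp2 = comp2,
                 pair = paste(comp1, comp2, sep = "-"))
}
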