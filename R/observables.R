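#' Effective prey biomass
#'
#' Prey biomass as perceived by the predator: actual biomass weighted by
#' the attack rate relative to its maximum and by the conversion efficiency
#' relative to its maximum, `x_eff = x * a(u,v)/a0 * g(v)/g0`. It can never
#' exceed the actual biomass and collapses onto it when the prey is
#' undefended and offense is free.
#'
#' @inheritParams prey_fitness
#' @return Numeric vector of effective biomasses.
#' @examples
#' effective_prey_biomass(data.frame(x = 1, y = 0, u = 0.3, v = 0.3),
#'                        model_params())
#' @export
effective_prey_biomass <- function(state, params) {
  s <- as_state(state)
  s$x * (attack_rate(s$u, s$v, params) / params$a0) *
    (conversion_efficiency(s$v, params) / params$g0)
}

#' Append the effective prey biomass to a trajectory
#'
#' @param traj A `"coevo_trajectory"`.
#' @param params Model parameters; default taken from the trajectory.
#' @return `traj` with an extra `x_eff` column.
#' @export
add_effective_biomass <- function(traj, params = traj_params(traj)) {
  out <- dplyr::mutate(traj, x_eff = effective_prey_biomass(traj, params))
  for (at in c("params", "adaptation", "control")) {
    attr(out, at) <- attr(traj, at)
  }
  class(out) <- class(traj)
  out
}

#' Geber decomposition of fitness change along a trajectory
#'
#' The time derivative of each Malthusian fitness is, by the multivariate
#' chain rule, the sum of four component effects: the partial derivative of
#' fitness with respect to a state variable times that variable's rate of
#' change. Both factors are evaluated analytically at each sample, so the
#' decomposition is exact up to solver error: `Ex_x + Ey_x + Eu_x + Ev_x =
#' dWx/dt` and likewise for the predator. `Ey_y` is identically zero
#' because predator fitness does not depend on predator biomass, and
#' `Eu_x`, `Ev_y` are nonnegative because each trait climbs its own
#' fitness gradient.
#'
#' @param traj A `"coevo_trajectory"`.
#' @param params,adaptation Parameter objects; defaults taken from `traj`.
#' @return A tibble of class `"coevo_components"` with columns `t`, the
#'   eight components `Ex_x`, `Ey_x`, `Eu_x`, `Ev_x`, `Ex_y`, `Ey_y`,
#'   `Eu_y`, `Ev_y` (units 1/time^2), and the fitness series `Wx`, `Wy`.
#' @examples
#' \donttest{
#' std <- standard_params("speed")
#' traj <- simulate_coevolution(std$model, std$adaptation,
#'                              sim_control(t_total = 2000, t_transient = 1000))
#' comp <- geber_components(traj)
#' }
#' @export
geber_components <- function(traj, params = traj_params(traj),
                             adaptation = traj_adaptation(traj)) {
  part <- fitness_partials(traj, params)
  der <- system_derivatives(traj, params, adaptation)
  out <- tibble::tibble(
    t = traj$t,
    Ex_x = part$dWx_dx * der$dx,
    Ey_x = part$dWx_dy * der$dy,
    Eu_x = part$dWx_du * der$du,
    Ev_x = part$dWx_dv * der$dv,
    Ex_y = part$dWy_dx * der$dx,
    Ey_y = part$dWy_dy * der$dy,
    Eu_y = part$dWy_du * der$du,
    Ev_y = part$dWy_dv * der$dv,
    Wx = prey_fitness(traj, params),
    Wy = predator_fitness(traj, params)
  )
  attr(out, "params") <- params
  attr(out, "adaptation") <- adaptation
  attr(out, "control") <- attr(traj, "control")
  class(out) <- c("coevo_components", class(out))
  out
}

component_names <- function() {
  c("Ex_x", "Ey_x", "Eu_x", "Ev_x", "Ex_y", "Ey_y", "Eu_y", "Ev_y")
}

#' Standardize component series by their absolute maxima
#'
#' Divides every component by its own maximum absolute value over the
#' series so all components range within [-1, 1] and can share one plot
#' panel. All-zero components (such as `Ey_y`) are left at zero.
#'
#' @param components A `"coevo_components"` tibble.
#' @return The standardized tibble (fitness columns untouched).
#' @export
standardize_components <- function(components) {
  out <- components
  for (col in component_names()) {
    m <- max(abs(out[[col]]))
    if (m > 0) out[[col]] <- out[[col]] / m
  }
  out
}
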