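#' Attack rate as a function of defense and offense
#'
#' The capture rate of the predator depends on the two traits only through
#' their difference (a unidirectional trait axis): it is a downward logistic
#' in `u - v`, saturating at `a0` when offense greatly exceeds defense and
#' approaching zero in the opposite limit. The exponent `theta * (u - v)` is
#' clamped to +/- 700 so the result saturates instead of overflowing.
#'
#' @param u,v Defense and offense trait values (vectorized).
#' @param params A [model_params()] object.
#' @return Attack rate(s), strictly within `(0, a0)` up to floating point.
#' @examples
#' attack_rate(0.2, 0.2, model_params())  # equal traits: a0 / 2
#' @export
attack_rate <- function(u, v, params) {
  z <- pmin(pmax(params$theta * (u - v), -700), 700)
  params$a0 / (1 + exp(z))
}

# d attack_rate / d u; the v-derivative is its negative.
attack_rate_du <- function(u, v, params) {
  a <- attack_rate(u, v, params)
  -params$theta * a * (1 - a / params$a0)
}

#' Prey growth rate under the defense trade-off
#'
#' @inheritParams attack_rate
#' @return Realized intrinsic growth rate `r(u)`, at most `r0`.
#' @export
prey_growth_rate <- function(u, params) {
  if (!is.null(params$prey_tradeoff)) return(params$prey_tradeoff$value(u))
  params$r0 * exp(-params$cx * u^2)
}

prey_growth_rate_du <- function(u, params) {
  if (!is.null(params$prey_tradeoff)) return(params$prey_tradeoff$derivative(u))
  -2 * params$cx * u * params$r0 * exp(-params$cx * u^2)
}

#' Predator conversion efficiency under the offense trade-off
#'
#' @inheritParams attack_rate
#' @return Realized conversion efficiency `g(v)`, at most `g0`.
#' @export
conversion_efficiency <- function(v, params) {
  if (!is.null(params$predator_tradeoff)) return(params$predator_tradeoff$value(v))
  params$g0 * exp(-params$cy * v^2)
}

conversion_efficiency_dv <- function(v, params) {
  if (!is.null(params$predator_tradeoff)) return(params$predator_tradeoff$derivative(v))
  -2 * params$cy * v * params$g0 * exp(-params$cy * v^2)
}

# Coerce a state argument (data frame, tibble or named list of vectors with
# x, y, u, v) into a plain list of equal-length numeric vectors.
as_state <- function(state) {
  need <- c("x", "y", "u", "v")
  if (!all(need %in% names(state))) {
    stop("`state` must supply columns x, y, u and v", call. = FALSE)
  }
  lapply(stats::setNames(need, need), function(nm) as.numeric(state[[nm]]))
}

#' Malthusian fitness of prey and predator
#'
#' Per-capita net growth rates: prey fitness is logistic growth under the
#' defense trade-off minus Holling type II predation losses; predator
#' fitness is conversion of captured prey minus mortality and does not
#' depend on predator biomass.
#'
#' @param state A data frame (or named list) with columns `x`, `y`, `u`,
#'   `v`; vectorized over rows.
#' @param params A [model_params()] object.
#' @return Numeric vector of fitness values (1/time).
#' @examples
#' prey_fitness(data.frame(x = 0.5, y = 0.3, u = 0.2, v = 0.2), model_params())
#' @export
prey_fitness <- function(state, params) {
  s <- as_state(state)
  a <- attack_rate(s$u, s$v, params)
  prey_growth_rate(s$u, params) * (1 - s$x / params$K) -
    a * s$y / (1 + a * params$h * s$x)
}

#' @rdname prey_fitness
#' @export
predator_fitness <- function(state, params) {
  s <- as_state(state)
  a <- attack_rate(s$u, s$v, params)
  conversion_efficiency(s$v, params) * a * s$x / (1 + a * params$h * s$x) -
    params$d
}

#' Analytic partial derivatives of fitness
#'
#' All first-order partial derivatives of the two fitness functions with
#' respect to the four state variables, in closed form. These are the
#' sensitivities the Geber decomposition multiplies with the time
#' derivatives of the state, and `dWx_du`, `dWy_dv` are the selection
#' gradients that drive trait evolution.
#'
#' @inheritParams prey_fitness
#' @return A tibble with one row per state row and columns `dWx_dx`,
#'   `dWx_dy`, `dWx_du`, `dWx_dv`, `dWy_dx`, `dWy_dy`, `dWy_du`, `dWy_dv`
#'   (`dWy_dy` is identically zero).
#' @export
fitness_partials <- function(state, params) {
  s <- as_state(state)
  a <- attack_rate(s$u, s$v, params)
  a_u <- attack_rate_du(s$u, s$v, params)
  r <- prey_growth_rate(s$u, params)
  g <- conversion_efficiency(s$v, params)
  den <- 1 + a * params$h * s$x
  den2 <- den^2
  tibble::tibble(
    dWx_dx = -r / params$K + a^2 * params$h * s$y / den2,
    dWx_dy = -a / den,
    dWx_du = prey_growth_rate_du(s$u, params) * (1 - s$x / params$K) -
      s$y * a_u / den2,
    dWx_dv = -s$y * (-a_u) / den2,
    dWy_dx = g * a / den2,
    dWy_dy = rep(0, length(s$x)),
    dWy_du = g * s$x * a_u / den2,
    dWy_dv = conversion_efficiency_dv(s$v, params) * a * s$x / den +
      g * s$x * (-a_u) / den2
  )
}

#' Selection gradients of the two traits
#'
#' @inheritParams prey_fitness
#' @return A tibble with columns `dWx_du` (selection on defense) and
#'   `dWy_dv` (selection on offense).
#' @export
fitness_gradients <- function(state, params) {
  fitness_partials(state, params)[, c("dWx_du", "dWy_dv")]
}

#' Time derivatives of the coupled eco-evolutionary system
#'
#' Biomasses change at fitness times biomass; each trait follows its own
#' selection gradient at speed `Gx`/`Gy`, damped by the boundary factor
#' `exp(-eps/trait)` near zero.
#'
#' @inheritParams prey_fitness
#' @param adaptation An [adaptation_params()] object.
#' @return A tibble with columns `dx`, `dy`, `du`, `dv`.
#' @export
system_derivatives <- function(state, params, adaptation) {
  s <- as_state(state)
  if (any(s$u <= 0) || any(s$v <= 0)) {
    stop("trait values must be strictly positive", call. = FALSE)
  }
  grad <- fitness_partials(state, params)
  Wx <- prey_fitness(state, params)
  Wy <- predator_fitness(state, params)
  tibble::tibble(
    dx = Wx * s$x,
    dy = Wy * s$y,
    du = adaptation$Gx * grad$dWx_du * exp(-adaptation$eps / s$u),
    dv = adaptation$Gy * grad$dWy_dv * exp(-adaptation$eps / s$v)
  )
}

# Plain-R right-hand side in deSolve form; used when a custom trade-off
# replaces the defaults (the compiled RHS hard-codes the Gaussian forms).
rhs_r <- function(t, y, parms) {
  state <- list(x = max(y[[1]], 0), y = max(y[[2]], 0),
                u = max(y[[3]], 1e-300), v = max(y[[4]], 1e-300))
  d <- system_derivatives(state, parms$params, parms$adaptation)
  list(c(d$dx, d$dy, d$du, d$dv))
}
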