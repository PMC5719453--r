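#' Simulate the coevolutionary predator-prey system
#'
#' Integrates the four coupled ODEs (prey biomass, predator biomass,
#' defense, offense) with an adaptive stiff-capable solver and returns the
#' trajectory sampled on a uniform grid. With the default Gaussian
#' trade-offs the right-hand side runs as compiled C; custom trade-offs
#' fall back to the plain-R right-hand side.
#'
#' @param params A [model_params()] object.
#' @param adaptation An [adaptation_params()] object.
#' @param control A [sim_control()] object (time horizon, sampling,
#'   tolerances, initial state).
#'
#' @return A tibble of class `"coevo_trajectory"` with columns `t`, `x`,
#'   `y`, `u`, `v`, carrying the parameter objects as attributes
#'   `params`, `adaptation` and `control`.
#' @examples
#' \donttest{
#' std <- standard_params("speed")
#' traj <- simulate_coevolution(std$model, std$adaptation,
#'                              sim_control(t_total = 2000, t_transient = 1000))
#' }
#' @export
simulate_coevolution <- function(params = model_params(),
                                 adaptation = adaptation_params(),
                                 control = sim_control()) {
  stopifnot(inherits(params, "coevo_params"),
            inherits(adaptation, "coevo_adaptation"),
            inherits(control, "coevo_control"))
  times <- seq(0, control$t_total, by = control$dt_sample)
  y0 <- control$init

  if (uses_default_tradeoffs(params)) {
    sol <- deSolve::lsoda(
      y = y0, times = times, func = "coevo_derivs",
      parms = param_vector(params, adaptation),
      dllname = "coevocycles", initfunc = "coevo_init",
      rtol = control$rtol, atol = control$atol, maxsteps = 50000
    )
  } else {
    sol <- deSolve::lsoda(
      y = y0, times = times, func = rhs_r,
      parms = list(params = params, adaptation = adaptation),
      rtol = control$rtol, atol = control$atol, maxsteps = 50000
    )
  }

  sol <- as.data.frame(sol)
  names(sol) <- c("t", "x", "y", "u", "v")
  if (nrow(sol) < length(times) || anyNA(sol)) {
    stop("integration failed (step-size collapse or NaN state) for ",
         "parameters: ",
         paste(names(param_vector(params, adaptation)),
               signif(param_vector(params, adaptation), 4),
               sep = "=", collapse = ", "),
         call. = FALSE)
  }

  # biomass marginally below zero is solver noise; clip within atol, else fail
  for (col in c("x", "y")) {
    neg <- sol[[col]] < 0
    if (any(neg)) {
      if (min(sol[[col]]) < -10 * control$atol) {
        stop("negative ", col, " beyond solver tolerance", call. = FALSE)
      }
      sol[[col]][neg] <- 0
    }
  }
  if (any(sol$u <= 0) || any(sol$v <= 0)) {
    stop("sampled trait values are not strictly positive", call. = FALSE)
  }

  traj <- tibble::as_tibble(sol)
  attr(traj, "params") <- params
  attr(traj, "adaptation") <- adaptation
  attr(traj, "control") <- control
  class(traj) <- c("coevo_trajectory", class(traj))
  traj
}

traj_params <- function(traj) {
  p <- attr(traj, "params")
  if (is.null(p)) stop("trajectory carries no `params` attribute", call. = FALSE)
  p
}

traj_adaptation <- function(traj) {
  a <- attr(traj, "adaptation")
  if (is.null(a)) stop("trajectory carries no `adaptation` attribute", call. = FALSE)
  a
}

traj_control <- function(traj) {
  cc <- attr(traj, "control")
  if (is.null(cc)) stop("trajectory carries no `control` attribute", call. = FALSE)
  cc
}

#' Restrict a trajectory to its analysis window
#'
#' Drops the transient (`t < t_transient`) or, with `last`, keeps only the
#' final stretch of the horizon.
#'
#' @param traj A `"coevo_trajectory"` (or any tibble with a `t` column).
#' @param last If given, keep samples with `t >= t_total - last` instead of
#'   the post-transient window.
#' @return The filtered tibble; attributes are preserved.
#' @export
analysis_window <- function(traj, last = NULL) {
  t_end <- max(traj$t)
  from <- if (is.null(last)) {
    cc <- attr(traj, "control")
    if (is.null(cc)) stop("need `last` when trajectory has no control attribute",
                          call. = FALSE)
    cc$t_transient
  } else {
    t_end - last
  }
  keep <- traj$t >= from
  out <- traj[keep, , drop = FALSE]
  for (at in c("params", "adaptation", "control")) {
    attr(out, at) <- attr(traj, at)
  }
  class(out) <- class(traj)
  out
}

#' Classify the asymptotic outcome of a simulation
#'
#' Partitions runs into predator extinction (minimum predator biomass over
#' the analysis window below the extinction threshold), stable equilibrium
#' (coefficients of variation of both biomasses over the final window below
#' the equilibrium threshold) and sustained cycles (everything else).
#'
#' @param traj A `"coevo_trajectory"`.
#' @param control A [sim_control()]; defaults to the one stored on `traj`.
#' @return A one-row tibble of class `"coevo_outcome"`: `outcome` plus the
#'   mean and amplitude (max - min) of each state variable over the
#'   analysis window.
#' @export
classify_outcome <- function(traj, control = traj_control(traj)) {
  win <- traj[traj$t >= control$t_transient, , drop = FALSE]
  if (nrow(win) == 0) stop("trajectory does not cover the analysis window",
                           call. = FALSE)
  tail_win <- traj[traj$t >= max(traj$t) - control$equilibrium_window, ,
                   drop = FALSE]
  cv <- function(z) {
    m <- mean(z)
    if (m == 0) return(0)
    stats::sd(z) / abs(m)
  }
  label <- if (min(win$y) < control$extinction_threshold) {
    "predator_extinct"
  } else if (cv(tail_win$x) < control$equilibrium_cv_threshold &&
             cv(tail_win$y) < control$equilibrium_cv_threshold) {
    "equilibrium"
  } else {
    "cycles"
  }
  summ <- lapply(c(x = "x", y = "y", u = "u", v = "v"), function(col) {
    c(mean = mean(win[[col]]), amp = max(win[[col]]) - min(win[[col]]))
  })
  out <- tibble::tibble(
    outcome = label,
    mean_x = summ$x[["mean"]], amp_x = summ$x[["amp"]],
    mean_y = summ$y[["mean"]], amp_y = summ$y[["amp"]],
    mean_u = summ$u[["mean"]], amp_u = summ$u[["amp"]],
    mean_v = summ$v[["mean"]], amp_v = summ$v[["amp"]]
  )
  class(out) <- c("coevo_outcome", class(out))
  out
}

#' Closed-form interior equilibrium of the non-evolutionary limit
#'
#' With both adaptation speeds at zero and traits pinned at zero the model
#' collapses to the classical Holling type II predator-prey system, whose
#' interior equilibrium is `x* = d / (a (g0 - d h))` and
#' `y* = r(0) (1 - x*/K) (1 + a h x*) / a` with `a = a0/2` at `u = v = 0`.
#'
#' @param params A [model_params()] object.
#' @param u,v Trait values at which the ecology is frozen (default 0).
#' @return A named numeric vector `c(x = , y = )`.
#' @export
holling_equilibrium <- function(params, u = 0, v = 0) {
  a <- attack_rate(u, v, params)
  g <- conversion_efficiency(v, params)
  denom <- a * (g - params$d * params$h)
  if (denom <= 0) stop("no interior equilibrium: g(v) <= d*h", call. = FALSE)
  xs <- params$d / denom
  ys <- prey_growth_rate(u, params) * (1 - xs / params$K) *
    (1 + a * params$h * xs) / a
  c(x = xs, y = ys)
}
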