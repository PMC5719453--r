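#' Ecological and trade-off parameters
#'
#' Constructs the parameter set of the coevolutionary predator-prey model:
#' logistic prey growth, a Holling type II functional response whose attack
#' rate depends on the difference between predator offense and prey defense,
#' and Gaussian trade-offs tying defense to the prey growth rate and offense
#' to the predator conversion efficiency. Defaults are the standard values of
#' the adaptation-speed analysis.
#'
#' @param r0 Maximum prey growth rate (1/time), attained at zero defense.
#' @param K Prey carrying capacity (biomass).
#' @param a0 Maximum attack rate (1/(biomass x time)), attained when offense
#'   greatly exceeds defense.
#' @param h Handling time (time).
#' @param theta Steepness of the attack-rate response to the trait
#'   difference `u - v` (dimensionless).
#' @param g0 Maximum conversion efficiency (dimensionless), attained at zero
#'   offense.
#' @param d Predator per-capita mortality (1/time).
#' @param cx Costliness of defense (dimensionless, >= 0).
#' @param cy Costliness of offense (dimensionless, >= 0).
#' @param prey_tradeoff,predator_tradeoff Optional [tradeoff()] objects
#'   replacing the default Gaussian trade-offs `r0 * exp(-cx u^2)` and
#'   `g0 * exp(-cy v^2)`. When supplied, simulation falls back to the
#'   plain-R right-hand side instead of the compiled one.
#'
#' @return A list of class `"coevo_params"`.
#' @seealso [adaptation_params()], [sim_control()], [standard_params()]
#' @examples
#' p <- model_params()
#' attack_rate(u = 0.2, v = 0.2, params = p)
#' @export
model_params <- function(r0 = 1, K = 1, a0 = 1, h = 0.1, theta = 10,
                         g0 = 1, d = 0.1, cx = 3, cy = 2,
                         prey_tradeoff = NULL, predator_tradeoff = NULL) {
  p <- list(r0 = r0, K = K, a0 = a0, h = h, theta = theta,
            g0 = g0, d = d, cx = cx, cy = cy)
  for (nm in names(p)) {
    val <- p[[nm]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  if (p$cx < 0) stop("`cx` must be >= 0", call. = FALSE)
  if (p$cy < 0) stop("`cy` must be >= 0", call. = FALSE)
  if (p$h < 0) stop("`h` must be >= 0", call. = FALSE)
  strict <- c("r0", "K", "a0", "theta", "g0", "d")
  for (nm in strict) {
    if (p[[nm]] <= 0) stop("`", nm, "` must be > 0", call. = FALSE)
  }
  if (!is.null(prey_tradeoff)) stopifnot(inherits(prey_tradeoff, "coevo_tradeoff"))
  if (!is.null(predator_tradeoff)) stopifnot(inherits(predator_tradeoff, "coevo_tradeoff"))
  p$prey_tradeoff <- prey_tradeoff
  p$predator_tradeoff <- predator_tradeoff
  structure(p, class = "coevo_params")
}

#' Adaptation (evolutionary speed) parameters
#'
#' The traits evolve along their fitness gradients at speeds set by the
#' additive genetic variances `Gx` (prey defense) and `Gy` (predator
#' offense); a value of 1 means evolution as fast as the ecology. The
#' boundary factor `exp(-eps/trait)` smoothly halts trait change as a trait
#' approaches zero, keeping both traits positive.
#'
#' @param Gx Additive genetic variance of prey defense (>= 0).
#' @param Gy Additive genetic variance of predator offense (>= 0).
#' @param eps Boundary constant of the trait positivity guard (> 0).
#'
#' @return A list of class `"coevo_adaptation"`.
#' @examples
#' adaptation_params(Gx = 1e-1, Gy = 10^-0.9)
#' @export
adaptation_params <- function(Gx = 1e-2, Gy = 1e-2, eps = 1e-3) {
  stopifnot(is.numeric(Gx), length(Gx) == 1L, is.finite(Gx),
            is.numeric(Gy), length(Gy) == 1L, is.finite(Gy),
            is.numeric(eps), length(eps) == 1L, is.finite(eps))
  if (Gx < 0) stop("`Gx` must be >= 0", call. = FALSE)
  if (Gy < 0) stop("`Gy` must be >= 0", call. = FALSE)
  if (eps <= 0) stop("`eps` must be > 0", call. = FALSE)
  structure(list(Gx = Gx, Gy = Gy, eps = eps), class = "coevo_adaptation")
}

#' Simulation control settings
#'
#' @param t_total Simulation length in model time units.
#' @param t_transient Initial span discarded before any analysis; the long
#'   default makes results a property of the attractor, not the start.
#' @param dt_sample Output sampling interval (model time units).
#' @param init Named numeric initial state `c(x=, y=, u=, v=)`; traits must
#'   be strictly positive.
#' @param rtol,atol Relative and absolute tolerances of the adaptive
#'   integrator.
#' @param extinction_threshold Predator biomass below which the predator is
#'   declared extinct over the analysis window.
#' @param equilibrium_cv_threshold Coefficient of variation of `x` and `y`
#'   (over the last `equilibrium_window` time units) below which the run is
#'   classified as a stable equilibrium.
#' @param equilibrium_window Length of the window used for the equilibrium
#'   check, in model time units.
#'
#' @return A list of class `"coevo_control"`.
#' @export
sim_control <- function(t_total = 50000, t_transient = 30000, dt_sample = 1,
                        init = c(x = 0.5, y = 0.3, u = 0.1, v = 0.1),
                        rtol = 1e-8, atol = 1e-10,
                        extinction_threshold = 1e-9,
                        equilibrium_cv_threshold = 1e-4,
                        equilibrium_window = 5000) {
  if (!(t_transient > 0 && t_transient < t_total)) {
    stop("need 0 < t_transient < t_total", call. = FALSE)
  }
  if (dt_sample <= 0) stop("`dt_sample` must be > 0", call. = FALSE)
  init <- init[c("x", "y", "u", "v")]
  if (anyNA(init)) stop("`init` must name x, y, u and v", call. = FALSE)
  if (init[["x"]] < 0 || init[["y"]] < 0) {
    stop("initial biomasses must be >= 0", call. = FALSE)
  }
  if (init[["u"]] <= 0 || init[["v"]] <= 0) {
    stop("initial traits must be > 0", call. = FALSE)
  }
  structure(list(t_total = t_total, t_transient = t_transient,
                 dt_sample = dt_sample, init = init, rtol = rtol, atol = atol,
                 extinction_threshold = extinction_threshold,
                 equilibrium_cv_threshold = equilibrium_cv_threshold,
                 equilibrium_window = equilibrium_window),
            class = "coevo_control")
}

#' Standard parameter sets of the speed and cost analyses
#'
#' Convenience bundles of [model_params()] and [adaptation_params()] at the
#' standard values of the two analysis families: the adaptation-speed
#' analysis (short handling time `h = 0.1`, defense slightly costlier than
#' offense) and the trait-cost analysis (long handling time `h = 1`, both
#' adaptation speeds at `1e-2`, the two costs being the swept axes).
#'
#' @param analysis `"speed"` or `"cost"`.
#' @param ... Overrides for individual fields of either parameter set, e.g.
#'   `Gx = 1e-1` or `cx = 5`.
#'
#' @return A list with elements `model` and `adaptation`.
#' @examples
#' standard_params("speed", Gx = 1e-1, Gy = 10^-0.9)
#' @export
standard_params <- function(analysis = c("speed", "cost"), ...) {
  analysis <- match.arg(analysis)
  model_args <- switch(analysis,
    speed = list(h = 0.1, cx = 3, cy = 2),
    cost  = list(h = 1, cx = 3, cy = 2)
  )
  adapt_args <- list(Gx = 1e-2, Gy = 1e-2)
  dots <- list(...)
  unknown <- setdiff(names(dots),
                     c(names(formals(model_params)), names(formals(adaptation_params))))
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(dots)) {
    if (nm %in% names(formals(adaptation_params))) {
      adapt_args[[nm]] <- dots[[nm]]
    } else {
      model_args[[nm]] <- dots[[nm]]
    }
  }
  list(model = do.call(model_params, model_args),
       adaptation = do.call(adaptation_params, adapt_args))
}

#' Pluggable trait trade-off
#'
#' A trade-off maps a trait value to a rate (prey growth or predator
#' conversion efficiency) and must supply its analytic derivative, which the
#' fitness gradients require. The model defaults to Gaussian trade-offs; a
#' custom trade-off replaces them through the `prey_tradeoff` /
#' `predator_tradeoff` arguments of [model_params()].
#'
#' @param value Function of the trait returning the rate.
#' @param derivative Function of the trait returning d(rate)/d(trait).
#'
#' @return An object of class `"coevo_tradeoff"`.
#' @examples
#' lin <- tradeoff(function(q) pmax(1 - 0.5 * q, 0),
#'                 function(q) ifelse(q < 2, -0.5, 0))
#' lin$value(0.4)
#' @export
tradeoff <- function(value, derivative) {
  stopifnot(is.function(value), is.function(derivative))
  structure(list(value = value, derivative = derivative),
            class = "coevo_tradeoff")
}

#' @export
print.coevo_params <- function(x, ...) {
  cat("<coevo_params>\n")
  num <- unlist(x[c("r0", "K", "a0", "h", "theta", "g0", "d", "cx", "cy")])
  print(num)
  if (!is.null(x$prey_tradeoff) || !is.null(x$predator_tradeoff)) {
    cat("custom trade-off(s) attached\n")
  }
  invisible(x)
}

#' @export
print.coevo_adaptation <- function(x, ...) {
  cat("<coevo_adaptation>\n")
  print(unlist(x))
  invisible(x)
}

# Parameter vector in the order the compiled right-hand side expects.
param_vector <- function(params, adaptation) {
  c(r0 = params$r0, K = params$K, a0 = params$a0, h = params$h,
    theta = params$theta, g0 = params$g0, d = params$d,
    cx = params$cx, cy = params$cy,
    Gx = adaptation$Gx, Gy = adaptation$Gy, eps = adaptation$eps)
}

uses_default_tradeoffs <- function(params) {
  is.null(params$prey_tradeoff) && is.null(params$predator_tradeoff)
}
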