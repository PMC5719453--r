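#' Fourier phase lag between two oscillatory series
#'
#' Estimates how far the follower series lags behind the reference at the
#' reference's dominant frequency. Both series are mean-removed; the
#' dominant frequency is the nonzero bin maximizing the reference's power
#' spectrum, and the lag is the cross-spectrum phase at that bin,
#' normalized to cycle fractions and mapped into [-1, 0]. A follower
#' peaking a quarter period after the reference gives `phi = -0.25`, half
#' a period gives `-0.5`, and a follower identical to the reference gives 0.
#'
#' Flat or non-oscillatory input has no dominant peak above the noise
#' floor and raises a classed error (`"coevo_phase_undefined"`).
#'
#' @param reference,follower Equal-length, uniformly sampled numeric series
#'   covering at least a handful of dominant periods.
#' @param dt_sample Sampling interval (model time units).
#' @param min_peak_ratio Dominant-peak power must exceed this multiple of
#'   the median nonzero-bin power, otherwise the phase is undefined.
#' @return A one-row tibble with `phi` (cycle fraction in [-1, 0]) and
#'   `period` (model time units).
#' @examples
#' t <- 0:9999
#' phase_lag(sin(2 * pi * t / 100), sin(2 * pi * (t - 25) / 100))
#' @export
phase_lag <- function(reference, follower, dt_sample = 1,
                      min_peak_ratio = 30) {
  stopifnot(length(reference) == length(follower), length(reference) >= 16)
  n <- length(reference)
  ref <- reference - mean(reference)
  fol <- follower - mean(follower)

  if (stats::sd(ref) < 1e-12 * max(1, abs(mean(reference)))) {
    phase_undefined("reference series is flat")
  }

  fr <- stats::fft(ref)
  ff <- stats::fft(fol)
  kmax <- floor(n / 2)
  pow <- Mod(fr[2:(kmax + 1)])^2
  k <- which.max(pow)
  if (pow[k] < min_peak_ratio * stats::median(pow)) {
    phase_undefined("no dominant spectral peak above the noise floor")
  }

  cross <- ff[k + 1] * Conj(fr[k + 1])
  phi <- Arg(cross) / (2 * pi)      # principal value in (-0.5, 0.5]
  # report on the [-1, 0] scale; a sub-roundoff positive value is in phase
  if (phi > 1e-12) phi <- phi - 1 else if (phi > 0) phi <- 0
  tibble::tibble(phi = phi, period = n * dt_sample / k)
}

phase_undefined <- function(msg) {
  stop(structure(class = c("coevo_phase_undefined", "error", "condition"),
                 list(message = paste0("phase undefined: ", msg),
                      call = NULL)))
}

#' Classify a phase lag into cycle types
#'
#' Symmetric bands of half-width `width` around the canonical lags:
#' antiphase at -0.5, quarter-lag at -0.25, in-phase at 0 (equivalently
#' -1); anything between bands is `"intermediate"`.
#'
#' @param phi Phase lag(s) in [-1, 0]; `NA` yields `"undefined"`.
#' @param width Band half-width (cycle fraction).
#' @return Character vector of labels.
#' @examples
#' classify_phase(c(-0.52, -0.25, -0.38, NA))
#' @export
classify_phase <- function(phi, width = 0.1) {
  dplyr::case_when(
    is.na(phi) ~ "undefined",
    abs(phi + 0.5) <= width ~ "antiphase",
    abs(phi + 0.25) <= width ~ "quarter_lag",
    phi > -width | phi < -1 + width ~ "in_phase",
    TRUE ~ "intermediate"
  )
}

#' Phase relationships of a simulated trajectory
#'
#' The three phase lags the cycle taxonomy rests on: predator behind prey,
#' predator behind effective prey biomass, and effective prey biomass
#' behind actual prey biomass, all estimated over the final stretch of the
#' horizon (by default the last 20,000 time units).
#'
#' @param traj A `"coevo_trajectory"`.
#' @param window Length of the analysis window in model time units.
#' @param params Model parameters; default taken from the trajectory.
#' @param width Classification band half-width, passed to [classify_phase()].
#' @return A tibble with one row per pair (`x_y`, `xeff_y`, `x_xeff`):
#'   `phi`, `period`, `label`. Undefined phases (non-cycling runs) appear
#'   as `NA` with label `"undefined"`.
#' @export
phase_relationships <- function(traj, window = 20000,
                                params = traj_params(traj), width = 0.1) {
  win <- analysis_window(traj, last = window)
  xeff <- effective_prey_biomass(win, params)
  dt <- traj_control(traj)$dt_sample
  pairs <- list(
    x_y = list(win$x, win$y),
    xeff_y = list(xeff, win$y),
    x_xeff = list(win$x, xeff)
  )
  res <- purrr::map(pairs, function(p) {
    tryCatch(phase_lag(p[[1]], p[[2]], dt_sample = dt),
             coevo_phase_undefined = function(e) {
               tibble::tibble(phi = NA_real_, period = NA_real_)
             })
  })
  out <- dplyr::bind_rows(res, .id = "pair")
  out$label <- classify_phase(out$phi, width = width)
  out
}
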