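#' Synthetic series with known ground truth
#'
#' Deterministic test signals for exercising the phase and correlation
#' stages independently of the simulator: a pair of sinusoids with a known
#' phase lag (`"sinusoid_pair"`), a pair tied by a strictly increasing
#' transform so their rank correlation is exactly 1 (`"monotone_pair"`),
#' and a constant pair on which the phase is undefined (`"flat"`). Optional
#' Gaussian noise is seed-controlled.
#'
#' @param kind One of `"sinusoid_pair"`, `"monotone_pair"`, `"flat"`.
#' @param n Number of samples.
#' @param dt_sample Sampling interval.
#' @param period Dominant period of the sinusoids (model time units).
#' @param lag Phase lag of the follower behind the reference, as a cycle
#'   fraction in \[-1, 0\] (`-0.25` = quarter-period delay).
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param seed Seed used for the noise (ignored when `noise_sd = 0`).
#' @return A tibble with columns `t`, `ref`, `fol`; the ground truth is
#'   attached as attributes `true_lag` (sinusoids) or `true_spearman`
#'   (monotone pair).
#' @examples
#' fx <- fixture_series("sinusoid_pair", n = 4000, period = 80, lag = -0.25)
#' phase_lag(fx$ref, fx$fol)
#' @export
fixture_series <- function(kind = c("sinusoid_pair", "monotone_pair", "flat"),
                           n = 20000, dt_sample = 1, period = 60,
                           lag = -0.25, noise_sd = 0, seed = 1) {
  kind <- match.arg(kind)
  t <- seq(0, by = dt_sample, length.out = n)
  out <- switch(kind,
    sinusoid_pair = {
      ref <- sin(2 * pi * t / period)
      fol <- sin(2 * pi * (t / period + lag))
      tibble::tibble(t = t, ref = ref, fol = fol)
    },
    monotone_pair = {
      ref <- sin(2 * pi * t / period) + t / max(t)
      tibble::tibble(t = t, ref = ref, fol = exp(ref) + ref^3)
    },
    flat = tibble::tibble(t = t, ref = rep(1, n), fol = rep(2, n))
  )
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    out$ref <- out$ref + stats::rnorm(n, sd = noise_sd)
    out$fol <- out$fol + stats::rnorm(n, sd = noise_sd)
  }
  attr(out, "kind") <- kind
  if (kind == "sinusoid_pair") attr(out, "true_lag") <- lag
  if (kind == "monotone_pair") attr(out, "true_spearman") <- 1
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) return(invisible())
  assign(".Random.seed", old, envir = globalenv())
}
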