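---
title: "Methods: coevolutionary predator-prey cycles and their decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coevolutionary predator-prey cycles and their decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`coevocycles` simulates a single prey ($x$) and predator ($y$) whose
interaction is shaped by two coevolving quantitative traits: prey defense
$u$ and predator offense $v$. The ecology is Rosenzweig–MacArthur with a
Holling type II functional response,

$$
\frac{dx}{dt} = \Big(r(u)\big(1 - \tfrac{x}{K}\big)
  - \frac{a(u,v)\,y}{1 + a(u,v)\,h\,x}\Big)\,x,
\qquad
\frac{dy}{dt} = \Big(g(v)\,\frac{a(u,v)\,x}{1 + a(u,v)\,h\,x} - d\Big)\,y,
$$

where the attack rate depends on the traits only through their difference
(a *unidirectional trait axis*):

$$
a(u,v) = \frac{a_0}{1 + e^{\theta(u-v)}}.
$$

Defense is effective only relative to offense: well-defended prey facing a
well-armed predator are captured at the same rate as undefended prey facing
a harmless one. $\theta$ sets how sharply capture success switches as one
trait overtakes the other.

Both traits are costly. Defense depresses the intrinsic growth rate and
offense depresses the conversion efficiency, each through a Gaussian
trade-off:

$$
r(u) = r_0\,e^{-c_x u^2}, \qquad g(v) = g_0\,e^{-c_y v^2}.
$$

Trait dynamics follow the quantitative-genetics (Lande) equation: each
trait climbs its own fitness gradient at a speed set by the additive
genetic variance, with fitness the per-capita net growth rate
($W_x = \frac{1}{x}\frac{dx}{dt}$, $W_y = \frac{1}{y}\frac{dy}{dt}$):

$$
\frac{du}{dt} = G_x\,\frac{\partial W_x}{\partial u}\,e^{-\varepsilon/u},
\qquad
\frac{dv}{dt} = G_y\,\frac{\partial W_y}{\partial v}\,e^{-\varepsilon/v}.
$$

The factors $e^{-\varepsilon/u}$, $e^{-\varepsilon/v}$ ($\varepsilon =
10^{-3}$) are boundary functions: they leave the dynamics essentially
untouched for traits away from zero but smoothly extinguish trait change as
a trait approaches zero, keeping both traits positive without a hard
constraint. $G_x = G_y = 1$ would mean evolution as fast as the ecology.

All fitness gradients are closed-form (`fitness_partials()`); no numerical
differentiation occurs anywhere in the model code. The finite-difference
versions exist only as oracles in the test suite.

### Parameters

| name | meaning | units | default |
|------|---------|-------|---------|
| `r0` | maximum prey growth rate | 1/time | 1 |
| `K`  | prey carrying capacity | biomass | 1 |
| `a0` | maximum attack rate | 1/(biomass·time) | 1 |
| `h`  | handling time | time | 0.1 (speed) / 1 (cost) |
| `theta` | trait-difference steepness | — | 10 |
| `g0` | maximum conversion efficiency | — | 1 |
| `d`  | predator mortality | 1/time | 0.1 |
| `cx`, `cy` | costliness of defense / offense | — | 3 / 2 |
| `Gx`, `Gy` | adaptation speed (additive genetic variance) | — | $10^{-2}$ |
| `eps` | trait-positivity boundary constant | trait | $10^{-3}$ |

`standard_params("speed")` and `standard_params("cost")` bundle the two
canonical configurations; the *speed* analysis sweeps $G_x, G_y \in
[10^{-2.5}, 1]$ (log-spaced) and the *cost* analysis sweeps $c_x, c_y \in
[0, 10]$ (linear).

## Numerical integration

The four ODEs are integrated with `deSolve::lsoda` (adaptive, switches
between stiff and non-stiff methods) with `rtol = 1e-8`, `atol = 1e-10`.
The right-hand side is compiled C for the default Gaussian trade-offs; a
user-supplied `tradeoff()` object switches to an equivalent plain-R
right-hand side. The test suite confirms that halving the tolerances moves
the downstream phase-lag estimates by less than $10^{-3}$ of a cycle.

Choices that the problem leaves open, fixed here as follows:

* **Horizon and windows.** `t_total = 50000` model time units sampled at
  `dt_sample = 1`, with the first 30,000 discarded as transient. Phase lags
  use the last 20,000 time units, component correlations the last 5,000,
  the equilibrium check the last 5,000.
* **Initial condition.** $x_0 = 0.5$, $y_0 = 0.3$, $u_0 = v_0 = 0.1$.
  Because everything is measured on the attractor after a 30,000-unit
  transient, the start point is immaterial; a sensitivity test verifies
  that a different initial state changes the estimated phase lag by less
  than 0.01 cycles.
* **Negative biomass.** The right-hand side freezes a biomass that the
  solver steps below zero ($W\cdot\max(z,0)$), so extinction cannot be
  amplified into a spurious negative exponential; sampled values below
  zero but within solver tolerance are clipped to 0, anything larger
  aborts. Without the freeze, a predator crash can underflow to a slightly
  negative biomass which then grows exponentially negative once prey
  recover — a purely numerical resurrection artifact.
* **Exponent clamping.** $\theta(u-v)$ is clamped to $\pm 700$ before
  exponentiation, so the attack rate saturates monotonically instead of
  overflowing to `NaN`.
* **Outcome thresholds.** A run is *predator-extinct* if predator biomass
  falls below $10^{-9}$ anywhere in the analysis window, *equilibrium* if
  the coefficients of variation of both biomasses over the last 5,000
  units fall below $10^{-4}$, otherwise *cycles*. Both thresholds sit many
  orders of magnitude away from the amplitudes of observed cycles, so the
  classification is insensitive to their exact values.

## Effective prey biomass

The predator does not experience prey biomass as such; it experiences
biomass it can catch and digest. The effective prey biomass weights actual
biomass by the relative attack rate and relative conversion efficiency:

$$
x_{\mathrm{eff}} = x \cdot \frac{a(u,v)}{a_0} \cdot \frac{g(v)}{g_0},
\qquad 0 \le x_{\mathrm{eff}} \le x .
$$

The central empirical regularity the package reproduces is that the
predator follows $x_{\mathrm{eff}}$ with roughly a quarter-period lag in
every cycling regime, so the predator–prey phase relationship is set by
how far $x_{\mathrm{eff}}$ lags behind $x$: coincident peaks give classic
quarter-lag cycles, a quarter-period delay gives antiphase cycles.

## Geber decomposition

Fitness change decomposes exactly by the multivariate chain rule into the
contributions of the four changing state variables,

$$
\frac{dW_x}{dt} =
\underbrace{\frac{\partial W_x}{\partial x}\frac{dx}{dt}}_{E_x^{(x)}} +
\underbrace{\frac{\partial W_x}{\partial y}\frac{dy}{dt}}_{E_y^{(x)}} +
\underbrace{\frac{\partial W_x}{\partial u}\frac{du}{dt}}_{E_u^{(x)}} +
\underbrace{\frac{\partial W_x}{\partial v}\frac{dv}{dt}}_{E_v^{(x)}},
$$

and likewise for $W_y$. `geber_components()` evaluates both factors
analytically at every sample, so the identity holds to solver accuracy.
Structural properties, all covered by tests: $E_y^{(y)} \equiv 0$
(predator fitness does not depend on predator biomass), and
$E_u^{(x)}, E_v^{(y)} \ge 0$ (each trait follows its own gradient, so its
own-level component is a squared gradient times a positive factor).

When the identity is *tested*, the time derivative of the fitness series
must come from somewhere independent — a second-order central difference
of the sampled $W$ series. That oracle carries its own $O(\Delta t^2)$
truncation error, which at `dt_sample = 1` exceeds the identity's residual
by orders of magnitude for the shorter-period regimes. The tests therefore
assert the identity on a ten-fold finer sampling grid (where the oracle
error is below $10^{-3}$ in max norm relative to the derivative's
amplitude) and separately assert that the residual against the
coarse-grid oracle contracts by the factor 4 per halving of `dt_sample`
that second-order truncation predicts.

## Phase estimation

`phase_lag(ref, fol)` mean-removes both series, locates the dominant
nonzero frequency of the reference power spectrum, and takes the
cross-spectrum phase at that bin, normalized to cycle fractions on the
$[-1, 0]$ scale: $0$ (and $-1$) is in phase, $-0.25$ a quarter-period lag
of the follower behind the reference, $-0.5$ antiphase. Cross-spectrum
phase (rather than peak-to-peak timing) is the standard spectral
realization of this estimator and is robust to additive noise; the
property tests require exactness to $10^{-3}$ on constructed sinusoids and
better than $0.01$ at a signal-to-noise ratio of 50. No taper is applied:
the analyzed series are long (20,000 samples) and near-periodic, so
leakage is negligible at the dominant bin.

A series with no dominant peak at least 30 times the median nonzero-bin
power — a flat or noise-dominated record — has no meaningful phase and
raises a classed error rather than returning a number. In the sweep
pipeline this situation is pre-empted: phases are only computed for cells
classified as cycling.

Classification uses symmetric bands of half-width 0.1 around $-0.5$
(antiphase), $-0.25$ (quarter-lag) and $0/-1$ (in phase), with an explicit
`intermediate` class between bands; the dynamics do produce intermediate
lags over narrow parameter ranges at the transition between regimes, and
forcing them into either class would bias the association analysis.

## Component correlations and associations

Within one simulation, `component_correlations()` computes Spearman rank
correlations $r_C$ between component pairs over the last 5,000 time units.
Four of the twelve pairs are excluded: $E_x^{(x)}$–$E_y^{(x)}$ and
$E_x^{(y)}$–$E_y^{(y)}$ because they restate the predator-prey phase
relationship itself, and the two pairs involving $E_y^{(y)}$ because that
component is identically zero. Rank correlation makes per-series
standardization irrelevant, so correlations are computed on raw
components; a zero-variance component yields a missing value, never zero.

`run_sweep_set()` simulates a full focal-parameter grid ("set"),
`set_association()` then correlates (again Spearman, across the cycling
cells of the set) the phase lag $\varphi$ with each $r_C$, giving eight
associations $r_A$ per set. Sets that do not contain both antiphase and
quarter-lag cells carry no information about what distinguishes the two
regimes and are excluded, as are sets with fewer than three usable cells.
`aggregate_associations()` reports the mean and standard deviation of each
$r_A$ across included sets. Cells that end in equilibrium or extinction
have no defined $\varphi$ and drop out of the association computation.

The diagnostic association is the one between $E_x^{(y)}$ and $E_u^{(y)}$
— whether changes in prey biomass and in defense push predator fitness in
the same or opposite directions. Antiphase cycles are characterized by a
strongly negative correlation (prey biomass and defense rise together, so
their effects on the predator oppose), quarter-lag cycles by a strongly
positive one.

### Problem sizes

The full-scale analysis uses 25 × 25 grids and on the order of a
hundred sets per family. The package defaults keep that full scale
available, while the test suite and the acceptance script use a reduced
replication chosen to preserve the structure of the analysis: 9 × 9 grids
over the full $[10^{-2.5}, 1]$ speed range and four sets ($K \in \{1, 2\}
\times c_x \in \{2, 3\}$, everything else standard). Under these
conditions two of the four sets contain both cycle types (the cheap-defense
set at $K = 1$ is entirely predator-extinct, and at $K = 2$ entirely
antiphase, so the stated inclusion rule discards both), and the mean
association for $E_x^{(y)}$–$E_u^{(y)}$ remains strong, positive and
stable across the included sets.

## Synthetic fixtures

`fixture_series()` generates the signals used to test the phase and
correlation stages in isolation: sinusoid pairs with an exactly known lag
(optionally with seeded Gaussian noise), monotone-coupled pairs whose
Spearman correlation is exactly 1, and flat pairs exercising the
undefined-phase path. These fixtures emulate the *spectral* structure of
the simulated series — one dominant frequency, a stable lag — but not
their relaxation-type waveform asymmetry or amplitude modulation, so
passing them demonstrates correctness of the estimators, not robustness to
every waveform the model can produce. The simulated regimes themselves
cover the latter.

## Limitations

* One prey and one predator clone, one unidirectional trait axis;
  multi-clonal or bidirectional variants are out of scope.
* The Gaussian trade-off is the default and only built-in form; the
  `tradeoff()` hook accepts any differentiable replacement but the
  compiled fast path covers only the default.
* No continuation or bifurcation analysis: regime boundaries are resolved
  only to grid resolution.
* Deterministic dynamics only — no demographic or environmental
  stochasticity; biomasses can become arbitrarily small and recover,
  which real finite populations cannot.
* Phase lags are single numbers per run; time-varying phase (e.g. during
  long transients or near regime boundaries) is not tracked.
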