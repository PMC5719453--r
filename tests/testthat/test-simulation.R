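test_that("non-evolutionary limit reproduces the Holling type II model", {
  # adaptation frozen, traits pinned at equal (tiny) values: the ecology is
  # the classical two-ODE predator-prey model with a = a0/2
  p <- model_params(h = 0.1, K = 1, cx = 3, cy = 2)
  still <- adaptation_params(Gx = 0, Gy = 0)
  ctrl <- sim_control(t_total = 5000, t_transient = 2500,
                      init = c(x = 0.5, y = 0.3, u = 1e-8, v = 1e-8))
  traj <- simulate_coevolution(p, still, ctrl)
  expect_equal(unique(traj$u), 1e-8)
  expect_equal(unique(traj$v), 1e-8)

  eq <- holling_equilibrium(p)
  expect_equal(eq[["x"]], p$d / (0.5 * (p$g0 - p$d * p$h)), tolerance = 1e-12)

  # equilibrium is stable here; the trajectory must settle onto it
  final <- traj[nrow(traj), ]
  expect_equal(final$x, eq[["x"]], tolerance = 1e-6)
  expect_equal(final$y, eq[["y"]], tolerance = 1e-6)

  # independent two-ODE reference integration (plain-R Holling RHS)
  rhs2 <- function(t, s, parms) {
    a <- 0.5
    den <- 1 + a * parms$h * s[1]
    list(c(s[1] * (parms$r0 * (1 - s[1] / parms$K) - a * s[2] / den),
           s[2] * (parms$g0 * a * s[1] / den - parms$d)))
  }
  ref <- deSolve::lsoda(c(0.5, 0.3), seq(0, 5000, 1), rhs2,
                        list(r0 = 1, K = 1, h = 0.1, g0 = 1, d = 0.1),
                        rtol = 1e-10, atol = 1e-12)
  expect_equal(traj$x, ref[, 2], tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(traj$y, ref[, 3], tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("the example regimes produce sustained cycles with positive traits", {
  for (nm in c("fig1a", "fig1b", "fig1c")) {
    traj <- regime_trajectory(nm)
    expect_equal(nrow(traj), 50001)
    expect_true(all(traj$u > 0))
    expect_true(all(traj$v > 0))
    expect_true(all(traj$x >= 0))
    expect_true(all(traj$y >= 0))
    out <- classify_outcome(traj)
    expect_identical(out$outcome, "cycles")
    expect_gt(out$amp_x, 0.1)
  }
  # slow-predator regime shows high-amplitude defense oscillations
  expect_gt(classify_outcome(regime_trajectory("fig1a"))$amp_u, 0.3)
})

test_that("outcome classification separates extinction / equilibrium / cycles", {
  # very costly defense and offense: stable coexistence at equilibrium
  std <- standard_params("cost", cx = 9, cy = 9)
  traj_eq <- simulate_coevolution(std$model, std$adaptation)
  expect_identical(classify_outcome(traj_eq)$outcome, "equilibrium")

  # offense much more costly than defense: the predator starves out
  std2 <- standard_params("cost", cx = 1, cy = 9)
  traj_ext <- simulate_coevolution(std2$model, std2$adaptation)
  expect_identical(classify_outcome(traj_ext)$outcome, "predator_extinct")

  # a constant synthetic trajectory is an equilibrium
  flat <- tibble::tibble(t = 0:1000, x = 0.4, y = 0.2, u = 0.1, v = 0.1)
  ctrl <- sim_control(t_total = 1000, t_transient = 500,
                      equilibrium_window = 200)
  expect_identical(classify_outcome(flat, ctrl)$outcome, "equilibrium")
})

test_that("phase estimates are converged in the integration tolerances", {
  for (nm in c("fig1a", "fig1b")) {
    std <- regime_params(nm)
    phi_def <- phase_relationships(regime_trajectory(nm))$phi[1]
    tight <- simulate_coevolution(std$model, std$adaptation,
                                  sim_control(rtol = 5e-9, atol = 5e-11))
    phi_tight <- phase_relationships(tight)$phi[1]
    expect_lt(abs(phi_def - phi_tight), 1e-3)
  }
})

test_that("the attractor, not the initial condition, sets the phase lag", {
  std <- regime_params("fig1a")
  alt <- simulate_coevolution(std$model, std$adaptation,
    sim_control(init = c(x = 0.9, y = 0.05, u = 0.4, v = 0.2)))
  phi_ref <- phase_relationships(regime_trajectory("fig1a"))$phi[1]
  phi_alt <- phase_relationships(alt)$phi[1]
  expect_lt(abs(phi_ref - phi_alt), 0.01)
})

test_that("trajectories carry their provenance and window helpers work", {
  traj <- regime_trajectory("fig1a")
  expect_s3_class(traj, "coevo_trajectory")
  expect_identical(attr(traj, "params")$cx, 3)
  win <- analysis_window(traj)
  expect_equal(min(win$t), 30000)
  last5 <- analysis_window(traj, last = 5000)
  expect_equal(nrow(last5), 5001)
})
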