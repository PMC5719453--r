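test_that("attack rate follows the logistic trait-difference form", {
  p <- model_params(a0 = 1, theta = 10)

  # equal traits sit exactly at half the maximum
  expect_equal(attack_rate(0.37, 0.37, p), 0.5)
  expect_equal(attack_rate(2, 2, p), 0.5)

  # high-precision evaluation at u = 1, v = 0
  expect_equal(attack_rate(1, 0, p), 1 / (1 + exp(10)), tolerance = 1e-12)

  # saturation limits
  expect_equal(attack_rate(0, 10, p), 1, tolerance = 1e-40)
  expect_equal(attack_rate(1e6, 0, p), 0)
  expect_false(is.nan(attack_rate(1e9, 0, p)))
  expect_false(is.nan(attack_rate(0, 1e9, p)))

  # monotone: decreasing in defense, increasing in offense
  u <- seq(0, 2, by = 0.1)
  expect_true(all(diff(attack_rate(u, 1, p)) < 0))
  expect_true(all(diff(attack_rate(1, u, p)) > 0))
})

test_that("attack rate is symmetric: a(u,v) + a(v,u) = a0", {
  p <- model_params(a0 = 1.7, theta = 10)
  st <- random_states(50)
  expect_equal(attack_rate(st$u, st$v, p) + attack_rate(st$v, st$u, p),
               rep(1.7, 50))
})

test_that("Gaussian trade-offs match their closed forms", {
  p <- model_params(r0 = 1, cx = 3, g0 = 1, cy = 2)
  expect_equal(prey_growth_rate(0, p), 1)
  expect_equal(conversion_efficiency(0, p), 1)
  expect_equal(prey_growth_rate(0.5, p), exp(-0.75), tolerance = 1e-12)
  expect_equal(conversion_efficiency(1, p), exp(-2), tolerance = 1e-12)

  free <- model_params(cx = 0, cy = 0)
  u <- seq(0, 3, by = 0.5)
  expect_equal(prey_growth_rate(u, free), rep(free$r0, length(u)))
  expect_equal(conversion_efficiency(u, free), rep(free$g0, length(u)))
})

test_that("fitness functions reduce correctly in limiting cases", {
  p <- model_params()

  # prey at carrying capacity with no predators: zero net growth
  expect_equal(prey_fitness(list(x = p$K, y = 0, u = 0.4, v = 0.1), p), 0)
  # vanishing prey, no predators: intrinsic growth r(u)
  expect_equal(prey_fitness(list(x = 1e-14, y = 0, u = 0.4, v = 0.1), p),
               prey_growth_rate(0.4, p), tolerance = 1e-10)
  # starving predator loses at its mortality rate
  expect_equal(predator_fitness(list(x = 0, y = 1, u = 0.1, v = 0.1), p), -p$d)

  # term-by-term arithmetic at a generic state
  s <- list(x = 0.5, y = 0.3, u = 0.2, v = 0.2)
  a <- p$a0 / 2 # equal traits
  expect_equal(prey_fitness(s, p),
               p$r0 * exp(-p$cx * 0.04) * (1 - 0.5 / p$K) -
                 a * 0.3 / (1 + a * p$h * 0.5))
  expect_equal(predator_fitness(s, p),
               p$g0 * exp(-p$cy * 0.04) * a * 0.5 / (1 + a * p$h * 0.5) - p$d)
})

test_that("predator fitness is independent of predator biomass", {
  p <- model_params()
  st <- random_states(30)
  st2 <- dplyr::mutate(st, y = y * 7 + 1)
  expect_identical(predator_fitness(st, p), predator_fitness(st2, p))
  expect_true(all(fitness_partials(st, p)$dWy_dy == 0))
})

test_that("analytic fitness partials match central finite differences", {
  p <- model_params(h = 1, cx = 4, cy = 3, theta = 10)
  st <- random_states(100)
  part <- fitness_partials(st, p)
  hstep <- 1e-6
  fd <- function(fit, var) {
    up <- st; dn <- st
    up[[var]] <- up[[var]] + hstep
    dn[[var]] <- dn[[var]] - hstep
    (fit(up, p) - fit(dn, p)) / (2 * hstep)
  }
  for (var in c("x", "y", "u", "v")) {
    fdx <- fd(prey_fitness, var)
    ana <- part[[paste0("dWx_d", var)]]
    expect_lt(max(abs(ana - fdx) / pmax(abs(fdx), 1e-3)), 1e-6)
    fdy <- fd(predator_fitness, var)
    any_ <- part[[paste0("dWy_d", var)]]
    expect_lt(max(abs(any_ - fdy) / pmax(abs(fdy), 1e-3)), 1e-6)
  }
})

test_that("selection gradients have the expected structure at boundaries", {
  p <- model_params()
  # without predators, defense is pure cost
  st <- tibble::tibble(x = 0.5, y = 0, u = c(0.2, 0.8), v = 0.1)
  expect_true(all(fitness_gradients(st, p)$dWx_du < 0))
  # at u = 0 the cost derivative vanishes; only predation release remains
  st0 <- list(x = 0.5, y = 0.4, u = 0, v = 0.2)
  g0 <- fitness_gradients(st0, p)$dWx_du
  expect_gt(g0, 0)
})

test_that("system derivatives honour boundaries and frozen evolution", {
  p <- model_params()
  still <- adaptation_params(Gx = 0, Gy = 0)
  st <- random_states(20)
  d <- system_derivatives(st, p, still)
  expect_true(all(d$du == 0))
  expect_true(all(d$dv == 0))

  # the boundary factor kills trait change as traits approach zero
  adapt <- adaptation_params(Gx = 1, Gy = 1)
  near0 <- list(x = 0.5, y = 0.5, u = 1e-6, v = 1e-6)
  dn <- system_derivatives(near0, p, adapt)
  expect_equal(dn$du, 0, tolerance = 1e-300)
  expect_equal(dn$dv, 0, tolerance = 1e-300)

  # total extinction is absorbing for both biomasses
  gone <- list(x = 0, y = 0, u = 0.3, v = 0.3)
  dg <- system_derivatives(gone, p, adapt)
  expect_identical(dg$dx, 0)
  expect_identical(dg$dy, 0)

  expect_error(system_derivatives(list(x = 1, y = 1, u = -1, v = 1), p, adapt),
               "strictly positive")
})

test_that("custom trade-offs are honoured by rates and gradients", {
  lin <- tradeoff(function(q) 2 - 0.5 * q, function(q) rep(-0.5, length(q)))
  p <- model_params(prey_tradeoff = lin)
  expect_equal(prey_growth_rate(1, p), 1.5)
  st <- list(x = 0.2, y = 0, u = 1, v = 0.5)
  # y = 0: gradient is r'(u) (1 - x/K) = -0.5 * 0.8
  expect_equal(fitness_gradients(st, p)$dWx_du, -0.4)
})

test_that("parameter validation names the offending field", {
  expect_error(model_params(cx = -1), "cx")
  expect_error(model_params(K = 0), "K")
  expect_error(adaptation_params(Gx = -0.1), "Gx")
  expect_error(adaptation_params(eps = 0), "eps")
  expect_error(sim_control(t_transient = 6e4), "t_transient")
  expect_error(sim_control(init = c(x = 0.5, y = 0.3, u = 0, v = 0.1)),
               "traits")
})
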