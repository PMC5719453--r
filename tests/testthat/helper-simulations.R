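# Full-horizon reference simulations of the three example regimes, computed
# once per test run and shared across test files.
.sim_cache <- new.env(parent = emptyenv())

regime_params <- function(name) {
  switch(name,
    fig1a = standard_params("speed"),                            # antiphase
    fig1b = standard_params("speed", Gx = 1e-1, Gy = 10^-0.9),   # 1/4-lag (fast predator)
    fig1c = standard_params("cost", cx = 5, h = 2),              # 1/4-lag (costly defense)
    stop("unknown regime ", name)
  )
}

regime_trajectory <- function(name, control = sim_control()) {
  key <- paste0(name, "_", control$t_total, "_", control$dt_sample)
  if (!exists(key, envir = .sim_cache)) {
    std <- regime_params(name)
    assign(key, simulate_coevolution(std$model, std$adaptation, control),
           envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

random_states <- function(n, seed = 42) {
  withr::with_seed(seed, tibble::tibble(
    x = runif(n, 0.01, 2),
    y = runif(n, 0.01, 2),
    u = runif(n, 0.02, 1.5),
    v = runif(n, 0.02, 1.5)
  ))
}
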