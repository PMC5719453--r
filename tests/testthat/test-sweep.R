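short_ctrl <- sim_control(t_total = 6000, t_transient = 3000)

test_that("grids match the canonical axes and spacing", {
  g <- sweep_grid("speed", grid_size = 25)
  expect_equal(nrow(g), 625)
  expect_equal(range(g$Gx), c(10^-2.5, 1))
  # log-spaced: constant ratio between consecutive axis values
  vals <- sort(unique(g$Gx))
  expect_equal(diff(log10(vals)), rep(2.5 / 24, 24))

  gc <- sweep_grid("cost", grid_size = 25)
  expect_equal(range(gc$cx), c(0, 10))
  expect_equal(diff(sort(unique(gc$cy))), rep(10 / 24, 24))
})

test_that("a toy grid produces complete, independent cell records", {
  sw <- run_sweep_set("speed", grid_size = 2, control = short_ctrl,
                      phase_window = 3000, corr_window = 2000)
  expect_s3_class(sw, "coevo_sweep")
  expect_equal(nrow(sw), 4)
  expect_true(all(c("Gx", "Gy", "outcome", "phi_xy", "label",
                    coevocycles:::rc_col_names()) %in% names(sw)))
  expect_true(all(sw$outcome %in%
    c("cycles", "equilibrium", "predator_extinct", "error")))

  # recomputing one cell in isolation reproduces its record bit-identically
  cell <- sw[3, ]
  std <- standard_params("speed")
  redo <- run_sweep_set("speed", grid_size = 2, control = short_ctrl,
                        phase_window = 3000, corr_window = 2000)
  expect_identical(cell$phi_xy, redo$phi_xy[3])
  expect_identical(cell$outcome, redo$outcome[3])
  expect_identical(unlist(cell[coevocycles:::rc_col_names()]),
                   unlist(redo[3, coevocycles:::rc_col_names()]))
})

test_that("association is +1 when r_c increases monotonically with phi", {
  sw <- run_sweep_set("speed", grid_size = 2, control = short_ctrl,
                      phase_window = 3000, corr_window = 2000)
  fake <- sw
  fake$phi_xy <- seq(-0.5, -0.2, length.out = nrow(fake))
  fake$label <- c("antiphase", "quarter_lag", "quarter_lag", "quarter_lag")
  for (col in coevocycles:::rc_col_names()) {
    fake[[col]] <- tanh(fake$phi_xy * 3) # strictly increasing in phi
  }
  assoc <- set_association(fake)
  expect_true(all(assoc$r_a == 1))
  expect_true(all(assoc$included))
})

test_that("sets lacking either cycle type are excluded", {
  sw <- run_sweep_set("speed", grid_size = 2, control = short_ctrl,
                      phase_window = 3000, corr_window = 2000)
  only_anti <- sw
  only_anti$phi_xy <- rep(-0.5, nrow(sw)) + c(0, 0.01, -0.01, 0.02)
  only_anti$label <- rep("antiphase", nrow(sw))
  for (col in coevocycles:::rc_col_names()) {
    only_anti[[col]] <- c(0.1, 0.4, 0.2, 0.3)
  }
  assoc <- set_association(only_anti)
  expect_false(any(assoc$included))
  expect_equal(nrow(aggregate_associations(list(assoc))), 0)

  # fewer than three usable cells is also not enough
  thin <- only_anti
  thin$label <- c("antiphase", "quarter_lag", "undefined", "undefined")
  thin$phi_xy[3:4] <- NA
  assoc_thin <- set_association(thin)
  expect_true(all(is.na(assoc_thin$r_a)))
})

test_that("aggregation over a single included set is mean = r_a, sd = 0", {
  sw <- run_sweep_set("speed", grid_size = 2, control = short_ctrl,
                      phase_window = 3000, corr_window = 2000)
  fake <- sw
  fake$phi_xy <- c(-0.5, -0.45, -0.3, -0.25)
  fake$label <- c("antiphase", "antiphase", "quarter_lag", "quarter_lag")
  for (col in coevocycles:::rc_col_names()) {
    fake[[col]] <- c(0.1, 0.05, 0.8, 0.9)
  }
  assoc <- set_association(fake)
  agg <- aggregate_associations(list(assoc))
  expect_equal(nrow(agg), 8)
  expect_equal(agg$mean_ra, assoc$r_a[match(agg$pair, assoc$pair)])
  expect_true(all(agg$sd_ra == 0))
  expect_true(all(agg$n_sets == 1))
})

test_that("slow predator adaptation never yields quarter-lag cycles", {
  # coarse but full-length grid; quarter-lag requires rapid predator
  # adaptation (the fig1b cell), never appears at the slow-Gy edge
  sw <- run_sweep_set("speed", grid_size = 3)
  slow_edge <- sw[sw$Gy == min(sw$Gy), ]
  expect_identical(sw$label[sw$Gx == min(sw$Gx) & sw$Gy == min(sw$Gy)],
                   "antiphase")
  expect_false(any(slow_edge$label == "quarter_lag"))
  ph <- phase_relationships(regime_trajectory("fig1b"))
  expect_identical(ph$label[ph$pair == "x_y"], "quarter_lag")
})

test_that("family runner applies per-set overrides and aggregates", {
  sets <- tidyr::expand_grid(K = c(1, 1.5))
  fam <- run_sweep_family(sets, family = "speed", grid_size = 2,
                          control = short_ctrl, phase_window = 3000,
                          corr_window = 2000)
  expect_length(fam$sweeps, 2)
  expect_equal(attr(fam$sweeps[[2]], "params")$K, 1.5)
  expect_s3_class(fam$summary, "tbl_df")

  presets <- family_sets("speed")
  expect_equal(nrow(presets), 96)
  expect_equal(nrow(family_sets("cost", max_sets = 5)), 5)
})

test_that("tidy and glance summarise sweeps", {
  sw <- run_sweep_set("speed", grid_size = 2, control = short_ctrl,
                      phase_window = 3000, corr_window = 2000)
  td <- tidy(sw)
  expect_equal(nrow(td), 4 * 8)
  expect_true(all(c("Gx", "Gy", "pair", "r_c") %in% names(td)))
  gl <- glance(sw)
  expect_equal(gl$n_cells, 4)
  expect_equal(gl$n_cycles + gl$n_equilibrium + gl$n_extinct + gl$n_error, 4)
})
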