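#' Focal-parameter grid for a sweep set
#'
#' A "set" is one grid of simulations over two focal parameters with
#' everything else fixed: adaptation speeds `Gx`, `Gy` on a log-spaced
#' grid over \[10^-2.5, 1\] for the speed analysis, trait costs `cx`, `cy`
#' on a linear grid over \[0, 10\] for the cost analysis.
#'
#' @param family `"speed"` or `"cost"`.
#' @param grid_size Number of values per axis (the full analysis uses 25).
#' @return A tibble with `grid_size^2` rows and the two focal-axis columns.
#' @examples
#' sweep_grid("speed", grid_size = 3)
#' @export
sweep_grid <- function(family = c("speed", "cost"), grid_size = 25) {
  family <- match.arg(family)
  stopifnot(grid_size >= 2)
  if (family == "speed") {
    vals <- 10^seq(-2.5, 0, length.out = grid_size)
    tidyr::expand_grid(Gx = vals, Gy = vals)
  } else {
    vals <- seq(0, 10, length.out = grid_size)
    tidyr::expand_grid(cx = vals, cy = vals)
  }
}

rc_col_names <- function() {
  p <- correlation_pairs()
  paste0("rc_", gsub("_", "", p$comp1), "_", gsub("_", "", p$comp2))
}

# Simulate, classify and analyze one grid cell; returns a one-row tibble.
run_cell <- function(params, adaptation, control, phase_window, corr_window,
                     width) {
  traj <- simulate_coevolution(params, adaptation, control)
  outcome <- classify_outcome(traj, control)$outcome
  rc <- stats::setNames(rep(NA_real_, 8), rc_col_names())
  phi <- c(phi_xy = NA_real_, phi_xeffy = NA_real_, phi_xxeff = NA_real_)
  period <- NA_real_
  label <- "undefined"
  if (outcome == "cycles") {
    ph <- phase_relationships(traj, window = phase_window, width = width)
    phi <- stats::setNames(ph$phi, c("phi_xy", "phi_xeffy", "phi_xxeff"))
    period <- ph$period[ph$pair == "x_y"]
    label <- ph$label[ph$pair == "x_y"]
    comp <- geber_components(analysis_window(traj, last = corr_window))
    cors <- component_correlations(comp, window = NULL)
    rc[] <- cors$r_c
  }
  tibble::tibble(outcome = outcome,
                 phi_xy = phi[["phi_xy"]], phi_xeffy = phi[["phi_xeffy"]],
                 phi_xxeff = phi[["phi_xxeff"]], period = period,
                 label = label, !!!as.list(rc), error = NA_character_)
}

#' Run one sweep set
#'
#' Simulates every cell of a focal-parameter grid, classifies its outcome,
#' and for cycling cells estimates the three phase lags and the eight
#' component correlations. Cells are independent; a failing cell is
#' recorded (outcome `"error"`) without aborting the set.
#'
#' @param family `"speed"` (focal axes `Gx`, `Gy`) or `"cost"` (`cx`, `cy`).
#' @param grid_size Cells per axis; the full analysis uses 25.
#' @param params,adaptation Fixed parameters of the set; defaults are the
#'   standard values of the chosen family.
#' @param control A [sim_control()].
#' @param phase_window,corr_window Analysis windows (model time units) for
#'   the phase and correlation stages.
#' @param width Phase classification band half-width.
#' @param verbose Print per-cell progress.
#' @return A tibble of class `"coevo_sweep"`: the two focal-axis columns,
#'   `outcome`, `phi_xy`, `phi_xeffy`, `phi_xxeff`, `period`, `label`, the
#'   eight `rc_*` columns and `error`. The family and fixed parameters are
#'   attached as attributes.
#' @examples
#' \donttest{
#' sw <- run_sweep_set("speed", grid_size = 2,
#'                     control = sim_control(t_total = 2000, t_transient = 1000),
#'                     phase_window = 1000, corr_window = 500)
#' }
#' @export
run_sweep_set <- function(family = c("speed", "cost"), grid_size = 25,
                          params = NULL, adaptation = NULL,
                          control = sim_control(),
                          phase_window = 20000, corr_window = 5000,
                          width = 0.1, verbose = FALSE) {
  family <- match.arg(family)
  std <- standard_params(family)
  if (is.null(params)) params <- std$model
  if (is.null(adaptation)) adaptation <- std$adaptation
  grid <- sweep_grid(family, grid_size)
  axes <- names(grid)

  cells <- purrr::pmap(grid, function(...) {
    focal <- list(...)
    p <- params
    a <- adaptation
    if (family == "speed") {
      a <- adaptation_params(Gx = focal$Gx, Gy = focal$Gy, eps = adaptation$eps)
    } else {
      p <- modify_params(params, cx = focal$cx, cy = focal$cy)
    }
    if (verbose) {
      message(sprintf("cell %s=%.4g %s=%.4g", axes[1], focal[[1]],
                      axes[2], focal[[2]]))
    }
    tryCatch(
      run_cell(p, a, control, phase_window, corr_window, width),
      error = function(e) {
        tibble::tibble(outcome = "error", phi_xy = NA_real_,
                       phi_xeffy = NA_real_, phi_xxeff = NA_real_,
                       period = NA_real_, label = "undefined",
                       !!!stats::setNames(as.list(rep(NA_real_, 8)),
                                          rc_col_names()),
                       error = conditionMessage(e))
      }
    )
  })

  out <- dplyr::bind_cols(grid, dplyr::bind_rows(cells))
  attr(out, "family") <- family
  attr(out, "params") <- params
  attr(out, "adaptation") <- adaptation
  attr(out, "control") <- control
  class(out) <- c("coevo_sweep", class(out))
  out
}

# Rebuild a coevo_params with some fields replaced.
modify_params <- function(params, ...) {
  repl <- list(...)
  fields <- params[c("r0", "K", "a0", "h", "theta", "g0", "d", "cx", "cy")]
  fields[names(repl)] <- repl
  fields$prey_tradeoff <- params$prey_tradeoff
  fields$predator_tradeoff <- params$predator_tradeoff
  do.call(model_params, fields)
}

#' Per-set associations between phase lag and component correlations
#'
#' For one sweep set, the association `r_a` of each component-correlation
#' pair is the Spearman rank correlation, across grid cells, between the
#' predator-prey phase lag `phi_xy` and that pair's `r_c`. Only cells where
#' both are defined (cycling cells) enter. A set is included in the final
#' aggregation only if it contains both antiphase and quarter-lag cells;
#' fewer than three usable cells also excludes it.
#'
#' @param sweep A `"coevo_sweep"` tibble.
#' @return A tibble of class `"coevo_association"` with columns `pair`,
#'   `r_a`, `n_cells` and `included` (same flag on every row).
#' @export
set_association <- function(sweep) {
  pairs <- correlation_pairs()
  cols <- rc_col_names()
  both_types <- any(sweep$label == "antiphase") &&
    any(sweep$label == "quarter_lag")
  res <- purrr::map2(pairs$pair, cols, function(pair, col) {
    ok <- !is.na(sweep$phi_xy) & !is.na(sweep[[col]])
    n <- sum(ok)
    r_a <- if (n >= 3) {
      # zero-variance phi or r_c (single cycle type) gives NA, not a warning
      suppressWarnings(
        stats::cor(sweep$phi_xy[ok], sweep[[col]][ok], method = "spearman")
      )
    } else {
      NA_real_
    }
    tibble::tibble(pair = pair, r_a = r_a, n_cells = n)
  })
  out <- dplyr::bind_rows(res)
  out$included <- both_types & out$n_cells >= 3
  attr(out, "family") <- attr(sweep, "family")
  class(out) <- c("coevo_association", class(out))
  out
}

#' Aggregate associations across sets
#'
#' Pools the per-set associations of one analysis family: excluded sets
#' (those lacking either cycle type) are dropped, then the mean and
#' standard deviation of each pair's `r_a` are taken across the included
#' sets.
#'
#' @param associations A list of [set_association()] results (or of
#'   `"coevo_sweep"` objects, which are converted first).
#' @return A tibble with one row per pair: `pair`, `mean_ra`, `sd_ra`,
#'   `n_sets`. With zero included sets the tibble has zero rows.
#' @export
aggregate_associations <- function(associations) {
  assocs <- purrr::map(associations, function(a) {
    if (inherits(a, "coevo_sweep")) set_association(a) else a
  })
  pooled <- dplyr::bind_rows(assocs, .id = "set")
  pooled <- dplyr::filter(pooled, .data$included, !is.na(.data$r_a))
  if (nrow(pooled) == 0) {
    return(tibble::tibble(pair = character(), mean_ra = double(),
                          sd_ra = double(), n_sets = integer()))
  }
  dplyr::summarise(
    dplyr::group_by(pooled, .data$pair),
    mean_ra = mean(.data$r_a),
    sd_ra = if (dplyr::n() > 1) stats::sd(.data$r_a) else 0,
    n_sets = dplyr::n(),
    .groups = "drop"
  )
}

#' Run a family of sweep sets
#'
#' Runs one sweep set per row of `sets` (each row giving the fixed
#' model-parameter overrides for that set, e.g. columns `K` and `cx`),
#' computes the per-set associations, and aggregates them across the
#' included sets.
#'
#' @param sets A data frame of per-set overrides for [model_params()]
#'   fields (and/or `Gx`, `Gy` for cost-family sets).
#' @inheritParams run_sweep_set
#' @return A list with elements `sweeps` (list of `"coevo_sweep"`),
#'   `associations` (list of `"coevo_association"`), and `summary` (the
#'   [aggregate_associations()] tibble).
#' @examples
#' \dontrun{
#' fam <- run_sweep_family(tidyr::expand_grid(K = c(1, 2), cx = c(2, 3)),
#'                         family = "speed", grid_size = 9)
#' fam$summary
#' }
#' @export
run_sweep_family <- function(sets, family = c("speed", "cost"),
                             grid_size = 25, control = sim_control(),
                             phase_window = 20000, corr_window = 5000,
                             width = 0.1, verbose = FALSE) {
  family <- match.arg(family)
  std <- standard_params(family)
  adapt_fields <- c("Gx", "Gy", "eps")
  sweeps <- purrr::map(seq_len(nrow(sets)), function(i) {
    over <- as.list(sets[i, , drop = FALSE])
    p <- do.call(modify_params,
                 c(list(std$model), over[setdiff(names(over), adapt_fields)]))
    a_over <- over[intersect(names(over), adapt_fields)]
    a <- do.call(adaptation_params,
                 utils::modifyList(std$adaptation[adapt_fields], a_over))
    if (verbose) {
      message("set ", i, "/", nrow(sets), ": ",
              paste(names(over), unlist(over), sep = "=", collapse = ", "))
    }
    run_sweep_set(family, grid_size, params = p, adaptation = a,
                  control = control, phase_window = phase_window,
                  corr_window = corr_window, width = width, verbose = verbose)
  })
  associations <- purrr::map(sweeps, set_association)
  list(sweeps = sweeps, associations = associations,
       summary = aggregate_associations(associations))
}

#' Table 1-style set families
#'
#' The default crossings of fixed parameters that generate the replication
#' families: the speed family crosses carrying capacity, handling time and
#' the two costs; the cost family crosses carrying capacity, maximum attack
#' rate, handling time and the prey adaptation speed.
#'
#' @param family `"speed"` or `"cost"`.
#' @param max_sets Optional cap on the number of sets (taken from the head
#'   of the crossing) for desk-scale runs.
#' @return A tibble of per-set overrides, one row per set.
#' @export
family_sets <- function(family = c("speed", "cost"), max_sets = NULL) {
  family <- match.arg(family)
  sets <- if (family == "speed") {
    tidyr::expand_grid(K = c(1, 1.5, 2), h = c(0.1, 1),
                       cx = c(2, 3, 4, 5), cy = c(2, 3, 4, 5))
  } else {
    tidyr::expand_grid(K = c(1, 1.5, 2), a0 = c(0.5, 0.75, 1, 1.25, 1.5, 1.75, 2),
                       h = c(1, 1.5, 2), Gx = c(1e-2, 10^-1.5))
  }
  if (!is.null(max_sets)) sets <- utils::head(sets, max_sets)
  sets
}
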