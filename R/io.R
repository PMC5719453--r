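#' Load a run configuration file
#'
#' Reads a YAML (or JSON) configuration with up to four blocks -- `model`,
#' `adaptation`, `sim` and `sweep` -- validates every key, and fills all
#' omitted values with the standard defaults. Unknown keys anywhere are
#' rejected with an error naming the offending key. An empty file yields
#' the full standard configuration.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A list of class `"coevo_config"` with elements `model`
#'   ([model_params()]), `adaptation` ([adaptation_params()]), `sim`
#'   ([sim_control()]) and `sweep` (list with `family`, `grid_size`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a key-value mapping", call. = FALSE)

  blocks <- c("model", "adaptation", "sim", "sweep")
  unknown <- setdiff(names(raw), blocks)
  if (length(unknown) > 0) {
    stop("unknown config block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  check_keys <- function(block, allowed) {
    bad <- setdiff(names(raw[[block]]), allowed)
    if (length(bad) > 0) {
      stop("unknown key(s) in `", block, "`: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  model_keys <- setdiff(names(formals(model_params)),
                        c("prey_tradeoff", "predator_tradeoff"))
  check_keys("model", model_keys)
  check_keys("adaptation", names(formals(adaptation_params)))
  check_keys("sim", names(formals(sim_control)))
  check_keys("sweep", c("family", "grid_size"))

  sim_args <- raw$sim
  if (!is.null(sim_args$init)) sim_args$init <- unlist(sim_args$init)
  sweep <- utils::modifyList(list(family = "speed", grid_size = 25),
                             as.list(raw$sweep))
  if (!sweep$family %in% c("speed", "cost")) {
    stop("`sweep$family` must be \"speed\" or \"cost\"", call. = FALSE)
  }
  cfg <- list(
    model = do.call(model_params, as.list(raw$model)),
    adaptation = do.call(adaptation_params, as.list(raw$adaptation)),
    sim = do.call(sim_control, as.list(sim_args)),
    sweep = sweep
  )
  structure(cfg, class = "coevo_config")
}

#' Write and read trajectory and component CSV files
#'
#' Plain CSV export of the package's tabular results. Values round-trip at
#' full double precision (shortest round-trip representation).
#'
#' @param traj,components,sweep The object to write.
#' @param path Output file path.
#' @return The input, invisibly (writers); a tibble (readers).
#' @name coevo_io
#' @export
write_trajectory <- function(traj, path) {
  out <- dplyr::select(traj,
                       dplyr::any_of(c("t", "x", "y", "u", "v", "x_eff")))
  readr::write_csv(format_doubles(out), path)
  invisible(traj)
}

# 17 significant digits: bit-faithful round trip for doubles
format_doubles <- function(df) {
  dplyr::mutate(tibble::as_tibble(df), dplyr::across(
    dplyr::where(is.double),
    function(z) ifelse(is.na(z), NA_character_, sprintf("%.17g", z))
  ))
}

#' @rdname coevo_io
#' @export
read_trajectory <- function(path) {
  # base strtod is correctly rounded, preserving the 17-digit round trip
  dat <- tibble::as_tibble(utils::read.csv(path))
  need <- c("t", "x", "y", "u", "v")
  if (!all(need %in% names(dat))) {
    stop("trajectory CSV must have columns t,x,y,u,v", call. = FALSE)
  }
  dat
}

#' @rdname coevo_io
#' @export
write_components <- function(components, path) {
  out <- dplyr::select(components, "t", dplyr::all_of(component_names()))
  readr::write_csv(format_doubles(out), path)
  invisible(components)
}

#' @rdname coevo_io
#' @export
write_sweep <- function(sweep, path) {
  readr::write_csv(format_doubles(sweep), path)
  invisible(sweep)
}
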