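#' Read and write trajectories
#'
#' Trajectories are stored as plain CSV, one row per particle per frame
#' (`time_s`, `cell_id`, `particle_index`, `x_um`, `y_um`, `k_e`), with a
#' JSON sidecar (`<file>.json`) holding the fully resolved configuration,
#' so any run can be re-analysed from disk. Positions are stored at 1e-6 um
#' precision.
#'
#' @param sim a `myxo_sim` (or a frame tibble).
#' @param file output CSV path.
#' @param config optional list written to the JSON sidecar.
#' @return `write_trajectory()` the file path, invisibly;
#'   `read_trajectory()` the frame tibble (with the sidecar, if present,
#'   attached as attribute `"config"`).
#' @export
write_trajectory <- function(sim, file, config = NULL) {
  frames <- if (inherits(sim, "myxo_sim")) sim$frames else sim
  frames <- dplyr::mutate(frames,
                          x_um = round(.data$x_um, 6),
                          y_um = round(.data$y_um, 6))
  readr::write_csv(frames, file)
  if (inherits(sim, "myxo_sim")) {
    meta <- c(list(mode = sim$mode,
                   duration_min = sim$duration_min,
                   record_every_s = sim$record_every_s,
                   params = unclass(sim$params)),
              config)
    jsonlite::write_json(meta, paste0(file, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (!is.null(config)) {
    jsonlite::write_json(config, paste0(file, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(file)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file) {
  frames <- readr::read_csv(
    file,
    col_types = readr::cols(
      time_s = readr::col_double(),
      cell_id = readr::col_integer(),
      particle_index = readr::col_integer(),
      x_um = readr::col_double(),
      y_um = readr::col_double(),
      k_e = readr::col_integer()
    )
  )
  sidecar <- paste0(file, ".json")
  if (file.exists(sidecar)) {
    attr(frames, "config") <- jsonlite::read_json(sidecar,
                                                  simplifyVector = TRUE)
  }
  frames
}

#' Run a configured simulation end to end
#'
#' Reads a YAML run configuration (or takes an equivalent list), builds the
#' scenario, runs the simulation, and writes `trajectory.csv` (+ JSON
#' sidecar with the resolved configuration), `log.csv` (collision and
#' guiding-pair counts per frame), and `summary.json` (final aggregate
#' table) into `out_dir`.
#'
#' Recognised configuration keys: every [model_params()] argument, plus
#' `scenario` (`random`, `dense_aligned`, `spiral`), `mode`, `density`,
#' `n_cells`, `duration_min`, `record_every_s`, and `seed`.
#'
#' @param config path to a YAML file, or a named list.
#' @param out_dir output directory, created if missing.
#' @return The `myxo_sim`, invisibly.
#' @export
run_simulation <- function(config, out_dir = ".") {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  par_names <- names(formals(model_params))
  params <- do.call(model_params, cfg[intersect(names(cfg), par_names)])
  scen <- cfg$scenario %||% "random"
  seed <- cfg$seed %||% 1L
  state <- switch(
    scen,
    random = random_configuration(params,
                                  density = cfg$density %||% 5e6,
                                  n_cells = cfg$n_cells, seed = seed),
    dense_aligned = dense_aligned_configuration(params,
                                                density = cfg$density %||% 4e7,
                                                n_cells = cfg$n_cells,
                                                seed = seed),
    spiral = spiral_configuration(params,
                                  n_cells = cfg$n_cells %||% 40),
    stop("unknown scenario '", scen, "'")
  )
  sim <- simulate_cells(state,
                        duration_min = cfg$duration_min %||% 10,
                        mode = cfg$mode %||% "none",
                        record_every_s = cfg$record_every_s %||% 30)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  resolved <- c(cfg[setdiff(names(cfg), par_names)],
                list(seed = seed, scenario = scen,
                     params = unclass(params)))
  write_trajectory(sim, file.path(out_dir, "trajectory.csv"),
                   config = resolved)
  readr::write_csv(sim$log, file.path(out_dir, "log.csv"))
  agg <- detect_aggregates(sim$final_state, params)
  jsonlite::write_json(
    list(n_cells = n_cells(sim$final_state),
         n_aggregates = max(agg$aggregate_id),
         aggregates = dplyr::distinct(
           agg, .data$aggregate_id, .data$size,
           .data$centroid_x_um, .data$centroid_y_um)),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
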