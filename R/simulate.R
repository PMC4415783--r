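#' Run the simulation
#'
#' Integrates a state forward with explicit overdamped (first-order)
#' dynamics: each particle moves by `force / gamma_particle * dt` per step,
#' positions wrapped into the periodic box. Forces per step are the
#' internal springs, the distributed engine, capsule collision response,
#' and - depending on `mode` - one of the short-range head-to-tail guiding
#' forces or the slime-trail field. Cells engaged in a head-to-tail guiding
#' pair have their reversal clock paused for that step.
#'
#' The run is fully deterministic given the initial state: repeated calls
#' produce bitwise-identical trajectories.
#'
#' @param state a [myxo_state()] from one of the scenario builders.
#' @param duration_min simulated duration, min.
#' @param mode `"none"`, `"adhesion"`, `"active_following"`,
#'   `"passive_following"`, or `"slime"`.
#' @param record_every_s cadence of recorded frames, s.
#' @param params parameter set; defaults to the one in `state`.
#' @param engine_mult optional per-cell engine force multiplier
#'   (diagnostic, e.g. to drive a leader cell above `v_b`).
#' @param pull_pn optional per-cell constant tangential force on the head
#'   particle, pN (diagnostic for the pulled-cell speed test).
#' @return A `myxo_sim` object: recorded `frames` and interaction `log`
#'   tibbles, the final state, and run metadata. `tidy()` returns the frame
#'   table, `glance()` a one-row run summary.
#' @examples
#' p <- model_params(domain = c(30, 30), dt = 3e-4)
#' st <- random_configuration(p, n_cells = 2, seed = 1)
#' sim <- simulate_cells(st, duration_min = 0.05, record_every_s = 1)
#' glance(sim)
#' @export
simulate_cells <- function(state, duration_min, mode = "none",
                           record_every_s = 30, params = state$params,
                           engine_mult = NULL, pull_pn = NULL) {
  stopifnot(inherits(state, "myxo_state"), duration_min >= 0)
  nc <- n_cells(state)
  np <- params$n_particles
  cp <- cpp_params(params, mode)
  n_steps <- round(duration_min * 60 / params$dt)
  record_every <- max(1L, round(record_every_s / params$dt))
  if (is.null(engine_mult)) engine_mult <- rep(1, nc)
  if (is.null(pull_pn)) pull_pn <- rep(0, nc)
  stopifnot(length(engine_mult) == nc, length(pull_pn) == nc)
  grid <- state$slime
  if (is.null(grid)) grid <- slime_grid(params$domain, params$dx_slime)
  res <- cpp_run(state$pos, state$ke, state$phase, cp,
                 as.integer(n_steps), as.integer(record_every),
                 as.numeric(engine_mult), as.numeric(pull_pn),
                 grid$sx, grid$sy)
  n_frames <- res$n_frames
  traj <- res$traj # dim (2, N, frames)
  N <- nc * np
  frames <- tibble::tibble(
    time_s = rep(res$times[seq_len(n_frames)], each = N),
    cell_id = rep(rep(seq_len(nc) - 1L, each = np), n_frames),
    particle_index = rep(rep(seq_len(np) - 1L, nc), n_frames),
    x_um = as.vector(traj[1, , seq_len(n_frames)]),
    y_um = as.vector(traj[2, , seq_len(n_frames)]),
    k_e = rep(as.integer(t(res$ke_frames[seq_len(n_frames), , drop = FALSE])),
              each = np)
  )
  log <- tibble::tibble(
    time_s = res$log[seq_len(n_frames), 1],
    n_collisions = as.integer(res$log[seq_len(n_frames), 2]),
    n_guiding_pairs = as.integer(res$log[seq_len(n_frames), 3])
  )
  final_slime <- if (mode == "slime") {
    structure(list(sx = res$sx, sy = res$sy, dx = params$dx_slime),
              class = "myxo_slime")
  } else {
    state$slime
  }
  final_state <- myxo_state(res$pos, res$ke, params, phase = res$phase,
                            time_s = state$time_s + n_steps * params$dt,
                            slime = final_slime)
  structure(
    list(frames = frames, log = log, final_state = final_state,
         params = params, mode = mode, duration_min = duration_min,
         record_every_s = record_every * params$dt, n_frames = n_frames),
    class = "myxo_sim"
  )
}

#' @export
print.myxo_sim <- function(x, ...) {
  cat(sprintf("<myxo_sim> mode = %s, %d cells, %.4g simulated min, %d frames\n",
              x$mode, n_cells(x$final_state), x$duration_min, x$n_frames))
  invisible(x)
}

#' @export
tidy.myxo_sim <- function(x, ...) x$frames

#' @export
glance.myxo_sim <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    n_cells = n_cells(x$final_state),
    duration_min = x$duration_min,
    n_frames = x$n_frames,
    dt_s = x$params$dt,
    mean_guiding_pairs = mean(x$log$n_guiding_pairs),
    mean_collisions = mean(x$log$n_collisions)
  )
}

#' Extract one recorded frame as a state
#'
#' @param sim a `myxo_sim`.
#' @param time_s frame time, s; the nearest recorded frame is used.
#' @return A [myxo_state()] at that frame.
#' @export
frame_state <- function(sim, time_s) {
  tt <- unique(sim$frames$time_s)
  t0 <- tt[which.min(abs(tt - time_s))]
  fr <- sim$frames[sim$frames$time_s == t0, ]
  fr <- fr[order(fr$cell_id, fr$particle_index), ]
  np <- sim$params$n_particles
  ke <- fr$k_e[seq(1, nrow(fr), by = np)]
  myxo_state(cbind(fr$x_um, fr$y_um), ke, sim$params, time_s = t0,
             slime = if (t0 == max(tt)) sim$final_state$slime else NULL)
}
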