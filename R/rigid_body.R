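#' Continuum rigid-body predictions for rotating circular aggregates
#'
#' Treat a stable rotating circular aggregate as a uniform disk of motile
#' material rotating rigidly at angular speed `omega`. Each area element
#' carries an engine force density along its local velocity and a drag
#' density proportional to local speed; free gliding fixes the ratio of
#' the two densities, so the engine density equals `gamma * v_eff` where
#' `v_eff` is the speed at which propulsion and drag balance. Zero net
#' torque about the center,
#' \deqn{\int_0^R (\gamma v_{eff} - \gamma \omega r)\, r \cdot 2\pi r\, dr = 0,}
#' gives `omega = (4/3) v_eff / R` and hence an edge speed
#' `v(R) = omega R = (4/3) v_eff` independent of the aggregate radius.
#'
#' Under head-to-tail *adhesion* the guiding forces are internal
#' action-reaction pairs and contribute no net torque, so `v_eff = v_b` and
#' the edge speed is `(4/3) v_b`. Under *active following* each follower
#' gains up to `F_g_max` of external tangential force on top of its engine,
#' so `v_eff = v_b (F_engine + F_g_max) / F_engine`; with a 100 pN engine
#' and 200 pN guiding this is `3 v_b`, an edge speed of `4 v_b`.
#'
#' @param mode `"adhesion"` or `"active_following"` (`"active"` accepted).
#' @param v_b free gliding speed, um/min.
#' @param F_engine engine force, pN.
#' @param F_g_max maximum guiding force, pN (ignored for adhesion).
#' @return `predict_edge_speed()`: the edge speed, um/min.
#' @examples
#' predict_edge_speed("adhesion")            # (4/3) * 4  = 5.33 um/min
#' predict_edge_speed("active_following")    # 4 * 4      = 16 um/min
#' max_pulled_speed()                        # 3 * 4      = 12 um/min
#' @export
predict_edge_speed <- function(mode = c("adhesion", "active_following",
                                        "active"),
                               v_b = 4, F_engine = 100, F_g_max = 200) {
  mode <- match.arg(mode)
  if (v_b <= 0 || F_engine <= 0 || F_g_max < 0) {
    stop("v_b and F_engine must be positive, F_g_max non-negative")
  }
  v_eff <- if (mode == "adhesion") v_b
           else v_b * (F_engine + F_g_max) / F_engine
  (4 / 3) * v_eff
}

#' @rdname predict_edge_speed
#' @param R aggregate radius, um.
#' @return `predict_angular_speed()`: the angular speed `omega`, 1/min
#'   (edge speed divided by `R`; strictly decreasing in `R`).
#' @export
predict_angular_speed <- function(mode = c("adhesion", "active_following",
                                           "active"),
                                  R, v_b = 4, F_engine = 100, F_g_max = 200) {
  if (any(R <= 0)) stop("R must be positive")
  predict_edge_speed(mode, v_b, F_engine, F_g_max) / R
}

#' @rdname predict_edge_speed
#' @return `max_pulled_speed()`: the maximal steady speed of a single cell
#'   pulled tangentially at the full guiding force under overdamped drag,
#'   `v_b (F_engine + F_g_max) / F_engine`, um/min.
#' @export
max_pulled_speed <- function(F_engine = 100, F_g_max = 200, v_b = 4) {
  if (v_b <= 0 || F_engine <= 0 || F_g_max < 0) {
    stop("v_b and F_engine must be positive, F_g_max non-negative")
  }
  v_b * (F_engine + F_g_max) / F_engine
}

#' Rigid-body prediction table
#'
#' @param modes guiding modes to tabulate.
#' @param R aggregate radii, um.
#' @inheritParams predict_edge_speed
#' @return A tibble with one row per mode and radius: `mode`,
#'   `v_free_effective_um_min`, `R_um`, `omega_per_min`, `v_edge_um_min`.
#' @export
rigid_body_predictions <- function(modes = c("adhesion", "active_following"),
                                   R = 10, v_b = 4, F_engine = 100,
                                   F_g_max = 200) {
  grid <- tidyr::expand_grid(mode = modes, R_um = R)
  dplyr::mutate(
    grid,
    v_free_effective_um_min = ifelse(
      .data$mode == "adhesion", v_b, v_b * (F_engine + F_g_max) / F_engine),
    v_edge_um_min = (4 / 3) * .data$v_free_effective_um_min,
    omega_per_min = .data$v_edge_um_min / .data$R_um
  )
}
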