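#' Model parameters
#'
#' Assembles and validates the full parameter set of the mechanical model.
#' Values are given in the units customary for the system (micrometres,
#' minutes, piconewtons, SI spring constants); internally the simulation
#' converts everything to a um/s/pN system.
#'
#' The drag coefficient is not a free parameter: overdamped free gliding at
#' the equilibrium speed `v_b` fixes `gamma_cell = F_engine / v_b`, and each
#' of the `n_particles` particles carries an equal share.
#'
#' @param W cell width (capsule diameter), um.
#' @param L cell rest length, um.
#' @param n_particles particles per cell; the chain has `n_particles - 1`
#'   segments of rest length `L / (n_particles - 1)`.
#' @param k_lin linear (stretching) spring constant, N/m. Chosen at least
#'   ten times `k_c` so that cells are effectively inextensible relative to
#'   contact forces.
#' @param k_a angular spring constant, N*m. The flexural rigidity of the
#'   discretised rod is approximately `k_a * seg_len`; the default 1e-17 N*m
#'   corresponds to a "flexible" cell (B ~ 6e-24 J*m).
#' @param k_c collision spring constant, N/m (0.01 for low-density runs,
#'   0.002 for crowded high-density runs).
#' @param F_engine total gliding engine force per cell, pN, distributed
#'   uniformly along the body.
#' @param v_b free gliding speed, um/min.
#' @param T_R reversal period, min; `Inf` for non-reversing cells.
#' @param F_g_max maximum short-range guiding force, pN (200 by default,
#'   100 for "weak guiding").
#' @param d_g guiding range: maximum surface gap at which head-to-tail
#'   guiding acts, um (half the cell width).
#' @param F_s_max maximum slime-trail steering force, pN.
#' @param dx_slime slime grid spacing, um.
#' @param dt integration time step, s. Two guards apply: the collision
#'   criterion `k_c * dt / gamma_particle < 0.2`, and the explicit-Euler
#'   stability limit of the stiffest chain mode
#'   (`4 * k_lin * dt / gamma_particle < 1.8`). The runtime integrator
#'   additionally aborts if any particle moves more than `0.1 * W` in one
#'   step.
#' @param domain periodic box side lengths, um (length-2 vector).
#'
#' @return An object of class `myxo_params` (a validated named list).
#' @examples
#' p <- model_params()
#' p$gamma_cell_pn_min_um # 25 pN min/um: 100 pN at 4 um/min
#' @export
model_params <- function(W = 0.5,
                         L = 5.2,
                         n_particles = 9,
                         k_lin = 0.1,
                         k_a = 1e-17,
                         k_c = 0.01,
                         F_engine = 100,
                         v_b = 4,
                         T_R = Inf,
                         F_g_max = 200,
                         d_g = 0.25,
                         F_s_max = 200,
                         dx_slime = 0.25,
                         dt = 5e-4,
                         domain = c(100, 100)) {
  stopifnot(W > 0, L > 0, n_particles >= 3, d_g > 0,
            k_lin > 0, k_a >= 0, k_c > 0, F_engine > 0, v_b > 0,
            F_g_max >= 0, F_s_max >= 0, dx_slime > 0, dt > 0,
            length(domain) == 2, all(domain > 0), T_R > 0)
  seg_len <- L / (n_particles - 1)
  gamma_cell <- F_engine / v_b            # pN min / um
  gamma_particle <- gamma_cell * 60 / n_particles  # pN s / um
  # step-size guards for the explicit update: the collision-spring criterion
  # k_c*dt/gamma_particle < 0.2, plus the hard Euler stability limit of the
  # stiffest chain mode (eigenvalue ~ 4*k_lin/gamma_particle), with margin
  if (k_c * 1e6 * dt / gamma_particle >= 0.2) {
    stop("dt = ", dt, " s too large for collision stiffness ", k_c,
         " N/m: k_c*dt/gamma_particle must be < 0.2 (reduce dt)")
  }
  if (4 * max(k_lin, k_c) * 1e6 * dt / gamma_particle >= 1.8) {
    stop("dt = ", dt, " s unstable for linear stiffness ", k_lin,
         " N/m (4*k*dt/gamma_particle must stay below 1.8); reduce dt")
  }
  p <- list(
    W = W, L = L, n_particles = as.integer(n_particles), seg_len = seg_len,
    k_lin = k_lin, k_a = k_a, k_c = k_c,
    F_engine = F_engine, v_b = v_b,
    gamma_cell_pn_min_um = gamma_cell,
    gamma_particle_pn_s_um = gamma_particle,
    T_R = T_R, F_g_max = F_g_max, d_g = d_g,
    F_s_max = F_s_max, dx_slime = dx_slime,
    dt = dt, domain = as.numeric(domain)
  )
  class(p) <- "myxo_params"
  p
}

#' @export
print.myxo_params <- function(x, ...) {
  cat("<myxo_params>\n")
  cat(sprintf("  cell: L = %.3g um, W = %.3g um, %d particles (seg %.3g um)\n",
              x$L, x$W, x$n_particles, x$seg_len))
  cat(sprintf("  springs: k_lin = %.3g N/m, k_a = %.3g N*m, k_c = %.3g N/m\n",
              x$k_lin, x$k_a, x$k_c))
  cat(sprintf("  engine: %.4g pN -> v_b = %.4g um/min; T_R = %s min\n",
              x$F_engine, x$v_b, format(x$T_R)))
  cat(sprintf("  guiding: F_g_max = %.4g pN over d_g = %.3g um; slime %.4g pN on %.3g um grid\n",
              x$F_g_max, x$d_g, x$F_s_max, x$dx_slime))
  cat(sprintf("  dt = %.3g s, domain %.4g x %.4g um\n",
              x$dt, x$domain[1], x$domain[2]))
  invisible(x)
}

# internal-unit parameter list handed to the C++ core
# (pN, um, s; mode: 0 none, 1 passive, 2 active, 3 adhesion, 4 slime)
cpp_params <- function(params, mode = "none") {
  stopifnot(inherits(params, "myxo_params"))
  list(
    guide_all = if (isTRUE(params$guide_all)) 1L else 0L,
    n_particles = params$n_particles,
    W = params$W,
    seg_len = params$seg_len,
    k_lin = params$k_lin * 1e6,
    k_a = params$k_a * 1e18,
    k_c = params$k_c * 1e6,
    F_engine = params$F_engine,
    gamma_particle = params$gamma_particle_pn_s_um,
    dt = params$dt,
    Lx = params$domain[1],
    Ly = params$domain[2],
    d_g = params$d_g,
    F_g_max = params$F_g_max,
    F_s_max = params$F_s_max,
    dx_slime = params$dx_slime,
    T_R = params$T_R,
    mode = mode_code(mode)
  )
}

mode_code <- function(mode) {
  modes <- c(none = 0L, passive_following = 1L, active_following = 2L,
             adhesion = 3L, slime = 4L)
  if (!mode %in% names(modes)) {
    stop("unknown guiding mode '", mode, "'; use one of: ",
         paste(names(modes), collapse = ", "))
  }
  modes[[mode]]
}
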