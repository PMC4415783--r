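#' Internal spring and engine forces of a single cell
#'
#' These evaluate one force source on one cell, mainly for inspection and
#' testing; the simulation loop evaluates the same compiled kernels.
#'
#' `linear_spring_forces()` applies Hookean forces along each segment with
#' magnitude `k_lin * (length - seg_len)`; `angular_spring_forces()` is the
#' exact negative gradient of the discrete bending energy
#' `sum 1/2 k_a theta_i^2` over interior joints, where `theta_i` is the
#' local deviation from straightness; `engine_forces()` distributes the
#' total engine force uniformly over the particles, each share directed
#' along the local tangent in the gliding direction set by the polarity.
#'
#' @param cell particle positions of one cell: an `n x 2` matrix or a data
#'   frame with `x_um`/`y_um` columns (um).
#' @param params a [model_params()] object.
#' @param k_e cell polarity, `+1` or `-1`.
#' @return A tibble with `particle_index`, `fx_pn`, `fy_pn` (forces in pN).
#' @examples
#' p <- model_params()
#' cell <- cbind(seq(0, p$L, length.out = p$n_particles), 0)
#' engine_forces(cell, p) # 100 pN total along the axis
#' @export
linear_spring_forces <- function(cell, params) {
  m <- as_cell_matrix(cell)
  F <- cpp_linear_forces(m, params$k_lin * 1e6, params$seg_len,
                         params$domain[1], params$domain[2])
  force_tibble(F)
}

#' @rdname linear_spring_forces
#' @export
angular_spring_forces <- function(cell, params) {
  m <- as_cell_matrix(cell)
  F <- cpp_angular_forces(m, params$k_a * 1e18,
                          params$domain[1], params$domain[2])
  force_tibble(F)
}

#' @rdname linear_spring_forces
#' @export
engine_forces <- function(cell, params, k_e = 1L) {
  stopifnot(k_e %in% c(-1L, 1L))
  m <- as_cell_matrix(cell)
  F <- cpp_engine_forces(m, as.integer(k_e), params$F_engine,
                         params$domain[1], params$domain[2])
  force_tibble(F)
}

#' Advance the reversal clock of one cell
#'
#' Cells switch their leading and trailing poles with period `T_R`. While a
#' cell is engaged in a head-to-tail guiding interaction the reversal is
#' suppressed: the clock is paused, not reset, so a cell that disengages
#' resumes where it left off.
#'
#' @param k_e current polarity (+1/-1).
#' @param phase_min elapsed time since the last reversal, min.
#' @param dt_min time increment, min.
#' @param suppressed is the cell currently engaged head-to-tail?
#' @param T_R reversal period, min (`Inf` = never reverse).
#' @return A tibble with the updated `k_e`, `phase_min`, and whether a
#'   reversal `fired`.
#' @export
advance_reversal <- function(k_e, phase_min, dt_min, suppressed = FALSE,
                             T_R = Inf) {
  stopifnot(k_e %in% c(-1L, 1L), phase_min >= 0, dt_min >= 0)
  fired <- FALSE
  if (!suppressed) {
    phase_min <- phase_min + dt_min
    if (is.finite(T_R) && phase_min >= T_R) {
      k_e <- -k_e
      phase_min <- 0
      fired <- TRUE
    }
  }
  tibble::tibble(k_e = as.integer(k_e), phase_min = phase_min, fired = fired)
}
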