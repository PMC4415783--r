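#' Slime-trail grid
#'
#' Long-range guiding field: a periodic square lattice covering the domain,
#' each element holding either a unit direction vector (a slime trail) or
#' nothing. Cells deposit a trail under their rear particle each step, and
#' the trail steers the head of any cell gliding over it.
#'
#' @param domain periodic box sides, um. Sides are assumed divisible by
#'   `dx` (the constructor enforces this within rounding).
#' @param dx grid spacing, um.
#' @return A `myxo_slime` list with matrices `sx`, `sy` (zero = no trail)
#'   and the spacing `dx`.
#' @export
slime_grid <- function(domain, dx = 0.25) {
  nx <- round(domain[1] / dx)
  ny <- round(domain[2] / dx)
  if (abs(nx * dx - domain[1]) > 1e-9 || abs(ny * dx - domain[2]) > 1e-9) {
    stop("domain sides must be divisible by the slime grid spacing dx")
  }
  structure(list(sx = matrix(0, nx, ny), sy = matrix(0, nx, ny), dx = dx),
            class = "myxo_slime")
}

#' Deposit slime under cell rears
#'
#' Writes the unit tangent at each cell's rear particle into the grid
#' element below it, overriding any previous value. Cells are processed in
#' ascending id order, so simultaneous deposits into one element resolve
#' deterministically (the highest id wins).
#'
#' @param state a [myxo_state()].
#' @param grid a [slime_grid()]; defaults to the grid carried by the state.
#' @param params parameter set.
#' @return The updated grid.
#' @export
deposit_slime <- function(state, grid = state$slime, params = state$params) {
  if (is.null(grid)) grid <- slime_grid(params$domain, params$dx_slime)
  res <- cpp_deposit_slime(state$pos, state$ke, cpp_params(params, "slime"),
                           grid$sx, grid$sy)
  grid$sx <- res$sx
  grid$sy <- res$sy
  grid
}

#' Slime steering force on cell heads
#'
#' For each cell whose head particle sits over a marked grid element with
#' trail direction `s`, the force `sgn(o . s) * F_s_max * s` (with `o` the
#' head orientation and `sgn(0) := +1`) is projected onto the body normal
#' and applied to the head particle. The tangential component is exactly
#' zero, so the trail reorients the tip without changing the cell's speed,
#' and the sign convention turns the cell by an acute angle: trails are
#' bidirectional.
#'
#' @inheritParams deposit_slime
#' @return A tibble with `cell_id`, `particle_index`, `fx_pn`, `fy_pn`.
#' @export
slime_force <- function(state, grid = state$slime, params = state$params) {
  if (is.null(grid)) stop("state has no slime grid; build one with slime_grid()")
  F <- cpp_slime_force(state$pos, state$ke, cpp_params(params, "slime"),
                       grid$sx, grid$sy)
  state_force_tibble(F, params)
}

#' Tidy the marked elements of a slime grid
#'
#' @param x a `myxo_slime` grid.
#' @param ... unused.
#' @return A tibble with 0-based element indices `ix`, `iy` and the trail
#'   direction `sx`, `sy` for every marked element.
#' @export
tidy.myxo_slime <- function(x, ...) {
  idx <- which(x$sx != 0 | x$sy != 0, arr.ind = TRUE)
  dimnames(idx) <- NULL
  tibble::tibble(ix = idx[, 1] - 1L, iy = idx[, 2] - 1L,
                 sx = x$sx[idx], sy = x$sy[idx])
}
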