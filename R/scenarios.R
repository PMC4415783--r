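#' Initial configurations
#'
#' Builders for the three study configurations: a random low-density
#' population, a densely packed aligned population, and a pre-arranged
#' spiral aggregate. All are deterministic given `seed`.
#'
#' `random_configuration()` places straight cells uniformly at random
#' (positions and orientations) in the periodic box, rejection-sampling so
#' that no two cell axes come closer than the cell width `W`. The cell
#' count defaults to `round(density * area)`.
#'
#' @param params a [model_params()] object; its `domain` sets the box.
#' @param density areal cell density, cells/cm^2 (5e6 is the low-density
#'   condition, 4e7 the high-density one).
#' @param n_cells explicit cell count, overriding the density-derived one.
#' @param seed RNG seed for reproducible placement.
#' @param max_tries placement attempts per cell before giving up.
#' @return A [myxo_state()].
#' @examples
#' p <- model_params(domain = c(40, 40))
#' st <- random_configuration(p, n_cells = 10, seed = 1)
#' n_cells(st)
#' @export
random_configuration <- function(params, density = 5e6, n_cells = NULL,
                                 seed = NULL, max_tries = 2000) {
  if (!is.null(seed)) set.seed(seed)
  dom <- params$domain
  if (is.null(n_cells)) {
    n_cells <- round(density * dom[1] * dom[2] / 1e8) # um^2 per cm^2
  }
  if (n_cells < 1) stop("density and domain give no cells to place")
  axes <- matrix(NA_real_, n_cells, 4) # whole-cell axis segments
  half <- params$L / 2
  for (i in seq_len(n_cells)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      ctr <- stats::runif(2) * dom
      ang <- stats::runif(1, 0, 2 * pi)
      ax <- c(ctr + half * c(cos(ang), sin(ang)),
              ctr - half * c(cos(ang), sin(ang)))
      ok <- TRUE
      if (i > 1) {
        for (j in seq_len(i - 1)) {
          v <- cpp_seg_closest(ax, axes[j, ], dom[1], dom[2], TRUE)
          if (v[["d"]] < params$W) { ok <- FALSE; break }
        }
      }
      if (ok) {
        axes[i, ] <- ax
        placed <- TRUE
        attr(axes, paste0("ang", i)) <- ang
        break
      }
    }
    if (!placed) {
      stop("could not place cell ", i, " after ", max_tries,
           " attempts; use a larger domain or lower density")
    }
  }
  pos <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
    ang <- attr(axes, paste0("ang", i))
    ctr <- (axes[i, 1:2] + axes[i, 3:4]) / 2
    straight_cell(ctr, ang, params)
  }))
  myxo_state(pos, rep(1L, n_cells), params)
}

#' @describeIn random_configuration Densely packed rows of aligned cells
#'   with random gliding directions (the high-density condition). Cells
#'   share a common axis along x; the row pitch follows from the density.
#' @param axial_gap end-to-end spacing between consecutive cells in a row,
#'   um.
#' @export
dense_aligned_configuration <- function(params, density = 4e7, n_cells = NULL,
                                        seed = NULL, axial_gap = 0.3) {
  if (!is.null(seed)) set.seed(seed)
  dom <- params$domain
  if (is.null(n_cells)) n_cells <- round(density * dom[1] * dom[2] / 1e8)
  if (n_cells < 1) stop("density and domain give no cells to place")
  slot <- params$L + axial_gap
  per_row <- floor(dom[1] / slot)
  if (per_row < 1) stop("domain too small for the cell length")
  rows <- ceiling(n_cells / per_row)
  pitch <- dom[2] / rows
  if (pitch < 0.5 * params$W) {
    stop("domain too small for ", n_cells, " cells: row pitch ",
         signif(pitch, 3), " um is below W/2")
  }
  ke <- sample(c(-1L, 1L), n_cells, replace = TRUE)
  pos <- do.call(rbind, lapply(seq_len(n_cells) - 1L, function(i) {
    row <- i %/% per_row
    col <- i %% per_row
    ctr <- c((col + 0.5) * slot, (row + 0.5) * pitch)
    straight_cell(ctr, 0, params)
  }))
  myxo_state(pos, ke, params)
}

#' @describeIn random_configuration Cells laid head-to-tail along an
#'   Archimedean spiral, bent to the local curvature, all circulating the
#'   same way; consecutive cells are separated by a surface gap inside the
#'   guiding range, so the whole aggregate is one guiding chain from the
#'   start. Heads point inward (each trailing cell sits slightly farther
#'   from the rotation axis than its leader).
#' @param pitch radial spacing between spiral turns, um; must be at least
#'   `W` so that turns do not overlap.
#' @param gap surface gap between a follower's head and its leader's tail,
#'   um; must lie in `(0, d_g)`.
#' @param r0 inner spiral radius, um.
#' @param center spiral center, um; defaults to the domain center.
#' @export
spiral_configuration <- function(params, n_cells, pitch = 1.1 * params$W,
                                 gap = params$d_g / 2, r0 = 2,
                                 center = params$domain / 2) {
  if (n_cells < 0) stop("n_cells must be >= 0")
  if (pitch < params$W) stop("spiral pitch must be at least the cell width W")
  if (gap <= 0 || gap >= params$d_g) stop("gap must lie in (0, d_g)")
  if (n_cells == 0) {
    return(myxo_state(matrix(numeric(0), 0, 2), integer(0), params))
  }
  b <- pitch / (2 * pi)
  # arc-length table of r = b * phi, from the inner radius outward
  phi0 <- r0 / b
  s_cell <- params$L + params$W + gap # head-to-head arc spacing
  s_total <- n_cells * s_cell + params$L
  phi_hi <- sqrt(phi0^2 + 2 * (s_total + 2) / b) # ds = b*sqrt(1+phi^2) dphi
  phi <- seq(phi0, phi_hi, length.out = 20000)
  ds <- b * sqrt(1 + phi^2)
  s <- c(0, cumsum((ds[-1] + ds[-length(phi)]) / 2 * diff(phi)))
  phi_at <- stats::approxfun(s, phi)
  np <- params$n_particles
  pos <- do.call(rbind, lapply(seq_len(n_cells) - 1L, function(k) {
    sp <- k * s_cell + (seq_len(np) - 1) * params$seg_len
    ph <- phi_at(sp)
    cbind(center[1] + b * ph * cos(ph), center[2] + b * ph * sin(ph))
  }))
  # particle 0 of each cell is the innermost: with ke = +1 it is the head,
  # and gliding (-tangent) points inward along the spiral
  myxo_state(pos, rep(1L, n_cells), params)
}
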