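#' Construct a simulation state
#'
#' A `myxo_state` bundles everything the integrator steps: particle
#' positions of all cells, per-cell polarity and reversal clocks, the slime
#' grid (when present), the simulation time, and the parameter set.
#'
#' @param pos numeric matrix `(n_cells * n_particles) x 2` of particle
#'   positions in um, cells stored as consecutive row blocks. Particle 0 of
#'   a cell is its head when the cell's polarity is `+1`.
#' @param ke integer vector of per-cell polarities, each `+1` or `-1`.
#' @param params a [model_params()] object.
#' @param phase per-cell elapsed time since the last reversal, min.
#' @param time_s simulation time, s.
#' @param slime optional slime grid from [slime_grid()].
#' @return An object of class `myxo_state`.
#' @export
myxo_state <- function(pos, ke, params, phase = NULL, time_s = 0,
                       slime = NULL) {
  stopifnot(inherits(params, "myxo_params"), is.matrix(pos), ncol(pos) == 2)
  np <- params$n_particles
  if (nrow(pos) %% np != 0) stop("nrow(pos) is not a multiple of n_particles")
  nc <- nrow(pos) / np
  ke <- as.integer(ke)
  if (length(ke) != nc || !all(ke %in% c(-1L, 1L))) {
    stop("ke must be a vector of +1/-1, one per cell")
  }
  if (is.null(phase)) phase <- numeric(nc)
  pos[, 1] <- pos[, 1] %% params$domain[1]
  pos[, 2] <- pos[, 2] %% params$domain[2]
  structure(
    list(pos = pos, ke = ke, phase = as.numeric(phase), time_s = time_s,
         slime = slime, params = params),
    class = "myxo_state"
  )
}

#' Number of cells in a state
#' @param state a `myxo_state`.
#' @return integer cell count.
#' @export
n_cells <- function(state) {
  stopifnot(inherits(state, "myxo_state"))
  nrow(state$pos) / state$params$n_particles
}

#' @export
print.myxo_state <- function(x, ...) {
  cat(sprintf("<myxo_state> %d cells x %d particles, t = %.4g s, domain %.4g x %.4g um\n",
              n_cells(x), x$params$n_particles, x$time_s,
              x$params$domain[1], x$params$domain[2]))
  if (!is.null(x$slime)) {
    cat(sprintf("  slime grid %d x %d (dx = %.3g um), %d marked elements\n",
                nrow(x$slime$sx), ncol(x$slime$sx), x$slime$dx,
                sum(x$slime$sx != 0 | x$slime$sy != 0)))
  }
  invisible(x)
}

#' Tidy a state into a particle table
#'
#' @param x a `myxo_state`.
#' @param ... unused.
#' @return A tibble with one row per particle: `cell_id` (0-based),
#'   `particle_index` (0-based along the chain), `x_um`, `y_um`, `k_e`.
#' @export
tidy.myxo_state <- function(x, ...) {
  np <- x$params$n_particles
  nc <- n_cells(x)
  tibble::tibble(
    cell_id = rep(seq_len(nc) - 1L, each = np),
    particle_index = rep(seq_len(np) - 1L, nc),
    x_um = x$pos[, 1],
    y_um = x$pos[, 2],
    k_e = rep(x$ke, each = np)
  )
}

#' @export
as.data.frame.myxo_state <- function(x, ...) as.data.frame(tidy(x))

# positions of one cell (0-based id) as an n_particles x 2 matrix
cell_matrix <- function(state, cell_id) {
  np <- state$params$n_particles
  state$pos[cell_id * np + seq_len(np), , drop = FALSE]
}

# head/tail particle row indices (1-based into state$pos)
head_index <- function(state, cell_id) {
  np <- state$params$n_particles
  cell_id * np + if (state$ke[cell_id + 1] == 1L) 1L else np
}
tail_index <- function(state, cell_id) {
  np <- state$params$n_particles
  cell_id * np + if (state$ke[cell_id + 1] == 1L) np else 1L
}

# straight cell particle block: center (x, y), axis angle, head at the
# "front" end so that gliding with ke = +1 moves toward +axis
straight_cell <- function(center, angle, params) {
  np <- params$n_particles
  s <- (seq_len(np) - 1) * params$seg_len - params$L / 2
  # particle 0 (head for ke = +1) sits at +L/2 along the axis: the gliding
  # direction -t points along +axis
  s <- rev(s)
  cbind(center[1] + s * cos(angle), center[2] + s * sin(angle))
}

# accept a tibble/data.frame with x/y columns or a plain matrix
as_cell_matrix <- function(cell) {
  if (is.matrix(cell)) return(cell)
  df <- as.data.frame(cell)
  cols <- intersect(c("x_um", "y_um"), names(df))
  if (length(cols) == 2) return(as.matrix(df[, cols]))
  cols <- intersect(c("x", "y"), names(df))
  if (length(cols) == 2) return(as.matrix(df[, cols]))
  stop("cell must be a matrix or a data frame with x_um/y_um (or x/y) columns")
}

force_tibble <- function(F) {
  tibble::tibble(particle_index = seq_len(nrow(F)) - 1L,
                 fx_pn = F[, 1], fy_pn = F[, 2])
}
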