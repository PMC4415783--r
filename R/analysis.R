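#' Per-segment speeds from a trajectory
#'
#' Speed of a line segment is the average speed of its two endpoint
#' particles. Particle speeds are minimum-image displacements between
#' frames separated by (approximately) `window_min`, divided by the actual
#' frame interval; a window of a minute smooths integrator noise and
#' matches the usual um/min colour scales.
#'
#' @param frames a frame tibble (from `tidy()` on a `myxo_sim`, or a
#'   `myxo_sim` itself) with `time_s`, `cell_id`, `particle_index`,
#'   `x_um`, `y_um`.
#' @param params a [model_params()] object (for the periodic domain and
#'   chain layout). Defaults to the parameter set of a `myxo_sim` input.
#' @param window_min measurement window, min.
#' @return A tibble with `time_s` (window start), `cell_id`,
#'   `segment_index`, `speed_um_min`.
#' @export
segment_speeds <- function(frames, params = NULL, window_min = 1) {
  if (inherits(frames, "myxo_sim")) {
    if (is.null(params)) params <- frames$params
    frames <- frames$frames
  }
  if (is.null(params)) stop("params must be supplied with a plain frame table")
  if (window_min <= 0) stop("window_min must be positive")
  xm <- frame_matrices(frames, params)
  tt <- xm$times
  if (length(tt) < 2) stop("need at least two frames")
  cadence <- stats::median(diff(tt))
  lag <- max(1L, round(window_min * 60 / cadence))
  if (lag >= length(tt)) lag <- length(tt) - 1L
  dom <- params$domain
  np <- params$n_particles
  nc <- xm$n_cells
  out <- vector("list", length(tt) - lag)
  for (i in seq_len(length(tt) - lag)) {
    dt_min <- (tt[i + lag] - tt[i]) / 60
    dx <- mi_vec(xm$x[, i + lag] - xm$x[, i], dom[1])
    dy <- mi_vec(xm$y[, i + lag] - xm$y[, i], dom[2])
    sp <- sqrt(dx^2 + dy^2) / dt_min # per-particle, um/min
    m <- matrix(sp, nrow = np)
    seg <- (m[-np, , drop = FALSE] + m[-1, , drop = FALSE]) / 2
    out[[i]] <- tibble::tibble(
      time_s = tt[i],
      cell_id = rep(seq_len(nc) - 1L, each = np - 1L),
      segment_index = rep(seq_len(np - 1L) - 1L, nc),
      speed_um_min = as.vector(seg)
    )
  }
  dplyr::bind_rows(out)
}

#' Collision strain energies
#'
#' For every colliding segment pair (axis distance `d < W`) the potential
#' energy of the collision spring, `1/2 k_c (d - W)^2`, is computed and
#' half of it booked to each of the two segments involved. Segments not in
#' any collision carry zero.
#'
#' @param state a [myxo_state()].
#' @param params parameter set.
#' @return A tibble with `cell_id`, `segment_index`, `energy_J` for every
#'   segment; the total over all colliding pairs is attached as attribute
#'   `"total_J"`.
#' @export
strain_energies <- function(state, params = state$params) {
  res <- cpp_find_interactions(state$pos, state$ke, cpp_params(params, "none"))
  cm <- res$contacts
  nseg <- params$n_particles - 1L
  nc <- n_cells(state)
  e <- numeric(nc * nseg)
  total <- 0
  if (nrow(cm) > 0) {
    # pair energy in pN*um (1 pN*um = 1e-18 J)
    pair_e <- 0.5 * (params$k_c * 1e6) * (cm[, 5] - params$W)^2
    for (k in seq_len(nrow(cm))) {
      e[cm[k, 1] + 1] <- e[cm[k, 1] + 1] + pair_e[k] / 2
      e[cm[k, 2] + 1] <- e[cm[k, 2] + 1] + pair_e[k] / 2
    }
    total <- sum(pair_e)
  }
  out <- tibble::tibble(
    cell_id = rep(seq_len(nc) - 1L, each = nseg),
    segment_index = rep(seq_len(nseg) - 1L, nc),
    energy_J = e * 1e-18
  )
  attr(out, "total_J") <- total * 1e-18
  out
}

#' Detect cell aggregates
#'
#' Connected components of the proximity graph in which two cells are
#' linked when any of their segments come closer than `W + d_g` (i.e. they
#' touch or sit within guiding range).
#'
#' @param state a [myxo_state()].
#' @param params parameter set.
#' @return A tibble with one row per cell: `cell_id`, `aggregate_id`
#'   (1-based, ordered by decreasing size), component `size`, and the
#'   aggregate centroid (`centroid_x_um`, `centroid_y_um`, computed with
#'   minimum-image unwrapping relative to one member).
#' @export
detect_aggregates <- function(state, params = state$params) {
  nc <- n_cells(state)
  edges <- cpp_proximity_edges(state$pos, cpp_params(params, "none"))
  g <- igraph::make_empty_graph(n = nc, directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges + 1L))
  comp <- igraph::components(g)
  ord <- order(-comp$csize, seq_along(comp$csize))
  relabel <- match(seq_along(comp$csize), ord)
  agg <- relabel[comp$membership]
  cent <- cell_centroids(state, params)
  dom <- params$domain
  cx <- cy <- numeric(max(agg))
  for (a in seq_len(max(agg))) {
    idx <- which(agg == a)
    rx <- cent$x_um[idx[1]]
    ry <- cent$y_um[idx[1]]
    cx[a] <- (rx + mean(mi_vec(cent$x_um[idx] - rx, dom[1]))) %% dom[1]
    cy[a] <- (ry + mean(mi_vec(cent$y_um[idx] - ry, dom[2]))) %% dom[2]
  }
  tibble::tibble(
    cell_id = seq_len(nc) - 1L,
    aggregate_id = agg,
    size = comp$csize[comp$membership],
    centroid_x_um = cx[agg],
    centroid_y_um = cy[agg]
  )
}

#' Rigid-body rotation profile of an aggregate
#'
#' Fits the rigid-body law `v(r) = omega * r` to per-cell mean speeds over
#' a trajectory window. The rotation center is found by direct search
#' (coarse grid over the cell cloud's bounding box, then local
#' refinement) minimising the residual of the through-origin fit of speed
#' against radius. The rigidity score is the coefficient of determination
#' of that fit; the edge speed is the mean speed of cells in the outermost
#' decile of radii.
#'
#' @param frames frame tibble or `myxo_sim`.
#' @param params parameter set (taken from a `myxo_sim` input).
#' @param cells optional cell ids (0-based) restricting the profile to one
#'   aggregate.
#' @param t_start,t_end window bounds in seconds; default to the full
#'   recorded range.
#' @return A `myxo_rotation` object. `tidy()` gives the per-cell table
#'   (`cell_id`, `r_um`, `v_um_min`, `omega_per_min`); `glance()` gives the
#'   fit: center, signed `omega_per_min`, `edge_speed_um_min` (mean speed of
#'   the outer-decile cells), `v_edge_rigid_um_min` (the rigid-body edge
#'   speed `v(R) = omega R`, with `R` the 95th percentile of cell radii; on
#'   small aggregates the decile mean sits below `omega R` because the
#'   outermost cells do not all lie at the rim), and `rigidity`.
#' @export
rotation_profile <- function(frames, params = NULL, cells = NULL,
                             t_start = NULL, t_end = NULL) {
  if (inherits(frames, "myxo_sim")) {
    if (is.null(params)) params <- frames$params
    frames <- frames$frames
  }
  if (is.null(params)) stop("params must be supplied with a plain frame table")
  if (!is.null(cells)) frames <- frames[frames$cell_id %in% cells, ]
  if (!is.null(t_start)) frames <- frames[frames$time_s >= t_start, ]
  if (!is.null(t_end)) frames <- frames[frames$time_s <= t_end, ]
  xm <- frame_matrices(frames, params)
  nf <- length(xm$times)
  nc <- xm$n_cells
  if (nf < 3) stop("rotation profile needs at least 3 frames")
  if (nc < 3) stop("rotation profile needs at least 3 cells")
  dom <- params$domain
  np <- params$n_particles
  # per-frame cell centroids, unwrapped in time (continuous paths)
  cxw <- matrix(0, nc, nf)
  cyw <- matrix(0, nc, nf)
  for (i in seq_len(nf)) {
    cen <- centroid_xy(xm$x[, i], xm$y[, i], np, dom)
    cxw[, i] <- cen$x
    cyw[, i] <- cen$y
  }
  cx <- cxw
  cy <- cyw
  for (i in 2:nf) {
    cx[, i] <- cx[, i - 1] + mi_vec(cxw[, i] - cxw[, i - 1], dom[1])
    cy[, i] <- cy[, i - 1] + mi_vec(cyw[, i] - cyw[, i - 1], dom[2])
  }
  dt_min <- diff(xm$times) / 60
  total_min <- sum(dt_min)
  # mean speed along the path, um/min
  v <- colSums(sqrt(diff(t(cx))^2 + diff(t(cy))^2)) / total_min
  # time-averaged distance to a candidate center (not the distance of the
  # time-averaged position, which is biased inward for arcs)
  r_at <- function(ctr) {
    rowMeans(sqrt((cx - ctr[1])^2 + (cy - ctr[2])^2))
  }
  sse_at <- function(ctr) {
    r <- r_at(ctr)
    w <- sum(v * r) / sum(r^2)
    sum((v - w * r)^2)
  }
  # coarse grid over the cloud's bounding box, then local refinements
  mx <- rowMeans(cx)
  my <- rowMeans(cy)
  lo <- c(min(mx), min(my))
  hi <- c(max(mx), max(my))
  ctr <- c(mean(mx), mean(my))
  span <- pmax(hi - lo, 1e-6)
  best <- sse_at(ctr)
  for (level in 1:3) {
    gx <- seq(ctr[1] - span[1] / 2, ctr[1] + span[1] / 2, length.out = 11)
    gy <- seq(ctr[2] - span[2] / 2, ctr[2] + span[2] / 2, length.out = 11)
    for (xx in gx) for (yy in gy) {
      s <- sse_at(c(xx, yy))
      if (s < best) { best <- s; ctr <- c(xx, yy) }
    }
    span <- span / 5
  }
  r <- r_at(ctr)
  # rotation rate from positions relative to the instantaneous centroid:
  # exactly zero for pure translation, exactly omega for rigid rotation
  qx <- sweep(cx, 2, colMeans(cx))
  qy <- sweep(cy, 2, colMeans(cy))
  ang <- atan2(t(qy), t(qx)) # nf x nc
  dang <- diff(ang)
  dang <- (dang + pi) %% (2 * pi) - pi
  omega_signed_cell <- colSums(dang) / total_min
  q2 <- rowMeans(qx^2 + qy^2)
  omega_signed <- sum(q2 * omega_signed_cell) / sum(q2)
  omega_fit <- sum(v * r) / sum(r^2)
  # rigidity: coefficient of determination of the through-origin v ~ r fit,
  # measured against the speed variance (0 when speeds carry no radial
  # structure, e.g. uniform translation)
  ss_tot <- sum((v - mean(v))^2)
  rigidity <- if (ss_tot > 0) max(0, min(1, 1 - best / ss_tot)) else 0
  edge_idx <- which(r >= stats::quantile(r, 0.9))
  cells_tbl <- tibble::tibble(
    cell_id = xm$cell_ids,
    r_um = r,
    v_um_min = v,
    omega_per_min = ifelse(r > 1e-9, v / r, NA_real_),
    omega_signed_per_min = omega_signed_cell
  )
  structure(
    list(cells = cells_tbl,
         center = ctr %% dom,
         omega_per_min = omega_signed,
         omega_magnitude_per_min = omega_fit,
         edge_speed_um_min = mean(v[edge_idx]),
         v_edge_rigid_um_min = abs(omega_signed) *
           as.numeric(stats::quantile(r, 0.95)),
         rigidity = rigidity,
         n_frames = nf, window_min = total_min),
    class = "myxo_rotation"
  )
}

#' @export
print.myxo_rotation <- function(x, ...) {
  cat(sprintf("<myxo_rotation> %d cells over %.3g min\n",
              nrow(x$cells), x$window_min))
  cat(sprintf("  center (%.3g, %.3g) um, omega = %.4g /min, edge speed = %.4g um/min, rigidity = %.3f\n",
              x$center[1], x$center[2], x$omega_per_min,
              x$edge_speed_um_min, x$rigidity))
  invisible(x)
}

#' @export
tidy.myxo_rotation <- function(x, ...) x$cells

#' @export
glance.myxo_rotation <- function(x, ...) {
  tibble::tibble(
    center_x_um = x$center[1], center_y_um = x$center[2],
    omega_per_min = x$omega_per_min,
    omega_magnitude_per_min = x$omega_magnitude_per_min,
    edge_speed_um_min = x$edge_speed_um_min,
    v_edge_rigid_um_min = x$v_edge_rigid_um_min,
    rigidity = x$rigidity,
    n_cells = nrow(x$cells), n_frames = x$n_frames,
    window_min = x$window_min
  )
}

#' Cell centroids of a state
#'
#' @param state a [myxo_state()].
#' @param params parameter set.
#' @return A tibble `cell_id`, `x_um`, `y_um` (centroids wrapped into the
#'   domain; particles are unwrapped within each cell first).
#' @export
cell_centroids <- function(state, params = state$params) {
  cen <- centroid_xy(state$pos[, 1], state$pos[, 2], params$n_particles,
                     params$domain)
  tibble::tibble(cell_id = seq_along(cen$x) - 1L,
                 x_um = cen$x %% params$domain[1],
                 y_um = cen$y %% params$domain[2])
}

# --- internal helpers -------------------------------------------------------

mi_vec <- function(dx, L) dx - L * round(dx / L)

# centroids from stacked particle vectors (unwrap each cell about its
# first particle)
centroid_xy <- function(x, y, np, dom) {
  xm <- matrix(x, nrow = np)
  ym <- matrix(y, nrow = np)
  x0 <- xm[1, ]
  y0 <- ym[1, ]
  dx <- mi_vec(sweep(xm, 2, x0), dom[1])
  dy <- mi_vec(sweep(ym, 2, y0), dom[2])
  list(x = x0 + colMeans(dx), y = y0 + colMeans(dy))
}

# reshape a frame tibble into particle-by-frame matrices
frame_matrices <- function(frames, params) {
  stopifnot(all(c("time_s", "cell_id", "particle_index", "x_um", "y_um")
                %in% names(frames)))
  frames <- frames[order(frames$time_s, frames$cell_id,
                         frames$particle_index), ]
  tt <- unique(frames$time_s)
  n_per <- nrow(frames) / length(tt)
  if (n_per != round(n_per)) stop("frame table is ragged across times")
  cell_ids <- unique(frames$cell_id[frames$time_s == tt[1]])
  list(
    x = matrix(frames$x_um, ncol = length(tt)),
    y = matrix(frames$y_um, ncol = length(tt)),
    times = tt,
    n_cells = length(cell_ids),
    cell_ids = cell_ids
  )
}

#' Orbital winding of cell trajectories
#'
#' How much each cell's direction of motion turns over a trajectory
#' window, together with how confined its path is. A cell circulating in a
#' rotating aggregate keeps turning the same way - its heading winds
#' through full revolutions - while staying in place (small net
#' displacement relative to path length). Cells travelling in streams
#' accumulate little net winding; cells in transient swirls wind briefly
#' but do not persist. Requiring a group of cells with winding beyond a
#' full turn and a confined path is therefore a robust detector of
#' persistent rotating aggregates that does not depend on delineating the
#' aggregate beforehand.
#'
#' @param frames frame tibble or `myxo_sim`.
#' @param params parameter set (taken from a `myxo_sim` input).
#' @param t_start,t_end window bounds, s.
#' @return A tibble with `cell_id`, `winding_rad` (signed accumulated
#'   heading change), `turns` (`winding_rad / 2 pi`), `path_um`, and
#'   `confinement` (net displacement over path length; 0 = returns to its
#'   start, 1 = straight line).
#' @export
orbital_winding <- function(frames, params = NULL, t_start = NULL,
                            t_end = NULL) {
  if (inherits(frames, "myxo_sim")) {
    if (is.null(params)) params <- frames$params
    frames <- frames$frames
  }
  if (is.null(params)) stop("params must be supplied with a plain frame table")
  if (!is.null(t_start)) frames <- frames[frames$time_s >= t_start, ]
  if (!is.null(t_end)) frames <- frames[frames$time_s <= t_end, ]
  xm <- frame_matrices(frames, params)
  nf <- length(xm$times)
  if (nf < 3) stop("orbital winding needs at least 3 frames")
  nc <- xm$n_cells
  dom <- params$domain
  cxw <- matrix(0, nc, nf)
  cyw <- matrix(0, nc, nf)
  for (i in seq_len(nf)) {
    cen <- centroid_xy(xm$x[, i], xm$y[, i], params$n_particles, dom)
    cxw[, i] <- cen$x
    cyw[, i] <- cen$y
  }
  cx <- cxw
  cy <- cyw
  for (i in 2:nf) {
    cx[, i] <- cx[, i - 1] + mi_vec(cxw[, i] - cxw[, i - 1], dom[1])
    cy[, i] <- cy[, i - 1] + mi_vec(cyw[, i] - cyw[, i - 1], dom[2])
  }
  dx <- diff(t(cx))
  dy <- diff(t(cy))
  heading <- atan2(dy, dx)
  dh <- diff(heading)
  dh <- (dh + pi) %% (2 * pi) - pi
  winding <- colSums(dh)
  path <- colSums(sqrt(dx^2 + dy^2))
  net <- sqrt((cx[, nf] - cx[, 1])^2 + (cy[, nf] - cy[, 1])^2)
  tibble::tibble(
    cell_id = xm$cell_ids,
    winding_rad = winding,
    turns = winding / (2 * pi),
    path_um = path,
    confinement = net / pmax(path, 1e-9)
  )
}
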