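#' Closest points between two segments
#'
#' Closest-point parameters and distance between two 2D segments, under the
#' minimum-image convention when a periodic domain is given. For parallel
#' segments with a continuum of minimisers the midpoint of the overlap
#' interval is returned.
#'
#' @param a,b segments as 2 x 2 matrices (rows = endpoints, um) or length-4
#'   vectors `(x1, y1, x2, y2)`.
#' @param domain periodic box sides, um, or `NULL` for plain Euclidean
#'   geometry.
#' @return A tibble with `p1`, `p2` (parameters in `[0, 1]` along `a` and
#'   `b`), `d` (closest distance, um), and the unit vector `ux`, `uy`
#'   pointing from the closest point on `a` to the closest point on `b`.
#' @examples
#' segment_closest_points(c(0, 0, 1, 0), c(0, 1, 1, 1))
#' @export
segment_closest_points <- function(a, b, domain = NULL) {
  a <- as_segment(a)
  b <- as_segment(b)
  if (all(a[1:2] == a[3:4]) || all(b[1:2] == b[3:4])) {
    stop("zero-length segment")
  }
  periodic <- !is.null(domain)
  if (!periodic) domain <- c(1, 1)
  v <- cpp_seg_closest(a, b, domain[1], domain[2], periodic)
  tibble::tibble(p1 = v[["p1"]], p2 = v[["p2"]], d = v[["d"]],
                 ux = v[["ux"]], uy = v[["uy"]])
}

as_segment <- function(s) {
  if (is.matrix(s)) s <- c(t(s))
  s <- as.numeric(s)
  if (length(s) != 4) stop("a segment is 4 numbers or a 2 x 2 matrix")
  s
}

#' Broad-phase candidate segment pairs
#'
#' Uniform spatial hash over segment midpoints, returning a superset of all
#' segment pairs whose axes are closer than `W + d_g`. Same-cell adjacent
#' segments (which share a particle) are excluded.
#'
#' @param state a [myxo_state()].
#' @param params parameter set; defaults to the one stored in `state`.
#' @return A tibble of candidate pairs with 0-based global segment ids and
#'   the owning cells.
#' @export
broad_phase <- function(state, params = state$params) {
  m <- cpp_broad_phase(state$pos, cpp_params(params))
  nseg <- params$n_particles - 1L
  tibble::tibble(
    seg_a = m[, 1], seg_b = m[, 2],
    cell_a = m[, 1] %/% nseg, cell_b = m[, 2] %/% nseg
  )
}

#' Detected contacts and guiding pairs of a state
#'
#' Narrow-phase interaction detection. Collisions are segment pairs with
#' axis distance `d < W`, after removing duplicated contacts at shared
#' particles and spurious contacts against the farther of two adjacent
#' segments of the same other cell. Head-to-tail guiding pairs are
#' (follower head segment, leader tail segment) pairs with
#' `W < d < W + d_g`; each head keeps only its nearest qualifying tail.
#'
#' @inheritParams broad_phase
#' @param mode guiding mode; guiding pairs are only searched for the three
#'   short-range modes.
#' @return A list of two tibbles, `collisions` (with `seg_a`, `seg_b`,
#'   `p1`, `p2`, `d`) and `guiding` (with `follower`, `leader`, `d`).
#' @export
contact_pairs <- function(state, params = state$params, mode = "adhesion") {
  res <- cpp_find_interactions(state$pos, state$ke, cpp_params(params, mode))
  cm <- res$contacts
  gm <- res$guides
  nseg <- params$n_particles - 1L
  list(
    collisions = tibble::tibble(
      seg_a = as.integer(cm[, 1]), seg_b = as.integer(cm[, 2]),
      cell_a = as.integer(cm[, 1]) %/% nseg,
      cell_b = as.integer(cm[, 2]) %/% nseg,
      p1 = cm[, 3], p2 = cm[, 4], d = cm[, 5]
    ),
    guiding = tibble::tibble(
      follower = as.integer(gm[, 1]), leader = as.integer(gm[, 2]),
      d = gm[, 3]
    )
  )
}

#' @rdname contact_pairs
#' @export
find_head_tail_pairs <- function(state, params = state$params,
                                 mode = "adhesion") {
  contact_pairs(state, params, mode)$guiding
}

#' Collision and guiding forces of a state
#'
#' Per-particle forces from one interaction source. Collision forces are
#' linear repulsions `k_c * (W - d)` along the closest-point line,
#' distributed to the four segment endpoints with barycentric weights.
#' Guiding forces are linear attractions `F_g_max / d_g * (d - W)` (clamped
#' at `F_g_max`) applied at the follower's head particle and - for adhesion
#' only - as an equal and opposite reaction at the leader's tail particle;
#' passive following keeps only the component normal to the follower body.
#'
#' @inheritParams contact_pairs
#' @return A tibble with `cell_id`, `particle_index`, `fx_pn`, `fy_pn`.
#' @export
collision_forces <- function(state, params = state$params) {
  F <- cpp_state_forces(state$pos, state$ke, cpp_params(params, "none"),
                        "collision")
  state_force_tibble(F, params)
}

#' @rdname collision_forces
#' @param mode one of `"adhesion"`, `"active_following"`,
#'   `"passive_following"`.
#' @export
guiding_forces <- function(state, params = state$params, mode = "adhesion") {
  if (!mode %in% c("adhesion", "active_following", "passive_following")) {
    stop("guiding_forces needs a short-range mode, got '", mode, "'")
  }
  F <- cpp_state_forces(state$pos, state$ke, cpp_params(params, mode),
                        "guiding")
  state_force_tibble(F, params)
}

state_force_tibble <- function(F, params) {
  np <- params$n_particles
  nc <- nrow(F) / np
  tibble::tibble(
    cell_id = rep(seq_len(nc) - 1L, each = np),
    particle_index = rep(seq_len(np) - 1L, nc),
    fx_pn = F[, 1], fy_pn = F[, 2]
  )
}
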