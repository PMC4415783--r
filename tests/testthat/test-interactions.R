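# exact point-to-segment distance, vectorised over points
point_seg_dist <- function(px, py, q1, q2) {
  vx <- q2[1] - q1[1]
  vy <- q2[2] - q1[2]
  tt <- ((px - q1[1]) * vx + (py - q1[2]) * vy) / (vx^2 + vy^2)
  tt <- pmin(1, pmax(0, tt))
  sqrt((q1[1] + tt * vx - px)^2 + (q1[2] + tt * vy - py)^2)
}

# dense-sampling oracle: minimum over 1001 points along segment a of the
# exact distance to segment b
brute_seg_dist <- function(a, b, n = 1001) {
  s <- seq(0, 1, length.out = n)
  px <- a[1] + s * (a[3] - a[1])
  py <- a[2] + s * (a[4] - a[2])
  min(point_seg_dist(px, py, b[1:2], b[3:4]))
}

test_that("segment closest points match examples and tie rules", {
  # collinear touching segments sharing an endpoint
  r <- segment_closest_points(c(0, 0, 1, 0), c(1, 0, 2, 0))
  expect_equal(r$d, 0)
  # full-overlap parallel segments: overlap midpoint, distance 1
  r2 <- segment_closest_points(c(0, 0, 1, 0), c(0, 1, 1, 1))
  expect_equal(r2$d, 1)
  expect_equal(r2$p1, 0.5)
  expect_equal(r2$p2, 0.5)
  # zero-length segment errors
  expect_error(segment_closest_points(c(0, 0, 0, 0), c(0, 1, 1, 1)),
               "zero-length")
})

test_that("segment distance agrees with a dense-sampling oracle", {
  set.seed(101)
  for (k in 1:200) {
    a0 <- runif(2, 0, 3)
    b0 <- runif(2, 0, 3)
    a <- c(a0, a0 + runif(2, -1, 1))
    b <- c(b0, b0 + runif(2, -1, 1))
    if (all(a[1:2] == a[3:4]) || all(b[1:2] == b[3:4])) next
    d <- segment_closest_points(a, b)$d
    d0 <- brute_seg_dist(a, b, n = 4001)
    # the sampled minimum can only overshoot the true one
    expect_gte(d0 - d, -1e-9)
    expect_lt(abs(d - d0), 1e-3)
  }
})

test_that("periodic distances use the minimum image", {
  p <- small_params()
  # segments on opposite edges of a 30x30 box are close across the seam
  r <- segment_closest_points(c(0.5, 10, 0.5, 11), c(29.5, 10, 29.5, 11),
                              domain = p$domain)
  expect_equal(r$d, 1)
})

test_that("broad phase returns a superset of interacting pairs", {
  p <- small_params()
  set.seed(5)
  st <- random_configuration(p, n_cells = 12, seed = 5)
  cand <- broad_phase(st)
  # exhaustive O(n^2) oracle at threshold W + d_g
  np <- p$n_particles
  nseg <- np - 1L
  segs <- list()
  for (c_id in 0:(n_cells(st) - 1)) {
    m <- myxoglide:::cell_matrix(st, c_id)
    for (i in seq_len(nseg)) {
      segs[[c_id * nseg + i]] <- c(m[i, ], m[i + 1, ])
    }
  }
  S <- length(segs)
  in_range <- list()
  for (g in seq_len(S - 1)) {
    for (h in (g + 1):S) {
      cg <- (g - 1) %/% nseg
      ch <- (h - 1) %/% nseg
      if (cg == ch && abs(g - h) == 1) next
      d <- myxoglide:::cpp_seg_closest(segs[[g]], segs[[h]],
                                       p$domain[1], p$domain[2], TRUE)[["d"]]
      if (d < p$W + p$d_g) in_range[[length(in_range) + 1]] <- c(g - 1, h - 1)
    }
  }
  if (length(in_range)) {
    need <- do.call(rbind, in_range)
    got <- paste(cand$seg_a, cand$seg_b)
    expect_true(all(paste(need[, 1], need[, 2]) %in% got))
  }
  # no same-cell adjacent pairs in the candidates
  same_adj <- cand$cell_a == cand$cell_b & abs(cand$seg_a - cand$seg_b) == 1
  expect_false(any(same_adj))
})

test_that("broad phase sees neighbours across the periodic boundary", {
  p <- small_params()
  a <- myxoglide:::straight_cell(c(2, 15), pi / 2, p)
  b <- myxoglide:::straight_cell(c(29.7, 15), pi / 2, p) # 2.3 um across seam
  st <- myxo_state(rbind(a, b), c(1L, 1L), p)
  # bring them into range: shift cell b to 0.4 um from cell a across seam
  b2 <- myxoglide:::straight_cell(c(1.4, 15), pi / 2, p)
  b2[, 1] <- (b2[, 1] - 2.0) %% 30 # centre at 29.4: crosses the seam
  st2 <- myxo_state(rbind(a, b2), c(1L, 1L), p)
  expect_gt(nrow(broad_phase(st2)), 0)
})

test_that("collision forces follow the linear repulsion law", {
  p <- small_params()
  # two parallel straight cells with axis distance 0.45 um: overlap 0.05
  a <- myxoglide:::straight_cell(c(15, 15), 0, p)
  b <- myxoglide:::straight_cell(c(15, 15.45), 0, p)
  st <- myxo_state(rbind(a, b), c(1L, 1L), p)
  f <- collision_forces(st)
  fa <- colSums(as.matrix(f[f$cell_id == 0, 3:4]))
  fb <- colSums(as.matrix(f[f$cell_id == 1, 3:4]))
  # action = -reaction overall
  expect_equal(fa + fb, c(0, 0), tolerance = 1e-9, ignore_attr = TRUE)
  # each parallel overlapping segment pair contributes k_c (W - d) = 500 pN;
  # after de-duplication, one contact per opposing segment pair
  pairs <- contact_pairs(st, mode = "none")$collisions
  expect_true(all(abs(pairs$d - 0.45) < 1e-9))
  per_pair <- p$k_c * 1e6 * (p$W - 0.45)
  expect_equal(per_pair, 500)
  expect_equal(as.numeric(abs(fb[2])), nrow(pairs) * 500, tolerance = 1e-6)
  # touching cells (d = W): no force
  b2 <- myxoglide:::straight_cell(c(15, 15.5), 0, p)
  st2 <- myxo_state(rbind(a, b2), c(1L, 1L), p)
  f2 <- collision_forces(st2)
  expect_lt(max(abs(c(f2$fx_pn, f2$fy_pn))), 1e-9)
})

test_that("a contact at a shared particle is counted once", {
  p <- small_params()
  # cell a vertical; cell b horizontal, its 4th particle closest to a's axis
  a <- myxoglide:::straight_cell(c(15, 15), pi / 2, p)
  b <- myxoglide:::straight_cell(c(15 + p$L / 2 + 0.4, 15), 0, p)
  st <- myxo_state(rbind(a, b), c(1L, 1L), p)
  cp <- contact_pairs(st, mode = "none")$collisions
  # b's head particle (shared by its two first segments) faces a:
  # exactly one contact, not two
  expect_equal(nrow(cp), 1L)
})

test_that("only the closer of two adjacent same-cell contacts is kept", {
  p <- small_params()
  a <- myxoglide:::straight_cell(c(15, 15), pi / 2, p)
  # b parallel to a, slightly overlapping: b's consecutive segments all face
  # a's segments; the de-duplication must not leave two contacts of one
  # segment of a with adjacent segments of b
  b <- myxoglide:::straight_cell(c(15.45, 15.1), pi / 2, p)
  st <- myxo_state(rbind(a, b), c(1L, 1L), p)
  cp <- contact_pairs(st, mode = "none")$collisions
  expect_gt(nrow(cp), 0)
  key <- split(cp$seg_b, cp$seg_a)
  for (gb in key) expect_false(any(diff(sort(gb)) == 1))
  key2 <- split(cp$seg_a, cp$seg_b)
  for (ga in key2) expect_false(any(diff(sort(ga)) == 1))
})

test_that("head-tail pairs respect the guiding window and nearest-tail rule", {
  p <- small_params()
  st <- follower_pair_state(p, gap = p$d_g / 2)
  g <- find_head_tail_pairs(st, mode = "adhesion")
  expect_equal(nrow(g), 1L)
  expect_equal(g$follower, 0L)
  expect_equal(g$leader, 1L)
  expect_true(g$d > p$W && g$d < p$W + p$d_g)

  # beyond d_g: no pair
  st2 <- follower_pair_state(p, gap = p$d_g * 1.5)
  expect_equal(nrow(find_head_tail_pairs(st2, mode = "adhesion")), 0L)

  # two leaders in range: only the nearer is kept
  lead1 <- myxoglide:::straight_cell(c(20, 15), 0, p)          # closer
  lead2 <- myxoglide:::straight_cell(c(20.1, 15.35), 0, p)     # farther
  foll <- myxoglide:::straight_cell(c(20 - p$L - p$W - 0.1, 15), 0, p)
  st3 <- myxo_state(rbind(foll, lead1, lead2), c(1L, 1L, 1L), p)
  g3 <- find_head_tail_pairs(st3, mode = "adhesion")
  g3 <- g3[g3$follower == 0L, ]
  expect_equal(nrow(g3), 1L)
  expect_equal(g3$leader, 1L)
})

test_that("guiding force magnitude is linear in the gap and clamped", {
  p <- small_params()
  kg <- p$F_g_max / p$d_g
  for (gap in c(0.5, 0.25, 0.75) * p$d_g) {
    st <- follower_pair_state(p, gap = gap)
    f <- guiding_forces(st, mode = "active_following")
    mag <- sqrt(sum(colSums(as.matrix(f[f$cell_id == 0, 3:4]))^2))
    expect_equal(mag, kg * gap, tolerance = 1e-6)
  }
  # at d = W the force vanishes (continuity with collision response)
  st0 <- follower_pair_state(p, gap = 1e-9)
  f0 <- guiding_forces(st0, mode = "active_following")
  expect_lt(max(abs(c(f0$fx_pn, f0$fy_pn))), 1e-3)
})

test_that("adhesion is an action-reaction pair; active/passive are not", {
  p <- small_params()
  st <- follower_pair_state(p)
  fa <- guiding_forces(st, mode = "adhesion")
  tot <- colSums(as.matrix(fa[, 3:4]))
  expect_equal(tot, c(0, 0), tolerance = 1e-12, ignore_attr = TRUE)
  # follower head pulled toward +x, leader tail pulled toward -x
  expect_gt(sum(fa$fx_pn[fa$cell_id == 0]), 0)
  expect_lt(sum(fa$fx_pn[fa$cell_id == 1]), 0)

  fact <- guiding_forces(st, mode = "active_following")
  expect_gt(sum(abs(colSums(as.matrix(fact[, 3:4])))), 10)
  expect_equal(sum(abs(fact$fx_pn[fact$cell_id == 1])), 0)

  # passive: force on the follower head is normal to its body only
  fp <- guiding_forces(st, mode = "passive_following")
  # follower lies along +x, so the tangential (x) component must vanish
  expect_equal(sum(abs(fp$fx_pn)), 0, tolerance = 1e-12)
})

test_that("passive steering has zero tangential component for bent cells", {
  p <- small_params()
  set.seed(9)
  for (k in 1:5) {
    ang <- runif(1, 0, 2 * pi)
    lead <- myxoglide:::straight_cell(c(17, 15.2), ang / 3, p)
    # bent follower approaching the leader tail at an angle
    s <- (seq_len(p$n_particles) - 1) * p$seg_len
    head0 <- lead[p$n_particles, ] + (p$W + p$d_g * runif(1, 0.2, 0.8)) *
      c(cos(ang), sin(ang))
    m <- cbind(head0[1] + s * cos(ang + 0.1 * s),
               head0[2] + s * sin(ang + 0.1 * s))
    st <- myxo_state(rbind(m, lead), c(1L, 1L), p)
    g <- find_head_tail_pairs(st, mode = "passive_following")
    if (nrow(g) == 0 || !any(g$follower == 0)) next
    f <- guiding_forces(st, mode = "passive_following")
    fh <- unlist(f[f$cell_id == 0 & f$particle_index == 0, 3:4])
    tangent <- m[1, ] - m[2, ]
    tangent <- tangent / sqrt(sum(tangent^2))
    expect_lt(abs(sum(fh * tangent)), 1e-9 * (1 + sqrt(sum(fh^2))))
  }
})

test_that("guiding and collision forces are continuous at contact", {
  p <- small_params()
  eps <- 1e-4
  st_in <- follower_pair_state(p, gap = -eps) # just overlapping
  st_out <- follower_pair_state(p, gap = eps) # just separated
  f_in <- collision_forces(st_in)
  f_out <- guiding_forces(st_out, mode = "adhesion")
  expect_lt(max(abs(c(f_in$fx_pn, f_in$fy_pn))), 5)
  expect_lt(max(abs(c(f_out$fx_pn, f_out$fy_pn))), 1)
})

test_that("a cell can follow its own tail", {
  p <- small_params()
  # nearly closed circular cell: own head within guiding range of own tail
  np <- p$n_particles
  gap_arc <- p$W + p$d_g / 2
  circumference <- p$L + gap_arc
  r <- circumference / (2 * pi)
  phi <- (seq_len(np) - 1) * p$seg_len / r
  m <- cbind(15 + r * cos(-phi), 15 + r * sin(-phi))
  st <- myxo_state(m, 1L, p)
  g <- find_head_tail_pairs(st, mode = "adhesion")
  expect_equal(nrow(g), 1L)
  expect_equal(g$follower, 0L)
  expect_equal(g$leader, 0L)
})
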