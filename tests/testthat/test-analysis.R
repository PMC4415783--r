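# synthetic frame builders for speed/rotation oracles
synthetic_frames <- function(pos_fun, times, params, n_cells_ = 10) {
  np <- params$n_particles
  purrr::map_dfr(times, function(t) {
    m <- pos_fun(t) # (n_cells_*np) x 2
    tibble::tibble(
      time_s = t,
      cell_id = rep(seq_len(n_cells_) - 1L, each = np),
      particle_index = rep(seq_len(np) - 1L, n_cells_),
      x_um = m[, 1] %% params$domain[1],
      y_um = m[, 2] %% params$domain[2],
      k_e = 1L
    )
  })
}

test_that("segment speeds match uniform translation and stated averaging", {
  p <- model_params(domain = c(200, 200))
  np <- p$n_particles
  base <- do.call(rbind, lapply(1:10, function(i) {
    myxoglide:::straight_cell(c(20 + 6 * (i %% 5), 20 + 8 * (i %/% 5)), 0.2, p)
  }))
  # rigid translation at 4 um/min toward +x
  fr <- synthetic_frames(function(t) base + cbind(rep(4 * t / 60, nrow(base)), 0),
                         seq(0, 120, by = 30), p)
  sp <- segment_speeds(fr, p, window_min = 1)
  expect_equal(unique(round(sp$speed_um_min, 9)), 4)

  # two endpoints at 2 and 4 um/min: segment speed is their mean, 3
  p3 <- model_params(n_particles = 3, L = 1.3, domain = c(50, 50))
  fr3 <- purrr::map_dfr(c(0, 60), function(t) tibble::tibble(
    time_s = t, cell_id = 0L, particle_index = 0:2,
    x_um = c(10 + 2 * t / 60, 10.65 + 3 * t / 60, 11.3 + 4 * t / 60),
    y_um = 5, k_e = 1L
  ))
  sp3 <- segment_speeds(fr3, p3, window_min = 1)
  expect_equal(sp3$speed_um_min, c(2.5, 3.5))
  expect_equal(mean(sp3$speed_um_min), 3)

  # speeds use the minimum image across the periodic seam
  frw <- purrr::map_dfr(c(0, 60), function(t) tibble::tibble(
    time_s = t, cell_id = 0L, particle_index = 0:2,
    x_um = (c(199, 199.65, 200.3) + 4 * t / 60) %% 200,
    y_um = 5, k_e = 1L
  ))
  spw <- segment_speeds(frw, model_params(n_particles = 3, L = 1.3,
                                          domain = c(200, 200)))
  expect_equal(unique(round(spw$speed_um_min, 9)), 4)

  expect_error(segment_speeds(fr, p, window_min = 0), "positive")
})

test_that("segment speeds reproduce circular motion", {
  p <- model_params(n_particles = 3, L = 1.3, domain = c(100, 100))
  om <- 0.5 # rad/min
  pos_fun <- function(t) {
    phi <- om * t / 60
    r <- c(10, 10.65, 11.3)
    cbind(50 + r * cos(phi), 50 + r * sin(phi))
  }
  fr <- purrr::map_dfr(seq(0, 60, by = 6), function(t) tibble::tibble(
    time_s = t, cell_id = 0L, particle_index = 0:2,
    x_um = pos_fun(t)[, 1], y_um = pos_fun(t)[, 2], k_e = 1L
  ))
  sp <- segment_speeds(fr, p, window_min = 0.1)
  # chord/arc discretisation error at 0.05 rad steps is ~1e-4 relative
  expect_equal(mean(sp$speed_um_min[sp$segment_index == 0]),
               om * mean(c(10, 10.65)), tolerance = 1e-3)
})

test_that("strain energies implement the half-split collision energy", {
  p <- small_params()
  # no contacts: all zeros
  st0 <- one_cell_state(p)
  se0 <- strain_energies(st0)
  expect_true(all(se0$energy_J == 0))
  expect_equal(attr(se0, "total_J"), 0)

  # overlapping parallel cells at axis distance 0.45 (overlap 0.05 um):
  # each surviving contact stores 1/2 k_c (d-W)^2 = 1.25e-17 J, split as
  # 6.25e-18 J per involved segment
  p2 <- small_params(n_particles = 3, L = 1.3)
  a <- myxoglide:::straight_cell(c(15, 15), 0, p2)
  b <- myxoglide:::straight_cell(c(15, 15.45), 0, p2)
  st <- myxo_state(rbind(a, b), c(1L, 1L), p2)
  se <- strain_energies(st)
  pairs <- contact_pairs(st, mode = "none")$collisions
  expect_gt(nrow(pairs), 0)
  expect_equal(attr(se, "total_J"), nrow(pairs) * 1.25e-17, tolerance = 1e-9)
  expect_equal(sort(unique(se$energy_J[se$energy_J > 0])), 6.25e-18,
               tolerance = 1e-9)
  # the 50/50 split conserves the pair total
  expect_equal(sum(se$energy_J), attr(se, "total_J"), tolerance = 1e-12)

  # random crowded state: segment sum equals pair sum exactly
  p3 <- small_params()
  st3 <- random_configuration(p3, n_cells = 20, seed = 8)
  sim <- simulate_cells(st3, duration_min = 1, mode = "adhesion",
                        record_every_s = 30)
  se3 <- strain_energies(sim$final_state)
  expect_equal(sum(se3$energy_J), attr(se3, "total_J"), tolerance = 1e-12)
  expect_true(all(se3$energy_J >= 0))
})

test_that("aggregate detection matches a union-find oracle", {
  p <- small_params()
  # two well-separated pairs plus a bridge chain A-B-C
  mk <- function(ctr, ang = 0) myxoglide:::straight_cell(ctr, ang, p)
  st <- myxo_state(rbind(mk(c(5, 5)), mk(c(5, 5.6)),          # cluster 1
                         mk(c(20, 20)), mk(c(20, 20.6)),      # cluster 2
                         mk(c(20, 21.2))),                    # chained to 2
                   rep(1L, 5), p)
  agg <- detect_aggregates(st)
  expect_equal(length(unique(agg$aggregate_id)), 2L)
  expect_equal(sort(unique(agg$size)), c(2L, 3L))
  expect_equal(agg$aggregate_id[3], agg$aggregate_id[4])
  expect_equal(agg$aggregate_id[4], agg$aggregate_id[5])

  # 50-cell random state vs a brute-force union-find on whole-cell distances
  st2 <- random_configuration(small_params(domain = c(60, 60)),
                              n_cells = 50, seed = 13)
  agg2 <- detect_aggregates(st2)
  parent <- 1:50
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  np <- p$n_particles
  segs <- lapply(0:49, function(i) myxoglide:::cell_matrix(st2, i))
  for (i in 1:49) for (j in (i + 1):50) {
    dmin <- Inf
    for (a in 1:(np - 1)) for (b in 1:(np - 1)) {
      d <- myxoglide:::cpp_seg_closest(
        c(segs[[i]][a, ], segs[[i]][a + 1, ]),
        c(segs[[j]][b, ], segs[[j]][b + 1, ]), 60, 60, TRUE)[["d"]]
      dmin <- min(dmin, d)
    }
    if (dmin < p$W + p$d_g) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(1:50, find, integer(1))
  # identical partitions: same co-membership for every pair
  for (i in 1:49) for (j in (i + 1):50) {
    expect_equal(roots[i] == roots[j],
                 agg2$aggregate_id[i] == agg2$aggregate_id[j])
  }
})

test_that("rotation profile recovers synthetic rigid-body rotation", {
  p <- model_params(n_particles = 3, L = 1.3, domain = c(100, 100))
  om <- 0.5 # 1/min
  nc <- 10
  radii <- 1:10
  ang0 <- seq(0, 2 * pi, length.out = nc + 1)[-(nc + 1)]
  pos_fun <- function(t) {
    phi <- om * t / 60
    do.call(rbind, lapply(1:nc, function(i) {
      # small straight cell tangential at its radius
      c0 <- c(50 + radii[i] * cos(ang0[i] + phi),
              50 + radii[i] * sin(ang0[i] + phi))
      dir <- c(-sin(ang0[i] + phi), cos(ang0[i] + phi))
      rbind(c0 - 0.65 * dir, c0, c0 + 0.65 * dir)
    }))
  }
  fr <- synthetic_frames(pos_fun, seq(0, 300, by = 30), p, n_cells_ = nc)
  rp <- rotation_profile(fr, p)
  gl <- glance(rp)
  expect_equal(gl$omega_per_min, om, tolerance = 0.01)
  expect_gt(gl$rigidity, 0.999)
  expect_equal(gl$center_x_um, 50, tolerance = 0.1)
  expect_equal(gl$center_y_um, 50, tolerance = 0.1)
  # edge speed = omega * R within 2% (outermost decile = radius 10)
  expect_equal(gl$edge_speed_um_min, om * 10, tolerance = 0.02)
  # per-cell omega = v / r for every cell
  cells <- tidy(rp)
  expect_equal(cells$omega_per_min, rep(om, nc), tolerance = 0.01,
               ignore_attr = TRUE)

  # pure translation: near-zero omega, low rigidity
  pos_fun_t <- function(t) pos_fun(0) + 4 * t / 60
  frt <- synthetic_frames(pos_fun_t, seq(0, 300, by = 30), p, n_cells_ = nc)
  glt <- glance(rotation_profile(frt, p))
  expect_lt(abs(glt$omega_per_min), 0.05)
  expect_lt(glt$rigidity, 0.5)

  # degenerate inputs error
  expect_error(rotation_profile(fr[fr$time_s == 0, ], p), "3 frames")
})
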