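# shared fixtures: small parameter sets and hand-built states

small_params <- function(...) {
  args <- list(...)
  if (!"domain" %in% names(args)) args$domain <- c(30, 30)
  do.call(model_params, args)
}

# one straight cell centred at `center`, gliding toward +axis for ke = +1
one_cell_state <- function(params = small_params(), center = c(15, 15),
                           angle = 0, ke = 1L) {
  myxo_state(myxoglide:::straight_cell(center, angle, params), ke, params)
}

# two straight cells laid head-to-tail along +x:
# leader ahead, follower behind, head-tail particle gap `gap + W` apart
follower_pair_state <- function(params = small_params(), gap = params$d_g / 2,
                                y = 15) {
  lead <- myxoglide:::straight_cell(c(20, y), 0, params)
  d <- params$W + gap
  foll <- myxoglide:::straight_cell(c(20 - params$L - d, y), 0, params)
  myxo_state(rbind(foll, lead), c(1L, 1L), params)
}

# energy functions used as numeric-gradient oracles
stretch_energy <- function(m, params) {
  l <- sqrt(diff(m[, 1])^2 + diff(m[, 2])^2)
  sum(0.5 * (params$k_lin * 1e6) * (l - params$seg_len)^2)
}

bend_energy <- function(m, params) {
  v <- diff(m)
  th <- numeric(nrow(m) - 2)
  for (i in seq_along(th)) {
    a <- v[i, ]
    b <- v[i + 1, ]
    th[i] <- atan2(a[1] * b[2] - a[2] * b[1], sum(a * b))
  }
  sum(0.5 * (params$k_a * 1e18) * th^2)
}

num_gradient <- function(f, m, eps = 1e-7) {
  g <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    for (j in 1:2) {
      mp <- m; mp[i, j] <- mp[i, j] + eps
      mm <- m; mm[i, j] <- mm[i, j] - eps
      g[i, j] <- (f(mp) - f(mm)) / (2 * eps)
    }
  }
  g
}

# a gently bent chain used by several force tests
bent_chain <- function(params, amp = 0.3, n = params$n_particles) {
  s <- (seq_len(n) - 1) * params$seg_len
  cbind(10 + s, 10 + amp * sin(s / params$L * pi))
}
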