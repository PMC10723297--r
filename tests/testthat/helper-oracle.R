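# Independent brute-force references, written as plain nested loops against
# the printed formulas. They deliberately share no code with the package
# internals beyond the public constructors.

oracle_upsilon <- function(x, theta, sigma1, v_max) {
  v_max * exp(-(x - theta)^2 / (2 * sigma1^2))
}

# p(V | theta, x), plain Gaussian density
oracle_meas_density <- function(v, center, sigma2) {
  stats::dnorm(v, mean = center, sd = sigma2)
}

# EID by direct nested loops: for every candidate x and hypothetical V,
# form the posterior pointwise, take entropies, and integrate over V by
# the trapezoidal rule with p(V|x) renormalized over [0, 1].
oracle_eid <- function(mass, theta, v_grid, sigma1, v_max, sigma2) {
  nx <- length(theta)
  nv <- length(v_grid)
  s0 <- 0
  for (i in seq_len(nx)) if (mass[i] > 0) s0 <- s0 - mass[i] * log(mass[i])
  trap <- function(y, x) sum((y[-1] + y[-length(y)]) / 2 * diff(x))
  raw <- numeric(nx)
  for (ix in seq_len(nx)) {
    x <- theta[ix]
    pv <- numeric(nv)
    ds <- numeric(nv)
    for (iv in seq_len(nv)) {
      v <- v_grid[iv]
      post <- numeric(nx)
      for (it in seq_len(nx)) {
        ups <- oracle_upsilon(x, theta[it], sigma1, v_max)
        post[it] <- oracle_meas_density(v, ups, sigma2) * mass[it]
      }
      pv[iv] <- sum(post)
      post <- post / sum(post)
      h <- 0
      for (it in seq_len(nx)) if (post[it] > 0) h <- h - post[it] * log(post[it])
      ds[iv] <- s0 - h
    }
    raw[ix] <- trap(pv * ds, v_grid) / trap(pv, v_grid)
  }
  clipped <- pmax(raw, 0)
  list(raw = raw,
       normalized = if (sum(clipped) > 0) clipped / sum(clipped)
                    else rep(1 / nx, nx))
}

# Handy fixture: a small non-uniform belief on an arbitrary grid
lumpy_belief <- function(grid) {
  m <- exp(-((grid$points - 0.4 * grid$hi) / (0.15 * (grid$hi - grid$lo)))^2) + 0.2
  belief(grid, m / sum(m))
}
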