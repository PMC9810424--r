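# Independent oracles used across the suite. These re-derive quantities by
# brute force or closed form, never through the package's vectorized paths.

# Scalar re-evaluation of the game payoffs, member by member.
oracle_group_payoffs <- function(x, y, env, mode = "full") {
  n <- length(x)
  Sx <- 0; Sy <- 0
  for (i in seq_len(n)) { Sx <- Sx + x[i]; Sy <- Sy + y[i] }
  bx <- max(0, env$b1 * Sx + env$b2 * Sx^2)
  lo <- tanh(env$beta * env$w); hi <- tanh(env$beta * (1 - env$w))
  by <- (tanh(env$beta * (Sy / n - env$w)) + lo) / (hi + lo)
  share <- switch(mode, full = bx * by / n, M1 = by / n, M2 = bx / n)
  out <- numeric(n)
  for (j in seq_len(n)) {
    cx <- env$cost_coeff_x * x[j]^env$cost_exponent
    cy <- env$cost_coeff_y * y[j]^env$cost_exponent
    cost <- switch(mode, full = cx + cy, M1 = cy, M2 = cx)
    out[j] <- share - cost
  }
  out
}

# Closed-form selection gradient of the default forms at an interior resident
# (hand-derived partial derivatives of the invasion fitness).
oracle_gradient <- function(r, env, n = 5) {
  Sx <- n * r[1]; Sy <- n * r[2]
  bx <- max(0, env$b1 * Sx + env$b2 * Sx^2)
  dbx <- if (env$b1 * Sx + env$b2 * Sx^2 > 0) env$b1 + 2 * env$b2 * Sx else 0
  lo <- tanh(env$beta * env$w); hi <- tanh(env$beta * (1 - env$w))
  den <- hi + lo
  by <- (tanh(env$beta * (Sy / n - env$w)) + lo) / den
  dby <- (env$beta / n) * (1 / cosh(env$beta * (Sy / n - env$w))^2) / den
  k <- env$cost_exponent
  c(bx = dbx * by / n - env$cost_coeff_x * k * r[1]^(k - 1),
    by = bx * dby / n - env$cost_coeff_y * k * r[2]^(k - 1))
}

# Brute-force Euclidean projection onto {x >= 0, y >= 0, x + y <= 1} by grid
# search.
oracle_project <- function(x, y, grid_n = 400L) {
  g <- seq(0, 1, length.out = grid_n)
  pts <- expand.grid(px = g, py = g)
  pts <- pts[pts$px + pts$py <= 1 + 1e-12, ]
  d2 <- (pts$px - x)^2 + (pts$py - y)^2
  i <- which.min(d2)
  c(pts$px[i], pts$py[i])
}

# Default environment used in many tests (representative homeostatic X +
# thresholded Y).
test_env <- function(...) {
  args <- list(b1 = 20, b2 = -4, w = 0.3, beta = 3)
  do.call(colony_env, utils::modifyList(args, list(...)))
}

random_simplex <- function(n) {
  e <- matrix(rexp(3 * n), ncol = 3)
  e <- e / rowSums(e)
  list(x = e[, 1], y = e[, 2])
}
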