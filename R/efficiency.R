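# Social optimum (differential evolution over the joint group allocation),
# relative colony efficiency (price of anarchy) and social efficiency deficit.

# mean individual payoff of one joint allocation; xs, ys length n (feasible)
.alloc_mean_payoff <- function(xs, ys, env, n, mode) {
  combined_benefit(sum(xs), sum(ys), env, n, mode) -
    mean(individual_cost(xs, ys, env, mode))
}

# project a 2n-vector (x1..xn, y1..yn) member-wise onto the feasible triangle
.project_alloc <- function(v, n, mode) {
  xs <- v[seq_len(n)]
  ys <- v[n + seq_len(n)]
  if (mode == "M1") xs <- rep(0, n)
  if (mode == "M2") ys <- rep(0, n)
  p <- project_simplex(xs, ys)
  c(p$x, p$y)
}

.de_maximize <- function(objective, d, NP, CR = 0.7, F = 0.5,
                         maxiter = 250L, tol = 1e-8) {
  pop <- matrix(stats::runif(NP * d), nrow = NP)
  fit <- apply(pop, 1L, objective)
  for (it in seq_len(maxiter)) {
    best <- pop[which.max(fit), ]
    r1 <- sample.int(NP, NP, replace = TRUE)
    r2 <- sample.int(NP, NP, replace = TRUE)
    mut <- matrix(best, nrow = NP, ncol = d, byrow = TRUE) +
      F * (pop[r1, , drop = FALSE] - pop[r2, , drop = FALSE])
    mut <- pmin(pmax(mut, 0), 1)
    cross <- matrix(stats::runif(NP * d) < CR, nrow = NP)
    jrand <- cbind(seq_len(NP), sample.int(d, NP, replace = TRUE))
    cross[jrand] <- TRUE
    trial <- ifelse(cross, mut, pop)
    tfit <- apply(trial, 1L, objective)
    sel <- tfit > fit
    pop[sel, ] <- trial[sel, , drop = FALSE]
    fit[sel] <- tfit[sel]
    if (max(fit) - stats::median(fit) < tol && it > 20L) break
  }
  i <- which.max(fit)
  list(par = pop[i, ], value = fit[i])
}

#' Socially optimal workforce allocation
#'
#' Maximizes the mean individual payoff of one n-member game over the joint
#' allocation (each member's (x, y) on the feasible simplex, 2n dimensions)
#' by differential evolution (best/1/bin, CR = 0.7, F = 0.5, population 15x
#' dimension) with restarts and a Nelder-Mead polish. The best symmetric
#' (all-members-equal) allocation is reported alongside for comparison, since
#' branching steady states are themselves asymmetric.
#'
#' @param env a [colony_env()].
#' @param n group size.
#' @param mode game mode.
#' @param restarts independent optimizer restarts (>= 1).
#' @param seed RNG seed for the optimizer.
#' @param maxiter DE generations per restart.
#' @return Object of class `optimal_allocation`: `traits` (n x 2 matrix),
#'   `mean_payoff`, `symmetric` (best equal-trait allocation), and
#'   `optimizer_trace` (best value per restart).
#' @export
optimal_allocation <- function(env, n = 5L, mode = "full", restarts = 5L,
                               seed = 1L, maxiter = 250L) {
  if (restarts < 1L) stop("restarts must be >= 1", call. = FALSE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  d <- 2L * n
  obj <- function(v) {
    p <- .project_alloc(v, n, mode)
    .alloc_mean_payoff(p[seq_len(n)], p[n + seq_len(n)], env, n, mode)
  }
  trace <- numeric(restarts)
  best <- NULL
  for (r in seq_len(restarts)) {
    res <- .de_maximize(obj, d, NP = 15L * d, maxiter = maxiter)
    pol <- stats::optim(res$par, obj, method = "Nelder-Mead",
                        control = list(fnscale = -1, maxit = 500L))
    cand <- if (pol$value > res$value) list(par = pol$par, value = pol$value)
      else res
    trace[r] <- cand$value
    if (is.null(best) || cand$value > best$value) best <- cand
  }
  p <- .project_alloc(best$par, n, mode)
  traits <- cbind(x = p[seq_len(n)], y = p[n + seq_len(n)])

  sym <- .symmetric_optimum(env, n, mode)
  structure(list(traits = traits, mean_payoff = best$value,
                 symmetric = sym, optimizer_trace = trace,
                 n = n, mode = mode), class = "optimal_allocation")
}

# best equal-trait allocation: dense feasible grid plus Nelder-Mead polish
.symmetric_optimum <- function(env, n, mode, grid_n = 101L) {
  g <- seq(0, 1, length.out = grid_n)
  if (mode == "full") {
    gr <- expand.grid(x = g, y = g, KEEP.OUT.ATTRS = FALSE)
    gr <- gr[gr$x + gr$y <= 1, ]
  } else if (mode == "M1") {
    gr <- data.frame(x = 0, y = g)
  } else {
    gr <- data.frame(x = g, y = 0)
  }
  val <- combined_benefit(n * gr$x, n * gr$y, env, n, mode) -
    individual_cost(gr$x, gr$y, env, mode)
  i <- which.max(val)
  start <- c(gr$x[i], gr$y[i])
  pol <- stats::optim(start, function(v) {
    p <- project_simplex(v[1L], v[2L])
    x <- if (mode == "M1") 0 else p$x
    y <- if (mode == "M2") 0 else p$y
    combined_benefit(n * x, n * y, env, n, mode) -
      individual_cost(x, y, env, mode)
  }, method = "Nelder-Mead", control = list(fnscale = -1, maxit = 400L))
  p <- project_simplex(pol$par[1L], pol$par[2L])
  x <- if (mode == "M1") 0 else p$x
  y <- if (mode == "M2") 0 else p$y
  best_val <- max(val[i], pol$value)
  if (pol$value < val[i]) { x <- gr$x[i]; y <- gr$y[i] }
  list(x = x, y = y, mean_payoff = best_val)
}

#' @export
print.optimal_allocation <- function(x, ...) {
  cat(sprintf("Social optimum (%s mode, n = %d): mean payoff %.4f\n",
              x$mode, x$n, x$mean_payoff))
  cat("  member allocations (x, y):\n")
  for (i in seq_len(nrow(x$traits))) {
    cat(sprintf("    (%.3f, %.3f)\n", x$traits[i, 1L], x$traits[i, 2L]))
  }
  cat(sprintf("  best symmetric allocation: (%.3f, %.3f), mean payoff %.4f\n",
              x$symmetric$x, x$symmetric$y, x$symmetric$mean_payoff))
  invisible(x)
}

#' Relative colony efficiency and social efficiency deficit
#'
#' The relative colony efficiency is the ratio between the mean individual
#' payoff achieved by the population at steady state and the mean payoff of
#' the socially optimal allocation (the price of anarchy: 1 means optimal
#' regulation). The social efficiency deficit (SED) is the raw difference
#' `optimal - achieved`. Negative achieved payoffs are clamped to 0 for the
#' ratio (its reported range is 0 to 1); the SED is left unclamped.
#'
#' @param achieved a `colony_sim` (steady-state mean payoff is time-averaged
#'   over the final `window` fraction) or a numeric payoff.
#' @param optimal an [optimal_allocation()] or a numeric payoff.
#' @param window analysis window fraction when `achieved` is a simulation.
#' @return Object of class `efficiency_report`: `achieved`, `optimal`,
#'   `ratio` (NA with a warning when the optimum is non-positive), `sed`,
#'   `defined`.
#' @export
relative_efficiency <- function(achieved, optimal, window = 0.1) {
  if (inherits(achieved, "colony_sim")) {
    s <- achieved$summary
    achieved <- mean(s$mean_payoff[s$step > (1 - window) * max(s$step)])
  }
  if (inherits(optimal, "optimal_allocation")) {
    optimal <- optimal$mean_payoff
  }
  defined <- optimal > 1e-12
  if (!defined) {
    warning("optimal mean payoff is non-positive; efficiency ratio undefined",
            call. = FALSE)
  }
  ratio <- if (defined) max(achieved, 0) / optimal else NA_real_
  structure(list(achieved = achieved, optimal = optimal, ratio = ratio,
                 sed = optimal - achieved, defined = defined),
            class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf("Relative colony efficiency: %s (achieved %.4f / optimal %.4f), SED = %.4f\n",
              if (x$defined) sprintf("%.3f", x$ratio) else "undefined",
              x$achieved, x$optimal, x$sed))
  invisible(x)
}

#' Efficiency map over an environment-parameter grid
#'
#' Per grid cell: run the dynamics to steady state from the same initial
#' conditions as the region sweeps (uniform on the simplex), compute the
#' differential-evolution social optimum, and report the efficiency ratio and
#' SED. Cells with a non-positive optimum are flagged, not dropped.
#'
#' @inheritParams region_sweep
#' @param restarts DE restarts per cell.
#' @param window steady-state window fraction.
#' @return Object of class `efficiency_map` whose `cells` data frame has the
#'   parameter values and achieved/optimal/ratio/sed/defined columns.
#' @export
efficiency_sweep <- function(param1, param2, grid1, grid2, env,
                             control = learning_control(), mode = "full",
                             seed = 1L, restarts = 3L, window = 0.1) {
  cells <- expand.grid(v1 = grid1, v2 = grid2, KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(cells[, 1L], cells[, 2L], achieved = NA_real_,
                    optimal = NA_real_, ratio = NA_real_, sed = NA_real_,
                    defined = NA)
  names(out)[1:2] <- c(param1, param2)
  for (i in seq_len(nrow(cells))) {
    e <- env
    e[[param1]] <- cells$v1[i]
    e[[param2]] <- cells$v2[i]
    si <- (as.integer(seed) + i * 211L) %% 2147483587L
    sim <- simulate_colony(e, control, init_uniform_simplex(), mode, seed = si)
    opt <- optimal_allocation(e, control$n, mode, restarts = restarts,
                              seed = si + 1L)
    rep_i <- suppressWarnings(relative_efficiency(sim, opt, window))
    out$achieved[i] <- rep_i$achieved
    out$optimal[i] <- rep_i$optimal
    out$ratio[i] <- rep_i$ratio
    out$sed[i] <- rep_i$sed
    out$defined[i] <- rep_i$defined
  }
  structure(list(cells = out, param1 = param1, param2 = param2, mode = mode),
            class = "efficiency_map")
}

#' @export
print.efficiency_map <- function(x, ...) {
  cat(sprintf("Efficiency map (%s mode): %d cells over %s x %s\n",
              x$mode, nrow(x$cells), x$param1, x$param2))
  def <- x$cells$ratio[x$cells$defined]
  if (length(def) > 0L) {
    cat(sprintf("  defined ratios: min %.3f, median %.3f, max %.3f\n",
                min(def), stats::median(def), max(def)))
  }
  invisible(x)
}
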