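# Discrete-time social-learning engine: game assignment, payoff computation,
# softmax recruitment (Wright-Fisher resampling), Gaussian trait mutation with
# Euclidean simplex projection.

#' Learning-dynamics control parameters
#'
#' @param n group size (agents per game).
#' @param N population size; must be a multiple of `n` so the population
#'   partitions exactly into `K = N/n` games.
#' @param alpha selection intensity of social learning (inverse payoff units);
#'   0 means neutral copying.
#' @param mu mutation rate: per-agent, per-step probability of behavioural
#'   exploration.
#' @param sigma mutation size: standard deviation of the Gaussian trait
#'   perturbation.
#' @param steps number of time steps to simulate.
#' @param record_every interval (in steps) between full population snapshots;
#'   per-step summaries are always recorded.
#' @param update recruitment scheme: `"wright_fisher"` (synchronous softmax
#'   resampling of the whole population, the default) or `"imitation"`
#'   (each agent compares itself with one random partner per step and adopts
#'   the partner's traits with the Fermi probability
#'   `1/(1 + exp(-alpha * payoff difference))`).
#' @return An object of class `learning_control`.
#' @export
learning_control <- function(n = 5L, N = 100L, alpha = 2, mu = 0.01,
                             sigma = 0.005, steps = 30000L,
                             record_every = 100L,
                             update = c("wright_fisher", "imitation")) {
  update <- match.arg(update)
  n <- as.integer(n); N <- as.integer(N)
  steps <- as.integer(steps); record_every <- as.integer(record_every)
  if (N %% n != 0L) {
    stop("N (", N, ") must be a multiple of the group size n (", n, ")",
         call. = FALSE)
  }
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (steps < 1L) stop("steps must be >= 1", call. = FALSE)
  if (record_every < 1L) stop("record_every must be >= 1", call. = FALSE)
  structure(list(n = n, N = N, alpha = alpha, mu = mu, sigma = sigma,
                 steps = steps, record_every = record_every, update = update),
            class = "learning_control")
}

#' @export
print.learning_control <- function(x, ...) {
  cat(sprintf(
    "Learning control: N = %d agents, games of n = %d, alpha = %g, mu = %g, sigma = %g, %d steps\n",
    x$N, x$n, x$alpha, x$mu, x$sigma, x$steps))
  invisible(x)
}

#' Initial-population specifications
#'
#' @param x0,y0 trait values of the shared strategy (monomorphic) or the
#'   centre of a noisy blob.
#' @param sd blob standard deviation.
#' @param x,y explicit trait vectors.
#' @return An `init_spec` object consumed by [simulate_colony()].
#' @name init_spec
NULL

#' @rdname init_spec
#' @export
init_monomorphic <- function(x0, y0) {
  trait_triple(x0, y0)  # validates
  structure(list(kind = "monomorphic", x0 = x0, y0 = y0), class = "init_spec")
}

#' @rdname init_spec
#' @export
init_uniform_simplex <- function() {
  structure(list(kind = "uniform_simplex"), class = "init_spec")
}

#' @rdname init_spec
#' @export
init_explicit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (any(x < 0) || any(y < 0) || any(x + y > 1 + 1e-12)) {
    stop("explicit initial traits must lie on the simplex", call. = FALSE)
  }
  structure(list(kind = "explicit", x = x, y = y), class = "init_spec")
}

#' @rdname init_spec
#' @export
init_blob <- function(x0, y0, sd = 0.01) {
  structure(list(kind = "blob", x0 = x0, y0 = y0, sd = sd),
            class = "init_spec")
}

#' Build an initial population from a specification
#'
#' @param control a [learning_control()].
#' @param init an `init_spec` (see [init_monomorphic()] and friends).
#' @param mode `"full"`, `"M1"` (x frozen at 0) or `"M2"` (y frozen at 0).
#' @return List with numeric vectors `x` and `y` of length `N`.
#' @export
init_population <- function(control, init = init_uniform_simplex(),
                            mode = "full") {
  N <- control$N
  pop <- switch(init$kind,
    monomorphic = list(x = rep(init$x0, N), y = rep(init$y0, N)),
    uniform_simplex = {
      # uniform Dirichlet(1,1,1) via normalized exponentials
      e <- matrix(stats::rexp(3L * N), ncol = 3L)
      e <- e / rowSums(e)
      list(x = e[, 1L], y = e[, 2L])
    },
    explicit = {
      if (length(init$x) != N) {
        stop("explicit initial population has length ", length(init$x),
             ", expected N = ", N, call. = FALSE)
      }
      list(x = init$x, y = init$y)
    },
    blob = {
      p <- project_simplex(init$x0 + stats::rnorm(N, 0, init$sd),
                           init$y0 + stats::rnorm(N, 0, init$sd))
      list(x = p$x, y = p$y)
    },
    stop("unknown init spec '", init$kind, "'", call. = FALSE))
  if (mode == "M1") pop$x <- rep(0, N)
  if (mode == "M2") pop$y <- rep(0, N)
  pop
}

#' Random partition of the population into games
#'
#' @param N population size.
#' @param n group size.
#' @return Integer vector: a permutation of `1:N`; consecutive blocks of `n`
#'   indices form the `K = N/n` games.
#' @export
partition_games <- function(N, n) {
  if (N %% n != 0L) {
    stop("cannot partition ", N, " agents into games of ", n, call. = FALSE)
  }
  sample.int(N)
}

#' Payoffs of the whole population under a game partition
#'
#' @param x,y trait vectors of length `N`.
#' @param perm a permutation from [partition_games()].
#' @param env a [colony_env()].
#' @param n group size.
#' @param mode game mode.
#' @return Numeric vector of `N` payoffs aligned with population indexing.
#' @export
compute_payoffs <- function(x, y, perm, env, n, mode = "full") {
  N <- length(x)
  K <- N %/% n
  xs <- x[perm]; ys <- y[perm]
  dim(xs) <- c(n, K); dim(ys) <- c(n, K)
  share <- combined_benefit(.colSums(xs, n, K), .colSums(ys, n, K),
                            env, n, mode)
  payoff <- numeric(N)
  payoff[perm] <- rep(share, each = n)
  payoff - individual_cost(x, y, env, mode)
}

#' Softmax recruitment weights
#'
#' Probability that each agent is copied, proportional to
#' `exp(alpha * payoff)` over the whole population (max-shifted for overflow
#' safety).
#'
#' @param payoffs numeric vector of payoffs.
#' @param alpha selection intensity.
#' @return Probability vector summing to 1.
#' @export
softmax_weights <- function(payoffs, alpha) {
  if (any(!is.finite(payoffs))) {
    stop("non-finite payoffs in recruitment step: ",
         paste(utils::head(which(!is.finite(payoffs))), collapse = ", "),
         call. = FALSE)
  }
  w <- exp(alpha * (payoffs - max(payoffs)))
  w / sum(w)
}

#' Euclidean projection onto the feasible trait set
#'
#' Projects points `(x, y)` onto `{x >= 0, y >= 0, x + y <= 1}` (the closest
#' feasible point in Euclidean distance). Vectorized.
#'
#' @param x,y numeric vectors.
#' @return List with projected vectors `x` and `y`.
#' @export
project_simplex <- function(x, y) {
  px <- pmax(x, 0); py <- pmax(y, 0)
  over <- px + py > 1
  if (any(over)) {
    # project onto the line x + y = 1, then clamp to the segment's ends
    xo <- x[over]; yo <- y[over]
    t <- (xo - yo + 1) / 2
    t <- pmin(pmax(t, 0), 1)
    px[over] <- t
    py[over] <- 1 - t
  }
  list(x = px, y = py)
}

.mutate <- function(x, y, mu, sigma, mode) {
  N <- length(x)
  if (mu <= 0 || sigma <= 0) return(list(x = x, y = y))
  hit <- which(stats::runif(N) < mu)
  m <- length(hit)
  if (m == 0L) return(list(x = x, y = y))
  if (mode == "M1") {
    yn <- y[hit] + stats::rnorm(m, 0, sigma)
    y[hit] <- pmin(pmax(yn, 0), 1)
  } else if (mode == "M2") {
    xn <- x[hit] + stats::rnorm(m, 0, sigma)
    x[hit] <- pmin(pmax(xn, 0), 1)
  } else {
    p <- project_simplex(x[hit] + stats::rnorm(m, 0, sigma),
                         y[hit] + stats::rnorm(m, 0, sigma))
    x[hit] <- p$x
    y[hit] <- p$y
  }
  list(x = x, y = y)
}

#' Simulate the social-learning dynamics
#'
#' Runs the discrete-time loop: random game assignment, payoff computation,
#' population-wide softmax recruitment (synchronous Wright-Fisher resampling
#' of parents with weights `exp(alpha * payoff)`), then Gaussian trait
#' mutation projected back onto the simplex. Identical `seed` and
#' configuration give bitwise-identical trajectories.
#'
#' @param env a [colony_env()].
#' @param control a [learning_control()].
#' @param init an `init_spec`; default uniform on the trait simplex.
#' @param mode `"full"` (both tasks + inactivity), `"M1"` (task Y +
#'   inactivity) or `"M2"` (task X + inactivity).
#' @param seed integer RNG seed.
#' @param cull optional culling experiment: a list with elements `t_cull`
#'   (step at which workers are removed), `fraction` (proportion of active
#'   workers removed, in (0, 1)) and optionally `activity_threshold` (z cutoff
#'   below which an agent counts as active; default 0.5). The removal count is
#'   rounded down to a multiple of `n` so the survivors still partition into
#'   games.
#' @return An object of class `colony_sim`: list with `summary` (per-step
#'   data frame: step, mean_x, mean_y, mean_z, var_z, mean_payoff,
#'   active_frac), `snapshots` (list of population matrices with columns
#'   x, y, z), `snapshot_steps`, and the resolved configuration.
#' @examples
#' env <- colony_env(b1 = 23, b2 = -6, w = 0.25, beta = 3)
#' sim <- simulate_colony(env, learning_control(steps = 500), seed = 1)
#' sim
#' @export
simulate_colony <- function(env, control = learning_control(),
                            init = init_uniform_simplex(), mode = "full",
                            seed = 1L, cull = NULL) {
  stopifnot(inherits(env, "colony_env"), inherits(control, "learning_control"))
  mode <- match.arg(mode, c("full", "M1", "M2"))
  if (!is.null(cull)) {
    if (is.null(cull$activity_threshold)) cull$activity_threshold <- 0.5
    if (!(cull$fraction > 0 && cull$fraction < 1)) {
      stop("cull$fraction must lie in (0, 1)", call. = FALSE)
    }
    if (cull$t_cull >= control$steps) {
      stop("cull$t_cull must precede the end of the run", call. = FALSE)
    }
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)

  n <- control$n; N <- control$N
  steps <- control$steps; rec <- control$record_every
  pop <- init_population(control, init, mode)
  x <- pop$x; y <- pop$y

  sm <- matrix(NA_real_, nrow = steps, ncol = 8L)
  snap_steps <- if (rec <= steps) unique(c(seq(rec, steps, by = rec), steps))
    else steps
  snapshots <- vector("list", length(snap_steps))
  snap_i <- 1L
  cull_record <- NULL

  for (t in seq_len(steps)) {
    perm <- partition_games(N, n)
    payoff <- compute_payoffs(x, y, perm, env, n, mode)
    if (control$update == "wright_fisher") {
      prob <- softmax_weights(payoff, control$alpha)
      parents <- sample.int(N, N, replace = TRUE, prob = prob)
      x <- x[parents]; y <- y[parents]
    } else {
      partner <- sample.int(N, N, replace = TRUE)
      p_adopt <- 1 / (1 + exp(-control$alpha * (payoff[partner] - payoff)))
      adopt <- stats::runif(N) < p_adopt
      x[adopt] <- x[partner[adopt]]
      y[adopt] <- y[partner[adopt]]
    }
    mut <- .mutate(x, y, control$mu, control$sigma, mode)
    x <- mut$x; y <- mut$y

    if (!is.null(cull) && t == cull$t_cull) {
      z <- 1 - x - y
      active <- which(z < cull$activity_threshold)
      n_remove <- (floor(cull$fraction * length(active)) %/% n) * n
      if (n_remove > length(active)) {
        stop("culling requested more active agents than available",
             call. = FALSE)
      }
      if (n_remove > 0L) {
        victims <- active[sample.int(length(active), n_remove)]
        x <- x[-victims]; y <- y[-victims]
        N <- length(x)
      }
      cull_record <- list(t_cull = t, removed = n_remove, N_after = N,
                          fraction = cull$fraction,
                          activity_threshold = cull$activity_threshold)
    }

    z <- 1 - x - y
    sm[t, ] <- c(mean(x), mean(y), mean(z), stats::var(x), stats::var(y),
                 stats::var(z), mean(payoff), mean(z < 0.5))
    if (snap_i <= length(snap_steps) && t == snap_steps[snap_i]) {
      snapshots[[snap_i]] <- cbind(x = x, y = y, z = z)
      snap_i <- snap_i + 1L
    }
  }

  summary_df <- data.frame(step = seq_len(steps),
                           mean_x = sm[, 1L], mean_y = sm[, 2L],
                           mean_z = sm[, 3L], var_x = sm[, 4L],
                           var_y = sm[, 5L], var_z = sm[, 6L],
                           mean_payoff = sm[, 7L], active_frac = sm[, 8L])
  structure(list(summary = summary_df, snapshots = snapshots,
                 snapshot_steps = snap_steps, env = env, control = control,
                 init = init, mode = mode, seed = as.integer(seed),
                 cull = cull_record),
            class = "colony_sim")
}

#' Culling experiment: remove active workers at steady state
#'
#' Convenience wrapper around [simulate_colony()] with a `cull`
#' specification; removes `fraction` of the active workers (z below
#' `activity_threshold`) at step `t_cull` and lets the reduced colony evolve
#' on.
#'
#' @inheritParams simulate_colony
#' @param t_cull step at which workers are removed.
#' @param fraction proportion of active workers removed, in (0, 1).
#' @param activity_threshold z cutoff below which an agent counts as active.
#' @return A `colony_sim` (see [simulate_colony()]); its `cull` element
#'   records the removal.
#' @export
cull_experiment <- function(env, control = learning_control(),
                            init = init_uniform_simplex(), mode = "full",
                            seed = 1L, t_cull, fraction = 0.2,
                            activity_threshold = 0.5) {
  simulate_colony(env, control, init, mode, seed,
                  cull = list(t_cull = t_cull, fraction = fraction,
                              activity_threshold = activity_threshold))
}

#' @export
print.colony_sim <- function(x, ...) {
  s <- x$summary
  last <- s[nrow(s), ]
  cat(sprintf("Colony simulation (%s mode): %d agents, %d steps, seed %d\n",
              x$mode, x$control$N, x$control$steps, x$seed))
  cat(sprintf("  final means: x = %.3f, y = %.3f, z = %.3f; mean payoff = %.3f\n",
              last$mean_x, last$mean_y, last$mean_z, last$mean_payoff))
  if (!is.null(x$cull)) {
    cat(sprintf("  culled %d active agents at step %d (N now %d)\n",
                x$cull$removed, x$cull$t_cull, x$cull$N_after))
  }
  invisible(x)
}

#' Steady-state summary of a simulation
#'
#' Averages the trait summaries over the final `window` fraction of the run
#' and reports the cluster structure of the pooled window snapshots.
#'
#' @param object a `colony_sim`.
#' @param window final fraction of the run treated as the steady-state
#'   analysis window.
#' @param ... unused.
#' @return List of class `summary.colony_sim`.
#' @export
summary.colony_sim <- function(object, window = 0.1, ...) {
  s <- object$summary
  idx <- s$step > (1 - window) * max(s$step)
  win <- s[idx, ]
  cl <- detect_clusters(window_snapshot(object, window))
  out <- list(window = window,
              mean_x = mean(win$mean_x), mean_y = mean(win$mean_y),
              mean_z = mean(win$mean_z), mean_payoff = mean(win$mean_payoff),
              active_frac = mean(win$active_frac), clusters = cl,
              mode = object$mode, steps = object$control$steps)
  class(out) <- "summary.colony_sim"
  out
}

#' @export
print.summary.colony_sim <- function(x, ...) {
  cat(sprintf("Steady-state window (final %d%% of %d steps):\n",
              round(100 * x$window), x$steps))
  cat(sprintf("  mean traits: x = %.3f, y = %.3f, z = %.3f\n",
              x$mean_x, x$mean_y, x$mean_z))
  cat(sprintf("  mean payoff = %.3f, active fraction = %.3f\n",
              x$mean_payoff, x$active_frac))
  print(x$clusters)
  invisible(x)
}

#' Pooled population snapshot over the analysis window
#'
#' @param sim a `colony_sim`.
#' @param window final fraction of the run to pool.
#' @return Matrix with columns x, y, z; one row per agent per recorded
#'   snapshot in the window.
#' @export
window_snapshot <- function(sim, window = 0.1) {
  keep <- sim$snapshot_steps > (1 - window) * sim$control$steps
  do.call(rbind, sim$snapshots[keep])
}

#' @export
plot.colony_sim <- function(x, ...) {
  s <- x$summary
  oldpar <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(oldpar))
  graphics::matplot(s$step, s[, c("mean_x", "mean_y", "mean_z")],
                    type = "l", lty = 1, col = c("firebrick", "steelblue", "grey40"),
                    xlab = "step", ylab = "mean trait", main = "Trait means", ...)
  graphics::legend("topright", c("x", "y", "z"), lty = 1, bty = "n",
                   col = c("firebrick", "steelblue", "grey40"))
  graphics::plot(s$step, s$mean_payoff, type = "l", xlab = "step",
                 ylab = "mean payoff", main = "Mean payoff")
  if (!is.null(x$cull)) graphics::abline(v = x$cull$t_cull, lty = 2)
  invisible(x)
}
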