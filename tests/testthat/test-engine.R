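test_that("initial populations honour their specifications", {
  ctl <- learning_control(N = 10, steps = 10)
  pop <- init_population(ctl, init_monomorphic(0.3, 0.7))
  expect_equal(pop$x, rep(0.3, 10))
  expect_equal(pop$y, rep(0.7, 10))

  pop <- init_population(ctl, init_explicit(seq(0, 0.9, 0.1), rep(0.05, 10)))
  expect_equal(pop$x, seq(0, 0.9, 0.1))

  expect_error(init_population(ctl, init_explicit(runif(5) / 2, runif(5) / 2)),
               "length")

  # uniform simplex init has Dirichlet(1,1,1) moments: mean 1/3 per trait
  ctl <- learning_control(N = 10000, steps = 10)
  set.seed(1)
  pop <- init_population(ctl, init_uniform_simplex())
  z <- 1 - pop$x - pop$y
  expect_equal(mean(pop$x), 1 / 3, tolerance = 0.02)
  expect_equal(mean(pop$y), 1 / 3, tolerance = 0.02)
  expect_equal(mean(z), 1 / 3, tolerance = 0.02)
  expect_true(all(pop$x >= 0 & pop$y >= 0 & pop$x + pop$y <= 1 + 1e-12))
})

test_that("game partitions cover the population and are uniform", {
  set.seed(1)
  perm <- partition_games(10, 5)
  expect_setequal(perm, 1:10)
  expect_error(partition_games(11, 5), "partition")

  # P(agents 1 and 2 share a game) = (n-1)/(N-1) = 4/9
  hits <- replicate(10000, {
    p <- partition_games(10, 5)
    g <- integer(10); g[p] <- rep(1:2, each = 5)
    g[1] == g[2]
  })
  expect_equal(mean(hits), 4 / 9, tolerance = 0.03)
})

test_that("population payoffs align with per-group brute force", {
  env <- test_env()
  set.seed(3)
  for (rep in 1:20) {
    tr <- random_simplex(20)
    perm <- partition_games(20, 5)
    p <- compute_payoffs(tr$x, tr$y, perm, env, 5)
    expected <- numeric(20)
    for (k in 1:4) {
      idx <- perm[(5 * (k - 1) + 1):(5 * k)]
      expected[idx] <- oracle_group_payoffs(tr$x[idx], tr$y[idx], env)
    }
    expect_equal(p, expected, tolerance = 1e-12)
  }
  # monomorphic population: perfect payoff symmetry
  p <- compute_payoffs(rep(0.2, 20), rep(0.5, 20), partition_games(20, 5),
                       env, 5)
  expect_equal(var(p), 0)
  # all-inactive population earns nothing
  p <- compute_payoffs(rep(0, 20), rep(0, 20), partition_games(20, 5), env, 5)
  expect_equal(p, rep(0, 20))
})

test_that("softmax recruitment weights follow the stated formula", {
  expect_equal(softmax_weights(c(1, 0), alpha = 2),
               c(exp(2), 1) / (exp(2) + 1))
  # neutral selection and equal payoffs both give uniform weights
  expect_equal(softmax_weights(rnorm(10), alpha = 0), rep(0.1, 10))
  expect_equal(softmax_weights(rep(3.7, 8), alpha = 2), rep(1 / 8, 8))
  # overflow safety at large payoffs
  expect_equal(sum(softmax_weights(c(1e4, 1e4 - 1), alpha = 2)), 1)
  expect_error(softmax_weights(c(1, NaN), 2), "non-finite")
})

test_that("simplex projection matches the brute-force oracle", {
  pts <- list(c(0.7, 0.5), c(1.3, 0.2), c(-0.2, 0.6), c(-0.3, -0.4),
              c(1.2, 1.2), c(0.2, 0.3), c(1.5, -0.2))
  for (p in pts) {
    got <- project_simplex(p[1], p[2])
    want <- oracle_project(p[1], p[2])
    expect_equal(c(got$x, got$y), want, tolerance = 3e-3)
    expect_true(got$x >= 0 && got$y >= 0 && got$x + got$y <= 1 + 1e-12)
  }
  # interior points are fixed points
  expect_equal(project_simplex(0.2, 0.3), list(x = 0.2, y = 0.3))
})

test_that("runs are deterministic and conserve the simplex", {
  env <- test_env()
  ctl <- learning_control(N = 50, steps = 200)
  s1 <- simulate_colony(env, ctl, init_uniform_simplex(), seed = 11)
  s2 <- simulate_colony(env, ctl, init_uniform_simplex(), seed = 11)
  expect_identical(s1$summary, s2$summary)
  expect_identical(s1$snapshots, s2$snapshots)
  s3 <- simulate_colony(env, ctl, init_uniform_simplex(), seed = 12)
  expect_false(identical(s1$summary, s3$summary))
  # every recorded snapshot stays on the simplex with constant N
  for (sn in s1$snapshots) {
    expect_equal(nrow(sn), 50)
    expect_true(all(sn[, "x"] >= 0 & sn[, "y"] >= 0))
    expect_equal(rowSums(sn), rep(1, 50), tolerance = 1e-12)
  }
})

test_that("a monomorphic population without mutation is a fixed point", {
  env <- test_env()
  ctl <- learning_control(N = 20, mu = 0, steps = 100)
  sim <- simulate_colony(env, ctl, init_monomorphic(0.25, 0.6), seed = 5)
  expect_equal(sim$summary$mean_x, rep(0.25, 100))
  expect_equal(sim$summary$mean_y, rep(0.6, 100))
  expect_equal(sim$summary$var_z, rep(0, 100))
  # sigma = 0 likewise freezes the trait set
  ctl <- learning_control(N = 20, sigma = 0, steps = 50)
  sim <- simulate_colony(env, ctl, init_monomorphic(0.25, 0.6), seed = 5)
  expect_equal(sim$summary$mean_x, rep(0.25, 50))
})

test_that("neutral dynamics (alpha = 0) drift without direction", {
  env <- test_env()
  ctl <- learning_control(N = 50, alpha = 0, steps = 1000)
  deltas <- vapply(1:50, function(s) {
    sim <- simulate_colony(env, ctl, init_monomorphic(0.3, 0.4), seed = s)
    sim$summary$mean_x[1000] - 0.3
  }, numeric(1))
  tt <- t.test(deltas)
  expect_gt(tt$p.value, 0.01)
})

test_that("selection favours the strictly better trait", {
  # with all benefits switched off, payoff = -cost, so the lower-effort
  # strategy earns strictly more in every grouping; its one-step expected
  # frequency under softmax Wright-Fisher resampling is known in closed form
  env <- test_env(b1 = 0, b2 = 0)
  ctl <- learning_control(N = 50, mu = 0, steps = 1, record_every = 1)
  x0 <- c(rep(0.3, 25), rep(0.1, 25))
  y0 <- x0
  pi_hi <- -individual_cost(0.1, 0.1, env)   # better (cheaper) strategy
  pi_lo <- -individual_cost(0.3, 0.3, env)
  w <- exp(2 * c(pi_hi, pi_lo))
  expected <- 25 * w[1] / (25 * w[1] + 25 * w[2])
  freq <- vapply(1:200, function(s) {
    sim <- simulate_colony(env, ctl, init_explicit(x0, y0), seed = s)
    mean(sim$snapshots[[1]][, "x"] < 0.2)
  }, numeric(1))
  expect_equal(mean(freq), expected, tolerance = 0.03)
  expect_gt(mean(freq), 0.5)  # frequency of the better strategy rose
})

test_that("culling removes a multiple-of-n count of active agents and recovers bookkeeping", {
  env <- test_env(b1 = 28, b2 = -6)
  ctl <- learning_control(N = 60, steps = 400, record_every = 20)
  sim <- cull_experiment(env, ctl, init_monomorphic(0.3, 0.6), seed = 2,
                         t_cull = 200, fraction = 0.2)
  expect_false(is.null(sim$cull))
  expect_equal(sim$cull$removed %% 5, 0)
  expect_equal(sim$cull$N_after, 60 - sim$cull$removed)
  post <- sim$snapshots[[length(sim$snapshots)]]
  expect_equal(nrow(post), sim$cull$N_after)
  expect_equal(nrow(post) %% 5, 0)
  # activity ratio fractions always sum to 1
  ar <- activity_ratio(sim)
  expect_equal(ar$active + ar$inactive, rep(1, nrow(ar)))

  # a vanishing cull fraction removes nobody and replays the plain run exactly
  s0 <- simulate_colony(env, ctl, init_monomorphic(0.3, 0.6), seed = 2)
  s1 <- cull_experiment(env, ctl, init_monomorphic(0.3, 0.6), seed = 2,
                        t_cull = 200, fraction = 1e-4)
  expect_equal(s1$cull$removed, 0)
  expect_identical(s0$snapshots, s1$snapshots)
})

test_that("pairwise imitation updating preserves the engine contracts", {
  env <- test_env()
  ctl <- learning_control(N = 30, steps = 150, update = "imitation")
  s1 <- simulate_colony(env, ctl, init_uniform_simplex(), seed = 9)
  s2 <- simulate_colony(env, ctl, init_uniform_simplex(), seed = 9)
  expect_identical(s1$snapshots, s2$snapshots)
  for (sn in s1$snapshots) {
    expect_equal(rowSums(sn), rep(1, 30), tolerance = 1e-12)
  }
  # monomorphic fixed point holds under imitation too
  ctl0 <- learning_control(N = 30, mu = 0, steps = 50, update = "imitation")
  sim <- simulate_colony(env, ctl0, init_monomorphic(0.2, 0.3), seed = 1)
  expect_equal(sim$summary$mean_x, rep(0.2, 50))
})

test_that("sub-system modes freeze the absent trait", {
  env <- test_env()
  ctl <- learning_control(N = 20, steps = 100)
  sim1 <- simulate_colony(env, ctl, init_uniform_simplex(), mode = "M1",
                          seed = 3)
  expect_true(all(vapply(sim1$snapshots, function(s) all(s[, "x"] == 0),
                         logical(1))))
  sim2 <- simulate_colony(env, ctl, init_uniform_simplex(), mode = "M2",
                          seed = 3)
  expect_true(all(vapply(sim2$snapshots, function(s) all(s[, "y"] == 0),
                         logical(1))))
})
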