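test_that("homeostatic benefit is the clamped quadratic", {
  env <- test_env(b1 = 20, b2 = -4)
  expect_identical(benefit_x(0, env), 0)
  # vertex of the parabola at -b1/(2 b2) = 2.5
  expect_equal(benefit_x(2.5, env), 25)
  # root at Sx = 5: clamp boundary, never negative
  expect_equal(benefit_x(5, env), 0)
  S <- seq(0, 5, by = 0.01)
  expect_true(all(benefit_x(S, env) >= 0))
  # monotone when b2 >= 0 (maximizing task)
  envm <- test_env(b2 = 2)
  expect_true(all(diff(benefit_x(S, envm)) >= 0))
  expect_error(benefit_x(6, env), "outside")
  expect_error(benefit_x(-0.1, env), "outside")
})

test_that("thresholding benefit is an anchored, monotone sigmoid", {
  env <- test_env(w = 0.3, beta = 3)
  expect_equal(benefit_y(0, env), 0)
  expect_equal(benefit_y(5, env), 1)
  # symmetric about the inflection when w = 1/2
  env5 <- test_env(w = 0.5, beta = 3)
  expect_equal(benefit_y(2.5, env5), 0.5)
  # non-decreasing, with the steepest rise in the bin containing Sy/n = w
  for (w in c(0.1, 0.25, 0.4)) for (beta in 2:5) {
    e <- test_env(w = w, beta = beta)
    S <- seq(0, 5, length.out = 201)
    v <- benefit_y(S, e, n = 5)
    expect_true(all(diff(v) >= -1e-12))
    j <- which.max(diff(v))   # steepest bin [S_j, S_j+1] must straddle n*w
    expect_lte(S[j], 5 * w + 1e-9)
    expect_gte(S[j + 1], 5 * w - 1e-9)
  }
  expect_error(benefit_y(5.5, env), "outside")
})

test_that("benefits stay non-negative across the swept parameter ranges", {
  S <- seq(0, 5, length.out = 101)
  for (b1 in c(12, 20, 30)) for (b2 in c(-10, -4, 0, 10)) {
    e <- test_env(b1 = b1, b2 = b2)
    expect_true(all(benefit_x(S, e) >= 0))
  }
  for (w in c(0.1, 0.3, 0.5)) for (beta in 1:5) {
    e <- test_env(w = w, beta = beta)
    expect_true(all(benefit_y(S, e) >= 0))
  }
})

test_that("combined benefit couples multiplicatively and splits by mode", {
  env <- test_env(b1 = 20, b2 = -4, w = 0.3, beta = 3)
  # multiplicative coupling annihilates with either factor
  expect_equal(combined_benefit(0, 3, env, 5, "full"), 0)
  # (1/5) * 25 * 1 at the X vertex with saturated Y
  expect_equal(combined_benefit(2.5, 5, env, 5, "full"), 5)
  # sub-systems keep only their own factor
  expect_equal(combined_benefit(2.5, 5, env, 5, "M1"), 0.2)
  expect_equal(combined_benefit(2.5, 5, env, 5, "M2"), 5)
  expect_error(combined_benefit(1, 1, env, 5, "M3"), "unknown mode")
})

test_that("costs are additive, concave and zero at inactivity", {
  env <- test_env(cost_coeff_x = 1, cost_coeff_y = 1, cost_exponent = 0.5)
  expect_equal(individual_cost(0, 0, env), 0)
  expect_equal(individual_cost(0.25, 0, env), 0.5)
  expect_equal(individual_cost(0.25, 0.25, env), 1.0)
  # additivity: C(x, y) = C(x, 0) + C(0, y)
  x <- runif(20); y <- runif(20) * (1 - x)
  expect_equal(individual_cost(x, y, env),
               individual_cost(x, 0, env) + individual_cost(0, y, env))
  # concave increasing in each effort
  e <- seq(0.01, 1, length.out = 100)
  cx <- individual_cost(e, 0, env)
  expect_true(all(diff(cx) > 0))
  expect_true(all(diff(diff(cx)) < 1e-12))
})

test_that("group payoffs match a scalar per-member re-evaluation", {
  set.seed(42)
  for (mode in c("full", "M1", "M2")) {
    env <- test_env(b1 = runif(1, 12, 30), b2 = runif(1, -10, 0),
                    w = runif(1, 0.1, 0.5), beta = sample(1:5, 1),
                    cost_exponent = 0.65)
    for (rep in 1:333) {
      tr <- random_simplex(5)
      if (mode == "M1") tr$x <- rep(0, 5)
      if (mode == "M2") tr$y <- rep(0, 5)
      expect_equal(group_payoffs(tr$x, tr$y, env, mode = mode),
                   oracle_group_payoffs(tr$x, tr$y, env, mode),
                   tolerance = 1e-12)
    }
  }
})

test_that("equal traits earn equal payoffs; homogeneous groups in closed form", {
  env <- test_env()
  # two identical members in a random group
  set.seed(7)
  tr <- random_simplex(5)
  tr$x[2] <- tr$x[1]; tr$y[2] <- tr$y[1]
  p <- group_payoffs(tr$x, tr$y, env)
  expect_equal(p[1], p[2])
  # all-zero traits: zero benefit, zero cost
  expect_equal(group_payoffs(rep(0, 5), rep(0, 5), env), rep(0, 5))
  # homogeneous group with trait (x, y): (1/n) Bx(nx) By(ny) - C(x, y)
  for (i in 1:20) {
    t1 <- random_simplex(1)
    expected <- benefit_x(5 * t1$x, env) * benefit_y(5 * t1$y, env) / 5 -
      individual_cost(t1$x, t1$y, env)
    expect_equal(group_payoffs(rep(t1$x, 5), rep(t1$y, 5), env),
                 rep(expected, 5))
  }
  expect_error(group_payoffs(runif(4), runif(4), env, n = 5), "size mismatch")
})

test_that("trait triples and environments enforce their invariants", {
  expect_equal(trait_triple(0.3, 0.7), c(x = 0.3, y = 0.7, z = 0))
  expect_error(trait_triple(0.6, 0.6), "simplex")
  expect_error(trait_triple(-0.1, 0.5), "simplex")
  expect_error(colony_env(20, -4, w = 1.5, beta = 3), "w must")
  expect_error(colony_env(20, -4, w = 0.3, beta = 3, cost_exponent = 1.5),
               "cost_exponent")
  expect_error(colony_env(20, -4, 0.3, 3, benefit_x_shape = "nope"),
               "unknown benefit shape")
})

test_that("user-registered shapes are picked up by name", {
  register_shape("linear_ramp", function(S, env, n) S / n, "benefit")
  env <- test_env(benefit_y_shape = "linear_ramp")
  expect_equal(benefit_y(2.5, env, 5), 0.5)
})
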