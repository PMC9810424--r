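# Benefit, cost and payoff functions of the n-player task-allocation game.
#
# Two prototypical tasks: X is homeostatic (concave, unimodal collective
# benefit; over-investment hurts), Y is thresholding (sigmoidal collective
# benefit with inflection at per-capita effort w). Group benefits couple
# multiplicatively and are shared equally; costs are individual and additive
# across tasks, with marginally decreasing (concave) cost per task.

.shape_registry <- new.env(parent = emptyenv())

#' Register a benefit or cost shape
#'
#' Benefit and cost functions are pluggable by name so that alternative
#' functional forms (e.g. a monotone maximizing-task benefit) can be dropped
#' in without touching the engine. A benefit shape is a function
#' `function(S, env, n)` returning a non-negative benefit for collective
#' effort `S` in `[0, n]`; a cost shape is a function
#' `function(effort, coeff, env)` returning the individual cost of scalar
#' effort in `[0, 1]`.
#'
#' @param name shape name used in [colony_env()].
#' @param fun the shape function (see Details above).
#' @param kind `"benefit"` or `"cost"`.
#' @return `name`, invisibly.
#' @export
register_shape <- function(name, fun, kind = c("benefit", "cost")) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(paste0(kind, ".", name), fun, envir = .shape_registry)
  invisible(name)
}

.get_shape <- function(name, kind) {
  key <- paste0(kind, ".", name)
  if (!exists(key, envir = .shape_registry, inherits = FALSE)) {
    stop("unknown ", kind, " shape: '", name, "'", call. = FALSE)
  }
  get(key, envir = .shape_registry, inherits = FALSE)
}

.register_default_shapes <- function() {
  # Quadratic-clamped homeostatic benefit: b1*S + b2*S^2, floored at 0.
  register_shape("quadratic", function(S, env, n) {
    pmax(0, env$b1 * S + env$b2 * S^2)
  }, "benefit")
  # Normalized tanh sigmoid in per-capita effort, anchored at 0 and 1 so that
  # B(0) = 0 and B(n) = 1; inflection at S/n = w, steepness beta. As beta -> 0
  # this tends to the linear ramp S/n.
  register_shape("tanh_sigmoid", function(S, env, n) {
    lo <- tanh(env$beta * env$w)
    hi <- tanh(env$beta * (1 - env$w))
    (tanh(env$beta * (S / n - env$w)) + lo) / (hi + lo)
  }, "benefit")
  # Power-law cost, concave for exponent <= 1 ("tasks become easier with
  # practice"); cost of zero effort is exactly 0.
  register_shape("power", function(effort, coeff, env) {
    coeff * effort^env$cost_exponent
  }, "cost")
}

.register_default_shapes()

#' Environment parameters of the task-allocation game
#'
#' Bundles the parameters that describe the two tasks and the individual cost
#' of effort, fully determining the game's benefit and cost functions.
#'
#' @param b1 linear benefit coefficient of task X (payoff units per unit
#'   collective effort). Larger values mean easier regulation.
#' @param b2 quadratic benefit coefficient of task X. Negative values give a
#'   unimodal homeostatic benefit; non-negative values a monotone maximizing
#'   task.
#' @param w inflection point of the task-Y benefit, as a per-capita effort
#'   fraction in (0, 1); roughly, `1/w` indexes the minimum collective work
#'   the task requires.
#' @param beta slope of the task-Y benefit at its inflection (>= 1 for a
#'   threshold-like shape; `beta = 1` is nearly linear).
#' @param cost_coeff_x,cost_coeff_y cost scale of each task (payoff units at
#'   full effort).
#' @param cost_exponent concavity of the cost in own effort, in (0, 1].
#' @param benefit_x_shape,benefit_y_shape,cost_shape names of registered
#'   functional forms (see [register_shape()]).
#' @return An object of class `colony_env`.
#' @examples
#' env <- colony_env(b1 = 20, b2 = -4, w = 0.3, beta = 3)
#' benefit_x(2.5, env)   # vertex of the homeostatic parabola
#' @export
colony_env <- function(b1, b2, w, beta,
                       cost_coeff_x = 0.6, cost_coeff_y = 0.6,
                       cost_exponent = 0.65,
                       benefit_x_shape = "quadratic",
                       benefit_y_shape = "tanh_sigmoid",
                       cost_shape = "power") {
  stopifnot(is.numeric(b1), is.numeric(b2), is.numeric(w), is.numeric(beta))
  if (!(w > 0 && w < 1)) stop("w must lie strictly in (0, 1)", call. = FALSE)
  if (beta < 0) stop("beta must be non-negative", call. = FALSE)
  if (cost_coeff_x < 0 || cost_coeff_y < 0) {
    stop("cost coefficients must be non-negative", call. = FALSE)
  }
  if (!(cost_exponent > 0 && cost_exponent <= 1)) {
    stop("cost_exponent must lie in (0, 1] (marginally decreasing costs)",
         call. = FALSE)
  }
  env <- structure(
    list(b1 = b1, b2 = b2, w = w, beta = beta,
         cost_coeff_x = cost_coeff_x, cost_coeff_y = cost_coeff_y,
         cost_exponent = cost_exponent,
         benefit_x_shape = benefit_x_shape,
         benefit_y_shape = benefit_y_shape,
         cost_shape = cost_shape),
    class = "colony_env")
  # resolve now so bad names fail fast
  .get_shape(benefit_x_shape, "benefit")
  .get_shape(benefit_y_shape, "benefit")
  .get_shape(cost_shape, "cost")
  env
}

#' @export
print.colony_env <- function(x, ...) {
  cat("Task-allocation environment\n")
  cat(sprintf("  task X (%s): b1 = %g, b2 = %g\n",
              x$benefit_x_shape, x$b1, x$b2))
  cat(sprintf("  task Y (%s): w = %g, beta = %g\n",
              x$benefit_y_shape, x$w, x$beta))
  cat(sprintf("  costs (%s): coeff = (%g, %g), exponent = %g\n",
              x$cost_shape, x$cost_coeff_x, x$cost_coeff_y, x$cost_exponent))
  invisible(x)
}

#' Trait triple of one worker
#'
#' A worker's behavioural strategy is a point on the 2-simplex: the
#' probabilities of engaging in task X (`x`), task Y (`y`) and remaining
#' inactive (`z = 1 - x - y`). `z` is stored implicitly.
#'
#' @param x,y task engagement probabilities, with `x, y >= 0` and
#'   `x + y <= 1`.
#' @return Named numeric vector `c(x, y, z)`.
#' @export
trait_triple <- function(x, y) {
  if (any(x < 0) || any(y < 0) || any(x + y > 1 + 1e-12)) {
    stop("trait triple off the simplex: need x, y >= 0 and x + y <= 1",
         call. = FALSE)
  }
  c(x = x, y = y, z = max(0, 1 - x - y))
}

.check_effort <- function(S, n, label) {
  if (any(!is.finite(S)) || any(S < -1e-12) || any(S > n + 1e-12)) {
    stop(label, " collective effort outside [0, n]", call. = FALSE)
  }
}

#' Collective benefit of the homeostatic task X
#'
#' @param Sx collective task-X effort of one game group (sum of member `x`
#'   values, in `[0, n]`). Vectorized.
#' @param env a [colony_env()].
#' @param n group size.
#' @return Non-negative benefit value(s).
#' @export
benefit_x <- function(Sx, env, n = 5L) {
  .check_effort(Sx, n, "task-X")
  .get_shape(env$benefit_x_shape, "benefit")(Sx, env, n)
}

#' Collective benefit of the thresholding task Y
#'
#' The default normalized-tanh form rises sigmoidally from 0 at zero effort to
#' 1 at full collective effort, with inflection at per-capita effort `w` and
#' steepness `beta`.
#'
#' @inheritParams benefit_x
#' @param Sy collective task-Y effort (in `[0, n]`). Vectorized.
#' @return Benefit value(s) in `[0, 1]`.
#' @export
benefit_y <- function(Sy, env, n = 5L) {
  .check_effort(Sy, n, "task-Y")
  .get_shape(env$benefit_y_shape, "benefit")(Sy, env, n)
}

#' Per-member benefit share of a game group
#'
#' In the full system the two task benefits couple multiplicatively and the
#' product is shared equally among the n group members. The sub-systems keep
#' only their own task's benefit factor: `M1` is task Y plus inactivity,
#' `M2` is task X plus inactivity.
#'
#' @param Sx,Sy collective efforts of the group (vectorized in parallel).
#' @param env a [colony_env()].
#' @param n group size.
#' @param mode `"full"`, `"M1"` or `"M2"`.
#' @return Per-member benefit share(s).
#' @export
combined_benefit <- function(Sx, Sy, env, n = 5L, mode = "full") {
  switch(mode,
    full = benefit_x(Sx, env, n) * benefit_y(Sy, env, n) / n,
    M1   = benefit_y(Sy, env, n) / n,
    M2   = benefit_x(Sx, env, n) / n,
    stop("unknown mode '", mode, "' (use \"full\", \"M1\" or \"M2\")",
         call. = FALSE))
}

#' Individual cost of effort
#'
#' Costs are borne individually and add across tasks:
#' `C(x, y) = C_X(x) + C_Y(y)` with concave per-task components, so the fully
#' inactive strategy is free. Sub-systems only carry their own task's cost
#' term.
#'
#' @param x,y individual efforts (vectorized in parallel).
#' @param env a [colony_env()].
#' @param mode `"full"`, `"M1"` or `"M2"`.
#' @return Cost value(s).
#' @export
individual_cost <- function(x, y, env, mode = "full") {
  costf <- .get_shape(env$cost_shape, "cost")
  cx <- costf(x, env$cost_coeff_x, env)
  cy <- costf(y, env$cost_coeff_y, env)
  switch(mode,
    full = cx + cy,
    M1   = cy,
    M2   = cx,
    stop("unknown mode '", mode, "'", call. = FALSE))
}

#' Payoffs of one game group
#'
#' Each of the n members receives the common benefit share minus their own
#' cost.
#'
#' @param x,y numeric vectors of length n: the members' trait values.
#' @param env a [colony_env()].
#' @param n group size; `length(x)` must equal `n`.
#' @param mode `"full"`, `"M1"` or `"M2"`.
#' @return Numeric vector of n payoffs, aligned with the members.
#' @export
group_payoffs <- function(x, y, env, n = length(x), mode = "full") {
  if (length(x) != n || length(y) != n) {
    stop("group size mismatch: expected ", n, " members", call. = FALSE)
  }
  share <- combined_benefit(sum(x), sum(y), env, n, mode)
  share - individual_cost(x, y, env, mode)
}
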