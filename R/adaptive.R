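# Adaptive-dynamics layer: invasion fitness of rare mutants, selection
# gradients, singular strategies with ESS/branching classification, and
# streamline fields over the trait simplex. Everything here is numerically
# generic: it only evaluates the pluggable benefit/cost forms, so alternative
# shapes registered via register_shape() are analysed identically.

.active_dims <- function(mode) {
  switch(mode, full = c(1L, 2L), M1 = 2L, M2 = 1L,
         stop("unknown mode '", mode, "'", call. = FALSE))
}

.feasible <- function(p, margin = 0) {
  p[1L] >= margin && p[2L] >= margin && p[1L] + p[2L] <= 1 - margin
}

#' Invasion payoff of a rare mutant
#'
#' Expected payoff of a single mutant playing in a group with n - 1 residents,
#' minus the payoff of a resident in an all-resident group. Zero at
#' `mutant == resident` by construction.
#'
#' @param mutant,resident numeric length-2 vectors `c(x, y)` on the feasible
#'   simplex.
#' @param env a [colony_env()].
#' @param n group size.
#' @param mode game mode.
#' @return Scalar invasion fitness.
#' @export
invasion_payoff <- function(mutant, resident, env, n = 5L, mode = "full") {
  if (!.feasible(mutant) || !.feasible(resident)) {
    stop("mutant and resident must lie on the feasible simplex", call. = FALSE)
  }
  sxm <- mutant[1L] + (n - 1) * resident[1L]
  sym <- mutant[2L] + (n - 1) * resident[2L]
  f_m <- combined_benefit(sxm, sym, env, n, mode) -
    individual_cost(mutant[1L], mutant[2L], env, mode)
  f_r <- combined_benefit(n * resident[1L], n * resident[2L], env, n, mode) -
    individual_cost(resident[1L], resident[2L], env, mode)
  f_m - f_r
}

# numerical partial derivative of invasion fitness wrt mutant coordinate d,
# at mutant = resident; one-sided near the feasible boundary
.inv_partial <- function(resident, d, env, n, mode, h) {
  base <- resident
  up <- base; up[d] <- up[d] + h
  dn <- base; dn[d] <- dn[d] - h
  if (.feasible(up) && .feasible(dn)) {
    (invasion_payoff(up, resident, env, n, mode) -
       invasion_payoff(dn, resident, env, n, mode)) / (2 * h)
  } else if (.feasible(up)) {
    invasion_payoff(up, resident, env, n, mode) / h
  } else if (.feasible(dn)) {
    -invasion_payoff(dn, resident, env, n, mode) / h
  } else {
    NA_real_
  }
}

#' Selection gradient at a resident strategy
#'
#' Partial derivatives of [invasion_payoff()] with respect to the mutant
#' traits, evaluated at mutant = resident. Central finite differences with
#' step `h`; a Richardson check (comparison of the `h` and `h/2` estimates)
#' is attached as attribute `"richardson_error"`.
#'
#' @param resident numeric `c(x, y)` on the feasible simplex.
#' @param env a [colony_env()].
#' @param n group size.
#' @param mode game mode; sub-system gradients are taken only along their own
#'   task direction (the frozen trait's component is 0).
#' @param h finite-difference step.
#' @return Numeric length-2 gradient `c(dx, dy)`.
#' @export
selection_gradient <- function(resident, env, n = 5L, mode = "full",
                               h = 1e-5) {
  dims <- .active_dims(mode)
  g <- c(0, 0)
  g2 <- c(0, 0)
  for (d in dims) {
    g[d] <- .inv_partial(resident, d, env, n, mode, h)
    g2[d] <- .inv_partial(resident, d, env, n, mode, h / 2)
  }
  if (any(!is.finite(g[dims]))) {
    stop("non-finite selection gradient at resident (",
         paste(signif(resident, 4), collapse = ", "), ")", call. = FALSE)
  }
  structure(g, richardson_error = max(abs(g2 - g)))
}

# Newton iteration on the gradient map restricted to the active dimensions
.newton_singular <- function(start, env, n, mode, tol = 1e-8, margin = 1e-4,
                             maxit = 60L) {
  dims <- .active_dims(mode)
  r <- start
  gfun <- function(p) selection_gradient(p, env, n, mode)[dims]
  for (it in seq_len(maxit)) {
    g <- gfun(r)
    if (max(abs(g)) < tol) return(list(root = r, ok = TRUE))
    J <- tryCatch(pracma::jacobian(function(v) {
      p <- r; p[dims] <- v; gfun(p)
    }, r[dims]), error = function(e) NULL)
    if (is.null(J) || any(!is.finite(J)) ||
        abs(det(as.matrix(J))) < 1e-14) {
      return(list(root = r, ok = FALSE))
    }
    step <- tryCatch(solve(J, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      return(list(root = r, ok = FALSE))
    }
    # damp long steps; keep a safe margin off the boundary
    sl <- sqrt(sum(step^2))
    if (sl > 0.2) step <- step * (0.2 / sl)
    cand <- r
    cand[dims] <- r[dims] - step
    cand[1L] <- min(max(cand[1L], margin), 1 - margin)
    cand[2L] <- min(max(cand[2L], margin), 1 - margin)
    if (cand[1L] + cand[2L] > 1 - margin) {
      cand <- cand * ((1 - margin) / (cand[1L] + cand[2L]))
    }
    if (max(abs(cand - r)) < 1e-13) return(list(root = r, ok = FALSE))
    r <- cand
  }
  list(root = r, ok = max(abs(gfun(r))) < tol)
}

.classify_singular <- function(root, env, n, mode, tol = 1e-5) {
  dims <- .active_dims(mode)
  H <- pracma::hessian(function(v) {
    m <- root; m[dims] <- v
    invasion_payoff(m, root, env, n, mode)
  }, root[dims])
  J <- pracma::jacobian(function(v) {
    p <- root; p[dims] <- v
    selection_gradient(p, env, n, mode)[dims]
  }, root[dims])
  eH <- eigen(as.matrix(H), symmetric = TRUE, only.values = TRUE)$values
  eJ <- eigen(as.matrix(J), only.values = TRUE)$values
  invadable <- max(eH) > tol
  uninvadable <- max(eH) < -tol
  conv_stable <- all(Re(eJ) < -tol)
  repelling <- any(Re(eJ) > tol)
  classification <- if (conv_stable && invadable) "branching_point"
    else if (conv_stable && uninvadable) "ESS"
    else if (repelling) "repeller"
    else "degenerate"
  list(second_order = list(mutant_hessian = H, gradient_jacobian = J,
                           hessian_eigen = eH, jacobian_eigen = eJ),
       classification = classification,
       convergence_stable = conv_stable, invadable = invadable)
}

.default_starts <- function(mode) {
  if (mode == "full") {
    lat <- expand.grid(x = c(0.15, 0.4, 0.7), y = c(0.15, 0.4, 0.7))
    lat <- lat[lat$x + lat$y <= 0.92, ]
    starts <- lapply(seq_len(nrow(lat)), function(i) c(lat$x[i], lat$y[i]))
    c(starts, list(c(0.05, 0.05), c(0.85, 0.05), c(0.05, 0.85),
                   c(0.3, 0.6), c(0.6, 0.3)))
  } else if (mode == "M1") {
    lapply(c(0.05, 0.2, 0.5, 0.8, 0.95), function(v) c(0, v))
  } else {
    lapply(c(0.05, 0.2, 0.5, 0.8, 0.95), function(v) c(v, 0))
  }
}

#' Find and classify singular strategies
#'
#' Root-finds the selection gradient from multiple starting residents
#' (damped Newton on the gradient map), deduplicates converged roots, and
#' classifies each by the standard second-order conditions: definiteness of
#' the mutant Hessian of invasion fitness (local uninvadability) and the
#' eigenvalues of the Jacobian of the gradient map (convergence stability).
#' A convergence-stable, invadable singular strategy is an evolutionary
#' branching point; convergence-stable and uninvadable is an ESS.
#'
#' @param env a [colony_env()].
#' @param n group size.
#' @param mode game mode.
#' @param starts list of starting residents `c(x, y)`; defaults to an
#'   interior lattice plus near-vertex points.
#' @param tol gradient tolerance for acceptance.
#' @return List of class `singular_list`; each element has `location`,
#'   `gradient_norm`, `classification`, `convergence_stable`, `invadable` and
#'   `second_order`.
#' @export
find_singular <- function(env, n = 5L, mode = "full", starts = NULL,
                          tol = 1e-8) {
  if (is.null(starts)) starts <- .default_starts(mode)
  dims <- .active_dims(mode)
  found <- list()
  for (s in starts) {
    res <- tryCatch(.newton_singular(s, env, n, mode, tol),
                    error = function(e) list(ok = FALSE))
    if (!isTRUE(res$ok)) next
    r <- res$root
    dup <- any(vapply(found, function(f)
      max(abs(f$location - r)) < 1e-4, logical(1)))
    if (dup) next
    g <- selection_gradient(r, env, n, mode)
    cls <- .classify_singular(r, env, n, mode)
    found[[length(found) + 1L]] <- c(
      list(location = r, gradient_norm = sqrt(sum(g[dims]^2))), cls)
  }
  structure(found, class = "singular_list")
}

#' @export
print.singular_list <- function(x, ...) {
  if (length(x) == 0L) {
    cat("No singular strategies found (flow runs to the simplex boundary)\n")
    return(invisible(x))
  }
  for (s in x) {
    cat(sprintf("Singular strategy at (x, y) = (%.4f, %.4f): %s\n",
                s$location[1L], s$location[2L], s$classification))
    cat(sprintf("  |gradient| = %.2e, convergence-stable: %s, invadable: %s\n",
                s$gradient_norm, s$convergence_stable, s$invadable))
  }
  invisible(x)
}

#' Selection-gradient field over the trait simplex
#'
#' @param env a [colony_env()].
#' @param n group size.
#' @param mode game mode.
#' @param grid_n nodes per axis.
#' @param margin distance kept off the simplex boundary.
#' @return Data frame with columns x, y, dx, dy (one row per feasible node).
#' @export
streamline_field <- function(env, n = 5L, mode = "full", grid_n = 15L,
                             margin = 0.02) {
  ax <- seq(margin, 1 - margin, length.out = grid_n)
  nodes <- expand.grid(x = ax, y = ax, KEEP.OUT.ATTRS = FALSE)
  nodes <- nodes[nodes$x + nodes$y <= 1 - margin, ]
  if (mode == "M1") nodes$x <- 0
  if (mode == "M2") nodes$y <- 0
  nodes <- unique(nodes)
  g <- t(vapply(seq_len(nrow(nodes)), function(i)
    as.numeric(selection_gradient(c(nodes$x[i], nodes$y[i]), env, n, mode)),
    numeric(2)))
  data.frame(x = nodes$x, y = nodes$y, dx = g[, 1L], dy = g[, 2L])
}

#' Integrate the monomorphic trait flow
#'
#' Follows the selection gradient from a starting resident by projected Euler
#' steps until the motion stalls (an attractor, possibly on the simplex
#' boundary).
#'
#' @param start resident `c(x, y)`.
#' @param env a [colony_env()].
#' @param n group size.
#' @param mode game mode.
#' @param step_size maximum trait displacement per step.
#' @param max_steps iteration cap.
#' @return List with `end` (final resident) and `path` (matrix of visited
#'   points).
#' @export
flow_trajectory <- function(start, env, n = 5L, mode = "full",
                            step_size = 0.01, max_steps = 3000L) {
  dims <- .active_dims(mode)
  r <- start
  path <- matrix(NA_real_, nrow = max_steps + 1L, ncol = 2L)
  path[1L, ] <- r
  eps <- 1e-9
  for (it in seq_len(max_steps)) {
    g <- c(0, 0)
    g[dims] <- vapply(dims, function(d)
      .inv_partial(r, d, env, n, mode, 1e-5), numeric(1))
    g[!is.finite(g)] <- 0
    gn <- sqrt(sum(g^2))
    if (gn < 1e-7) break
    stp <- g * min(step_size / gn, 0.5)
    p <- project_simplex(r[1L] + stp[1L], r[2L] + stp[2L])
    newr <- c(p$x, p$y)
    if (mode == "M1") newr[1L] <- 0
    if (mode == "M2") newr[2L] <- 0
    if (max(abs(newr - r)) < eps) break
    r <- newr
    path[it + 1L, ] <- r
  }
  list(end = r, path = path[stats::complete.cases(path), , drop = FALSE])
}

#' Analytic region prediction from adaptive dynamics
#'
#' Fast path for region maps: finds singular strategies and, failing an
#' interior attractor, integrates the monomorphic flow from canonical
#' starting residents to see which simplex corners attract.
#'
#' @param env a [colony_env()].
#' @param n group size.
#' @param mode game mode.
#' @return A region label: `"branching"`, `"uniform_partly_active"`,
#'   `"fully_inactive"`, `"uniform_full_active_or_inactive"` or
#'   `"unresolved"`.
#' @export
predicted_region <- function(env, n = 5L, mode = "full") {
  sing <- find_singular(env, n, mode)
  interior <- Filter(function(s) {
    p <- s$location
    lo <- 1e-3
    ok_sum <- p[1L] + p[2L] < 1 - lo
    if (mode == "full") p[1L] > lo && p[2L] > lo && ok_sum
    else if (mode == "M1") p[2L] > lo && p[2L] < 1 - lo
    else p[1L] > lo && p[1L] < 1 - lo
  }, sing)
  cls <- vapply(interior, `[[`, character(1), "classification")
  if (any(cls == "branching_point")) return("branching")
  if (any(cls == "ESS")) return("uniform_partly_active")
  if (any(cls == "degenerate")) return("unresolved")

  starts <- if (mode == "full") {
    list(c(0.45, 0.5), c(1 / 3, 1 / 3), c(0.02, 0.02), c(0.3, 0.6))
  } else if (mode == "M1") {
    list(c(0, 0.9), c(0, 0.5), c(0, 0.05))
  } else {
    list(c(0.9, 0), c(0.5, 0), c(0.05, 0))
  }
  ends <- vapply(starts, function(s)
    1 - sum(flow_trajectory(s, env, n, mode)$end), numeric(1))  # z at endpoint
  if (all(ends > 0.95)) return("fully_inactive")
  if (any(ends > 0.95) && any(ends < 0.05)) {
    return("uniform_full_active_or_inactive")
  }
  if (any(ends >= 0.05 & ends <= 0.95)) return("uniform_partly_active")
  # every start runs to full activity; the inactive corner is still locally
  # absorbing under concave costs, so the region is the bistable uniform one
  "uniform_full_active_or_inactive"
}
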