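# Steady-state detection, branching detection, and classification of runs
# into behavioural regions (uniform fully active/inactive, uniform partly
# active, branching, fully inactive).

REGION_LABELS <- c("uniform_full_active_or_inactive", "uniform_partly_active",
                   "branching", "fully_inactive")

# Classification thresholds. Branches count as distinct only when their
# z-means differ by > sep_min and each holds >= weight_min of the population;
# "full" activity/inactivity uses the 0.05/0.95 boundaries, well clear of the
# sigma = 0.005 mutation noise floor.
.cluster_opts <- list(sep_min = 0.2, weight_min = 0.1,
                      z_full = 0.95, z_empty = 0.05, persistence = 0.7)

#' Cluster a population snapshot into behavioural branches
#'
#' Fits 1-D Gaussian mixtures with 1-3 components to the inactivity trait z
#' (BIC model selection), then merges components whose z-means differ by at
#' most 0.2 or that hold under 10% of the population, so that mutation noise
#' around a single strategy never counts as branching.
#'
#' @param snapshot matrix with columns x, y, z (rows = agents), or a numeric
#'   vector of z values.
#' @return Object of class `cluster_summary`: `k`, per-cluster `means`
#'   (data frame x, y, z ordered by increasing z), `weights`, and
#'   `separation` (z-distance between extreme cluster means).
#' @export
detect_clusters <- function(snapshot) {
  if (is.null(dim(snapshot))) {
    snapshot <- cbind(x = NA_real_, y = NA_real_, z = as.numeric(snapshot))
  }
  z <- snapshot[, "z"]
  if (length(z) == 0L) stop("empty snapshot", call. = FALSE)
  uz <- unique(round(z, 6))
  if (stats::sd(z) < 1e-9 || length(z) < 10L) {
    cls <- rep(1L, length(z))
  } else if (length(uz) <= 3L) {
    # discrete mixtures (constructed fixtures): each distinct value is a
    # candidate cluster; the merge rules below still apply
    cls <- match(round(z, 6), uz)
  } else {
    fit <- tryCatch(
      mclust::Mclust(z, G = 1:3, modelNames = "V", verbose = FALSE),
      error = function(e) NULL)
    cls <- if (is.null(fit)) rep(1L, length(z)) else fit$classification
  }
  .summarize_clusters(snapshot, cls)
}

.summarize_clusters <- function(snapshot, cls) {
  z <- snapshot[, "z"]
  agg <- function(v, g) tapply(v, g, mean)
  repeat {
    ids <- sort(unique(cls))
    mz <- agg(z, cls)[as.character(ids)]
    wt <- as.numeric(table(cls)[as.character(ids)]) / length(cls)
    ord <- order(mz)
    ids <- ids[ord]; mz <- mz[ord]; wt <- wt[ord]
    if (length(ids) == 1L) break
    # merge the closest adjacent pair if too close, else drop (absorb) the
    # lightest under-threshold cluster into its nearest neighbour
    gaps <- diff(mz)
    j <- which.min(gaps)
    if (gaps[j] <= .cluster_opts$sep_min) {
      cls[cls == ids[j + 1L]] <- ids[j]
      next
    }
    small <- which(wt < .cluster_opts$weight_min)
    if (length(small) > 0L) {
      s <- small[which.min(wt[small])]
      nb <- if (s == 1L) 2L else if (s == length(ids)) length(ids) - 1L else
        if (gaps[s - 1L] < gaps[s]) s - 1L else s + 1L
      cls[cls == ids[s]] <- ids[nb]
      next
    }
    break
  }
  ids <- sort(unique(cls))
  mz <- agg(z, cls)[as.character(ids)]
  ord <- order(mz)
  ids <- ids[ord]
  means <- data.frame(
    x = as.numeric(agg(snapshot[, "x"], cls)[as.character(ids)]),
    y = as.numeric(agg(snapshot[, "y"], cls)[as.character(ids)]),
    z = as.numeric(agg(z, cls)[as.character(ids)]))
  weights <- as.numeric(table(cls)[as.character(ids)]) / length(cls)
  structure(list(k = length(ids), means = means, weights = weights,
                 separation = if (length(ids) > 1L)
                   max(means$z) - min(means$z) else 0),
            class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat(sprintf("  %d behavioural cluster%s (z-separation %.3f)\n",
              x$k, if (x$k == 1L) "" else "s", x$separation))
  for (i in seq_len(x$k)) {
    cat(sprintf("    cluster %d: weight %.2f, mean (x, y, z) = (%.3f, %.3f, %.3f)\n",
                i, x$weights[i], x$means$x[i], x$means$y[i], x$means$z[i]))
  }
  invisible(x)
}

#' Classify a finished run into a behavioural region
#'
#' Applies decision rules over the final-window cluster structure:
#' persistent multi-cluster structure (two clusters with z-separation > 0.2,
#' each >= 10% of the population, in at least 70% of window snapshots) is
#' branching; otherwise the window-mean inactivity decides between fully
#' inactive (z > 0.95), fully active (z < 0.05) and uniform partly active.
#' A window whose mean z still trends strongly is reported as `"unresolved"`
#' rather than force-labelled.
#'
#' @param sim a `colony_sim`.
#' @param window final fraction of the run to analyse.
#' @return Object of class `region_class`: `label` (one of `"branching"`,
#'   `"fully_inactive"`, `"uniform_partly_active"`, `"fully_active"`,
#'   `"unresolved"`), plus `clusters`, `persistence`, `drift` and `mean_z`
#'   diagnostics.
#' @export
classify_run <- function(sim, window = 0.1) {
  s <- sim$summary
  idx <- s$step > (1 - window) * max(s$step)
  win <- s[idx, ]
  # trend test: total drift of mean z across the window
  fit <- stats::lm(mean_z ~ step, data = win)
  drift <- abs(stats::coef(fit)[["step"]]) * (max(win$step) - min(win$step))

  keep <- which(sim$snapshot_steps > (1 - window) * sim$control$steps)
  pooled <- do.call(rbind, sim$snapshots[keep])
  cl <- detect_clusters(pooled)
  branched <- vapply(keep, function(i) {
    ci <- detect_clusters(sim$snapshots[[i]])
    ci$k >= 2L && ci$separation > .cluster_opts$sep_min
  }, logical(1))
  persistence <- mean(branched)
  mean_z <- mean(win$mean_z)

  label <- if (cl$k >= 2L && persistence >= .cluster_opts$persistence) {
    "branching"
  } else if (drift > 0.1) {
    "unresolved"
  } else if (mean_z > .cluster_opts$z_full) {
    "fully_inactive"
  } else if (mean_z < .cluster_opts$z_empty) {
    "fully_active"
  } else {
    "uniform_partly_active"
  }
  structure(list(label = label, clusters = cl, persistence = persistence,
                 drift = drift, mean_z = mean_z), class = "region_class")
}

#' @export
print.region_class <- function(x, ...) {
  cat(sprintf("Region: %s (mean z = %.3f, branch persistence %.2f, window drift %.3f)\n",
              x$label, x$mean_z, x$persistence, x$drift))
  print(x$clusters)
  invisible(x)
}

.canonical_inits <- function() {
  list(active = init_blob(0.45, 0.5, sd = 0.02),
       inactive = init_blob(0.02, 0.02, sd = 0.01),
       uniform = init_uniform_simplex())
}

#' Classify an environment point by simulation from several initial conditions
#'
#' Runs the dynamics from three canonical initial populations (active-leaning,
#' inactive-leaning, uniform on the simplex), several replicates each, and
#' aggregates the per-run labels: full inactivity must occur from every
#' initial condition; active and inactive outcomes from opposite-leaning
#' inits mark the bistable uniform region; otherwise the majority label wins.
#'
#' @param env a [colony_env()].
#' @param control a [learning_control()].
#' @param mode game mode.
#' @param n_replicates replicates per initial condition (>= 2).
#' @param seed base seed; replicate seeds are derived deterministically.
#' @param window analysis window fraction.
#' @return Object of class `region_class_env` with `label` (one of the four
#'   region labels or `"unresolved"`),
#'   `agreement` (share of runs agreeing with the winning rule) and the
#'   per-run label matrix.
#' @export
classify_environment <- function(env, control = learning_control(),
                                 mode = "full", n_replicates = 2L,
                                 seed = 1L, window = 0.1) {
  if (n_replicates < 2L) stop("n_replicates must be >= 2", call. = FALSE)
  inits <- .canonical_inits()
  labels <- matrix(NA_character_, nrow = length(inits), ncol = n_replicates,
                   dimnames = list(names(inits), NULL))
  for (i in seq_along(inits)) {
    for (r in seq_len(n_replicates)) {
      s <- (as.integer(seed) * 97L + i * 13L + r) %% 2147483587L
      sim <- simulate_colony(env, control, inits[[i]], mode, seed = s)
      labels[i, r] <- classify_run(sim, window)$label
    }
  }
  tab <- table(labels)
  all_runs <- as.vector(labels)
  resolved <- all_runs[all_runs != "unresolved"]

  decide <- function() {
    if (length(resolved) == 0L) return(c("unresolved", 0))
    if (all(resolved == "fully_inactive")) {
      return(c("fully_inactive", 1))
    }
    if (any(all_runs == "branching")) {
      ag <- mean(all_runs == "branching")
      if (ag >= 0.5) return(c("branching", ag))
    }
    act <- labels["active", ]; inact <- labels["inactive", ]
    if (any(act == "fully_active") && any(inact == "fully_inactive")) {
      ag <- mean(all_runs %in% c("fully_active", "fully_inactive"))
      return(c("uniform_full_active_or_inactive", ag))
    }
    win <- names(which.max(table(resolved)))
    ag <- mean(all_runs == win)
    if (ag < 0.5) return(c("unresolved", ag))
    if (win == "fully_active") win <- "uniform_full_active_or_inactive"
    c(win, ag)
  }
  d <- decide()
  structure(list(label = d[1L], agreement = as.numeric(d[2L]),
                 runs = labels), class = "region_class_env")
}

#' @export
print.region_class_env <- function(x, ...) {
  cat(sprintf("Environment region: %s (agreement %.2f over %d runs)\n",
              x$label, x$agreement, length(x$runs)))
  invisible(x)
}

#' Map behavioural regions over a 2-D environment-parameter grid
#'
#' @param param1,param2 names of the two [colony_env()] parameters to sweep
#'   (e.g. `"b1"` and `"w"`).
#' @param grid1,grid2 numeric grids for the two parameters.
#' @param env baseline environment supplying all other parameters.
#' @param control a [learning_control()]; only used by the simulation method.
#' @param mode game mode (`"M1"` sweeps are conventionally over w and beta,
#'   `"M2"` over b1 and b2).
#' @param method `"adaptive"` (fast analytic classification via
#'   [predicted_region()]) or `"simulation"` (replicated
#'   [classify_environment()] per cell).
#' @param seed base seed (simulation method).
#' @param n_replicates replicates per cell (simulation method).
#' @return Object of class `region_map`: long-format data frame `cells` with
#'   the parameter values, `label` and `agreement` per grid cell.
#' @export
region_sweep <- function(param1, param2, grid1, grid2, env,
                         control = learning_control(), mode = "full",
                         method = c("adaptive", "simulation"), seed = 1L,
                         n_replicates = 2L) {
  method <- match.arg(method)
  stopifnot(length(grid1) >= 1L, length(grid2) >= 1L)
  cells <- expand.grid(v1 = grid1, v2 = grid2, KEEP.OUT.ATTRS = FALSE)
  labels <- character(nrow(cells))
  agreement <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    e <- env
    e[[param1]] <- cells$v1[i]
    e[[param2]] <- cells$v2[i]
    if (method == "adaptive") {
      labels[i] <- predicted_region(e, n = control$n, mode = mode)
      agreement[i] <- 1
    } else {
      cl <- classify_environment(e, control, mode, n_replicates,
                                 seed = (as.integer(seed) + i * 101L) %% 2147483587L)
      labels[i] <- cl$label
      agreement[i] <- cl$agreement
    }
  }
  names(cells) <- c(param1, param2)
  cells$label <- labels
  cells$agreement <- agreement
  structure(list(cells = cells, param1 = param1, param2 = param2,
                 mode = mode, method = method), class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("Region map (%s mode, %s method): %d cells over %s x %s\n",
              x$mode, x$method, nrow(x$cells), x$param1, x$param2))
  print(table(x$cells$label))
  invisible(x)
}

#' @export
plot.region_map <- function(x, ...) {
  g1 <- sort(unique(x$cells[[x$param1]]))
  g2 <- sort(unique(x$cells[[x$param2]]))
  lv <- sort(unique(x$cells$label))
  m <- matrix(match(x$cells$label, lv), nrow = length(g1))
  graphics::image(g1, g2, m, col = grDevices::hcl.colors(length(lv), "Set 2"),
                  xlab = x$param1, ylab = x$param2, main = "Behavioural regions")
  graphics::legend("topleft", legend = lv, bg = "white",
                   fill = grDevices::hcl.colors(length(lv), "Set 2"))
  invisible(x)
}

#' Active/inactive fractions over time
#'
#' @param sim a `colony_sim`.
#' @param threshold z cutoff: agents with `z < threshold` count as active.
#' @return Data frame with `step`, `active` and `inactive` fractions (summing
#'   to 1) at every recorded snapshot.
#' @export
activity_ratio <- function(sim, threshold = 0.5) {
  act <- vapply(sim$snapshots, function(s) mean(s[, "z"] < threshold),
                numeric(1))
  data.frame(step = sim$snapshot_steps, active = act, inactive = 1 - act)
}
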