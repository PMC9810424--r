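# Configuration files (YAML in, JSON out), defaults, and deterministic test
# fixtures.

.default_config <- function() {
  list(
    environment = list(
      b1 = 20, b2 = -4, w = 0.3, beta = 3,
      cost_coeff_x = 0.6, cost_coeff_y = 0.6, cost_exponent = 0.65,
      benefit_x_shape = "quadratic", benefit_y_shape = "tanh_sigmoid",
      cost_shape = "power"),
    learning = list(
      n = 5L, N = 100L, alpha = 2, mu = 0.01, sigma = 0.005,
      steps = 30000L, record_every = 100L),
    experiment = list(
      type = "simulate", mode = "full", seed = 1L,
      init = "uniform_simplex", x0 = NULL, y0 = NULL, window = 0.1,
      t_cull = NULL, fraction = NULL, activity_threshold = 0.5,
      out = "colony")
  )
}

# YAML 1.1 reads a bare `N` key as boolean FALSE; restore the intended name.
.fix_yaml_names <- function(x) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  if (!is.null(nm)) names(x) <- ifelse(nm == "FALSE", "N", nm)
  lapply(x, .fix_yaml_names)
}

# drop NULL placeholders recursively so resolved configs serialize cleanly
.strip_null <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, logical(1))]
  lapply(x, .strip_null)
}

.merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(defaults)) {
      stop("unknown configuration key: '", full, "'", call. = FALSE)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        stop("configuration key '", full, "' must be a mapping", call. = FALSE)
      }
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load a run configuration
#'
#' Reads a YAML or JSON configuration file, merges it over the documented
#' defaults (group size 5, selection intensity 2, mutation rate 0.01,
#' mutation size 0.005, 30000 steps), validates every invariant and rejects
#' unknown keys by name. An empty or missing-section file resolves to the
#' full defaults.
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`); `NULL` for
#'   pure defaults.
#' @return Object of class `colony_config`: validated `env`
#'   ([colony_env()]), `control` ([learning_control()]) and `experiment`
#'   settings, plus the resolved raw list in `$resolved`.
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    } else {
      yaml::read_yaml(path)
    }
    if (is.null(user)) user <- list()
    user <- .fix_yaml_names(user)
  }
  resolved <- .merge_config(.default_config(), user)
  env <- do.call(colony_env, resolved$environment)
  ctrl <- do.call(learning_control, resolved$learning)
  exp <- resolved$experiment
  exp$type <- match.arg(exp$type,
    c("simulate", "classify", "sweep", "cull", "ad", "streamlines",
      "efficiency"))
  exp$mode <- match.arg(exp$mode, c("full", "M1", "M2"))
  structure(list(env = env, control = ctrl, experiment = exp,
                 resolved = resolved),
            class = "colony_config")
}

#' Serialize a resolved configuration as JSON
#'
#' The emitted JSON round-trips through [load_config()] to an identical
#' resolved configuration, so every output can be reproduced from the config
#' written next to it.
#'
#' @param config a `colony_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "colony_config"))
  jsonlite::write_json(.strip_null(config$resolved), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.colony_config <- function(x, ...) {
  cat("Colony run configuration (experiment:", x$experiment$type, ")\n")
  print(x$env)
  print(x$control)
  invisible(x)
}

#' Deterministic test populations
#'
#' Generates small populations with known structure for tests and examples:
#' `"monomorphic"` (N copies of one trait), `"bimodal"` (a fraction at an
#' active strategy, the rest fully inactive), `"uniform_simplex"` (uniform on
#' the trait simplex) and `"noisy_blob"` (Gaussian scatter around one point,
#' projected back onto the simplex).
#'
#' @param name fixture name.
#' @param N population size.
#' @param seed RNG seed (generation is seed-deterministic).
#' @param x0,y0 focal trait (monomorphic, noisy_blob; active mode of
#'   bimodal).
#' @param frac active fraction of the bimodal fixture.
#' @param sd blob standard deviation.
#' @return Matrix with N rows and columns x, y, z.
#' @export
make_fixture <- function(name, N = 100L, seed = 1L, x0 = 0.3, y0 = 0.7,
                         frac = 0.5, sd = 0.01) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  pop <- switch(name,
    monomorphic = list(x = rep(x0, N), y = rep(y0, N)),
    bimodal = {
      n_act <- round(frac * N)
      list(x = c(rep(x0, n_act), rep(0, N - n_act)),
           y = c(rep(y0, n_act), rep(0, N - n_act)))
    },
    uniform_simplex = {
      e <- matrix(stats::rexp(3L * N), ncol = 3L)
      e <- e / rowSums(e)
      list(x = e[, 1L], y = e[, 2L])
    },
    noisy_blob = {
      p <- project_simplex(x0 + stats::rnorm(N, 0, sd),
                           y0 + stats::rnorm(N, 0, sd))
      list(x = p$x, y = p$y)
    },
    stop("unknown fixture '", name, "'", call. = FALSE))
  cbind(x = pop$x, y = pop$y, z = 1 - pop$x - pop$y)
}
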