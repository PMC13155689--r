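## Default configuration: the standard parameter setting of the
## three-phenotype model (a = 0.01, b = 1, S0 = 10, p = 1e-4, theta = 1e-8,
## gamma-distributed intervals with mean 100 and variance 5000).
default_config <- function() {
  list(
    a = 0.01, b = 1, mu_bar = 0.8,
    S0 = 10, p = 1e-4, theta = 1e-8,
    phenotypes = "three",          # three | pair | ladder | simplex
    ladder_n = 51, ladder_m = 2, ladder_c = 0.2,
    simplex_step = 0.2, simplex_extent = 5,
    interval = list(family = "gamma", shape = 2, scale = 50),
    env_mode = "uniform_random",
    t_end = 6e4, window = c(5e4, 6e4),
    X0 = 1
  )
}

#' Load (and validate) a run configuration
#'
#' Reads a YAML or JSON configuration, merges it over the defaults and
#' validates every parameter against the model invariants. An empty or
#' missing file yields the full default set. Unknown keys are rejected.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file, or `NULL` for the
#'   defaults.
#' @return validated configuration list of class `ff_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (length(user)) {
      unknown <- setdiff(names(user), names(cfg))
      if (length(unknown)) {
        stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
      }
      cfg[names(user)] <- user
    }
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid configuration: ", msg)
  chk(cfg$a > 0, "a must be positive")
  chk(cfg$b >= 0, "b must be non-negative")
  chk(cfg$mu_bar > 0, "mu_bar must be positive")
  chk(cfg$S0 > 0, "S0 must be positive")
  chk(cfg$theta >= 0, "theta must be non-negative")
  chk(cfg$p >= 0, "p must be non-negative")
  chk(cfg$phenotypes %in% c("three", "pair", "ladder", "simplex"),
      "phenotypes must be one of three/pair/ladder/simplex")
  chk(cfg$t_end > 0, "t_end must be positive")
  chk(length(cfg$window) == 2 && cfg$window[1] >= 0 &&
        cfg$window[2] <= cfg$t_end && cfg$window[2] > cfg$window[1],
      "window must lie inside [0, t_end]")
  chk(cfg$env_mode %in% c("uniform_random", "cycle"),
      "env_mode must be uniform_random or cycle")
  # materialize the interval spec to validate family parameters
  do.call(interval_spec, cfg$interval)
  structure(cfg, class = "ff_config")
}

#' @rdname load_config
#' @param cfg a configuration list.
#' @export
save_config <- function(cfg, path) {
  cfg <- unclass(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

## Build the model objects a configuration describes.
config_objects <- function(cfg) {
  params <- tradeoff_params(a = cfg$a, b = cfg$b, mu_bar = cfg$mu_bar)
  tab <- switch(cfg$phenotypes,
    three = build_three_phenotype_set(params),
    pair = build_pair_set(params),
    ladder = build_ladder_set(params, n = cfg$ladder_n, m = cfg$ladder_m,
                              c_step = cfg$ladder_c),
    simplex = build_simplex_set(params, step = cfg$simplex_step,
                                extent = cfg$simplex_extent))
  list(table = tab,
       A = switching_matrix(tab, cfg$p),
       spec = do.call(interval_spec, cfg$interval),
       selector = env_selector(cfg$env_mode, tab$n_environments),
       config = sim_config(S0 = cfg$S0, theta = cfg$theta, X0 = cfg$X0))
}

#' Cycle records of a trajectory as a data frame
#'
#' One row per supply event: pulse time, environment, interval, feast
#' duration, depletion flag and the end-of-cycle population of every
#' phenotype.
#'
#' @param x an `ff_trajectory`.
#' @param ... unused.
#' @return data.frame with one row per cycle.
#' @export
as.data.frame.ff_trajectory <- function(x, ...) {
  df <- data.frame(pulse_time = x$pulse_time, env = x$env,
                   interval = x$interval, T_plus = x$T_plus,
                   depleted = x$depleted)
  Xe <- t(x$X_end)
  colnames(Xe) <- paste0("X_", x$table$labels)
  cbind(df, Xe)
}

#' Run seeded replicates of a configured model and write their outputs
#'
#' Deterministic replicate orchestration: replicate r uses seed
#' `base_seed + r`, the manifest (config snapshot, seed list, output paths,
#' package version) is written before any simulation starts, each
#' replicate's cycle records go to `replicate_<r>.csv`, and a pooled
#' summary (per-phenotype time-average mean and standard error over
#' replicates) goes to `summary.json`. Identical manifests produce
#' byte-identical outputs. Replicate files that already exist are kept and
#' skipped, so an interrupted orchestration resumes where it stopped.
#'
#' @param cfg a configuration from [load_config()].
#' @param n_replicates number of replicates.
#' @param base_seed base integer seed (required; no silent
#'   nondeterminism).
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
orchestrate <- function(cfg, n_replicates, base_seed, out_dir) {
  if (missing(base_seed) || is.null(base_seed) || is.na(base_seed)) {
    stop("base_seed is required: runs must be reproducible")
  }
  cfg <- validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- base_seed + seq_len(n_replicates)
  paths <- file.path(out_dir, sprintf("replicate_%d.csv", seq_len(n_replicates)))
  manifest <- list(
    config = unclass(cfg), base_seed = base_seed, seeds = seeds,
    outputs = c(paths, file.path(out_dir, "summary.json")),
    package_version = as.character(utils::packageVersion("feastfamine")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  obj <- config_objects(cfg)
  avgs <- matrix(NA_real_, obj$table$n_phenotypes, n_replicates)
  for (r in seq_len(n_replicates)) {
    sch <- make_schedule(obj$spec, obj$selector, cfg$t_end, seeds[r])
    traj <- run_feast_famine(obj$table, obj$A, sch, obj$config)
    if (!file.exists(paths[r])) {
      utils::write.csv(as.data.frame(traj), paths[r], row.names = FALSE)
    }
    avgs[, r] <- time_average(traj, cfg$window)$time_avg
  }
  summary <- list(
    labels = obj$table$labels,
    time_avg_mean = rowMeans(avgs),
    time_avg_se = apply(avgs, 1, stats::sd) / sqrt(n_replicates),
    n_replicates = n_replicates, window = cfg$window)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
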