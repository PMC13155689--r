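#' Inter-pulse interval specification
#'
#' Describes the distribution of waiting times between nutrient supply
#' events. Supported families: `"constant"` (degenerate at `value`),
#' `"gamma"` (`shape`, `scale`), `"uniform"` (`min`, `max`) and `"normal"`
#' (`mean`, `sd`; resampled on non-positive draws so intervals are strictly
#' positive).
#'
#' @param family one of `"constant"`, `"gamma"`, `"uniform"`, `"normal"`.
#' @param ... family parameters (see Details above).
#' @return An object of class `interval_spec`.
#' @examples
#' interval_spec("gamma", shape = 2, scale = 50)   # mean 100, variance 5000
#' interval_spec("constant", value = 100)
#' @export
interval_spec <- function(family = c("constant", "gamma", "uniform", "normal"),
                          ...) {
  family <- match.arg(family)
  p <- list(...)
  need <- switch(family,
    constant = "value",
    gamma    = c("shape", "scale"),
    uniform  = c("min", "max"),
    normal   = c("mean", "sd"))
  if (!setequal(names(p), need)) {
    stop(sprintf("family '%s' needs parameters: %s", family,
                 paste(need, collapse = ", ")))
  }
  p <- p[need]
  ok <- switch(family,
    constant = p$value > 0,
    gamma    = p$shape > 0 && p$scale > 0,
    uniform  = p$min > 0 && p$max > p$min,
    normal   = p$mean > 0 && p$sd > 0)
  if (!isTRUE(ok)) stop("invalid interval parameters for family ", family)
  structure(c(list(family = family), p), class = "interval_spec")
}

#' @export
print.interval_spec <- function(x, ...) {
  pars <- unlist(x[-1])
  cat(sprintf("Interval spec: %s(%s)  [mean %g, variance %g]\n", x$family,
              paste(sprintf("%s=%g", names(pars), pars), collapse = ", "),
              interval_mean(x), interval_variance(x)))
  invisible(x)
}

#' Moments of an interval specification
#'
#' @param spec an [interval_spec()].
#' @return the mean (respectively variance) of the inter-pulse interval.
#' @export
interval_mean <- function(spec) {
  stopifnot(inherits(spec, "interval_spec"))
  switch(spec$family,
    constant = spec$value,
    gamma    = spec$shape * spec$scale,
    uniform  = (spec$min + spec$max) / 2,
    normal   = spec$mean)
}

#' @rdname interval_mean
#' @export
interval_variance <- function(spec) {
  stopifnot(inherits(spec, "interval_spec"))
  switch(spec$family,
    constant = 0,
    gamma    = spec$shape * spec$scale^2,
    uniform  = (spec$max - spec$min)^2 / 12,
    normal   = spec$sd^2)
}

#' Build an interval spec from a requested mean and variance
#'
#' Moment inversion per family: gamma gets `shape = mean^2/var`,
#' `scale = var/mean`; uniform gets half-width `sqrt(3 var)` around the
#' mean; normal gets `sd = sqrt(var)`; constant requires `variance = 0`.
#' Used to vary the mean interval at fixed variance (or vice versa) across
#' distribution families.
#'
#' @param family distribution family (see [interval_spec()]).
#' @param mean requested mean interval (> 0).
#' @param variance requested interval variance (>= 0).
#' @return An `interval_spec` with the requested moments.
#' @examples
#' make_spec_mean_variance("gamma", mean = 100, variance = 5000) # Gamma(2, 50)
#' @export
make_spec_mean_variance <- function(family, mean, variance) {
  stopifnot(mean > 0, variance >= 0)
  if (family == "constant") {
    if (variance != 0) stop("constant family requires variance = 0")
    return(interval_spec("constant", value = mean))
  }
  if (variance == 0) stop("zero variance requires the constant family")
  switch(family,
    gamma = interval_spec("gamma", shape = mean^2 / variance,
                          scale = variance / mean),
    uniform = {
      hw <- sqrt(3 * variance)
      if (hw >= mean) {
        stop("infeasible uniform spec: half-width ", signif(hw, 4),
             " reaches the mean; intervals would be non-positive")
      }
      interval_spec("uniform", min = mean - hw, max = mean + hw)
    },
    normal = interval_spec("normal", mean = mean, sd = sqrt(variance)),
    stop("unknown family: ", family))
}

#' Sample inter-pulse intervals
#'
#' Draws `n` strictly positive waiting times from `spec`. The normal family
#' uses rejection (resampling non-positive draws) rather than clipping, so
#' the conditional distribution stays smooth. Identical `spec` + `seed`
#' reproduce the identical sequence.
#'
#' @param spec an [interval_spec()].
#' @param n number of intervals (>= 1).
#' @param seed integer seed.
#' @return numeric vector of n positive intervals.
#' @export
sample_intervals <- function(spec, n, seed) {
  stopifnot(inherits(spec, "interval_spec"), n >= 1)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old))
  set.seed(as.integer(seed))
  draw <- function(k) switch(spec$family,
    constant = rep(spec$value, k),
    gamma    = stats::rgamma(k, shape = spec$shape, scale = spec$scale),
    uniform  = stats::runif(k, spec$min, spec$max),
    normal   = stats::rnorm(k, spec$mean, spec$sd))
  x <- draw(n)
  while (any(bad <- x <= 0)) x[bad] <- draw(sum(bad))
  x
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

## Deterministic derivation of per-stream seeds from one base seed, so that
## adding streams never reorders existing ones. Stream 1: intervals,
## stream 2: environment types; replicate r uses base + r.
derive_seed <- function(base_seed, stream) {
  (as.integer(base_seed) + stream * 1000003L) %% .Machine$integer.max
}

#' Environment selector
#'
#' How the nutrient type supplied at each pulse is chosen: independently and
#' uniformly at random (`"uniform_random"`), or deterministically cycling
#' through environments 1..E (`"cycle"`).
#'
#' @param mode `"uniform_random"` or `"cycle"`.
#' @param n_environments number of nutrient types E.
#' @return An object of class `env_selector`.
#' @export
env_selector <- function(mode = c("uniform_random", "cycle"),
                         n_environments = 2) {
  mode <- match.arg(mode)
  stopifnot(n_environments >= 1)
  structure(list(mode = mode, n_environments = as.integer(n_environments)),
            class = "env_selector")
}

#' Generate a nutrient-supply schedule
#'
#' Pulse times are the cumulative sums of intervals drawn from `spec`; the
#' first pulse arrives after one sampled interval (the simulation starts in
#' famine at t = 0). Nutrient types come from `selector`, drawn from a
#' seeded stream independent of the interval stream so changing E never
#' perturbs the pulse times.
#'
#' @param spec an [interval_spec()].
#' @param selector an [env_selector()].
#' @param t_end simulation horizon (> 0); pulses cover (0, t_end].
#' @param seed base integer seed.
#' @return An object of class `supply_schedule` with fields `times`
#'   (increasing pulse times), `env` (nutrient-type indices in 1..E), and
#'   the generating spec/selector/seed.
#' @examples
#' make_schedule(interval_spec("constant", value = 100),
#'               env_selector("cycle"), t_end = 350, seed = 1)
#' @export
make_schedule <- function(spec, selector, t_end, seed) {
  stopifnot(inherits(spec, "interval_spec"), inherits(selector, "env_selector"),
            t_end > 0)
  m <- interval_mean(spec)
  n_guess <- max(16L, ceiling(1.2 * t_end / m) + 8L)
  ivl <- sample_intervals(spec, n_guess, derive_seed(seed, 1L))
  times <- cumsum(ivl)
  chunk <- 2L
  while (times[length(times)] <= t_end) {
    more <- sample_intervals(spec, n_guess, derive_seed(seed, 1L) + chunk)
    times <- c(times, times[length(times)] + cumsum(more))
    chunk <- chunk + 1L
  }
  times <- times[times <= t_end]
  k <- length(times)
  if (k == 0) stop("no supply events before t_end; increase t_end")
  env <- if (selector$mode == "cycle") {
    rep_len(seq_len(selector$n_environments), k)
  } else {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old))
    set.seed(derive_seed(seed, 2L))
    sample.int(selector$n_environments, k, replace = TRUE)
  }
  structure(list(times = times, env = env, spec = spec, selector = selector,
                 t_end = t_end, seed = as.integer(seed)),
            class = "supply_schedule")
}

#' @export
print.supply_schedule <- function(x, ...) {
  cat(sprintf(
    "Supply schedule: %d pulses on (0, %g], %s intervals, %s nutrient types (E = %d), seed %d\n",
    length(x$times), x$t_end, x$spec$family, x$selector$mode,
    x$selector$n_environments, x$seed))
  invisible(x)
}

#' Write / read a supply schedule as CSV
#'
#' Two columns (`time`, `env`) for exact replay of a realized pulse
#' sequence.
#'
#' @param schedule a `supply_schedule`.
#' @param path file path.
#' @param t_end horizon to attach on read (defaults to the last pulse time).
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns a `supply_schedule` (with `spec`/`selector` set to `NULL`,
#'   since only the realization is stored).
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(data.frame(time = schedule$times, env = schedule$env),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path, t_end = NULL) {
  df <- utils::read.csv(path)
  if (is.unsorted(df$time, strictly = TRUE)) stop("pulse times must increase")
  structure(list(times = df$time, env = as.integer(df$env), spec = NULL,
                 selector = NULL,
                 t_end = if (is.null(t_end)) max(df$time) else t_end,
                 seed = NA_integer_),
            class = "supply_schedule")
}
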