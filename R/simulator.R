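#' Simulation configuration
#'
#' @param S0 nutrient amount delivered per pulse (> 0). Default 10.
#' @param theta extinction threshold: any phenotype below `theta` is set to
#'   zero at each supply event (and only there); switching can re-seed an
#'   extinct phenotype. Default 1e-8.
#' @param X0 initial population vector (recycled to N); default 1 for every
#'   phenotype.
#' @param env0 environment index whose death rates apply during the initial
#'   famine on [0, first pulse). Default 1.
#' @param literal_switching if `TRUE`, use the product-of-probabilities
#'   switching inflow \eqn{A_{ij}A_{ji}\mu_j X_j} instead of the
#'   flux-conserving \eqn{A_{ji}\mu_j X_j} (sensitivity check only; the
#'   conserving form is the model).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(S0 = 10, theta = 1e-8, X0 = 1, env0 = 1L,
                       literal_switching = FALSE) {
  stopifnot(S0 > 0, theta >= 0, all(X0 >= 0))
  structure(list(S0 = S0, theta = theta, X0 = X0, env0 = as.integer(env0),
                 literal_switching = isTRUE(literal_switching)),
            class = "sim_config")
}

#' Feast-phase generator matrix
#'
#' The linear system governing the populations while nutrient is present:
#' \deqn{dX_i/dt = (1 - \sum_{j\ne i} A_{ij}) \mu_{i,e} X_i +
#'       \sum_{j\ne i} A_{ji} \mu_{j,e} X_j,}
#' i.e. growth-coupled switching: a dividing cell of phenotype j places its
#' daughter in phenotype i with probability \eqn{A_{ji}}. The construction
#' conserves the total growth flux, \eqn{\sum_i (dX/dt)_i =
#' \sum_i \mu_{i,e} X_i}, which is exactly the nutrient consumption rate.
#'
#' @param table a `phenotype_table`.
#' @param A switching matrix from [switching_matrix()].
#' @param env environment index.
#' @param literal_switching use the literal \eqn{A_{ij}A_{ji}} inflow
#'   coefficient (does not conserve growth flux; for sensitivity checks).
#' @return N x N rate matrix M with `dX/dt = M X` during feast.
#' @export
feast_matrix <- function(table, A, env, literal_switching = FALSE) {
  mu_e <- table$mu[, env]
  s <- rowSums(A)
  inflow <- if (literal_switching) t(A * t(A)) else t(A)
  M <- inflow * rep(mu_e, each = nrow(A))  # M[i,j] = inflow[i,j] * mu_j
  diag(M) <- (1 - s) * mu_e
  M
}

## Spectral decomposition of a feast matrix M = K D_mu with K symmetric
## (always the case when the switching adjacency is symmetric): M is similar
## to the symmetric S = D^{1/2} K D^{1/2}, so its eigenvalues are real and
## the decomposition is numerically stable. Falls back to general eigen().
## Returns lambda, V, Vinv with M = V diag(lambda) Vinv, plus w = colSums(V)
## so that sum(X(t)) = w . (exp(lambda t) * (Vinv X0)).
decompose_feast <- function(M, mu_e = NULL) {
  n <- nrow(M)
  dec <- NULL
  if (!is.null(mu_e) && all(mu_e > 0)) {
    K <- M %*% diag(1 / mu_e, n)
    if (max(abs(K - t(K))) < 1e-12 * max(abs(K))) {
      d <- sqrt(mu_e)
      S <- (K * d) * rep(d, each = n)      # D^{1/2} K D^{1/2}
      S <- (S + t(S)) / 2
      es <- eigen(S, symmetric = TRUE)
      V <- es$vectors / d
      Vinv <- t(es$vectors) * rep(d, each = n)
      dec <- list(lambda = es$values, V = V, Vinv = Vinv)
    }
  }
  if (is.null(dec)) {
    es <- eigen(M)
    if (max(abs(Im(es$values))) > 1e-8 * max(abs(es$values))) {
      warning("feast matrix has markedly complex eigenvalues; ",
              "taking real parts")
    }
    V <- es$vectors
    dec <- list(lambda = Re(es$values), V = Re(V), Vinv = Re(solve(V)))
  }
  dec$w <- colSums(dec$V)
  dec
}

## Elementwise coef * exp(lam * s) evaluated in log scale, so that tiny
## spectral coefficients paired with large exponents (a near-extinct
## population failing to deplete over a long interval) never produce
## 0 * Inf or spurious overflow.
scaled_growth <- function(lam, coef, s) {
  out <- numeric(length(coef))
  nz <- coef != 0
  out[nz] <- sign(coef[nz]) * exp(lam[nz] * s + log(abs(coef[nz])))
  out
}

## Core feast solver on a precomputed decomposition. Finds the depletion
## time T+ solving sum(X(T+)) = sum(X0) + budget by bisection (non-finite
## overflow treated as "past depletion") followed by Newton polishing, so
## the per-cycle mass balance holds to machine precision.
feast_solve <- function(dec, X0, budget, interval) {
  total0 <- sum(X0)
  if (total0 <= 0) {
    return(list(X = X0, T_plus = interval, depleted = FALSE, S = budget))
  }
  cc <- drop(dec$Vinv %*% X0)
  lam <- dec$lambda
  w <- dec$w
  f <- function(s) sum(scaled_growth(lam, w * cc, s)) - total0 - budget
  fhi <- f(interval)
  if (is.finite(fhi) && fhi <= 0) {
    X <- drop(dec$V %*% scaled_growth(lam, cc, interval))
    X[X < 0] <- 0
    return(list(X = X, T_plus = interval, depleted = FALSE, S = -fhi))
  }
  lo <- 0; hi <- interval
  flo <- -budget
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (!is.finite(fm) || fm > 0) hi <- mid else { lo <- mid; flo <- fm }
    if (hi - lo < 1e-12 * max(1, hi)) break
  }
  root <- (lo + hi) / 2
  for (it in 1:4) {  # Newton polish inside the bracket
    fr <- f(root)
    dfr <- sum(scaled_growth(lam, w * cc * lam, root))
    if (!is.finite(fr) || !is.finite(dfr) || dfr <= 0) break
    step <- fr / dfr
    cand <- root - step
    if (cand <= lo || cand >= hi) break
    root <- cand
    if (abs(step) < 1e-15 * max(1, root)) break
  }
  X <- drop(dec$V %*% scaled_growth(lam, cc, root))
  X[X < 0] <- 0
  list(X = X, T_plus = root, depleted = TRUE, S = 0)
}

#' Integrate one feast phase exactly
#'
#' Evolves `X` under the linear system `dX/dt = M X` until either the
#' supplied nutrient budget is consumed (total population has grown by
#' `budget`, by unit-yield mass balance) or the inter-pulse interval ends,
#' whichever comes first. Uses the spectral solution of M and monotone
#' root-finding on the total population, so the depletion time is exact to
#' machine precision.
#'
#' @param X population vector at the pulse (after thresholding).
#' @param M feast rate matrix from [feast_matrix()].
#' @param interval time to the next pulse.
#' @param budget nutrient amount available (S0).
#' @param mu_e optional growth-rate vector of the current environment;
#'   enables the stable symmetric decomposition.
#' @return list with `X` (populations at depletion or pulse), `T_plus`
#'   (feast duration), `depleted` (logical), `S` (leftover nutrient).
#' @examples
#' feast_step(1, matrix(0.8), interval = 100, budget = 10) # T+ = ln(11)/0.8
#' @export
feast_step <- function(X, M, interval, budget, mu_e = NULL) {
  M <- as.matrix(M)
  stopifnot(length(X) == nrow(M), interval > 0, budget > 0)
  dec <- decompose_feast(M, mu_e)
  feast_solve(dec, X, budget, interval)
}

#' Integrate one famine phase exactly
#'
#' With no nutrient present each phenotype decays independently,
#' \eqn{X_i(t) = X_i(0) e^{-\gamma_i t}}; there is no switching during
#' famine.
#'
#' @param X population vector at famine onset.
#' @param gamma_e death-rate vector of the current environment (1/time).
#' @param duration famine duration (>= 0).
#' @return decayed population vector.
#' @export
famine_step <- function(X, gamma_e, duration) {
  stopifnot(duration >= 0, all(gamma_e >= 0))
  X * exp(-gamma_e * duration)
}

#' Apply the extinction threshold
#'
#' Population entries below `theta` are set to zero. In the full model this
#' is evaluated only at nutrient supply events; zero is not absorbing
#' because phenotypic switching re-seeds neighbors during feast.
#'
#' @param X population vector.
#' @param theta threshold (>= 0).
#' @return thresholded vector.
#' @export
apply_threshold <- function(X, theta) {
  stopifnot(theta >= 0)
  X[X < theta] <- 0
  X
}

#' Run the feast-famine population dynamics over a supply schedule
#'
#' Event-driven integration of the piecewise-linear model: at each pulse the
#' nutrient is reset to `S0` (any leftover discarded), the environment is
#' set to the pulse's nutrient type, populations below `theta` are zeroed,
#' then the feast phase is integrated exactly until depletion (or the next
#' pulse) and the famine decay fills the remainder of the interval. Both
#' phases use closed-form solutions, so trajectories are exact up to the
#' depletion-time root-finding (machine precision) and runs are
#' bit-reproducible given the schedule.
#'
#' @param table a `phenotype_table`.
#' @param A switching matrix (defaults to p = 0, no switching).
#' @param schedule a `supply_schedule`.
#' @param config a [sim_config()].
#' @return An object of class `ff_trajectory` holding per-cycle records:
#'   `pulse_time`, `env`, `interval`, `T_plus`, `depleted`, and matrices
#'   `X_start` (post-threshold at each pulse), `X_depl` (at nutrient
#'   depletion) and `X_end` (at the end of each cycle), plus everything
#'   needed to reconstruct the exact trajectory (see [time_average()]).
#' @examples
#' tab <- build_three_phenotype_set(tradeoff_params(mu_bar = 0.8))
#' sch <- make_schedule(interval_spec("constant", value = 100),
#'                      env_selector("cycle"), t_end = 2000, seed = 1)
#' traj <- run_feast_famine(tab, switching_matrix(tab, 1e-4), sch)
#' @export
run_feast_famine <- function(table, A = switching_matrix(table, 0),
                             schedule, config = sim_config()) {
  stopifnot(inherits(table, "phenotype_table"),
            inherits(schedule, "supply_schedule"),
            inherits(config, "sim_config"))
  n <- table$n_phenotypes
  if (!all(dim(A) == c(n, n))) stop("switching matrix dimension mismatch")
  if (any(schedule$env > table$n_environments)) {
    stop("schedule references an environment the phenotype table lacks")
  }
  decs <- lapply(seq_len(table$n_environments), function(e) {
    decompose_feast(feast_matrix(table, A, e, config$literal_switching),
                    table$mu[, e])
  })
  times <- schedule$times
  k_n <- length(times)
  intervals <- diff(c(times, schedule$t_end))
  if (intervals[k_n] <= 0) {  # last pulse exactly at t_end: drop it
    times <- times[-k_n]; intervals <- intervals[-k_n]
    k_n <- k_n - 1L
    envs <- schedule$env[seq_len(k_n)]
  } else envs <- schedule$env
  X <- rep_len(config$X0, n)
  X_init <- X
  # initial famine on [0, tau_1)
  X <- famine_step(X, table$gamma[, config$env0], times[1])
  X_start <- matrix(0, n, k_n)
  X_depl <- matrix(0, n, k_n)
  X_end <- matrix(0, n, k_n)
  T_plus <- numeric(k_n)
  depleted <- logical(k_n)
  for (k in seq_len(k_n)) {
    e <- envs[k]
    X <- apply_threshold(X, config$theta)
    X_start[, k] <- X
    fs <- feast_solve(decs[[e]], X, config$S0, intervals[k])
    T_plus[k] <- fs$T_plus
    depleted[k] <- fs$depleted
    X_depl[, k] <- fs$X
    X <- if (fs$depleted) {
      famine_step(fs$X, table$gamma[, e], intervals[k] - fs$T_plus)
    } else fs$X
    if (any(!is.finite(X))) {
      stop(sprintf("non-finite state at pulse %d (t = %g)", k, times[k]))
    }
    X_end[, k] <- X
  }
  structure(list(
    table = table, A = A, schedule = schedule, config = config,
    decs = decs, X_init = X_init,
    pulse_time = times, env = envs, interval = intervals,
    T_plus = T_plus, depleted = depleted,
    X_start = X_start, X_depl = X_depl, X_end = X_end
  ), class = "ff_trajectory")
}

#' @export
print.ff_trajectory <- function(x, ...) {
  cat(sprintf(
    "Feast-famine trajectory: %d phenotypes, %d supply events on (0, %g]\n",
    x$table$n_phenotypes, length(x$pulse_time), x$schedule$t_end))
  cat(sprintf("  mean feast duration <T+> = %.4g; %d/%d cycles depleted\n",
              mean(x$T_plus), sum(x$depleted), length(x$depleted)))
  cat("  final populations:",
      paste(signif(x$X_end[, ncol(x$X_end)], 4), collapse = " "), "\n")
  invisible(x)
}

#' Evaluate the exact trajectory at arbitrary times
#'
#' Reconstructs X(t) from the per-cycle closed forms (spectral feast
#' solution, exponential famine decay).
#'
#' @param traj an `ff_trajectory`.
#' @param t vector of times in [0, t_end].
#' @return length(t) x N matrix of populations.
#' @export
trajectory_at <- function(traj, t) {
  stopifnot(all(t >= 0), all(t <= traj$schedule$t_end))
  n <- traj$table$n_phenotypes
  out <- matrix(0, length(t), n)
  bounds <- c(traj$pulse_time, traj$schedule$t_end)
  for (ii in seq_along(t)) {
    tt <- t[ii]
    if (tt < traj$pulse_time[1]) {
      out[ii, ] <- famine_step(traj$X_init, traj$table$gamma[, traj$config$env0], tt)
      next
    }
    k <- findInterval(tt, bounds, rightmost.closed = TRUE)
    s <- tt - traj$pulse_time[k]
    e <- traj$env[k]
    if (s <= traj$T_plus[k]) {
      dec <- traj$decs[[e]]
      cc <- drop(dec$Vinv %*% traj$X_start[, k])
      x <- drop(dec$V %*% scaled_growth(dec$lambda, cc, s))
      x[x < 0] <- 0
      out[ii, ] <- x
    } else {
      out[ii, ] <- famine_step(traj$X_depl[, k], traj$table$gamma[, e],
                               s - traj$T_plus[k])
    }
  }
  colnames(out) <- traj$table$labels
  out
}
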