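## Exact integral of X over [s0, s1] within the feast phase of one cycle
## (times relative to the pulse), from the spectral coefficients.
feast_integral <- function(dec, cc, s0, s1) {
  lam <- dec$lambda
  small <- abs(lam) * (s1 - s0) < 1e-12
  term <- numeric(length(cc))
  big <- !small
  term[big] <- (scaled_growth(lam[big], cc[big], s1) -
                scaled_growth(lam[big], cc[big], s0)) / lam[big]
  term[small] <- cc[small] * (s1 - s0) *
    (exp(lam[small] * s0) + exp(lam[small] * s1)) / 2
  v <- drop(dec$V %*% term)
  v[v < 0] <- 0
  v
}

famine_integral <- function(Xd, gamma_e, u0, u1) {
  fac <- ifelse(gamma_e * (u1 - u0) < 1e-12,
                (u1 - u0) * exp(-gamma_e * (u0 + u1) / 2),
                (exp(-gamma_e * u0) - exp(-gamma_e * u1)) / gamma_e)
  Xd * fac
}

#' Time-weighted average population over a window
#'
#' Integrates the exact piecewise trajectory (closed-form feast and famine
#' segments, clipped analytically at the window edges) and divides by the
#' window length — the temporal average
#' \eqn{\frac{1}{w_1 - w_0}\int_{w_0}^{w_1} X_i(t)\,dt}. Also reports the
#' mean feast duration \eqn{\langle T^+\rangle} over cycles whose pulse
#' falls in the window.
#'
#' @param traj an `ff_trajectory` from [run_feast_famine()].
#' @param window numeric `c(w0, w1)` inside the trajectory span; default the
#'   full span.
#' @return An object of class `ff_summary`: `time_avg` (named per-phenotype
#'   averages), `mean_T_plus`, `n_cycles` (cycles with a pulse in the
#'   window), `window`, and `dominant` (label(s) of the maximal average;
#'   ties reported as a set).
#' @export
time_average <- function(traj, window = NULL) {
  stopifnot(inherits(traj, "ff_trajectory"))
  t_end <- traj$schedule$t_end
  if (is.null(window)) window <- c(0, t_end)
  w0 <- window[1]; w1 <- window[2]
  if (!(w0 >= 0 && w1 <= t_end && w1 > w0)) {
    stop("window must lie inside [0, t_end] with positive length")
  }
  n <- traj$table$n_phenotypes
  acc <- numeric(n)
  # initial famine on [0, tau_1)
  tau1 <- traj$pulse_time[1]
  if (w0 < tau1) {
    acc <- acc + famine_integral(traj$X_init,
                                 traj$table$gamma[, traj$config$env0],
                                 w0, min(w1, tau1))
  }
  k_n <- length(traj$pulse_time)
  ends <- traj$pulse_time + traj$interval
  first <- findInterval(w0, traj$pulse_time)            # last pulse <= w0
  for (k in max(1L, first):k_n) {
    t0 <- traj$pulse_time[k]
    if (t0 >= w1) break
    if (ends[k] <= w0) next
    e <- traj$env[k]
    # feast part [t0, t0 + T+]
    fs0 <- max(w0, t0) - t0
    fs1 <- min(w1, t0 + traj$T_plus[k]) - t0
    if (fs1 > fs0) {
      dec <- traj$decs[[e]]
      cc <- drop(dec$Vinv %*% traj$X_start[, k])
      acc <- acc + feast_integral(dec, cc, fs0, fs1)
    }
    # famine part [t0 + T+, end of cycle)
    gs0 <- max(w0, t0 + traj$T_plus[k]) - (t0 + traj$T_plus[k])
    gs1 <- min(w1, ends[k]) - (t0 + traj$T_plus[k])
    if (gs1 > gs0) {
      acc <- acc + famine_integral(traj$X_depl[, k], traj$table$gamma[, e],
                                   gs0, gs1)
    }
  }
  avg <- acc / (w1 - w0)
  names(avg) <- traj$table$labels
  in_win <- traj$pulse_time >= w0 & traj$pulse_time < w1
  mx <- max(avg)
  structure(list(
    time_avg = avg,
    mean_T_plus = if (any(in_win)) mean(traj$T_plus[in_win]) else NA_real_,
    n_cycles = sum(in_win),
    window = c(w0, w1),
    dominant = names(avg)[avg >= mx * (1 - 1e-12)]
  ), class = "ff_summary")
}

#' @export
print.ff_summary <- function(x, ...) {
  cat(sprintf("Time-weighted averages over [%g, %g] (%d cycles, <T+> = %.4g):\n",
              x$window[1], x$window[2], x$n_cycles, x$mean_T_plus))
  print(signif(x$time_avg, 5))
  cat("Dominant:", paste(x$dominant, collapse = ", "), "\n")
  invisible(x)
}

## Pooled specialist average for the symmetric sets: mean of the per-
## specialist time averages (the plotted quantity in the dominance scans).
pool_specialists <- function(avg) {
  idx <- names(avg) != "generalist"
  mean(avg[idx])
}

## One replicate of the three-phenotype model; shared by the scans.
run_three <- function(mu_bar, spec, seed, a = 0.01, b = 1, p = 1e-4,
                      S0 = 10, theta = 1e-8, t_end = 6e4,
                      window = c(5e4, 6e4),
                      env_mode = "uniform_random",
                      builder = build_three_phenotype_set) {
  tab <- builder(tradeoff_params(a = a, b = b, mu_bar = mu_bar))
  A <- switching_matrix(tab, p)
  sch <- make_schedule(spec, env_selector(env_mode, tab$n_environments),
                       t_end, seed)
  traj <- run_feast_famine(tab, A, sch, sim_config(S0 = S0, theta = theta))
  time_average(traj, window)
}

#' Dominance scan over the geometric-mean growth rate
#'
#' Runs the symmetric three-phenotype model across a grid of \eqn{\bar\mu}
#' and reports the generalist's and the pooled specialists' time-weighted
#' average populations (mean and standard error over replicates), the mean
#' feast duration, and the analytic ratio \eqn{r_g/r_s}. The dominant
#' strategy flips where \eqn{r_g/r_s} crosses 1.
#'
#' @param mu_bar_grid grid of \eqn{\bar\mu} values.
#' @param spec interval spec; default constant \eqn{\Delta\tau = 100}.
#' @param n_replicates replicates per grid point (seeds `base_seed + 1..`).
#' @param base_seed base integer seed.
#' @param t_end,window simulation horizon and averaging window.
#' @param a,b,p,S0,theta model parameters (defaults: the standard setting
#'   a = 0.01, b = 1, p = 1e-4, S0 = 10, theta = 1e-8).
#' @param builder phenotype-set constructor (swap in [build_pair_set()] for
#'   the asymmetric-pool scan).
#' @return data.frame with one row per \eqn{\bar\mu}: `generalist`,
#'   `specialist` (pooled), their standard errors, `mean_T_plus`,
#'   `r_ratio` (\eqn{r_g/r_s}) and `dominant`.
#' @export
dominance_scan <- function(mu_bar_grid,
                           spec = interval_spec("constant", value = 100),
                           n_replicates = 5, base_seed = 1,
                           t_end = 6e4, window = c(5e4, 6e4),
                           a = 0.01, b = 1, p = 1e-4, S0 = 10, theta = 1e-8,
                           builder = build_three_phenotype_set) {
  rows <- lapply(mu_bar_grid, function(mb) {
    gen <- spc <- tp <- numeric(n_replicates)
    for (rep in seq_len(n_replicates)) {
      sm <- run_three(mb, spec, base_seed + rep, a = a, b = b, p = p,
                      S0 = S0, theta = theta, t_end = t_end, window = window,
                      builder = builder)
      gen[rep] <- sm$time_avg[["generalist"]]
      spc[rep] <- pool_specialists(sm$time_avg)
      tp[rep] <- sm$mean_T_plus
    }
    r <- growth_death_ratio(builder(tradeoff_params(a = a, b = b, mu_bar = mb)))
    rr <- r[["generalist"]] / r[[which(names(r) != "generalist")[1]]]
    data.frame(
      mu_bar = mb,
      generalist = mean(gen), generalist_se = stats::sd(gen) / sqrt(n_replicates),
      specialist = mean(spc), specialist_se = stats::sd(spc) / sqrt(n_replicates),
      mean_T_plus = mean(tp), r_ratio = rr,
      dominant = if (mean(gen) >= mean(spc)) "generalist" else "specialist")
  })
  do.call(rbind, rows)
}

#' Interpolate where a scan's generalist/specialist balance flips
#'
#' Linear interpolation of \eqn{\log(\mathrm{generalist}) -
#' \log(\mathrm{specialist})} between the adjacent grid points that bracket
#' zero.
#'
#' @param df a [dominance_scan()] (interpolate over `mu_bar`) or
#'   [interval_scan()] table (interpolate over `mean_interval`).
#' @param xvar name of the grid column.
#' @return the interpolated flip location, or `NA` if the balance never
#'   changes sign on the grid.
#' @export
estimate_flip <- function(df, xvar = "mu_bar") {
  gap <- log(df$generalist) - log(df$specialist)
  s <- sign(gap)
  ix <- which(s[-1] != s[-length(s)])
  if (length(ix) == 0) return(NA_real_)
  i <- ix[1]
  x0 <- df[[xvar]][i]; x1 <- df[[xvar]][i + 1]
  x0 + (x1 - x0) * (0 - gap[i]) / (gap[i + 1] - gap[i])
}

#' Interval-mean scan at fixed variance
#'
#' Varies the mean inter-pulse interval at fixed interval variance
#' (moment-matched within one family) and reports the generalist's and the
#' pooled specialists' temporal averages. Under generalist-dominant
#' conditions the specialists' average rises over an intermediate range of
#' means and eventually exceeds the generalist's; the crossover mean is
#' interpolated in log-population between adjacent grid points.
#'
#' @param mean_grid grid of interval means.
#' @param variance fixed interval variance. Default 50.
#' @param mu_bar geometric-mean growth rate. Default 0.8.
#' @param family interval family (moment-matched). Default `"gamma"`.
#' @param n_replicates,base_seed,t_end,window,a,b,p,S0,theta as in
#'   [dominance_scan()].
#' @return list with `table` (one row per mean) and `crossover` (the
#'   interpolated mean where the pooled specialist average first exceeds the
#'   generalist's; `NA` if absent on the grid).
#' @export
interval_scan <- function(mean_grid, variance = 50, mu_bar = 0.8,
                          family = "gamma", n_replicates = 5, base_seed = 1,
                          t_end = 6e4, window = c(5e4, 6e4),
                          a = 0.01, b = 1, p = 1e-4, S0 = 10, theta = 1e-8) {
  rows <- lapply(mean_grid, function(m) {
    spec <- make_spec_mean_variance(family, m, variance)
    gen <- spc <- tp <- numeric(n_replicates)
    for (rep in seq_len(n_replicates)) {
      sm <- run_three(mu_bar, spec, base_seed + rep, a = a, b = b, p = p,
                      S0 = S0, theta = theta, t_end = t_end, window = window)
      gen[rep] <- sm$time_avg[["generalist"]]
      spc[rep] <- pool_specialists(sm$time_avg)
      tp[rep] <- sm$mean_T_plus
    }
    data.frame(
      mean_interval = m,
      generalist = mean(gen), generalist_se = stats::sd(gen) / sqrt(n_replicates),
      specialist = mean(spc), specialist_se = stats::sd(spc) / sqrt(n_replicates),
      mean_T_plus = mean(tp))
  })
  tab <- do.call(rbind, rows)
  list(table = tab, crossover = estimate_flip(tab, "mean_interval"))
}

#' Interval-variance scan at fixed mean
#'
#' Varies the interval variance at fixed mean (default 100) for one or
#' several distribution families and reports the strategy averages. In the
#' generalist-dominant regime the specialists' temporal average increases
#' with the variance (cumulant-series prediction, see [variance_boost()]).
#'
#' @param variance_grid variances to scan (0 allowed: the constant family is
#'   substituted).
#' @param mean_interval fixed mean. Default 100.
#' @param mu_bar geometric-mean growth rate.
#' @param families interval families to scan.
#' @param n_replicates,base_seed,t_end,window,a,b,p,S0,theta as in
#'   [dominance_scan()].
#' @return data.frame with one row per family x variance.
#' @export
variance_scan <- function(variance_grid, mean_interval = 100, mu_bar = 0.8,
                          families = "gamma", n_replicates = 5, base_seed = 1,
                          t_end = 6e4, window = c(5e4, 6e4),
                          a = 0.01, b = 1, p = 1e-4, S0 = 10, theta = 1e-8) {
  rows <- list()
  for (fam in families) {
    for (v in variance_grid) {
      spec <- if (v == 0) interval_spec("constant", value = mean_interval)
              else make_spec_mean_variance(fam, mean_interval, v)
      gen <- spc <- numeric(n_replicates)
      for (rep in seq_len(n_replicates)) {
        sm <- run_three(mu_bar, spec, base_seed + rep, a = a, b = b, p = p,
                        S0 = S0, theta = theta, t_end = t_end, window = window)
        gen[rep] <- sm$time_avg[["generalist"]]
        spc[rep] <- pool_specialists(sm$time_avg)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, variance = v,
        generalist = mean(gen), generalist_se = stats::sd(gen) / sqrt(n_replicates),
        specialist = mean(spc), specialist_se = stats::sd(spc) / sqrt(n_replicates))
    }
  }
  do.call(rbind, rows)
}

## Trailing-interval averaging window: [pulse time of the (K - n + 1)th
## supply event, t_end].
trailing_window <- function(traj, n_intervals) {
  k <- length(traj$pulse_time)
  c(traj$pulse_time[max(1L, k - n_intervals + 1L)], traj$schedule$t_end)
}

#' Ladder scan: abundance distribution on the quasi-continuous strategy
#' axis
#'
#' Simulates the N-phenotype ladder under constant intervals with
#' deterministic A/B alternation for each \eqn{\bar\mu} on a grid, and
#' reports the per-phenotype time-averaged population, its log normalized
#' to [0, 1] within each \eqn{\bar\mu} column, the most abundant phenotype
#' and the phenotype with maximal growth-to-death ratio. Below the
#' branching point the distribution is bimodal (a symmetric specialist
#' pair); above it the central generalist peaks.
#'
#' @param mu_bar_grid grid of \eqn{\bar\mu}.
#' @param n,m,c_step ladder geometry (see [build_ladder_set()]).
#' @param delta_tau constant inter-pulse interval. Default 10.
#' @param t_end simulation horizon. Default 2e4.
#' @param avg_intervals trailing supply intervals to average over.
#'   Default 20.
#' @param a,b,p,S0,theta model parameters.
#' @param seed schedule seed (the run is deterministic; the seed only feeds
#'   the reproducibility bookkeeping).
#' @param subset_keep optional phenotype indices to retain (e.g. the
#'   half-ladder with \eqn{\mu_A \le \mu_B}); adjacency is subset
#'   accordingly.
#' @return list with `distribution` (data.frame: mu_bar, phenotype, coord,
#'   time_avg, log_norm) and `summary` (per \eqn{\bar\mu}: argmax phenotype
#'   coordinate, max-r phenotype coordinate, a `bimodal` flag from counting
#'   interior local maxima of the abundance profile).
#' @export
ladder_scan <- function(mu_bar_grid, n = 51, m = 2, c_step = 0.2,
                        delta_tau = 10, t_end = 2e4, avg_intervals = 20,
                        a = 0.01, b = 1, p = 1e-4, S0 = 10, theta = 1e-8,
                        seed = 1, subset_keep = NULL) {
  dist_rows <- list(); sum_rows <- list()
  for (mb in mu_bar_grid) {
    tab <- build_ladder_set(tradeoff_params(a = a, b = b, mu_bar = mb),
                            n = n, m = m, c_step = c_step)
    if (!is.null(subset_keep)) tab <- subset_phenotypes(tab, subset_keep)
    A <- switching_matrix(tab, p)
    sch <- make_schedule(interval_spec("constant", value = delta_tau),
                         env_selector("cycle", 2), t_end, seed)
    traj <- run_feast_famine(tab, A, sch, sim_config(S0 = S0, theta = theta))
    sm <- time_average(traj, trailing_window(traj, avg_intervals))
    avg <- sm$time_avg
    pos <- avg[avg > 0]
    ln <- log(pmax(avg, if (length(pos)) min(pos) else 1))
    log_norm <- if (diff(range(ln)) > 0) (ln - min(ln)) / diff(range(ln))
                else rep(1, length(ln))
    r <- growth_death_ratio(tab)
    dist_rows[[length(dist_rows) + 1L]] <- data.frame(
      mu_bar = mb, phenotype = seq_along(avg), coord = tab$coords,
      label = tab$labels, time_avg = unname(avg), log_norm = unname(log_norm))
    sum_rows[[length(sum_rows) + 1L]] <- data.frame(
      mu_bar = mb,
      argmax_coord = tab$coords[which.max(avg)],
      max_r_coord = tab$coords[which.max(r)],
      n_modes = count_modes(avg),
      bimodal = count_modes(avg) >= 2)
  }
  list(distribution = do.call(rbind, dist_rows),
       summary = do.call(rbind, sum_rows))
}

## Count strict local maxima of an abundance profile along the ladder,
## ignoring peaks below 1e-6 of the global maximum (numerical dust).
count_modes <- function(x) {
  x <- as.numeric(x)
  floor_val <- 1e-6 * max(x)
  n <- length(x)
  if (n < 3) return(as.integer(max(x) > 0))
  left <- c(-Inf, x[-n]); right <- c(x[-1], -Inf)
  sum(x > left & x >= right & x > floor_val)
}

#' Keep a subset of phenotypes
#'
#' Restricts a phenotype table to the given indices (growth/death rates and
#' adjacency are subset; the trade-off constraints still hold row-wise).
#'
#' @param table a `phenotype_table`.
#' @param keep phenotype indices to retain.
#' @return a `phenotype_table`.
#' @export
subset_phenotypes <- function(table, keep) {
  stopifnot(inherits(table, "phenotype_table"), length(keep) >= 1)
  tb <- new_phenotype_table(table$mu[keep, , drop = FALSE], table$params,
                            table$adjacency[keep, keep, drop = FALSE],
                            labels = table$labels[keep],
                            coords = if (is.null(table$coords)) NULL else
                              if (is.matrix(table$coords))
                                table$coords[keep, , drop = FALSE]
                              else table$coords[keep])
  tb
}

#' Simplex scan: abundance distribution for three nutrient types
#'
#' Simulates the E = 3 simplex lattice under constant intervals with
#' deterministic cycling through the three nutrients, for each
#' \eqn{\bar\mu} in a list. At high \eqn{\bar\mu} the distribution
#' concentrates on the central generalist; at low \eqn{\bar\mu} it splits
#' into three clusters of two-environment specialists along the edges.
#'
#' @param mu_bar_list \eqn{\bar\mu} values.
#' @param step,extent lattice geometry (see [build_simplex_set()]).
#' @param delta_tau,t_end,avg_intervals,a,b,p,S0,theta,seed as in
#'   [ladder_scan()] (default trailing window: 30 intervals).
#' @return list with `distribution` (data.frame with the lattice coords
#'   k1, k2, k3 and time averages) and `summary` (per \eqn{\bar\mu}: the
#'   argmax phenotype's lattice coordinates and whether it is the center).
#' @export
simplex_scan <- function(mu_bar_list, step = 0.2, extent = 5,
                         delta_tau = 10, t_end = 2e4, avg_intervals = 30,
                         a = 0.01, b = 1, p = 1e-4, S0 = 10, theta = 1e-8,
                         seed = 1) {
  dist_rows <- list(); sum_rows <- list()
  for (mb in mu_bar_list) {
    tab <- build_simplex_set(tradeoff_params(a = a, b = b, mu_bar = mb),
                             step = step, extent = extent)
    A <- switching_matrix(tab, p)
    sch <- make_schedule(interval_spec("constant", value = delta_tau),
                         env_selector("cycle", 3), t_end, seed)
    traj <- run_feast_famine(tab, A, sch, sim_config(S0 = S0, theta = theta))
    sm <- time_average(traj, trailing_window(traj, avg_intervals))
    avg <- sm$time_avg
    imax <- which.max(avg)
    dist_rows[[length(dist_rows) + 1L]] <- data.frame(
      mu_bar = mb, phenotype = seq_along(avg),
      k1 = tab$coords[, 1], k2 = tab$coords[, 2], k3 = tab$coords[, 3],
      time_avg = unname(avg))
    sum_rows[[length(sum_rows) + 1L]] <- data.frame(
      mu_bar = mb, argmax_k1 = tab$coords[imax, 1],
      argmax_k2 = tab$coords[imax, 2], argmax_k3 = tab$coords[imax, 3],
      center_dominant = all(tab$coords[imax, ] == 0))
  }
  list(distribution = do.call(rbind, dist_rows),
       summary = do.call(rbind, sum_rows))
}

#' Two-phenotype set: one generalist, one specialist
#'
#' The asymmetric pool in which the environment-B specialist is missing:
#' phenotype 1 specializes in A (\eqn{2\bar\mu, \bar\mu/2}), phenotype 2 is
#' the generalist. With this pool the generalist dominates at every
#' \eqn{\bar\mu} — the specialist-dominant regime requires the symmetric
#' specialist pair cooperating to suppress the generalist.
#'
#' @param params a [tradeoff_params()].
#' @return a `phenotype_table`.
#' @export
build_pair_set <- function(params) {
  stopifnot(inherits(params, "tradeoff_params"))
  mb <- params$mu_bar
  mu <- rbind(c(2 * mb, mb / 2), c(mb, mb))
  colnames(mu) <- c("A", "B")
  adj <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2)
  new_phenotype_table(mu, params, adj, labels = c("specialist_A", "generalist"))
}

#' Asymmetric-pool scan
#'
#' Re-runs the dominance scan with a phenotype pool missing one symmetric
#' partner: either the two-phenotype set (one generalist + one specialist)
#' or the half-ladder (all phenotypes with \eqn{\mu_A > \mu_B} removed).
#' In both cases the generalist stays dominant across the whole
#' \eqn{\bar\mu} grid.
#'
#' @param mu_bar_grid grid of \eqn{\bar\mu}.
#' @param kind `"pair"` or `"half_ladder"`.
#' @param ... passed to [dominance_scan()] (for `"pair"`) or
#'   [ladder_scan()] (for `"half_ladder"`).
#' @return for `"pair"`, a [dominance_scan()] table; for `"half_ladder"`, a
#'   [ladder_scan()] result restricted to \eqn{\mu_A \le \mu_B}.
#' @export
asymmetric_pool_scan <- function(mu_bar_grid, kind = c("pair", "half_ladder"),
                                 ...) {
  kind <- match.arg(kind)
  if (kind == "pair") {
    dominance_scan(mu_bar_grid, builder = build_pair_set, ...)
  } else {
    args <- list(...)
    n <- if (is.null(args$n)) 51 else args$n
    args$mu_bar_grid <- mu_bar_grid
    args$subset_keep <- seq_len((n + 1) / 2)  # coords <= 0: mu_A <= mu_B
    do.call(ladder_scan, args)
  }
}
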