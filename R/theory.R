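#' Coarse-grained phenotype profile
#'
#' Averages the two (or E) environments into a single effective one: the
#' coarse growth and death rates are the arithmetic means of the
#' per-environment rates (note: the mean of the death rates, not the death
#' rate at the mean growth rate), and r is their ratio — the dominance
#' statistic.
#'
#' @param table a `phenotype_table`.
#' @param phenotype phenotype index.
#' @return An object of class `coarse_profile` with fields `mu`, `gamma`,
#'   `r`.
#' @examples
#' tab <- build_three_phenotype_set(tradeoff_params(mu_bar = 0.8))
#' coarse_grain(tab, 2)  # the generalist
#' @export
coarse_grain <- function(table, phenotype) {
  stopifnot(inherits(table, "phenotype_table"),
            phenotype >= 1, phenotype <= table$n_phenotypes)
  mu <- mean(table$mu[phenotype, ])
  gamma <- mean(table$gamma[phenotype, ])
  structure(list(mu = mu, gamma = gamma, r = mu / gamma,
                 label = table$labels[phenotype]),
            class = "coarse_profile")
}

#' @export
print.coarse_profile <- function(x, ...) {
  cat(sprintf("Coarse profile (%s): <mu> = %.6g, <gamma> = %.6g, r = %.6g\n",
              x$label, x$mu, x$gamma, x$r))
  invisible(x)
}

#' Steady-state feast duration of a monomorphic resident
#'
#' At the resident's feast-famine steady state the per-cycle net log growth
#' vanishes, which fixes the feast fraction:
#' \deqn{T^+ = \frac{1/\mu}{1/\gamma + 1/\mu}\,\Delta\tau.}
#' Fast death (\eqn{\gamma \to \infty}) pushes the feast to fill the whole
#' cycle; \eqn{\mu = \gamma} splits it in half.
#'
#' @param profile a [coarse_grain()] profile (or any list with `mu`,
#'   `gamma`).
#' @param delta_tau inter-pulse interval (> 0).
#' @return feast duration (time).
#' @export
resident_feast_duration <- function(profile, delta_tau) {
  stopifnot(delta_tau > 0, profile$mu > 0, profile$gamma > 0)
  delta_tau * (1 / profile$mu) / (1 / profile$gamma + 1 / profile$mu)
}

#' Invasion fitness of a rare phenotype
#'
#' Net log growth per feast-famine cycle of a rare invader \eqn{\beta} in
#' the steady population of resident \eqn{\alpha}:
#' \deqn{f_\beta = \gamma_\beta \frac{1/\mu_\alpha}{1/\mu_\alpha +
#'   1/\gamma_\alpha} \Delta\tau
#'   \left(\frac{\mu_\beta}{\gamma_\beta} -
#'         \frac{\mu_\alpha}{\gamma_\alpha}\right).}
#' The prefactor is positive, so \eqn{\beta} invades exactly when its
#' growth-to-death ratio exceeds the resident's.
#'
#' @param resident,invader [coarse_grain()] profiles.
#' @param delta_tau inter-pulse interval (> 0).
#' @return An object of class `invasion_result` with `f_invader`,
#'   `T_plus_resident` and `can_invade`.
#' @export
invasion_fitness <- function(resident, invader, delta_tau) {
  stopifnot(delta_tau > 0, resident$mu > 0, resident$gamma > 0,
            invader$mu > 0, invader$gamma > 0)
  tp <- resident_feast_duration(resident, delta_tau)
  f <- invader$mu * tp - invader$gamma * (delta_tau - tp)
  structure(list(f_invader = f, T_plus_resident = tp,
                 can_invade = f > 0), class = "invasion_result")
}

#' @export
print.invasion_result <- function(x, ...) {
  cat(sprintf("Invasion fitness f = %.6g (%s); resident T+ = %.6g\n",
              x$f_invader, if (x$can_invade) "can invade" else "cannot invade",
              x$T_plus_resident))
  invisible(x)
}

#' Dominance transition: the mu_bar where generalist and specialist tie
#'
#' Locates the geometric-mean growth rate at which the generalist's and the
#' specialists' growth-to-death ratios cross (\eqn{r_g/r_s = 1}), i.e. where
#' the dominant strategy flips, by bracketed root-finding on
#' \eqn{r_g(\bar\mu) - r_s(\bar\mu)}.
#'
#' @param a,b growth-death trade-off constants.
#' @param builder phenotype-set constructor taking a [tradeoff_params()];
#'   must label the generalist `"generalist"`.
#' @param bracket search interval for \eqn{\bar\mu}; defaults to
#'   `c(0.01, 2.5) / b`.
#' @param tol root tolerance.
#' @return the critical \eqn{\bar\mu^*} (1/time).
#' @examples
#' dominance_transition_mu_bar(a = 0.01, b = 1)
#' @export
dominance_transition_mu_bar <- function(a = 0.01, b = 1,
                                        builder = build_three_phenotype_set,
                                        bracket = c(0.01, 2.5) / max(b, 1e-12),
                                        tol = 1e-12) {
  gap <- function(mb) {
    r <- growth_death_ratio(builder(tradeoff_params(a = a, b = b, mu_bar = mb)))
    r[["generalist"]] - r[[which(names(r) != "generalist")[1]]]
  }
  g1 <- gap(bracket[1]); g2 <- gap(bracket[2])
  if (!is.finite(g1) || !is.finite(g2) || sign(g1) == sign(g2)) {
    stop("no dominance transition inside the bracket: r_g - r_s does not ",
         "change sign (with b = 0 the ratio r_g/r_s is constant and the ",
         "transition does not exist)")
  }
  stats::uniroot(gap, bracket, tol = tol)$root
}

#' Strategy-branching point on the two-environment trade-off curve
#'
#' Parameterizes the resource-use trade-off as \eqn{\mu_A = \bar\mu e^t},
#' \eqn{\mu_B = \bar\mu e^{-t}} (so every t keeps the geometric mean at
#' \eqn{\bar\mu}) and asks when the symmetric strategy t = 0 stops
#' maximizing \eqn{\log r(t)}. The returned \eqn{\bar\mu^*} is the root of
#' the curvature \eqn{d^2 \log r / dt^2 |_{t=0}}, located numerically with
#' Richardson-extrapolated central differences; for the exponential
#' trade-off \eqn{\gamma = a e^{b\mu}} the curvature is
#' \eqn{1 - u - u^2} with \eqn{u = b\bar\mu}, giving the closed form
#' \eqn{\bar\mu^* = (\sqrt 5 - 1)/(2b)} (see
#' [branching_mu_bar_closed()]). Below \eqn{\bar\mu^*} the curvature is
#' positive: the symmetric strategy is a local minimum of r along the
#' curve, specialization pays, and the abundance distribution in a
#' quasi-continuous phenotype space turns bimodal. Above it the symmetric
#' strategy is a local maximum and the generalist dominates.
#'
#' @param a,b growth-death trade-off constants; `b` must be positive.
#' @param bracket search interval for \eqn{\bar\mu}; default
#'   `c(0.05, 2) / b`.
#' @param tol root tolerance.
#' @return the branching \eqn{\bar\mu^*} (1/time).
#' @examples
#' branching_mu_bar(a = 0.01, b = 1)  # (sqrt(5) - 1) / 2 = 0.618...
#' @export
branching_mu_bar <- function(a = 0.01, b = 1, bracket = c(0.05, 2) / b,
                             tol = 1e-12) {
  stopifnot(b > 0)
  curv <- function(mb) log_r_curvature(mb, a, b)
  c1 <- curv(bracket[1]); c2 <- curv(bracket[2])
  if (sign(c1) == sign(c2)) {
    stop("log r curvature does not change sign in the bracket")
  }
  stats::uniroot(curv, bracket, tol = tol)$root
}

#' @rdname branching_mu_bar
#' @export
branching_mu_bar_closed <- function(b) {
  stopifnot(b > 0)
  (sqrt(5) - 1) / (2 * b)
}

#' Curvature of log r along the trade-off curve at the symmetric strategy
#'
#' \eqn{d^2/dt^2 \log[\langle\mu(t)\rangle / \langle\gamma(t)\rangle]} at
#' t = 0 for \eqn{\mu_{A,B} = \bar\mu e^{\pm t}}. Positive curvature means
#' the symmetric (generalist) strategy is a local minimum of r and
#' specialization pays. Computed by Romberg-extrapolated symmetric
#' differences (the function is even in t, so only forward steps are
#' needed).
#'
#' @param mu_bar geometric-mean growth rate.
#' @param a,b trade-off constants.
#' @param h0 largest step of the extrapolation ladder.
#' @param levels extrapolation depth.
#' @return the curvature (dimensionless).
#' @export
log_r_curvature <- function(mu_bar, a, b, h0 = 0.4, levels = 5) {
  f <- function(t) {
    # log <mu> - log <gamma> along the curve; the prefactor a cancels in
    # the second derivative but is kept for interpretability
    log(mu_bar * cosh(t)) -
      log(a * (exp(b * mu_bar * exp(t)) + exp(b * mu_bar * exp(-t))) / 2)
  }
  f0 <- f(0)
  hs <- h0 / 2^(0:(levels - 1))
  d <- 2 * (vapply(hs, f, numeric(1)) - f0) / hs^2  # even function
  # Romberg table in powers of h^2
  for (k in seq_len(levels - 1)) {
    fac <- 4^k
    d <- (fac * d[-1] - d[-length(d)]) / (fac - 1)
  }
  d
}

#' Predicted time-averaged specialist population under sparse constant
#' supply
#'
#' In the regime where a long famine levels the playing field before each
#' pulse, the specialists' time-averaged population under constant intervals
#' scales as
#' \deqn{\langle X_s \rangle \sim s\,\frac{e^{d\,\Delta\tau}}{\Delta\tau},}
#' two competing effects: the 1/\eqn{\Delta\tau} dilution from rarer supply
#' and the exponential gain from feast durations that grow linearly with the
#' interval. `d` and the amplitude `scale` are fit parameters estimated from
#' simulation scans (see [fit_specialist_scaling()]). The curve has a single
#' interior minimum at \eqn{\Delta\tau = 1/d}.
#'
#' @param delta_tau constant inter-pulse interval(s) (> 0).
#' @param d exponential gain rate (1/time, >= 0).
#' @param scale amplitude.
#' @return predicted time-averaged specialist population(s).
#' @export
specialist_interval_scaling <- function(delta_tau, d, scale = 1) {
  stopifnot(all(delta_tau > 0), d >= 0)
  scale * exp(d * delta_tau) / delta_tau
}

#' Fit the sparse-supply scaling law to scan output
#'
#' The log of the predicted population is linear in \eqn{\Delta\tau} once
#' the known \eqn{-\log\Delta\tau} dilution term is moved to the left-hand
#' side, so the fit is ordinary least squares:
#' \eqn{\log X + \log\Delta\tau = \log s + d\,\Delta\tau}.
#'
#' @param delta_tau intervals (> 0).
#' @param x observed time-averaged populations (> 0).
#' @return list with `d`, `scale`, `fitted` values and `r_squared` of the
#'   linearized fit.
#' @export
fit_specialist_scaling <- function(delta_tau, x) {
  stopifnot(length(delta_tau) == length(x), all(delta_tau > 0), all(x > 0))
  y <- log(x) + log(delta_tau)
  fit <- stats::lm(y ~ delta_tau)
  d <- unname(stats::coef(fit)[2])
  scale <- exp(unname(stats::coef(fit)[1]))
  list(d = d, scale = scale,
       fitted = specialist_interval_scaling(delta_tau, d, scale),
       r_squared = suppressWarnings(summary(fit))$r.squared)
}

#' Cumulants of an interval distribution
#'
#' Closed-form cumulants \eqn{\kappa_1..\kappa_n}: constant (all zero past
#' the mean), gamma (\eqn{\kappa_n = k\,\theta^n (n-1)!}), normal (zero past
#' the variance), uniform (Bernoulli-number series; supported to order 4).
#'
#' @param spec an [interval_spec()].
#' @param n highest cumulant order.
#' @return numeric vector \eqn{(\kappa_1, \ldots, \kappa_n)}.
#' @export
interval_cumulants <- function(spec, n = 4) {
  stopifnot(inherits(spec, "interval_spec"), n >= 1)
  k <- numeric(n)
  k[1] <- interval_mean(spec)
  if (n == 1) return(k)
  switch(spec$family,
    constant = k,
    gamma = {
      k[2:n] <- spec$shape * spec$scale^(2:n) * factorial((2:n) - 1)
      k
    },
    normal = { k[2] <- spec$sd^2; k },
    uniform = {
      if (n > 4) stop("uniform cumulants supported to order 4")
      w <- spec$max - spec$min
      k[2] <- w^2 / 12
      if (n >= 4) k[4] <- -w^4 / 120
      k
    })
}

#' Variance boost of the time-averaged specialist population
#'
#' Averaging the sparse-supply scaling law over a random interval
#' distribution (time-weighted, as a temporal average must be) gives
#' \deqn{\langle X_s \rangle \sim \frac{\exp\left(\sum_{n\ge1}
#'   \frac{d^n}{n!}\kappa_n\right)}{E[\Delta\tau]},}
#' a cumulant series in the interval distribution. All coefficients are
#' positive, so at fixed mean any extra variance (\eqn{\kappa_2}) raises the
#' specialists' temporal average. The series is truncated at
#' `n_cumulants` (default 4); if the next retained term would exceed 1e-3 of
#' the truncated sum a warning reports the truncation as unreliable.
#'
#' @param spec an [interval_spec()].
#' @param d exponential gain rate from [fit_specialist_scaling()].
#' @param n_cumulants truncation order (>= 1).
#' @return the multiplicative factor
#'   \eqn{\exp(\sum d^n \kappa_n/n!)/E[\Delta\tau]}; for a constant interval
#'   this reduces exactly to [specialist_interval_scaling()] with scale 1.
#' @export
variance_boost <- function(spec, d, n_cumulants = 4) {
  stopifnot(d >= 0, n_cumulants >= 1)
  kap <- interval_cumulants(spec, n_cumulants)
  nn <- seq_len(n_cumulants)
  terms <- d^nn * kap / factorial(nn)
  s <- sum(terms)
  nxt <- tryCatch(interval_cumulants(spec, n_cumulants + 1)[n_cumulants + 1],
                  error = function(e) NA_real_)
  if (is.finite(nxt) && s != 0) {
    rem <- abs(d^(n_cumulants + 1) * nxt / factorial(n_cumulants + 1))
    if (rem > 1e-3 * abs(s)) {
      warning("cumulant series truncation unreliable: next term is ",
              signif(rem / abs(s), 3), " of the retained sum")
    }
  }
  exp(s) / interval_mean(spec)
}
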