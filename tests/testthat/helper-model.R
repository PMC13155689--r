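# Shared fixtures: the standard parameter setting and small helper runs.

std_params <- function(mu_bar, a = 0.01, b = 1) {
  tradeoff_params(a = a, b = b, mu_bar = mu_bar)
}

# Three-phenotype run under the standard setting; small horizons by default
# so unit tests stay fast.
quick_run <- function(mu_bar, spec = interval_spec("constant", value = 100),
                      seed = 1, t_end = 6e3, p = 1e-4,
                      env_mode = "uniform_random", theta = 1e-8) {
  tab <- build_three_phenotype_set(std_params(mu_bar))
  sch <- make_schedule(spec, env_selector(env_mode, 2), t_end, seed)
  run_feast_famine(tab, switching_matrix(tab, p), sch,
                   sim_config(theta = theta))
}

# Growth-to-death ratios of the symmetric three-phenotype set, written as
# plain formulas (independent of the table construction code).
r_generalist <- function(mu_bar, a = 0.01, b = 1) {
  mu_bar / (a * exp(b * mu_bar))
}
r_specialist <- function(mu_bar, a = 0.01, b = 1) {
  (2 * mu_bar + mu_bar / 2) / 2 /
    ((a * exp(b * 2 * mu_bar) + a * exp(b * mu_bar / 2)) / 2)
}
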