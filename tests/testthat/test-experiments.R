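test_that("time averaging integrates the exact piecewise segments", {
  # pure famine stretch: closed-form (1 - e^{-gT}) / (gT)
  params <- std_params(0.8)
  tab <- build_three_phenotype_set(params)
  sch <- make_schedule(interval_spec("constant", value = 500),
                       env_selector("cycle", 2), 1000, seed = 1)
  traj <- run_feast_famine(tab, switching_matrix(tab, 0), sch, sim_config())
  # window fully inside the initial famine [0, 500): X = X0 e^{-gamma_A t}
  w <- c(0, 400)
  avg <- time_average(traj, w)$time_avg
  g <- tab$gamma[, 1]
  expect_equal(unname(avg), (1 - exp(-g * 400)) / (g * 400), tolerance = 1e-12)
  # window covering a feast+famine cycle reproduces a trapezoid quadrature
  # on a fine grid that includes the depletion kink
  w2 <- c(500, 1000)
  avg2 <- time_average(traj, w2)$time_avg
  kink <- traj$pulse_time[2] + traj$T_plus[2]
  tt <- sort(unique(c(seq(500, 1000, length.out = 20001), kink)))
  xx <- trajectory_at(traj, tt)
  dt <- diff(tt)
  trap <- colSums((xx[-1, ] + xx[-nrow(xx), ]) / 2 * dt) / 500
  expect_equal(unname(avg2), unname(trap), tolerance = 1e-5)
  # constant trajectory sanity: zero-death, zero-growth degenerate check
  expect_equal(time_average(traj, c(0, 1e-6))$time_avg,
               c(specialist_A = 1, generalist = 1, specialist_B = 1),
               tolerance = 1e-4)
})

test_that("dominance depends on mu_bar as the r-criterion predicts", {
  spec <- interval_spec("gamma", shape = 2, scale = 50)
  lo <- dominance_scan(0.4, spec = spec, n_replicates = 3, base_seed = 1,
                       t_end = 3e4, window = c(2e4, 3e4))
  hi <- dominance_scan(0.8, spec = spec, n_replicates = 3, base_seed = 1,
                       t_end = 3e4, window = c(2e4, 3e4))
  expect_equal(lo$dominant, "specialist")
  expect_equal(hi$dominant, "generalist")
  expect_lt(lo$r_ratio, 1)
  expect_gt(hi$r_ratio, 1)
})

test_that("symmetric specialists pool within sampling error", {
  spec <- interval_spec("gamma", shape = 2, scale = 50)
  n_rep <- 5
  s1 <- s3 <- numeric(n_rep)
  for (rep in seq_len(n_rep)) {
    tab <- build_three_phenotype_set(std_params(0.4))
    sch <- make_schedule(spec, env_selector("uniform_random", 2), 3e4,
                         seed = 100 + rep)
    avg <- time_average(run_feast_famine(tab, switching_matrix(tab, 1e-4),
                                         sch, sim_config()),
                        c(2e4, 3e4))$time_avg
    s1[rep] <- avg[["specialist_A"]]; s3[rep] <- avg[["specialist_B"]]
  }
  se <- stats::sd(s1 - s3) / sqrt(n_rep)
  expect_lt(abs(mean(s1) - mean(s3)), 2 * se + 1e-12)
})

test_that("feast duration shrinks as the standing population grows", {
  # at fixed rates, a larger population at the pulse exhausts S0 sooner:
  # within one run, T+ anticorrelates with the population at the pulse
  # (per environment, since the growth rates differ between A and B)
  traj <- quick_run(0.8, spec = interval_spec("gamma", shape = 2, scale = 50),
                    seed = 5, t_end = 3e4)
  keep <- traj$pulse_time > 1e4  # steady-state cycles
  for (e in 1:2) {
    sel <- keep & traj$env == e & traj$depleted
    rho <- stats::cor(colSums(traj$X_start[, sel]), traj$T_plus[sel],
                      method = "spearman")
    expect_lt(rho, -0.9)
  }
  # and <T+> itself falls as mu_bar (hence consumption speed) rises
  df <- dominance_scan(c(0.3, 0.5, 0.7, 0.9), n_replicates = 2,
                       base_seed = 5, t_end = 3e4, window = c(2e4, 3e4))
  expect_true(all(diff(df$mean_T_plus) < 0))
})

test_that("missing a symmetric partner leaves the generalist dominant", {
  df <- asymmetric_pool_scan(c(0.3, 0.4, 0.6), kind = "pair",
                             n_replicates = 3, base_seed = 2,
                             t_end = 3e4, window = c(2e4, 3e4))
  expect_true(all(df$dominant == "generalist"))
  # while the symmetric trio at the same mu_bar is specialist-dominant
  sym <- dominance_scan(0.4, n_replicates = 3, base_seed = 2,
                        t_end = 3e4, window = c(2e4, 3e4))
  expect_equal(sym$dominant, "specialist")
  # half-ladder: specialists present at small mu_bar but never dominant
  half <- asymmetric_pool_scan(0.45, kind = "half_ladder", n = 21,
                               t_end = 6e3)
  expect_equal(half$summary$argmax_coord, 0)
})

test_that("ladder distribution is bimodal below and unimodal above branching", {
  res <- ladder_scan(c(0.5, 0.7), n = 21, t_end = 8e3)
  s <- res$summary
  expect_true(s$bimodal[s$mu_bar == 0.5])
  expect_true(abs(s$argmax_coord[s$mu_bar == 0.5]) > 0)
  expect_false(s$bimodal[s$mu_bar == 0.7])
  expect_equal(s$argmax_coord[s$mu_bar == 0.7], 0)
  # the most abundant phenotype carries the best growth-to-death ratio
  expect_equal(abs(s$argmax_coord), abs(s$max_r_coord))
  # log-normalization spans [0, 1] per column
  d5 <- res$distribution[res$distribution$mu_bar == 0.5, ]
  expect_equal(range(d5$log_norm), c(0, 1))
})

test_that("simplex distribution concentrates centrally at high mu_bar and splits at low", {
  res <- simplex_scan(c(0.4, 0.7), extent = 3, t_end = 6e3)
  s <- res$summary
  expect_true(s$center_dominant[s$mu_bar == 0.7])
  expect_false(s$center_dominant[s$mu_bar == 0.4])
  # low mu_bar argmax is a two-environment specialist (one coordinate
  # strongly negative), not a one-environment corner specialist
  lowmax <- unlist(s[s$mu_bar == 0.4, c("argmax_k1", "argmax_k2", "argmax_k3")])
  expect_equal(sum(lowmax), 0)
  expect_equal(sum(lowmax == min(lowmax)), 1)
  # abundance symmetric under cyclic relabeling of the three environments:
  # the three images of the argmax under rotation all carry peak-level mass
  d4 <- res$distribution[res$distribution$mu_bar == 0.4, ]
  key <- function(k) paste(k, collapse = "/")
  rot <- rbind(lowmax, lowmax[c(2, 3, 1)], lowmax[c(3, 1, 2)])
  mass <- vapply(seq_len(3), function(i) {
    d4$time_avg[match(key(rot[i, ]), paste(d4$k1, d4$k2, d4$k3, sep = "/"))]
  }, numeric(1))
  expect_gt(min(mass) / max(mass), 0.5)
})

test_that("configuration defaults, validation and round-trips hold", {
  cfg <- load_config(NULL)
  expect_equal(cfg$a, 0.01); expect_equal(cfg$b, 1)
  expect_equal(cfg$S0, 10); expect_equal(cfg$p, 1e-4)
  expect_equal(cfg$theta, 1e-8)
  path <- withr::local_tempfile(fileext = ".yaml")
  save_config(cfg, path)
  expect_equal(unclass(load_config(path)), unclass(cfg))
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("S0: -3", bad)
  expect_error(load_config(bad), "S0")
  unk <- withr::local_tempfile(fileext = ".yaml")
  writeLines("flux_capacitor: 1", unk)
  expect_error(load_config(unk), "unknown")
})

test_that("orchestration is deterministic, seeded and resumable-shaped", {
  cfg <- load_config(NULL)
  cfg$t_end <- 3e3; cfg$window <- c(2e3, 3e3)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  orchestrate(cfg, n_replicates = 2, base_seed = 11, out_dir = d1)
  orchestrate(cfg, n_replicates = 2, base_seed = 11, out_dir = d2)
  expect_identical(readLines(file.path(d1, "summary.json")),
                   readLines(file.path(d2, "summary.json")))
  expect_identical(readLines(file.path(d1, "replicate_1.csv")),
                   readLines(file.path(d2, "replicate_1.csv")))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  man <- jsonlite::read_json(file.path(d1, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$seeds, c(12, 13))
  expect_error(orchestrate(cfg, 1, out_dir = d1), "seed")
})
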