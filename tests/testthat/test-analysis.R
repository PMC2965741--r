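test_that("amount criterion matches hand-computed cases and is symmetric", {
  expect_equal(amount_criterion(0.70, 0.70, 0.70)$amount_criterion, 0)
  a <- amount_criterion(0.70, 0.695, 0.70)
  expect_equal(a$amount_criterion, 0.005 / 0.70)
  expect_true(a$pass)
  b <- amount_criterion(0.70, 0.60, 0.70)
  expect_equal(b$amount_criterion, 0.1 / 0.70)
  expect_false(b$pass)
  # symmetry and scale invariance
  expect_equal(amount_criterion(0.6, 0.7, 0.7)$amount_criterion,
               amount_criterion(0.7, 0.6, 0.7)$amount_criterion)
  expect_equal(amount_criterion(7, 6, 7)$amount_criterion,
               b$amount_criterion)
  expect_error(amount_criterion(0.7, 0.7, 0), "positive")
})

test_that("curve matching is zero for identical and purely shifted curves", {
  a <- synth_outflow(delay = 40, peak_time = 60, width = 25, total_ng = 0.6,
                     noise = 0, seed = 1)
  expect_equal(curve_match(a, a)$curve_distance_ng, 0)
  shifted <- a
  shifted$time <- shifted$time + 30  # three whole fractions later
  shifted <- rbind(data.frame(time = c(10, 20, 30), ng = 0),
                   as.data.frame(shifted))
  cm <- curve_match(a, shifted)
  expect_equal(cm$curve_distance_ng, 0, tolerance = 1e-12)
  expect_equal(cm$aligned_offset_s, 30)
})

test_that("a constant per-interval offset gives distance epsilon/sqrt(N)", {
  n <- 40
  base <- data.frame(time = seq(10, 10 * n, 10),
                     ng = dnorm(seq_len(n), 15, 4))
  eps <- 0.01
  bumped <- base
  bumped$ng <- bumped$ng + eps
  # rebin onto the native fraction grid so intervals align one-to-one
  cm <- curve_match(base, bumped, n_intervals = n, align_frac = 1e-6)
  expect_equal(cm$curve_distance_ng, eps / sqrt(n), tolerance = 0.05)
})

test_that("rebinning conserves mass and zero series are rejected", {
  t_end <- c(10, 20, 30, 40)
  ng <- c(0.1, 0.4, 0.3, 0.2)
  out <- fibercapture:::rebin_mass(t_end, ng, seq(0, 40, length.out = 14))
  expect_equal(sum(out), sum(ng))
  expect_error(curve_match(data.frame(time = 1:3, ng = 0),
                           data.frame(time = 1:3, ng = 1)),
               "nonzero")
})

test_that("experimental CSV dialects are parsed and converted", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("volume_mL,ng", "0.5,0.0", "1.0,0.30", "1.5,0.15"), path)
  x <- read_outflow_csv(path, flow_rate = 0.6)
  expect_equal(x$time, c(50, 100, 150))  # 0.5 mL at 0.6 mL/min = 50 s
  expect_error(read_outflow_csv(path), "flow_rate")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,ng", "50,0.0", "100,0.30"), path2)
  expect_equal(read_outflow_csv(path2)$ng, c(0, 0.3))
})

test_that("agreement report combines both criteria against a simulation", {
  sim <- run_cached("coarse_control_an", run_simulation(coarse_config()))
  frac <- fractionate(sim)
  exp_tbl <- data.frame(time = frac$t_end_s, ng = frac$ng)
  rep <- agreement_report(sim, exp_tbl)
  expect_true(rep$amount_pass)
  expect_true(rep$curve_pass)
  expect_equal(rep$amount_criterion, 0, tolerance = 1e-8)
  expect_equal(rep$M_entering, 0.7)
})

test_that("retention summary partitions by zone and matches the ledger", {
  cfg <- coarse_config(
    sites = list(zones = data.frame(
      z_from = c(0, 0.25), z_to = c(0.25, 1), R0 = c(0, 1e4),
      H0 = c(5e5, 2.5e5), internalize = c(FALSE, TRUE))))
  sim <- run_simulation(cfg)
  rs <- retention_summary(sim)
  lg <- sim$ledger[nrow(sim$ledger), ]
  expect_equal(sum(rs$zones$bound_ng), lg$bound, tolerance = 1e-12)
  expect_equal(sum(rs$zones$internalized_ng), lg$internalized,
               tolerance = 1e-12)
  expect_equal(rs$totals$retained_ng, lg$injected - lg$exited)
  expect_equal(rs$totals$specific_retained_ng,
               rs$totals$retained_ng - 0.3 * lg$injected)
  # the no-internalization front zone accumulates none
  expect_equal(rs$zones$internalized_ng[1], 0)
  # washout control: no binding sites, no nonspecific loss, long run
  inert <- fiber_config(
    flow = list(nonspecific_loss_fraction = 0),
    sites = list(zones = data.frame(z_from = 0, z_to = 1, R0 = 0, H0 = 0,
                                    internalize = FALSE)),
    numerics = list(n_r = 12, n_z = 60, total_time = 600))
  rs0 <- retention_summary(run_simulation(inert), nonspecific_fraction = 0)
  expect_lt(rs0$totals$retained_pct, 2)
})

test_that("HSPG removal lowers specific retention at low flow", {
  g_ctrl <- glance(run_cached("coarse_control_an",
                              run_simulation(coarse_config())))
  cfg0 <- coarse_config(
    sites = list(zones = data.frame(z_from = 0, z_to = 1, R0 = 1e4, H0 = 0,
                                    internalize = TRUE)))
  g_hep <- glance(run_simulation(cfg0))
  expect_gt(g_ctrl$specific_retention_pct, g_hep$specific_retention_pct)
})

test_that("sweeps scale by the base case and preserve run summaries", {
  cfg <- coarse_config(n_r = 10, n_z = 40, total_time = 60)
  tb <- sweep_simulations(cfg, "kinetics.k_c", cfg$kinetics$k_c)
  expect_equal(tb$ratio_vs_base, 1, tolerance = 1e-12)
  tb2 <- sweep_simulations(cfg, "flow.volumetric_rate", c(0.63, 3.0),
                           include_base = FALSE)
  expect_equal(tb2$ratio_vs_base[1], 1)
  expect_lt(tb2$retained_ng[2], tb2$retained_ng[1])
})
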