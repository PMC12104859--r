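test_that("trajectory shapes evaluate in closed form", {
  expect_identical(trajectory_value("constant", list(theta = -0.3), 57), -0.3)

  # linear recovery calibrated from -50% at t=0 to -25% at t=50
  lin <- list(theta0 = rr_from_percent(-50),
              slope = (rr_from_percent(-25) - rr_from_percent(-50)) / 50)
  expect_equal(trajectory_value("linear", lin, 0), log(0.5), tolerance = 1e-12)
  expect_equal(trajectory_value("linear", lin, 50), log(0.75), tolerance = 1e-12)

  u <- list(theta_start = log(2.36), theta_min = log(0.32), t_min = 25)
  expect_equal(trajectory_value("u_shaped", u, 25), log(0.32), tolerance = 1e-12)
  expect_equal(trajectory_value("u_shaped", u, 0), log(2.36), tolerance = 1e-12)
  # rising tail is capped at the initial pulse
  expect_equal(trajectory_value("u_shaped", u, 110), log(2.36), tolerance = 1e-12)

  sat <- list(floor = -3.9, scale = 15)
  expect_equal(trajectory_value("saturating", sat, 0), -3.9, tolerance = 1e-12)
  expect_lt(abs(trajectory_value("saturating", sat, 90)), 0.01)

  expect_error(trajectory_value("wiggle", list(), 1), "unknown")
  expect_error(trajectory_value("linear", list(theta0 = 1), 1), "slope")
  expect_error(trajectory_value("constant", list(theta = 1), -2), ">= 0")
})

test_that("configuration validation rejects impossible settings", {
  expect_error(flat_config(0, tau = -0.1), "tau")
  expect_error(flat_config(0, missing_rate = 1.2), "missing_variance_rate")
  expect_error(synthetic_config(time_model = list(
    canopy.clearcut = list(shape = "constant", params = list(theta = 0)))),
    "canopy")
})

test_that("noise-free limit reproduces the configured ratio exactly", {
  g <- generate_dataset(flat_config(log(0.5), tau = 0, cv = 0,
                                    n_studies = 15, obs_per_study = 3,
                                    seed = 101))
  ratio <- g$dataset$mean_treatment / g$dataset$mean_control
  expect_equal(ratio, rep(0.5, nrow(g$dataset)), tolerance = 1e-12)
  expect_equal(g$truth$theta_obs, rep(log(0.5), nrow(g$truth)),
               tolerance = 1e-12)
})

test_that("null truth gives mean RR near zero and effects recover theta/tau", {
  # symmetry around theta = 0
  g0 <- generate_dataset(flat_config(0, tau = 0.15, cv = 0.2,
                                     n_studies = 700, obs_per_study = 3,
                                     seed = 55))
  eff0 <- add_effect_sizes(g0$dataset)
  mc_se <- sd(eff0$rr) / sqrt(nrow(eff0))
  expect_lt(abs(mean(eff0$rr)), 3 * mc_se + 0.15 / sqrt(700) * 3)

  # law-of-large-numbers recovery of theta and tau^2 from study means
  g <- generate_dataset(flat_config(-0.4, tau = 0.25, cv = 0.15,
                                    n_studies = 2000, obs_per_study = 1,
                                    seed = 56))
  eff <- add_effect_sizes(g$dataset)
  expect_lt(abs(mean(eff$rr) + 0.4), 3 * sd(eff$rr) / sqrt(2000))
  # between-study variance: total variance minus mean sampling variance
  tau2_hat <- var(eff$rr) - mean(eff$se_rr^2)
  expect_lt(abs(tau2_hat - 0.0625), 3 * 0.0625 * sqrt(2 / 2000) + 0.005)
})

test_that("identical seeds give byte-identical datasets", {
  cfg <- synthetic_config(n_studies = 25, seed = 77)
  g1 <- generate_dataset(cfg)
  g2 <- generate_dataset(cfg)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_dataset(g1$dataset, p1)
  write_dataset(g2$dataset, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_identical(g1$truth, g2$truth)
})

test_that("generated composition follows the configured stratum weights", {
  g <- generate_dataset(synthetic_config(n_studies = 400, seed = 91))
  sm <- summarize_dataset(g$dataset)
  n <- sm$n_obs
  boreal <- sm$by_biome$pct[sm$by_biome$level == "boreal"] / 100
  expect_lt(abs(boreal - 0.431), 3 * sqrt(0.431 * 0.569 / 400) + 0.02)
  live <- sm$by_pool$pct[sm$by_pool$level == "live_trees"] / 100
  expect_lt(abs(live - 0.254), 3 * sqrt(0.254 * 0.746 / n) + 0.02)
  # clearcut chronosequences run longer than partial-cut ones
  tt <- sm$time_by_treatment
  expect_gt(tt$max[tt$treatment == "clearcut"],
            tt$max[tt$treatment == "partial"])
  expect_lte(tt$max[tt$treatment == "clearcut"], 110)
})

test_that("zero-at-origin flag produces -100% clearcut live-tree rows", {
  cfg <- synthetic_config(n_studies = 150, seed = 2, zero_at_origin = TRUE)
  g <- generate_dataset(cfg)
  early_cc_live <- g$dataset$pool == "live_trees" &
    g$dataset$treatment == "clearcut" & g$dataset$time_since_treatment <= 1
  expect_gt(sum(early_cc_live), 0)
  expect_true(all(g$dataset$mean_treatment[early_cc_live] == 0))
  eff <- add_effect_sizes(g$dataset)
  expect_true(all(eff$percent_diff[early_cc_live] == -100))
  expect_true(all(!eff$defined[early_cc_live]))
})
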