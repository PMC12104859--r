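test_that("DerSimonian-Laird pooling matches the hand computation", {
  # effects {0.2, 0.4} with se 0.1: Q = 2, tau2 = (2-1)/(200-100) = 0.01,
  # equal weights so the pooled mean is 0.3
  fit <- pool_random_effects(c(0.2, 0.4), c(0.1, 0.1), method = "DL")
  expect_equal(fit$tau2, 0.01, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients), 0.3, tolerance = 1e-12)
  expect_equal(fit$q, 2, tolerance = 1e-12)

  # identical effects: no heterogeneity
  same <- pool_random_effects(rep(0.2, 3), rep(0.1, 3), method = "DL")
  expect_equal(same$tau2, 0, tolerance = 1e-12)
  expect_equal(unname(same$coefficients), 0.2, tolerance = 1e-12)

  expect_error(pool_random_effects(c(0.1, 0.2), c(0, 0)), "degenerate")
  expect_error(pool_random_effects(0.1, 0.1), ">= 2")
})

test_that("DL tau2 matches the explicit-loop oracle on random instances", {
  withr::with_seed(41, {
    for (r in 1:50) {
      k <- sample(2:25, 1)
      y <- rnorm(k, 0, 0.5)
      se <- runif(k, 0.05, 0.4)
      fit <- pool_random_effects(y, se, method = "DL")
      expect_equal(fit$tau2, oracle_dl_tau2(y, se), tolerance = 1e-10)
    }
  })
})

test_that("REML pooling agrees with metafor as an independent reference", {
  withr::with_seed(43, {
    for (r in 1:5) {
      k <- sample(10:40, 1)
      y <- rnorm(k, -0.3, 0.3)
      se <- runif(k, 0.05, 0.3)
      mine <- pool_random_effects(y, se, method = "REML")
      ref <- metafor::rma(yi = y, sei = se, method = "REML")
      expect_equal(mine$tau2, as.numeric(ref$tau2), tolerance = 1e-4)
      expect_equal(unname(mine$coefficients), as.numeric(ref$beta),
                   tolerance = 1e-5)
      expect_equal(unname(mine$se_coefficients), as.numeric(ref$se),
                   tolerance = 1e-4)
    }
  })
})

test_that("weighted pooling reduces to the arithmetic mean under equal SEs", {
  # spread small enough that tau2 = 0, equal weights: algebraic identity
  y <- c(0.10, 0.11, 0.09, 0.105)
  fit <- pool_random_effects(y, rep(1, 4), method = "DL")
  expect_equal(fit$tau2, 0, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients), mean(y), tolerance = 1e-12)
})

test_that("intercept-only meta-regression nests pool_random_effects", {
  g <- generate_dataset(flat_config(-0.3, tau = 0.15, cv = 0.2,
                                    n_studies = 60, obs_per_study = 2,
                                    seed = 44))
  eff <- add_effect_sizes(g$dataset)
  eff <- eff[!is.na(eff$se_rr), ]
  direct <- pool_random_effects(eff$rr, eff$se_rr, method = "REML")
  via_reg <- fit_meta_regression(eff, fixed = ~1, random = character(0),
                                 mode = "weighted", include_study = FALSE)
  expect_equal(via_reg$coefficients, direct$coefficients, tolerance = 1e-10)
  expect_equal(via_reg$tau2, direct$tau2, tolerance = 1e-10)
})

test_that("meta-regression recovers distinct treatment effects", {
  te <- default_true_effects()
  te$theta <- ifelse(te$treatment == "clearcut", -1.5, -0.6)
  cfg <- synthetic_config(
    n_studies = 150, obs_per_study = 2, true_effects = te, tau = 0.15,
    cv_within = 0.2, missing_variance_rate = 0, time_model = list(),
    zero_at_origin = FALSE,
    stratum_probs = list(biome = c(boreal = .5, temperate = .5),
                         partial_given_biome = c(boreal = .5, temperate = .5),
                         pool = c(live_trees = 1, snags = 0, understory = 0,
                                  coarse_woody_debris = 0, forest_floor = 0,
                                  mineral_soil = 0)),
    seed = 45)
  eff <- add_effect_sizes(generate_dataset(cfg)$dataset)

  for (mode in c("weighted", "unweighted")) {
    fit <- fit_meta_regression(eff, fixed = ~ treatment - 1,
                               random = "biome", mode = mode)
    expect_equal(unname(fit$coefficients["treatmentclearcut"]), -1.5,
                 tolerance = 0.12)
    expect_equal(unname(fit$coefficients["treatmentpartial"]), -0.6,
                 tolerance = 0.12)
    expect_gte(fit$tau2, 0)
    expect_true(all(fit$ci[, "lower"] <= fit$coefficients &
                      fit$coefficients <= fit$ci[, "upper"]))
  }
})

test_that("rank-deficient designs and single-level random factors are caught", {
  g <- generate_dataset(flat_config(-0.3, tau = 0.1, cv = 0.2,
                                    n_studies = 30, obs_per_study = 2,
                                    seed = 46))
  eff <- add_effect_sizes(g$dataset)
  eff$dup <- eff$treatment  # aliased moderator
  expect_error(fit_meta_regression(eff, fixed = ~ treatment + dup,
                                   mode = "unweighted"),
               "aliased")
  eff$onelevel <- "constant"
  expect_warning(fit_meta_regression(eff, fixed = ~treatment,
                                     random = c("biome", "onelevel"),
                                     mode = "unweighted"),
                 "single-level")
})

test_that("bootstrap CIs are deterministic, degenerate-safe and count failures", {
  df <- data.frame(study_id = rep(sprintf("S%d", 1:8), each = 4),
                   rr = rep(0.25, 32))
  b1 <- bootstrap_ci(df, function(d) mean(d$rr), n_boot = 300, seed = 9)
  b2 <- bootstrap_ci(df, function(d) mean(d$rr), n_boot = 300, seed = 9)
  expect_identical(b1$replicates, b2$replicates)
  expect_equal(unname(b1$lower), unname(b1$upper))  # width 0 on constant data
  expect_equal(unname(b1$point), 0.25)

  withr::with_seed(50, {
    df2 <- data.frame(study_id = rep(c("A", "B", "C"), each = 3),
                      rr = rnorm(9))
  })
  fragile <- function(d) {
    if (!"A" %in% d$study_id) stop("lost stratum")
    mean(d$rr)
  }
  expect_warning(
    b3 <- bootstrap_ci(df2, fragile, n_boot = 300, seed = 10),
    "failed")
  expect_gt(b3$n_failed, 0)
  expect_lt(b3$n_failed, 300)
})

test_that("stratum estimates back-transform after pooling, never before", {
  # strongly skewed effects: averaging percent differences first is a
  # different (wrong) estimator
  withr::with_seed(51, {
    rr <- rnorm(40, 0, 1.2)
    df <- data.frame(study_id = rep(sprintf("S%d", 1:10), 4), rr = rr,
                     se_rr = 0.2, defined = TRUE, pool = "live_trees",
                     treatment = "clearcut", biome = "boreal")
  })
  est <- estimate_stratum_effects(df, mode = "unweighted", n_boot = 300,
                                  seed = 52)
  expect_equal(est$percent, percent_difference(mean(rr)), tolerance = 1e-9)
  wrong <- mean(percent_difference(rr))
  expect_gt(abs(wrong - est$percent), 10)  # the estimators genuinely differ
})

test_that("small strata are reported as insufficient, not fitted", {
  df <- data.frame(study_id = c("A", "A", "B", "B", "B", "C"),
                   rr = c(0.1, 0.2, -0.1, 0.05, 0, 0.3),
                   se_rr = 0.1, defined = TRUE,
                   pool = c(rep("live_trees", 5), "snags"),
                   treatment = "clearcut", biome = "boreal")
  est <- estimate_stratum_effects(df, mode = "unweighted", n_boot = 300,
                                  seed = 53)
  expect_identical(est$status[est$pool == "snags"], "insufficient")
  expect_identical(est$status[est$pool == "live_trees"], "ok")
})
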