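test_that("Q decomposition matches the hand-computed two-group example", {
  # two groups of identical effects {0.1, 0.1} and {0.3, 0.3}, all se = 0.1:
  # weights 100 each, grand mean 0.2, so Q_w = 0 and
  # Q_b = 4 * 100 * 0.1^2 = 4 on 1 df
  res <- q_decomposition(c(0.1, 0.1, 0.3, 0.3), c("a", "a", "b", "b"),
                         weights = rep(100, 4), moderator = "grp")
  expect_equal(res$q_within, 0, tolerance = 1e-12)
  expect_equal(res$q_between, 4, tolerance = 1e-12)
  expect_identical(res$df_between, 1L)
  expect_equal(res$p_value, pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$p_value, 0.0455, tolerance = 1e-3)
})

test_that("degenerate groupings behave: equal effects and saturated splits", {
  res <- q_decomposition(rep(0.2, 6), rep(c("a", "b"), 3))
  expect_equal(res$q_total, 0, tolerance = 1e-12)
  expect_equal(res$q_between, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  # groups = observation index: all heterogeneity is between groups
  y <- c(0.1, -0.4, 0.9, 0.3)
  sat <- q_decomposition(y, as.character(seq_along(y)))
  expect_equal(sat$q_within, 0, tolerance = 1e-12)
  expect_equal(sat$q_between, sat$q_total, tolerance = 1e-12)

  expect_error(q_decomposition(c(1, 2), c("a", "a")), "2 non-empty groups")
})

test_that("Q decomposition agrees with the explicit-loop oracle", {
  withr::with_seed(17, {
    for (r in 1:100) {
      k <- sample(4:30, 1)
      y <- rnorm(k)
      g <- sample(letters[1:sample(2:4, 1)], k, replace = TRUE)
      if (length(unique(g)) < 2) g[1:2] <- c("a", "b")
      w <- if (r %% 2 == 0) runif(k, 0.5, 50) else NULL
      mine <- q_decomposition(y, g, weights = w)
      ref <- oracle_q(y, g, w)
      tol <- 1e-10 * max(1, ref$q_total)
      expect_lt(abs(mine$q_total - ref$q_total), tol)
      expect_lt(abs(mine$q_within - ref$q_within), tol)
      expect_lt(abs(mine$q_between - ref$q_between), tol)
      expect_lt(abs(mine$q_total - (mine$q_within + mine$q_between)), tol)
    }
  })
})

test_that("Q_between is invariant to relabelling of group levels", {
  withr::with_seed(23, {
    y <- rnorm(40)
    g <- sample(c("x", "y", "z"), 40, replace = TRUE)
    w <- runif(40, 1, 10)
    a <- q_decomposition(y, g, weights = w)
    relabel <- c(x = "group3", y = "group1", z = "group2")
    b <- q_decomposition(y, unname(relabel[g]), weights = w)
    expect_equal(a$q_between, b$q_between, tolerance = 1e-12)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  })
})

test_that("hierarchical partition recovers a constructed two-layer truth", {
  te <- default_true_effects()
  te$theta <- ifelse(te$pool == "live_trees",
                     ifelse(te$treatment == "clearcut", -1.5, -0.6),
                     ifelse(te$pool == "mineral_soil", 0, -0.2))
  cfg <- synthetic_config(
    n_studies = 80, obs_per_study = c(4, 8), true_effects = te, tau = 0.05,
    cv_within = 0.2, missing_variance_rate = 0, time_model = list(),
    zero_at_origin = FALSE,
    stratum_probs = list(biome = c(boreal = .5, temperate = .5),
                         partial_given_biome = c(boreal = .5, temperate = .5),
                         pool = c(live_trees = .3, snags = .14,
                                  understory = .14, coarse_woody_debris = .14,
                                  forest_floor = .14, mineral_soil = .14)),
    seed = 42)
  eff <- add_effect_sizes(generate_dataset(cfg)$dataset)
  tree <- hierarchical_partition(eff, c("pool", "treatment", "biome"),
                                 alpha = 0.05)
  expect_false(tree$leaf)
  expect_identical(tree$moderator, "pool")
  live <- tree$children$live_trees
  expect_false(live$leaf)
  expect_identical(live$moderator, "treatment")
})

test_that("partition of homogeneous data is a single leaf", {
  g <- generate_dataset(flat_config(-0.2, tau = 0.02, cv = 0.1,
                                    n_studies = 30, obs_per_study = 4,
                                    seed = 3))
  eff <- add_effect_sizes(g$dataset)
  tree <- hierarchical_partition(eff, c("pool", "treatment", "biome"),
                                 alpha = 0.001)
  expect_true(tree$leaf)
  expect_match(tree$reason, "no significant")
})

test_that("subgroups below the minimum size become diagnostic leaves", {
  df <- data.frame(rr = rnorm(10), pool = rep(c("a", "b"), 5),
                   treatment = "clearcut")
  tree <- hierarchical_partition(df, "pool", min_group = 20L)
  expect_true(tree$leaf)
  expect_match(tree$reason, "insufficient")
})

test_that("heterogeneity table reports Q_b overall and within pools", {
  g <- generate_dataset(synthetic_config(n_studies = 50, seed = 19))
  eff <- add_effect_sizes(g$dataset)
  tab <- heterogeneity_table(eff, c("pool", "treatment", "biome"),
                             split_by = "pool")
  expect_identical(tab$response[1], "ecosystem")
  expect_true(all(CARBON_POOLS %in% tab$response[-1]))
  expect_true(all(tab$qb_treatment >= 0 | is.na(tab$qb_treatment)))
  # the pool column only makes sense on the overall row
  expect_true(all(is.na(tab$qb_pool[-1])))
})
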