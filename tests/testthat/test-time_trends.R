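trend_data <- function(n, shape, params, tmax, sd = 0, tmin = 1,
                       seed = NULL) {
  build <- function() {
    t <- runif(n, tmin, tmax)
    data.frame(time_since_treatment = t,
               rr = trajectory_value(shape, params, t) + rnorm(n, 0, sd),
               defined = TRUE, se_rr = 0.2,
               study_id = sprintf("S%02d", seq_len(n)),
               percent_diff = NA_real_)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

test_that("noise-free linear truth is recovered exactly", {
  d <- trend_data(40, "linear", list(theta0 = -0.69, slope = 0.008), 80,
                  sd = 0, seed = 61)
  fit <- fit_time_trend(d, "linear")
  expect_equal(unname(fit$coefficients), c(-0.69, 0.008), tolerance = 1e-8)
  expect_equal(fit$predict_percent(0), percent_difference(-0.69),
               tolerance = 1e-6)
})

test_that("linear family is nested in the spline family", {
  d <- trend_data(60, "saturating", list(floor = -3.9, scale = 15), 80,
                  sd = 0.3, seed = 62)
  flin <- fit_time_trend(d, "linear")
  fspl <- fit_time_trend(d, "spline")
  expect_gte(fspl$loglik, flin$loglik)
  fcub <- fit_time_trend(d, "cubic")
  expect_gte(fcub$loglik, flin$loglik)
})

test_that("weighted fit with equal weights equals the unweighted fit", {
  d <- trend_data(30, "linear", list(theta0 = -0.5, slope = 0.005), 50,
                  sd = 0.2, seed = 63)
  d$se_rr <- 0.25  # constant: weights equal
  fw <- fit_time_trend(d, "cubic", weighted = TRUE)
  fu <- fit_time_trend(d, "cubic", weighted = FALSE)
  expect_equal(fw$coefficients, fu$coefficients, tolerance = 1e-10)
})

test_that("back-transformed predictions never cross -100%", {
  d <- trend_data(50, "saturating", list(floor = -4.5, scale = 10), 100,
                  sd = 0.4, seed = 64)
  fit <- fit_time_trend(d, "spline")
  preds <- fit$predict_percent(seq(0, 120, by = 1))
  expect_true(all(preds > -100))
})

test_that("selection returns intercept-only when no family is significant", {
  d <- trend_data(50, "constant", list(theta = 0), 60, sd = 0.3, seed = 65)
  sel <- select_trend_model(d, alpha = 1e-6)
  expect_identical(sel$winner$family, "intercept")
  expect_match(sel$note, "no candidate")
  expect_false(any(sel$table$selected))
})

test_that("degenerate trend inputs raise informative errors", {
  d <- trend_data(4, "linear", list(theta0 = 0, slope = 0), 50, seed = 66)
  expect_error(fit_time_trend(d, "linear"), ">= 5")
  d2 <- trend_data(30, "linear", list(theta0 = 0, slope = 0.01), 50,
                   sd = 0.1, seed = 67)
  expect_error(fit_time_trend(d2, "spline", knots = c(10, 200, 300)),
               "inside the time range")
})

test_that("curve crossing is located on noise-free recovery trajectories", {
  dcc <- trend_data(120, "saturating", list(floor = -3.9, scale = 15), 80,
                    sd = 0, seed = 68)
  dpc <- trend_data(120, "linear",
                    list(theta0 = log(0.5),
                         slope = (log(0.75) - log(0.5)) / 50), 50,
                    sd = 0, seed = 69)
  fcc <- fit_time_trend(dcc, "spline")
  fpc <- fit_time_trend(dpc, "linear")
  cross <- trend_crossing_time(fcc, fpc, c(5, 60))
  # analytic crossing of the generating curves is near year 33
  expect_equal(cross, 33, tolerance = 0.12)
})

test_that("binned profiles are consistent, deterministic and zero-aware", {
  g <- generate_dataset(synthetic_config(n_studies = 40, seed = 71))
  eff <- add_effect_sizes(g$dataset)

  # single bin covering everything equals the stratum mean estimate
  one <- binned_time_profile(eff, breaks = c(0, 200), n_boot = 300, seed = 5)
  live_cc <- one[one$pool == "live_trees" & one$treatment == "clearcut", ]
  sub <- eff[eff$pool == "live_trees" & eff$treatment == "clearcut" &
               eff$defined, ]
  expect_equal(live_cc$est_rr, mean(sub$rr), tolerance = 1e-10)

  p1 <- binned_time_profile(eff, n_boot = 300, seed = 6)
  p2 <- binned_time_profile(eff, n_boot = 300, seed = 6)
  expect_identical(p1, p2)
  expect_true(all(p1$status %in% c("ok", "empty", "insufficient", "all_zero")))
  # empty bins are reported empty, never interpolated
  expect_true(all(is.na(p1$percent[p1$status == "empty"])))

  # a bin made only of zero-treatment rows displays -100%
  zero <- data.frame(study_id = "Z", unit_id = "u", pool = "live_trees",
                     treatment = "clearcut", biome = "boreal",
                     time_since_treatment = c(0.1, 0.4, 0.6),
                     rr = NA_real_, defined = FALSE, percent_diff = -100,
                     se_rr = NA_real_)
  pz <- binned_time_profile(zero, breaks = c(0, 10), n_boot = 300, seed = 7)
  expect_identical(pz$status, "all_zero")
  expect_identical(pz$percent, -100)
})
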