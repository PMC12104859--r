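#' Evaluate a time-trajectory of the true log response ratio
#'
#' Phenomenological stand-in trajectories for how a pool's true effect
#' evolves with time since treatment:
#' * `constant` — `theta`, ignoring `t`;
#' * `linear` — `theta0 + slope * t` (gradual recovery after partial
#'   cutting);
#' * `saturating` — `floor * exp(-t / scale)`: starts at `floor` (a large
#'   negative deficit for clearcut live trees, or a positive pulse for
#'   understory vegetation) and decays toward the reference level;
#' * `u_shaped` — a quadratic `theta_min + (theta_start - theta_min) *
#'   ((t - t_min)/t_min)^2`, capped above at `theta_start`, crossing from
#'   positive through a minimum and back (the deadwood
#'   accumulation-then-decay arc).
#'
#' @param shape one of `"constant"`, `"linear"`, `"saturating"`,
#'   `"u_shaped"`.
#' @param params named list of the shape's parameters (see above).
#' @param t years since treatment, `>= 0`. Vectorized.
#' @return True log response ratio at `t`.
#' @examples
#' trajectory_value("constant", list(theta = -0.3), 57)
#' trajectory_value("linear", list(theta0 = log(0.5), slope = 0.008), 0)
#' @export
trajectory_value <- function(shape, params, t) {
  if (any(t < 0, na.rm = TRUE)) stop("t must be >= 0", call. = FALSE)
  need <- function(nm) {
    if (is.null(params[[nm]])) {
      stop(sprintf("trajectory '%s' requires parameter '%s'", shape, nm),
           call. = FALSE)
    }
    params[[nm]]
  }
  switch(shape,
    constant = rep(need("theta"), length(t)),
    linear = need("theta0") + need("slope") * t,
    saturating = need("floor") * exp(-t / need("scale")),
    u_shaped = {
      t_min <- need("t_min")
      th0 <- need("theta_start")
      # capped at the initial pulse so the rising tail levels off instead
      # of diverging on long chronosequences
      pmin(th0, need("theta_min") + (th0 - need("theta_min")) *
             ((t - t_min) / t_min)^2)
    },
    stop("unknown trajectory shape: ", shape, call. = FALSE)
  )
}

#' Default per-stratum true effects
#'
#' One row per pool x treatment x biome with the true log response ratio
#' used when no time trajectory is configured for the stratum. Magnitudes
#' follow the characteristic pattern of harvested northern forests: strong
#' aboveground losses that depend on cutting intensity (live trees,
#' snags), an understory release, a transient deadwood response, a modest
#' forest-floor loss confined to temperate clearcuts, and no mineral-soil
#' effect.
#'
#' @return Data frame with columns `pool`, `treatment`, `biome`, `theta`.
#' @export
default_true_effects <- function() {
  grid <- expand.grid(pool = CARBON_POOLS, treatment = HARVEST_TREATMENTS,
                      biome = FOREST_BIOMES, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  theta <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    theta[i] <- switch(grid$pool[i],
      live_trees = if (grid$treatment[i] == "clearcut") log(0.22) else log(0.55),
      snags = if (grid$treatment[i] == "clearcut") -0.9 else -0.45,
      understory = log(2.21),
      coarse_woody_debris = 0,
      forest_floor = if (grid$treatment[i] == "clearcut" &&
                           grid$biome[i] == "temperate") log(0.79) else 0,
      mineral_soil = 0)
  }
  grid$theta <- theta
  grid
}

#' Default time-trajectory models
#'
#' Named list keyed `"pool.treatment"`. Live trees recover linearly after
#' partial cutting (about -50% to -25% over 50 years) and along a steep
#' saturating curve after clearcutting (near-total loss at the origin,
#' close to the reference by year 60, crossing the partial-cut line in the
#' thirties). Coarse woody debris follows a U-shaped arc (an input pulse
#' at harvest, a mid-rotation deficit around year 25, slow return).
#' Understory vegetation pulses upward and decays within a couple of
#' decades. Pools without an entry use the constant effect from
#' [default_true_effects()].
#'
#' @return Named list of `list(shape =, params =)` entries.
#' @export
default_time_models <- function() {
  list(
    live_trees.clearcut = list(shape = "saturating",
                               params = list(floor = -3.9, scale = 15)),
    live_trees.partial = list(shape = "linear",
                              params = list(theta0 = log(0.5),
                                            slope = (log(0.75) - log(0.5)) / 50)),
    coarse_woody_debris.clearcut = list(shape = "u_shaped",
                                        params = list(theta_start = log(2.36),
                                                      theta_min = log(0.32),
                                                      t_min = 25)),
    coarse_woody_debris.partial = list(shape = "u_shaped",
                                       params = list(theta_start = log(1.43),
                                                     theta_min = log(0.32),
                                                     t_min = 25)),
    understory.clearcut = list(shape = "saturating",
                               params = list(floor = log(6), scale = 8)),
    understory.partial = list(shape = "saturating",
                              params = list(floor = log(2.25), scale = 8))
  )
}

#' Default reference-stand carbon ranges per pool
#'
#' Uniform sampling intervals (Mg C ha^-1) for the reference-stand mean of
#' each pool, sized so that a fully measured unit totals roughly
#' 220 Mg C ha^-1 with live trees and mineral soil dominating.
#'
#' @return Named list of `c(lo, hi)` intervals.
#' @export
default_control_ranges <- function() {
  list(live_trees = c(50, 140), mineral_soil = c(40, 110),
       forest_floor = c(15, 50), snags = c(5, 22),
       coarse_woody_debris = c(4, 18), understory = c(0.5, 3))
}

#' Build and validate a synthetic-data configuration
#'
#' The generative truth behind [generate_dataset()]: per-stratum true log
#' response ratios, between-study heterogeneity `tau`, within-arm sampling
#' error from a coefficient of variation and drawn replicate counts, a
#' missingness rate for variance information (default 0.19, i.e. 81% of
#' rows keep complete SD/n), time trajectories per pool x treatment, and
#' the composition of studies across biomes, treatments and pools. The
#' defaults emulate a synthesis of ~60 published harvest studies in
#' eastern North American boreal/temperate forests: 43% boreal
#' observations, partial cutting about twice as frequent in temperate as
#' in boreal studies, live trees and forest floor the best-sampled pools,
#' clearcut chronosequences reaching 110 years and partial ones 50.
#'
#' @param n_studies number of studies (default 61).
#' @param obs_per_study integer range `c(lo, hi)` (or scalar) of
#'   observations contributed per study.
#' @param true_effects data frame as [default_true_effects()].
#' @param tau between-study SD of true effects (default 0.2).
#' @param control_mean_range named list of per-pool reference intervals.
#' @param cv_within within-arm coefficient of variation of plot-level
#'   stocks (default 0.3); arm SE is `cv * mean / sqrt(n)`.
#' @param n_reps_range integer range of plot replicate counts per arm
#'   (default 3--10; both arms of a comparison share the count, as in
#'   paired plot designs).
#' @param missing_variance_rate fraction of rows stripped of SD/n.
#' @param time_model named list as [default_time_models()].
#' @param zero_at_origin generate exact zero treatment means for clearcut
#'   live-tree rows within a year of harvest (the -100% points that
#'   exercise downstream zero handling).
#' @param stratum_probs list with `biome` shares, `partial_given_biome`
#'   probabilities and `pool` composition weights.
#' @param prop_old_forest share of studies whose reference is an old
#'   forest rather than a long-unmanaged stand (default 0.55).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_studies = 61,
                             obs_per_study = c(3, 14),
                             true_effects = default_true_effects(),
                             tau = 0.2,
                             control_mean_range = default_control_ranges(),
                             cv_within = 0.3,
                             n_reps_range = c(3, 10),
                             missing_variance_rate = 0.19,
                             time_model = default_time_models(),
                             zero_at_origin = TRUE,
                             stratum_probs = list(
                               biome = c(boreal = 0.431, temperate = 0.569),
                               partial_given_biome = c(boreal = 0.103,
                                                       temperate = 0.206),
                               pool = c(live_trees = 0.254, snags = 0.153,
                                        understory = 0.087,
                                        coarse_woody_debris = 0.192,
                                        forest_floor = 0.201,
                                        mineral_soil = 0.114)),
                             prop_old_forest = 0.55,
                             seed = NULL) {
  if (length(obs_per_study) == 1L) obs_per_study <- rep(obs_per_study, 2L)
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  if (missing_variance_rate < 0 || missing_variance_rate > 1) {
    stop("missing_variance_rate must lie in [0, 1]", call. = FALSE)
  }
  if (cv_within < 0) stop("cv_within must be >= 0", call. = FALSE)
  stopifnot(n_studies >= 1, all(obs_per_study >= 1),
            obs_per_study[1] <= obs_per_study[2],
            all(n_reps_range >= 1), n_reps_range[1] <= n_reps_range[2])
  stopifnot(all(c("pool", "treatment", "biome", "theta") %in%
                  names(true_effects)))
  for (key in names(time_model)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    if (length(parts) != 2L ||
        !any(true_effects$pool == parts[1L] &
               true_effects$treatment == parts[2L])) {
      stop("time_model stratum not present in true_effects: ", key,
           call. = FALSE)
    }
    tm <- time_model[[key]]
    trajectory_value(tm$shape, tm$params, 0)  # validates shape + params
  }
  missing_rng <- setdiff(unique(true_effects$pool), names(control_mean_range))
  if (length(missing_rng) > 0L) {
    stop("control_mean_range missing pool(s): ",
         paste(missing_rng, collapse = ", "), call. = FALSE)
  }
  structure(list(n_studies = n_studies, obs_per_study = obs_per_study,
                 true_effects = true_effects, tau = tau,
                 control_mean_range = control_mean_range,
                 cv_within = cv_within, n_reps_range = n_reps_range,
                 missing_variance_rate = missing_variance_rate,
                 time_model = time_model, zero_at_origin = zero_at_origin,
                 stratum_probs = stratum_probs,
                 prop_old_forest = prop_old_forest, seed = seed),
            class = "synthetic_config")
}

# True effect for one observation, before the study-level deviation.
true_theta <- function(cfg, pool, treatment, biome, t) {
  tm <- cfg$time_model[[paste(pool, treatment, sep = ".")]]
  if (!is.null(tm)) return(trajectory_value(tm$shape, tm$params, t))
  hit <- cfg$true_effects$pool == pool &
    cfg$true_effects$treatment == treatment &
    cfg$true_effects$biome == biome
  if (!any(hit)) {
    stop(sprintf("no true effect configured for (%s, %s, %s)",
                 pool, treatment, biome), call. = FALSE)
  }
  cfg$true_effects$theta[which(hit)[1L]]
}

#' Generate a synthetic dataset with known truth
#'
#' Simulates the data structure the analysis assumes. Each study draws a
#' biome, a harvest treatment, a reference type and a study-level effect
#' deviation `b_s ~ N(0, tau^2)` shared by all its observations. Studies
#' contribute one or more experimental units (each a time point with a
#' subset of pools measured); for every observation the true effect
#' `theta(t) + b_s` is evaluated from the configured trajectory or
#' constant, the reference mean is drawn from the pool's range, the
#' treatment mean is `reference * exp(effect)`, and both observed arm
#' means receive Normal sampling error with SD `cv * mean / sqrt(n)`
#' (truncated just above zero for the reference arm). Reported SEs derive
#' from the true CV and the drawn replicate count; variance information is
#' then stripped from a `missing_variance_rate` fraction of rows.
#' Identical configuration and seed give identical output, byte-for-byte
#' after [write_dataset()].
#'
#' @param cfg a [synthetic_config()].
#' @return List with `dataset` (a validated `carbon_dataset`), `truth`
#'   (per-row generative record: trend effect, study deviation, realized
#'   effect, latent arm means) and `config`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  run <- function() generate_dataset_impl(cfg)
  if (is.null(cfg$seed)) run() else withr::with_seed(cfg$seed, run())
}

generate_dataset_impl <- function(cfg) {
  sp <- cfg$stratum_probs
  pool_names <- names(sp$pool)
  rows <- vector("list", cfg$n_studies)
  truth <- vector("list", cfg$n_studies)

  for (s in seq_len(cfg$n_studies)) {
    study_id <- sprintf("S%03d", s)
    biome <- sample(names(sp$biome), 1L, prob = sp$biome)
    treatment <- if (runif(1) < sp$partial_given_biome[[biome]]) {
      "partial"
    } else {
      "clearcut"
    }
    reference_type <- if (runif(1) < cfg$prop_old_forest) {
      "old_forest"
    } else {
      "unmanaged_80plus"
    }
    b_s <- rnorm(1L, 0, cfg$tau)
    n_obs <- sample(seq(cfg$obs_per_study[1], cfg$obs_per_study[2]), 1L)

    # split the study's observations into units of at most 6 pools
    # (fewer when the composition weights silence some pools)
    max_pools <- sum(sp$pool > 0)
    sizes <- integer(0)
    left <- n_obs
    while (left > 0L) {
      size <- min(left, max_pools,
                  sample(1:6, 1L, prob = c(.25, .25, .2, .12, .1, .08)))
      sizes <- c(sizes, size)
      left <- left - size
    }

    t_max <- if (treatment == "clearcut") 110 else 50
    t_med <- if (treatment == "clearcut") 15 else 9
    t_sd <- if (treatment == "clearcut") 1.0 else 0.8

    srows <- vector("list", length(sizes))
    struth <- vector("list", length(sizes))
    for (u in seq_along(sizes)) {
      unit_id <- sprintf("%s_u%02d", study_id, u)
      t <- min(rlnorm(1L, log(t_med), t_sd), t_max)
      pools <- sample(pool_names, sizes[u], replace = FALSE, prob = sp$pool)
      theta_trend <- vapply(pools, function(p) {
        true_theta(cfg, p, treatment, biome, t)
      }, numeric(1))
      theta_obs <- theta_trend + b_s

      mu_c <- vapply(pools, function(p) {
        rng <- cfg$control_mean_range[[p]]
        runif(1L, rng[1], rng[2])
      }, numeric(1))
      mu_t <- mu_c * exp(theta_obs)
      if (cfg$zero_at_origin) {
        zero <- pools == "live_trees" & treatment == "clearcut" & t <= 1
        mu_t[zero] <- 0
      }

      n_reps <- sample(seq(cfg$n_reps_range[1], cfg$n_reps_range[2]),
                       length(pools), replace = TRUE)
      sd_t <- cfg$cv_within * mu_t
      sd_c <- cfg$cv_within * mu_c
      obs_t <- pmax(rnorm(length(pools), mu_t, sd_t / sqrt(n_reps)), 0)
      obs_c <- pmax(rnorm(length(pools), mu_c, sd_c / sqrt(n_reps)), 1e-3)

      se_t <- sd_t / sqrt(n_reps)
      se_c <- sd_c / sqrt(n_reps)
      strip <- runif(length(pools)) < cfg$missing_variance_rate

      depth <- ifelse(pools == "mineral_soil",
                      pmin(pmax(rlnorm(length(pools), log(45), 0.45), 7), 150),
                      NA_real_)

      srows[[u]] <- data.frame(
        study_id = study_id, unit_id = unit_id, pool = pools,
        treatment = treatment, biome = biome,
        reference_type = reference_type, time_since_treatment = t,
        mean_treatment = obs_t, mean_control = obs_c,
        se_treatment = ifelse(strip, NA_real_, se_t),
        se_control = ifelse(strip, NA_real_, se_c),
        n_treatment = ifelse(strip, NA_integer_, n_reps),
        n_control = ifelse(strip, NA_integer_, n_reps),
        sampling_depth = depth,
        stringsAsFactors = FALSE, row.names = NULL)
      struth[[u]] <- data.frame(
        study_id = study_id, unit_id = unit_id, pool = pools,
        treatment = treatment, biome = biome, time_since_treatment = t,
        theta_trend = theta_trend, study_effect = b_s,
        theta_obs = theta_obs, mu_treatment = mu_t, mu_control = mu_c,
        stringsAsFactors = FALSE, row.names = NULL)
    }
    rows[[s]] <- do.call(rbind, srows)
    truth[[s]] <- do.call(rbind, struth)
  }

  df <- do.call(rbind, rows)
  truth <- do.call(rbind, truth)
  rownames(df) <- rownames(truth) <- NULL
  list(dataset = carbon_dataset(df, provenance = "synthetic",
                                on_invalid = "error"),
       truth = truth, config = cfg)
}
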