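# Explicit-loop oracles, kept deliberately free of the algebraic shortcuts
# used by the implementation.

oracle_q <- function(rr, groups, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(rr))
  num <- 0; den <- 0
  for (i in seq_along(rr)) {
    num <- num + weights[i] * rr[i]
    den <- den + weights[i]
  }
  grand <- num / den
  q_total <- 0
  for (i in seq_along(rr)) q_total <- q_total + weights[i] * (rr[i] - grand)^2
  q_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    num_g <- 0; den_g <- 0
    for (i in idx) {
      num_g <- num_g + weights[i] * rr[i]
      den_g <- den_g + weights[i]
    }
    m_g <- num_g / den_g
    for (i in idx) q_within <- q_within + weights[i] * (rr[i] - m_g)^2
  }
  list(q_total = q_total, q_within = q_within,
       q_between = q_total - q_within)
}

oracle_dl_tau2 <- function(rr, se) {
  k <- length(rr)
  w <- numeric(k)
  for (i in seq_len(k)) w[i] <- 1 / se[i]^2
  ybar <- sum(w * rr) / sum(w)
  q <- 0
  for (i in seq_len(k)) q <- q + w[i] * (rr[i] - ybar)^2
  c_const <- sum(w) - sum(w^2) / sum(w)
  max(0, (q - (k - 1)) / c_const)
}

# Small valid observation table with a mix of present/absent optional fields.
random_valid_table <- function(n = 20, seed = NULL) {
  build <- function() {
    pool <- sample(CARBON_POOLS, n, replace = TRUE)
    has_var <- runif(n) < 0.7
    nrep <- ifelse(has_var, sample(3:9, n, replace = TRUE), NA_integer_)
    data.frame(
      study_id = sprintf("S%02d", sample(1:6, n, replace = TRUE)),
      unit_id = sprintf("u%03d", seq_len(n)),
      pool = pool,
      treatment = sample(HARVEST_TREATMENTS, n, replace = TRUE),
      biome = sample(FOREST_BIOMES, n, replace = TRUE),
      reference_type = sample(REFERENCE_TYPES, n, replace = TRUE),
      time_since_treatment = round(runif(n, 0, 100), 3),
      mean_treatment = round(runif(n, 0.5, 150), 4),
      mean_control = round(runif(n, 1, 160), 4),
      se_treatment = ifelse(has_var, round(runif(n, 0.1, 12), 4), NA_real_),
      se_control = ifelse(has_var, round(runif(n, 0.1, 12), 4), NA_real_),
      n_treatment = nrep,
      n_control = nrep,
      sampling_depth = ifelse(pool == "mineral_soil",
                              round(runif(n, 7, 150), 1), NA_real_),
      stringsAsFactors = FALSE)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# Single-stratum generator configuration: constant true effect everywhere.
flat_config <- function(theta, tau = 0, cv = 0, n_studies = 20,
                        obs_per_study = 1, missing_rate = 0, seed = NULL,
                        ...) {
  te <- default_true_effects()
  te$theta <- theta
  synthetic_config(n_studies = n_studies, obs_per_study = obs_per_study,
                   true_effects = te, tau = tau, cv_within = cv,
                   missing_variance_rate = missing_rate,
                   time_model = list(), zero_at_origin = FALSE, seed = seed,
                   ...)
}
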