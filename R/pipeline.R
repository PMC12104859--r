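#' Configuration for a full pipeline run
#'
#' Bundles the knobs of the end-to-end analysis. The ecosystem-subset rule
#' names the pools an experimental unit must have measured for its rows to
#' be summed into a total-ecosystem carbon observation (the pools most
#' contributive to total carbon, by default live trees, mineral soil and
#' coarse woody debris).
#'
#' @param alpha significance level for heterogeneity tests.
#' @param level confidence level for all intervals.
#' @param tau2_method `"REML"` or `"DL"` for weighted pooling.
#' @param n_boot bootstrap replicates for the unweighted track.
#' @param seed integer seed recorded in the bundle and driving every
#'   stochastic stage.
#' @param time_bin_width decade bins by default.
#' @param mode `"unweighted"`, `"weighted"` or `"both"`.
#' @param moderators candidate moderators for the hierarchical partition,
#'   in tie-break priority order.
#' @param ecosystem_pools pools required by the total-carbon subset rule.
#' @param trend_pool pool whose time trend is modelled (default live
#'   trees, per treatment).
#' @param min_k minimum effects per stratum / subgroup.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(alpha = 0.05, level = 0.95,
                            tau2_method = "REML", n_boot = 1000,
                            seed = 1L, time_bin_width = 10,
                            mode = c("unweighted", "weighted", "both"),
                            moderators = c("pool", "treatment", "time_class",
                                           "biome", "reference_type"),
                            ecosystem_pools = c("live_trees", "mineral_soil",
                                                "coarse_woody_debris"),
                            trend_pool = "live_trees",
                            min_k = 3L) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1, level > 0, level < 1, n_boot >= 200)
  structure(list(alpha = alpha, level = level, tau2_method = tau2_method,
                 n_boot = n_boot, seed = as.integer(seed),
                 time_bin_width = time_bin_width, mode = mode,
                 moderators = moderators, ecosystem_pools = ecosystem_pools,
                 trend_pool = trend_pool, min_k = min_k),
            class = "analysis_config")
}

#' Total-ecosystem carbon effect
#'
#' Sums the pool means of every experimental unit that measured at least
#' the required pools (treatment and control arms separately; arm SEs
#' combined as the root sum of squares when every summed pool carries one,
#' otherwise the total observation carries no SE and falls to the
#' unweighted track), computes the total-carbon log response ratio per
#' unit, and estimates the pooled effect. Units missing a required pool
#' are excluded and listed.
#'
#' @param ds a `carbon_dataset`.
#' @param required_pools pools a unit must have measured.
#' @param mode `"unweighted"` (study-level bootstrap CI, default) or
#'   `"weighted"` (inverse-variance pooling of units with full variance
#'   info).
#' @param n_boot,seed,level,tau2_method estimation settings.
#' @return List with `estimate` (rr), `percent`, `lower`, `upper` (percent
#'   scale), `k_units`, `n_studies`, `mean_reference_total` (Mg C ha^-1
#'   across included units), `totals` (per-unit table) and `excluded`
#'   (units failing the rule); `k_units = 0` yields an explicit empty
#'   result.
#' @export
total_ecosystem_effect <- function(ds,
                                   required_pools = c("live_trees",
                                                      "mineral_soil",
                                                      "coarse_woody_debris"),
                                   mode = c("unweighted", "weighted"),
                                   n_boot = 1000, seed = NULL, level = 0.95,
                                   tau2_method = "REML") {
  mode <- match.arg(mode)
  df <- as.data.frame(ds)
  key <- paste(df$study_id, df$unit_id, df$treatment, df$time_since_treatment,
               sep = "\r")
  pieces <- split(df, key)

  totals <- list(); excluded <- list()
  for (piece in pieces) {
    have <- unique(piece$pool)
    info <- data.frame(study_id = piece$study_id[1L],
                       unit_id = piece$unit_id[1L],
                       treatment = piece$treatment[1L],
                       biome = piece$biome[1L],
                       time_since_treatment = piece$time_since_treatment[1L],
                       stringsAsFactors = FALSE)
    if (!all(required_pools %in% have)) {
      info$missing <- paste(setdiff(required_pools, have), collapse = ";")
      excluded[[length(excluded) + 1L]] <- info
      next
    }
    info$total_treatment <- sum(piece$mean_treatment)
    info$total_control <- sum(piece$mean_control)
    all_se <- !anyNA(piece$se_treatment) && !anyNA(piece$se_control)
    info$se_treatment <- if (all_se) sqrt(sum(piece$se_treatment^2)) else NA_real_
    info$se_control <- if (all_se) sqrt(sum(piece$se_control^2)) else NA_real_
    totals[[length(totals) + 1L]] <- info
  }

  empty <- list(estimate = NA_real_, percent = NA_real_, lower = NA_real_,
                upper = NA_real_, k_units = 0L, n_studies = 0L,
                mean_reference_total = NA_real_,
                totals = NULL,
                excluded = if (length(excluded)) do.call(rbind, excluded) else NULL)
  if (length(totals) == 0L) return(empty)
  totals <- do.call(rbind, totals)
  rownames(totals) <- NULL

  es <- compute_rr(totals$total_treatment, totals$total_control)
  totals$rr <- es$rr
  totals$defined <- es$defined
  have_se <- !is.na(totals$se_treatment) & totals$defined
  totals$se_rr <- NA_real_
  if (any(have_se)) {
    totals$se_rr[have_se] <- compute_se_rr(
      totals$total_treatment[have_se], totals$se_treatment[have_se],
      totals$total_control[have_se], totals$se_control[have_se])
  }

  use <- totals[totals$defined & !is.na(totals$rr), , drop = FALSE]
  if (mode == "weighted") {
    use <- use[!is.na(use$se_rr) & use$se_rr > 0, , drop = FALSE]
  }
  if (nrow(use) < 2L) {
    empty$totals <- totals
    return(empty)
  }
  if (mode == "unweighted") {
    unit <- if (length(unique(use$study_id)) >= 2L) "study" else "observation"
    bs <- bootstrap_ci(use, function(d) mean(d$rr), n_boot = n_boot,
                       seed = seed, unit = unit, level = level)
    est <- bs$point; lo <- bs$lower; hi <- bs$upper
  } else {
    fit <- pool_random_effects(use$rr, use$se_rr, method = tau2_method,
                               level = level)
    est <- fit$coefficients[[1L]]
    lo <- fit$ci[1L, "lower"]; hi <- fit$ci[1L, "upper"]
  }

  list(estimate = unname(est),
       percent = percent_difference(unname(est)),
       lower = percent_difference(unname(lo)),
       upper = percent_difference(unname(hi)),
       k_units = nrow(use),
       n_studies = length(unique(use$study_id)),
       mean_reference_total = mean(use$total_control),
       totals = totals,
       excluded = if (length(excluded)) do.call(rbind, excluded) else NULL)
}

#' Run the full meta-analytic pipeline
#'
#' Orchestrates: dataset summary -> effect sizes -> moderator
#' heterogeneity table and hierarchical partition -> per-stratum effect
#' estimates -> binned time profiles -> time-trend model selection for the
#' focal pool -> total-ecosystem carbon effect. Deterministic under the
#' configured seed. Stage failures mark the bundle partial with per-stage
#' diagnostics instead of truncating silently.
#'
#' @param ds a `carbon_dataset` (e.g. from [read_dataset()] or
#'   [generate_dataset()]).
#' @param cfg an [analysis_config()].
#' @param out_dir optional directory; when given, each table is written as
#'   CSV alongside a `config.csv` echo of the settings (seed included).
#' @return A `pipeline_result` list with elements `summary`,
#'   `heterogeneity`, `partition`, `strata`, `profiles`, `trends`,
#'   `ecosystem`, `errors` (named stage diagnostics, empty when complete)
#'   and `config`.
#' @export
run_pipeline <- function(ds, cfg = analysis_config(), out_dir = NULL) {
  stopifnot(inherits(ds, "carbon_dataset"), inherits(cfg, "analysis_config"))
  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  weighted <- cfg$mode %in% c("weighted", "both")
  unweighted <- cfg$mode %in% c("unweighted", "both")

  summary_tab <- stage("summary", summarize_dataset(ds))
  effects <- stage("effects", add_effect_sizes(ds, cfg$time_bin_width))
  if (is.null(effects)) {
    return(structure(list(summary = summary_tab, errors = errors,
                          config = cfg, partial = TRUE),
                     class = "pipeline_result"))
  }

  het <- stage("heterogeneity", heterogeneity_table(
    effects, moderators = cfg$moderators, split_by = "pool",
    weighted = FALSE, min_group = cfg$min_k))
  partition <- stage("partition", hierarchical_partition(
    effects, candidates = cfg$moderators, alpha = cfg$alpha,
    weighted = FALSE, min_group = cfg$min_k))

  strata <- stage("strata", {
    out <- NULL
    if (unweighted) {
      out <- estimate_stratum_effects(effects, mode = "unweighted",
                                      n_boot = cfg$n_boot, seed = cfg$seed,
                                      min_k = cfg$min_k, level = cfg$level)
      out$mode <- "unweighted"
    }
    if (weighted) {
      w <- estimate_stratum_effects(effects, mode = "weighted",
                                    min_k = cfg$min_k,
                                    tau2_method = cfg$tau2_method,
                                    level = cfg$level)
      w$mode <- "weighted"
      out <- rbind(out, w)
    }
    out
  })

  profiles <- stage("profiles", binned_time_profile(
    effects, n_boot = cfg$n_boot, seed = cfg$seed + 1000L,
    min_k = cfg$min_k, level = cfg$level))

  trends <- stage("trends", {
    lapply(setNames(nm = unique(effects$treatment)), function(tr) {
      sub <- effects[effects$pool == cfg$trend_pool &
                       effects$treatment == tr, , drop = FALSE]
      use_weights <- weighted && sum(!is.na(sub$se_rr) & sub$se_rr > 0) >= 10
      tryCatch(select_trend_model(sub, weighted = use_weights,
                                  alpha = cfg$alpha),
               error = function(e) conditionMessage(e))
    })
  })

  ecosystem <- stage("ecosystem", total_ecosystem_effect(
    ds, required_pools = cfg$ecosystem_pools,
    mode = if (weighted && !unweighted) "weighted" else "unweighted",
    n_boot = cfg$n_boot, seed = cfg$seed + 2000L, level = cfg$level,
    tau2_method = cfg$tau2_method))

  out <- structure(list(summary = summary_tab, heterogeneity = het,
                        partition = partition, strata = strata,
                        profiles = profiles, trends = trends,
                        ecosystem = ecosystem, errors = errors,
                        config = cfg, partial = length(errors) > 0L),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(out, out_dir)
  out
}

write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df) && is.data.frame(df)) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
  }
  wr(res$heterogeneity, "heterogeneity.csv")
  wr(res$strata, "stratum_effects.csv")
  wr(res$profiles, "time_profiles.csv")
  cfg <- res$config
  wr(data.frame(key = names(unlist(cfg, use.names = TRUE)),
                value = as.character(unlist(cfg))), "config.csv")
  if (!is.null(res$ecosystem) && !is.null(res$ecosystem$totals)) {
    wr(res$ecosystem$totals, "ecosystem_totals.csv")
  }
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result",
      if (isTRUE(x$partial)) "(PARTIAL: some stages failed)" else "(complete)",
      "\n")
  if (length(x$errors) > 0L) {
    for (nm in names(x$errors)) cat(sprintf("  stage %s: %s\n", nm, x$errors[[nm]]))
  }
  if (!is.null(x$summary)) {
    cat(sprintf("  %d observations from %d studies\n",
                x$summary$n_obs, x$summary$n_studies))
  }
  if (!is.null(x$ecosystem) && x$ecosystem$k_units > 0L) {
    cat(sprintf("  total ecosystem C effect: %.1f%% [%.1f, %.1f] over %d units\n",
                x$ecosystem$percent, x$ecosystem$lower, x$ecosystem$upper,
                x$ecosystem$k_units))
  }
  invisible(x)
}
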