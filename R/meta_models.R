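#' Random-effects pooling of log response ratios
#'
#' Intercept-only random-effects meta-analysis: observed effects
#' `y_i ~ N(mu, se_i^2 + tau^2)`, with the between-study variance `tau^2`
#' estimated either by the closed-form DerSimonian-Laird moment estimator
#' or by restricted maximum likelihood (profile REML, solved by
#' golden-section search to tolerance 1e-12 on `tau^2`). The pooled mean
#' uses weights `1/(se_i^2 + tau^2)` with a Wald confidence interval.
#'
#' @param rr log response ratios (length >= 2).
#' @param se their standard errors, all `> 0`.
#' @param method `"REML"` (default) or `"DL"`.
#' @param level confidence level (default 0.95).
#' @return A `meta_fit` with `coefficients` (the pooled mean), `tau2`,
#'   `ci`, `loglik` (ML log-likelihood at the estimates), `aic`,
#'   `n_effects`, `q` (the fixed-effects Q statistic) and `mode =
#'   "weighted"`.
#' @export
pool_random_effects <- function(rr, se, method = c("REML", "DL"),
                                level = 0.95) {
  method <- match.arg(method)
  keep <- !is.na(rr) & !is.na(se)
  rr <- rr[keep]; se <- se[keep]
  k <- length(rr)
  if (k < 2L) stop("need >= 2 effects with standard errors", call. = FALSE)
  if (all(se == 0)) {
    stop("degenerate weights: all standard errors are zero", call. = FALSE)
  }
  if (any(se <= 0)) stop("all standard errors must be > 0", call. = FALSE)

  w_fe <- 1 / se^2
  ybar_fe <- sum(w_fe * rr) / sum(w_fe)
  q_fe <- sum(w_fe * (rr - ybar_fe)^2)

  tau2_dl <- max(0, (q_fe - (k - 1)) / (sum(w_fe) - sum(w_fe^2) / sum(w_fe)))
  tau2 <- if (method == "DL") tau2_dl else {
    tryCatch(reml_tau2(rr, se), error = function(e) {
      warning("REML estimation failed (", conditionMessage(e),
              "); falling back to DerSimonian-Laird", call. = FALSE)
      tau2_dl
    })
  }

  w <- 1 / (se^2 + tau2)
  mu <- sum(w * rr) / sum(w)
  se_mu <- sqrt(1 / sum(w))
  z <- qnorm(1 - (1 - level) / 2)
  v <- se^2 + tau2
  loglik <- -0.5 * sum(log(2 * pi * v) + (rr - mu)^2 / v)

  structure(list(
    coefficients = c(intercept = mu),
    se_coefficients = c(intercept = se_mu),
    tau2 = tau2,
    random_terms = c(tau2 = tau2),
    ci = matrix(c(mu - z * se_mu, mu + z * se_mu), nrow = 1,
                dimnames = list("intercept", c("lower", "upper"))),
    ci_level = level,
    loglik = loglik,
    aic = -2 * loglik + 4,
    n_effects = k,
    q = q_fe,
    mode = "weighted",
    method = method
  ), class = "meta_fit")
}

# Profile restricted likelihood in tau^2 for the intercept-only model.
reml_tau2 <- function(rr, se, upper = NULL) {
  if (is.null(upper)) upper <- max(10 * var(rr), max(se^2), 1e-3)
  neg_rll <- function(tau2) {
    v <- se^2 + tau2
    w <- 1 / v
    mu <- sum(w * rr) / sum(w)
    0.5 * (sum(log(v)) + log(sum(w)) + sum(w * (rr - mu)^2))
  }
  opt <- optimize(neg_rll, interval = c(0, upper), tol = 1e-12)
  # guard against an interior optimum worse than the boundary at zero
  if (neg_rll(0) <= opt$objective) 0 else opt$minimum
}

#' Mixed-effects meta-regression of log response ratios
#'
#' The two parallel tracks of the analysis. The weighted track is an
#' inverse-variance mixed-effects meta-regression (via
#' [metafor::rma.mv()]): sampling variances `se_rr^2` enter as known, the
#' moderators in `fixed` are fixed effects, and each factor in `random`
#' contributes a random intercept. The unweighted track fits the same
#' fixed/random structure as a linear mixed model on `rr` with unit
#' residual weighting (via [lme4::lmer()]), which admits the rows lacking
#' variance information; study identity is included as an additional
#' random intercept by default on this track because multiple observations
#' per study violate independence.
#'
#' @param data data frame from [add_effect_sizes()] (needs `rr`, and
#'   `se_rr` for the weighted track; undefined effects are excluded).
#' @param fixed one-sided formula of fixed-effect moderators, e.g.
#'   `~ treatment`. `~ 1` fits a pooled intercept.
#' @param random character vector of grouping factors entering as random
#'   intercepts (default biome and decade time class). Factors with a
#'   single observed level are dropped with a warning.
#' @param mode `"weighted"` or `"unweighted"`.
#' @param include_study add a `study_id` random intercept; default `TRUE`
#'   for the unweighted track and `FALSE` for the weighted one.
#' @param tau2_method variance-component estimator for the weighted track,
#'   `"REML"` (default) or `"ML"`.
#' @param level confidence level for the Wald intervals.
#' @return A `meta_fit`; `random_terms` holds the estimated variance
#'   components and `fit` the underlying fitted object.
#' @export
fit_meta_regression <- function(data, fixed = ~treatment,
                                random = c("biome", "time_class"),
                                mode = c("weighted", "unweighted"),
                                include_study = NULL,
                                tau2_method = "REML", level = 0.95) {
  mode <- match.arg(mode)
  stopifnot(inherits(fixed, "formula"))
  if (is.null(include_study)) include_study <- (mode == "unweighted")
  data <- data[!is.na(data$rr), , drop = FALSE]

  random <- unique(c(random, if (include_study) "study_id"))
  for (f in random) {
    if (!f %in% names(data)) {
      stop("random factor not found in data: ", f, call. = FALSE)
    }
  }
  single <- random[vapply(random, function(f) {
    length(unique(as.character(data[[f]]))) < 2L
  }, logical(1))]
  if (length(single) > 0L) {
    warning("dropping single-level random factor(s): ",
            paste(single, collapse = ", "), call. = FALSE)
    random <- setdiff(random, single)
  }

  mm <- stats::model.matrix(fixed, data = data)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1L):ncol(mm)]]
    stop("rank-deficient fixed-effect design; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  intercept_only <- length(attr(stats::terms(fixed), "term.labels")) == 0L

  if (mode == "weighted") {
    n_missing <- sum(is.na(data$se_rr) | data$se_rr <= 0)
    if (n_missing > 0L) {
      warning(sprintf(
        "weighted track: excluding %d row(s) without usable se_rr", n_missing),
        call. = FALSE)
      data <- data[!is.na(data$se_rr) & data$se_rr > 0, , drop = FALSE]
    }
    if (length(random) == 0L && intercept_only) {
      return(pool_random_effects(data$rr, data$se_rr,
                                 method = if (tau2_method == "REML") "REML" else "DL",
                                 level = level))
    }
    rlist <- lapply(random, function(f) as.formula(paste0("~ 1 | ", f)))
    fit <- metafor::rma.mv(yi = rr, V = se_rr^2, mods = fixed,
                           random = if (length(rlist)) rlist else NULL,
                           data = data, method = tau2_method,
                           level = level * 100, sparse = TRUE)
    comp <- if (length(fit$sigma2)) setNames(fit$sigma2, fit$s.names) else numeric()
    out <- list(
      coefficients = setNames(as.numeric(fit$beta), rownames(fit$beta)),
      se_coefficients = setNames(fit$se, rownames(fit$beta)),
      tau2 = sum(comp),
      random_terms = comp,
      ci = matrix(c(fit$ci.lb, fit$ci.ub), ncol = 2,
                  dimnames = list(rownames(fit$beta), c("lower", "upper"))),
      ci_level = level, loglik = as.numeric(logLik(fit)), aic = AIC(fit),
      n_effects = fit$k, mode = "weighted", method = tau2_method, fit = fit)
  } else {
    if (length(random) == 0L) {
      stop("unweighted track needs at least one random grouping factor; ",
           "use lm()/pool on rr directly for a fully fixed model",
           call. = FALSE)
    }
    rhs <- paste(c(deparse(fixed[[2]]),
                   paste0("(1 | ", random, ")")), collapse = " + ")
    form <- as.formula(paste("rr ~", rhs))
    fit <- lme4::lmer(form, data = data, REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    comp <- setNames(vc$vcov[vc$grp != "Residual"], vc$grp[vc$grp != "Residual"])
    beta <- lme4::fixef(fit)
    se_beta <- sqrt(diag(as.matrix(vcov(fit))))
    z <- qnorm(1 - (1 - level) / 2)
    out <- list(
      coefficients = beta, se_coefficients = se_beta,
      tau2 = sum(comp), random_terms = comp,
      ci = cbind(lower = beta - z * se_beta, upper = beta + z * se_beta),
      ci_level = level, loglik = as.numeric(logLik(fit)), aic = AIC(fit),
      n_effects = stats::nobs(fit), mode = "unweighted", method = "REML",
      fit = fit)
  }
  structure(out, class = "meta_fit")
}

#' @export
print.meta_fit <- function(x, ...) {
  cat(sprintf("Meta-analytic fit (%s track, %s; k = %d)\n",
              x$mode, x$method, x$n_effects))
  est <- data.frame(estimate = x$coefficients, se = x$se_coefficients,
                    lower = x$ci[, "lower"], upper = x$ci[, "upper"])
  print(round(est, 4))
  cat(sprintf("tau^2 (sum of components) = %.4f;  logLik = %.2f, AIC = %.2f\n",
              x$tau2, x$loglik, x$aic))
  invisible(x)
}

#' Nonparametric case bootstrap confidence interval
#'
#' Resamples cases with replacement at the declared unit — whole studies
#' (the default, preserving within-study correlation) or single
#' observations — recomputes `statistic` on every replicate and returns
#' percentile confidence bounds. Replicates on which `statistic` errors
#' are dropped and counted. Deterministic under a fixed `seed`.
#'
#' @param data data frame; study-level resampling requires a `study_id`
#'   column.
#' @param statistic function of a data frame returning a numeric scalar or
#'   named vector.
#' @param n_boot number of replicates (>= 200).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param unit `"study"` or `"observation"`.
#' @param level confidence level (default 0.95).
#' @return A `bootstrap_result` with `point`, `lower`, `upper`, `n_boot`,
#'   `n_failed`, `seed`, `unit` and the replicate matrix.
#' @export
bootstrap_ci <- function(data, statistic, n_boot = 1000, seed = NULL,
                         unit = c("study", "observation"), level = 0.95) {
  unit <- match.arg(unit)
  stopifnot(is.function(statistic), n_boot >= 200)
  point <- statistic(data)
  p <- length(point)

  clusters <- if (unit == "study") {
    if (!"study_id" %in% names(data)) {
      stop("study-level resampling requires a study_id column", call. = FALSE)
    }
    split(seq_len(nrow(data)), as.character(data$study_id))
  } else {
    as.list(seq_len(nrow(data)))
  }
  kc <- length(clusters)

  run <- function() {
    reps <- matrix(NA_real_, nrow = n_boot, ncol = p)
    for (b in seq_len(n_boot)) {
      rows <- unlist(clusters[sample.int(kc, kc, replace = TRUE)],
                     use.names = FALSE)
      reps[b, ] <- tryCatch(
        as.numeric(statistic(data[rows, , drop = FALSE])),
        error = function(e) rep(NA_real_, p))
    }
    reps
  }
  reps <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  failed <- apply(reps, 1L, anyNA)
  n_failed <- sum(failed)
  if (n_failed == n_boot) stop("all bootstrap replicates failed", call. = FALSE)
  if (n_failed > 0.1 * n_boot) {
    warning(sprintf("%d of %d bootstrap replicates failed", n_failed, n_boot),
            call. = FALSE)
  }
  ok <- reps[!failed, , drop = FALSE]
  alpha <- (1 - level) / 2
  lower <- apply(ok, 2L, quantile, probs = alpha, names = FALSE)
  upper <- apply(ok, 2L, quantile, probs = 1 - alpha, names = FALSE)
  names(lower) <- names(upper) <- names(point)
  if (any(lower > point | upper < point)) {
    warning("percentile CI does not bracket the point estimate; ",
            "heavy skew in the bootstrap distribution", call. = FALSE)
  }
  structure(list(point = point, lower = lower, upper = upper,
                 n_boot = n_boot, n_failed = n_failed, seed = seed,
                 unit = unit, level = level, replicates = ok),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap percentile CI (%d replicates, %s resampling%s)\n",
              x$n_boot, x$unit,
              if (x$n_failed) sprintf(", %d failed", x$n_failed) else ""))
  print(round(data.frame(point = x$point, lower = x$lower, upper = x$upper), 4))
  invisible(x)
}

#' Per-stratum effect estimates with confidence intervals
#'
#' Estimates the mean log response ratio within each stratum (pool x
#' treatment x biome by default), back-transformed to the percent
#' difference display scale. The unweighted track uses the stratum mean
#' with a study-level case-bootstrap percentile CI; the weighted track
#' pools the rows that carry variance information with
#' [pool_random_effects()] and a Wald CI. Strata whose CI excludes zero
#' are flagged as significantly different from the reference stands.
#' Undefined effects (zero treatment mean) are excluded from estimation
#' and reported in `n_undefined`.
#'
#' @param data data frame from [add_effect_sizes()].
#' @param strata character vector of stratifying columns.
#' @param mode `"unweighted"` (default, full data) or `"weighted"`.
#' @param n_boot,seed bootstrap settings for the unweighted track; each
#'   stratum uses a sub-seed derived deterministically from `seed`.
#' @param min_k strata with fewer usable effects are reported as
#'   insufficient, not fitted (default 3).
#' @param tau2_method passed to [pool_random_effects()].
#' @param level confidence level.
#' @return Data frame with the stratum labels, `k`, `n_undefined`,
#'   `est_rr`, `percent`, `lower`, `upper` (percent scale),
#'   `significant`, and `status` (`"ok"` or `"insufficient"`).
#' @export
estimate_stratum_effects <- function(data,
                                     strata = c("pool", "treatment", "biome"),
                                     mode = c("unweighted", "weighted"),
                                     n_boot = 1000, seed = NULL,
                                     min_k = 3L, tau2_method = "REML",
                                     level = 0.95) {
  mode <- match.arg(mode)
  stopifnot(all(strata %in% names(data)))
  key <- interaction(lapply(strata, function(s) data[[s]]), drop = TRUE,
                     sep = "\r")
  pieces <- split(data, key)

  rows <- lapply(seq_along(pieces), function(i) {
    df <- pieces[[i]]
    labels <- as.data.frame(df[1L, strata, drop = FALSE], row.names = NULL)
    n_undef <- sum(!df$defined)
    use <- df[df$defined & !is.na(df$rr), , drop = FALSE]
    if (mode == "weighted") {
      use <- use[!is.na(use$se_rr) & use$se_rr > 0, , drop = FALSE]
    }
    base <- cbind(labels, k = nrow(use), n_undefined = n_undef,
                  stringsAsFactors = FALSE)
    if (nrow(use) < min_k) {
      return(cbind(base, est_rr = NA_real_, percent = NA_real_,
                   lower = NA_real_, upper = NA_real_, significant = NA,
                   status = "insufficient", stringsAsFactors = FALSE))
    }
    if (mode == "unweighted") {
      sub_seed <- if (is.null(seed)) NULL else (seed + i) %% .Machine$integer.max
      unit <- if (length(unique(use$study_id)) >= 2L) "study" else "observation"
      bs <- bootstrap_ci(use, function(d) mean(d$rr), n_boot = n_boot,
                         seed = sub_seed, unit = unit, level = level)
      est <- bs$point; lo <- bs$lower; hi <- bs$upper
    } else {
      fit <- pool_random_effects(use$rr, use$se_rr, method = tau2_method,
                                 level = level)
      est <- fit$coefficients[[1L]]
      lo <- fit$ci[1L, "lower"]; hi <- fit$ci[1L, "upper"]
    }
    cbind(base, est_rr = est,
          percent = percent_difference(est),
          lower = percent_difference(lo),
          upper = percent_difference(hi),
          significant = (lo > 0 | hi < 0),
          status = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
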