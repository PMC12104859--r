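#' Fit a time-since-treatment trend to effect sizes
#'
#' Regresses the log response ratio on continuous time since treatment
#' under one of three families: `"linear"` (affine in t), `"cubic"` (a
#' single cubic polynomial) or `"spline"` (a natural cubic spline with
#' interior knots at the 25/50/75% time quantiles, fitted by polynomial
#' regression). The weighted mode uses inverse-variance weights
#' `1/se_rr^2`. Fitting is on the log scale by default so that
#' back-transformed predictions can never cross -100%; `response =
#' "percent"` refits on the display scale as a sensitivity mode (it admits
#' the -100% zero-treatment rows that the log scale must exclude).
#'
#' @param data data frame from [add_effect_sizes()] with
#'   `time_since_treatment`; undefined effects are excluded on the log
#'   scale.
#' @param family `"linear"`, `"cubic"` or `"spline"`.
#' @param weighted use `1/se_rr^2` weights (rows lacking `se_rr` are
#'   excluded).
#' @param knots optional interior knot positions for the spline family;
#'   must lie inside the observed time range.
#' @param response `"rr"` (default) or `"percent"`.
#' @return A `trend_fit`: `family`, `coefficients`, `aic`, `loglik`,
#'   `weighted`, `t_range`, `n`, the underlying `lm` fit, and
#'   `predict_percent(t)` evaluating the back-transformed curve.
#' @export
fit_time_trend <- function(data, family = c("linear", "cubic", "spline"),
                           weighted = FALSE, knots = NULL,
                           response = c("rr", "percent")) {
  family <- match.arg(family)
  response <- match.arg(response)
  d <- trend_frame(data, weighted, response)
  if (nrow(d) < 5L) stop("need >= 5 effects with finite time", call. = FALSE)
  fit <- trend_lm(d, family, knots)
  n_par <- length(coef(fit))
  if (nrow(d) <= n_par) {
    stop("fewer points than model parameters", call. = FALSE)
  }
  make_trend_fit(fit, family, d, weighted, response)
}

# shared assembly of the modelling frame: columns y, t, w
trend_frame <- function(data, weighted, response) {
  stopifnot(all(c("time_since_treatment", "rr") %in% names(data)))
  if (response == "rr") {
    d <- data[data$defined %||% TRUE & !is.na(data$rr), , drop = FALSE]
    y <- d$rr
  } else {
    d <- data
    y <- d$percent_diff
  }
  out <- data.frame(y = y, t = d$time_since_treatment)
  if (weighted) {
    if (!"se_rr" %in% names(d)) {
      stop("weighted trend fitting requires se_rr", call. = FALSE)
    }
    out$w <- 1 / d$se_rr^2
    out <- out[!is.na(out$w) & out$w > 0, , drop = FALSE]
  } else {
    out$w <- 1
  }
  out[is.finite(out$t) & !is.na(out$y), , drop = FALSE]
}

trend_lm <- function(d, family, knots = NULL) {
  if (family == "spline") {
    kn <- knots %||% unname(quantile(d$t, c(.25, .5, .75)))
    if (any(kn <= min(d$t)) || any(kn >= max(d$t))) {
      stop("spline knots must lie strictly inside the time range",
           call. = FALSE)
    }
    form <- y ~ splines::ns(t, knots = kn)
    environment(form) <- list2env(list(kn = kn), parent = environment())
  } else {
    form <- switch(family,
                   intercept = y ~ 1,
                   linear = y ~ t,
                   cubic = y ~ t + I(t^2) + I(t^3))
  }
  lm(form, data = d, weights = w)
}

make_trend_fit <- function(fit, family, d, weighted, response) {
  t_range <- range(d$t)
  predict_percent <- function(t) {
    t <- pmin(pmax(t, 0), t_range[2])  # no extrapolation beyond the data
    yhat <- unname(predict(fit, newdata = data.frame(t = t)))
    if (response == "rr") percent_difference(yhat) else pmax(yhat, -100)
  }
  structure(list(family = family, coefficients = coef(fit),
                 aic = AIC(fit), loglik = as.numeric(logLik(fit)),
                 weighted = weighted, response = response,
                 t_range = t_range, n = nrow(d), fit = fit,
                 predict_percent = predict_percent),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Time-trend fit: %s family (%s, %s scale), n = %d, AIC = %.2f\n",
              x$family, if (x$weighted) "weighted" else "unweighted",
              x$response, x$n, x$aic))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' AIC selection among candidate trend families
#'
#' Fits every candidate family, keeps those whose defining terms are
#' significant (the linear slope against the intercept-only model; the
#' curvature terms of the cubic and spline families against the nested
#' linear model — F tests at `alpha`), and returns the survivor with the
#' lowest AIC together with the full comparison table. When no candidate
#' survives, the intercept-only fit is returned with a diagnostic.
#'
#' @inheritParams fit_time_trend
#' @param families candidate families (>= 2).
#' @param alpha significance level of the term tests.
#' @return A `trend_selection`: `winner` (a `trend_fit`), `table` (family,
#'   AIC, p-value, significance, selection flag) and `note`.
#' @export
select_trend_model <- function(data, families = c("linear", "cubic", "spline"),
                               weighted = FALSE, alpha = 0.05, knots = NULL,
                               response = c("rr", "percent")) {
  response <- match.arg(response)
  stopifnot(length(families) >= 2L,
            all(families %in% c("linear", "cubic", "spline")))
  d <- trend_frame(data, weighted, response)
  if (nrow(d) < 6L) stop("need >= 6 effects to compare trend families",
                         call. = FALSE)

  m0 <- trend_lm(d, "intercept")
  mlin <- trend_lm(d, "linear")
  fits <- list(); pvals <- c(); errs <- c()
  for (fam in families) {
    res <- tryCatch({
      m <- if (fam == "linear") mlin else trend_lm(d, fam, knots)
      ref <- if (fam == "linear") m0 else mlin
      p <- anova(ref, m)[2L, "Pr(>F)"]
      list(fit = m, p = p)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs[fam] <- conditionMessage(res)
    } else {
      fits[[fam]] <- res$fit
      pvals[fam] <- res$p
    }
  }
  if (length(fits) == 0L) {
    stop("all candidate fits failed: ",
         paste(sprintf("%s: %s", names(errs), errs), collapse = "; "),
         call. = FALSE)
  }

  aics <- vapply(fits, AIC, numeric(1))
  sig <- pvals < alpha
  sig[is.na(sig)] <- FALSE
  if (any(sig)) {
    winner_name <- names(fits)[sig][which.min(aics[sig])]
    winner <- make_trend_fit(fits[[winner_name]], winner_name, d, weighted,
                             response)
    note <- NA_character_
  } else {
    winner_name <- "intercept"
    winner <- make_trend_fit(m0, "intercept", d, weighted, response)
    note <- "no candidate family significant; intercept-only model returned"
  }
  table <- data.frame(family = names(fits), aic = unname(aics),
                      p_value = unname(pvals), significant = unname(sig),
                      selected = names(fits) == winner_name,
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(winner = winner, table = table, note = note, alpha = alpha),
            class = "trend_selection")
}

#' @export
print.trend_selection <- function(x, ...) {
  cat("Trend model selection (alpha =", x$alpha, ")\n")
  print(transform(x$table, aic = round(aic, 2), p_value = signif(p_value, 3)),
        row.names = FALSE)
  if (!is.na(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Crossing time of two fitted trend curves
#'
#' Root of the difference between two back-transformed trend predictions —
#' e.g., the year at which the clearcut recovery curve catches up with the
#' partial-cut one.
#'
#' @param fit_a,fit_b `trend_fit` objects.
#' @param interval search interval in years.
#' @return Crossing time in years, or `NA` when the curves do not cross in
#'   the interval.
#' @export
trend_crossing_time <- function(fit_a, fit_b, interval = c(5, 60)) {
  f <- function(t) fit_a$predict_percent(t) - fit_b$predict_percent(t)
  out <- tryCatch(uniroot(f, interval = interval)$root,
                  error = function(e) NA_real_)
  out
}

#' Binned time profiles of percent difference
#'
#' Per treatment x pool x time bin: the unweighted mean effect with a
#' study-level case-bootstrap percentile CI, back-transformed to percent
#' difference. Zero-treatment-mean observations enter the display layer
#' only: bins whose usable effects are all undefined are shown at -100%
#' (`status = "all_zero"`), and every bin reports its count of such rows.
#' Empty bins are reported empty, never interpolated.
#'
#' @param data data frame from [add_effect_sizes()].
#' @param breaks bin break points in years (default decades covering the
#'   data).
#' @param n_boot,seed,level bootstrap settings (sub-seeds are derived
#'   deterministically from `seed`).
#' @param min_k minimum usable effects per bin (default 3).
#' @return Data frame with `treatment`, `pool`, `bin`, `k`, `n_undefined`,
#'   `est_rr`, `percent`, `lower`, `upper`, `status`.
#' @export
binned_time_profile <- function(data, breaks = NULL, n_boot = 500,
                                seed = NULL, min_k = 3L, level = 0.95) {
  if (is.null(breaks)) {
    top <- ceiling(max(data$time_since_treatment, 10) / 10) * 10 + 10
    breaks <- seq(0, top, by = 10)
  }
  if (nrow(data) > 0L &&
      (min(data$time_since_treatment, na.rm = TRUE) < min(breaks) ||
       max(data$time_since_treatment, na.rm = TRUE) >= max(breaks))) {
    stop("breaks must cover the observed time range", call. = FALSE)
  }
  data$.bin <- cut(data$time_since_treatment, breaks = breaks, right = FALSE)

  combos <- expand.grid(treatment = unique(data$treatment),
                        pool = unique(data$pool),
                        bin = levels(data$.bin),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cb <- combos[i, ]
    df <- data[data$treatment == cb$treatment & data$pool == cb$pool &
                 as.character(data$.bin) == cb$bin, , drop = FALSE]
    base <- data.frame(treatment = cb$treatment, pool = cb$pool,
                       bin = cb$bin, k = 0L, n_undefined = 0L,
                       est_rr = NA_real_, percent = NA_real_,
                       lower = NA_real_, upper = NA_real_,
                       status = "empty", stringsAsFactors = FALSE)
    if (nrow(df) == 0L) return(base)
    use <- df[df$defined & !is.na(df$rr), , drop = FALSE]
    base$k <- nrow(use)
    base$n_undefined <- sum(!df$defined)
    if (nrow(use) == 0L && base$n_undefined > 0L) {
      base$percent <- -100
      base$status <- "all_zero"
      return(base)
    }
    if (nrow(use) < min_k) {
      base$status <- "insufficient"
      return(base)
    }
    sub_seed <- if (is.null(seed)) NULL else (seed + i) %% .Machine$integer.max
    unit <- if (length(unique(use$study_id)) >= 2L) "study" else "observation"
    bs <- bootstrap_ci(use, function(d) mean(d$rr), n_boot = n_boot,
                       seed = sub_seed, unit = unit, level = level)
    base$est_rr <- bs$point
    base$percent <- percent_difference(bs$point)
    base$lower <- percent_difference(bs$lower)
    base$upper <- percent_difference(bs$upper)
    base$status <- "ok"
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
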