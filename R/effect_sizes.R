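#' Log response ratio of a treatment/control comparison
#'
#' The effect size of the meta-analysis: `RR = ln(X_T / X_C)` for treated
#' mean `X_T` and reference mean `X_C`. A harvested stand can carry zero
#' carbon in a pool (e.g., live trees immediately after clearcutting); the
#' log is then undefined and the observation is flagged `defined = FALSE`
#' with its display value fixed at -100% change. Undefined observations are
#' excluded from all log-scale model fitting.
#'
#' @param mean_treatment treated-stand mean, Mg C ha^-1, `>= 0`. Vectorized.
#' @param mean_control reference-stand mean, Mg C ha^-1, `> 0`. Vectorized.
#' @return Data frame with columns `rr`, `percent_diff` and `defined`.
#' @examples
#' compute_rr(50, 100)   # rr = log(0.5)
#' compute_rr(0, 100)    # undefined, percent_diff = -100
#' @export
compute_rr <- function(mean_treatment, mean_control) {
  if (any(is.na(mean_control) | mean_control <= 0)) {
    stop("mean_control must be > 0 (log response-ratio denominator)",
         call. = FALSE)
  }
  if (any(is.na(mean_treatment) | mean_treatment < 0)) {
    stop("mean_treatment must be >= 0", call. = FALSE)
  }
  defined <- mean_treatment > 0
  rr <- ifelse(defined, log(mean_treatment / mean_control), NA_real_)
  data.frame(rr = rr,
             percent_diff = ifelse(defined, percent_difference(rr), -100),
             defined = defined)
}

#' Delta-method standard error of the log response ratio
#'
#' `SE(RR) = sqrt(SE_T^2 / X_T^2 + SE_C^2 / X_C^2)`: each arm contributes
#' the square of its coefficient-of-variation-of-the-mean, so the result
#' depends on the arms only through their relative errors (scale
#' invariance).
#'
#' @param mean_treatment,mean_control arm means, both `> 0`. Vectorized.
#' @param se_treatment,se_control standard errors of the arm means, `>= 0`.
#' @return Numeric vector of standard errors (dimensionless).
#' @export
compute_se_rr <- function(mean_treatment, se_treatment,
                          mean_control, se_control) {
  ok_means <- !is.na(mean_treatment) & !is.na(mean_control) &
    mean_treatment > 0 & mean_control > 0
  if (any(!ok_means)) {
    stop("both arm means must be > 0 to propagate SE to the log scale",
         call. = FALSE)
  }
  if (any(se_treatment < 0, na.rm = TRUE) || any(se_control < 0, na.rm = TRUE)) {
    stop("standard errors must be >= 0", call. = FALSE)
  }
  sqrt(se_treatment^2 / mean_treatment^2 + se_control^2 / mean_control^2)
}

#' Back-transform a log response ratio to a percent difference
#'
#' `(exp(RR) - 1) * 100`, the display scale of all results; strictly
#' increasing in RR and bounded below by -100%.
#'
#' @param rr log response ratio (finite). Vectorized.
#' @return Percent difference relative to the reference stand.
#' @export
percent_difference <- function(rr) {
  stopifnot(all(is.finite(rr) | is.na(rr)))
  (exp(rr) - 1) * 100
}

#' Inverse of [percent_difference()]
#'
#' @param percent percent difference in `(-100, Inf)`.
#' @return Log response ratio.
#' @export
rr_from_percent <- function(percent) {
  if (any(percent <= -100, na.rm = TRUE)) {
    stop("percent difference must exceed -100 to map back to the log scale",
         call. = FALSE)
  }
  log(percent / 100 + 1)
}

#' Convert biomass to carbon content
#'
#' Multiplies dry biomass by a carbon fraction, 0.5 by default (the
#' conventional biomass-to-carbon conversion).
#'
#' @param biomass Mg ha^-1, `>= 0`. Vectorized.
#' @param fraction carbon fraction of dry biomass, default 0.5.
#' @return Mg C ha^-1.
#' @export
biomass_to_carbon <- function(biomass, fraction = 0.5) {
  if (any(biomass < 0, na.rm = TRUE)) {
    stop("biomass must be >= 0", call. = FALSE)
  }
  stopifnot(is.numeric(fraction), length(fraction) == 1L, fraction > 0)
  fraction * biomass
}

#' Evaluate diameter-based allometric biomass equations
#'
#' Generic power-law evaluator `biomass = sum_j a_j * dbh^(b_j)` over the
#' tree components supplied by the caller (stem, bark, branches, foliage,
#' ...). Coefficients are always user-supplied — species-specific published
#' tables are deliberately not bundled, and there is no silent default.
#'
#' @param dbh diameter at breast height, cm, `> 0`. Vectorized.
#' @param coefficients data frame with numeric columns `a` and `b`, one row
#'   per component (an optional `component` column names them).
#' @return Biomass per tree (in the units of `a`), summed over components.
#' @examples
#' allometric_biomass(10, data.frame(a = 0.1, b = 2))  # 10
#' @export
allometric_biomass <- function(dbh, coefficients) {
  if (missing(coefficients) || is.null(coefficients)) {
    stop("allometric coefficients must be supplied; none are defaulted",
         call. = FALSE)
  }
  coefficients <- as.data.frame(coefficients)
  if (!all(c("a", "b") %in% names(coefficients)) || nrow(coefficients) == 0L) {
    stop("coefficients must carry columns 'a' and 'b' with >= 1 component",
         call. = FALSE)
  }
  if (any(dbh <= 0, na.rm = TRUE)) stop("dbh must be > 0", call. = FALSE)
  rowSums(outer(dbh, seq_len(nrow(coefficients)), function(d, j) {
    coefficients$a[j] * d^coefficients$b[j]
  }))
}

#' Append effect-size columns to a dataset
#'
#' Computes `rr`, `percent_diff`, `defined` and (where both arms carry
#' variance information) `se_rr` for every observation, returning the
#' dataset as a plain data frame ready for the heterogeneity and modelling
#' stages. A `time_class` factor (decade bins by default) is attached for
#' analyses that use time as a grouping factor.
#'
#' @param ds a `carbon_dataset`.
#' @param time_bin_width width of the time classes in years, default 10.
#' @return Data frame: the observation columns plus `rr`, `se_rr`,
#'   `percent_diff`, `defined`, `time_class`.
#' @export
add_effect_sizes <- function(ds, time_bin_width = 10) {
  stopifnot(inherits(ds, "carbon_dataset"))
  df <- as.data.frame(ds)
  es <- compute_rr(df$mean_treatment, df$mean_control)
  df$rr <- es$rr
  df$percent_diff <- es$percent_diff
  df$defined <- es$defined
  df$se_rr <- rep(NA_real_, nrow(df))
  have_var <- complete.cases(df[, c("se_treatment", "se_control")]) & df$defined
  if (any(have_var)) {
    df$se_rr[have_var] <- compute_se_rr(
      df$mean_treatment[have_var], df$se_treatment[have_var],
      df$mean_control[have_var], df$se_control[have_var])
  }
  df$time_class <- assign_time_class(df$time_since_treatment,
                                     width = time_bin_width)
  df
}
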