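#' Hedges-Olkin Q-statistic decomposition for one moderator
#'
#' Partitions the total heterogeneity of a set of effect sizes into
#' within-group (`Q_w`) and between-group (`Q_b`) components for a
#' categorical moderator:
#' `Q_total = sum_i w_i (y_i - ybar)^2` around the weighted grand mean,
#' `Q_w` is the same statistic around the weighted group means, and
#' `Q_b = Q_total - Q_w` is referred to a chi-square distribution on
#' (number of groups - 1) degrees of freedom. Weights are `1/se^2` in the
#' weighted track and unit weights in the unweighted track; both modes use
#' identical formulas.
#'
#' @param rr numeric vector of log response ratios (length >= 2).
#' @param groups vector of group labels, same length; empty levels are
#'   dropped (with a warning when they were explicit factor levels).
#' @param weights optional positive weights (`1/se_rr^2` for the
#'   inverse-variance track); `NULL` means unit weights.
#' @param moderator name of the moderator, carried into the result.
#' @return A `heterogeneity_result` list: `moderator`, `q_total`,
#'   `q_within`, `q_between`, `df_between`, `p_value`, `k`, and a
#'   `group_table` of per-level k and weighted means.
#' @export
q_decomposition <- function(rr, groups, weights = NULL,
                            moderator = deparse(substitute(groups))) {
  keep <- !is.na(rr) & !is.na(groups)
  if (!is.null(weights)) keep <- keep & !is.na(weights)
  rr <- rr[keep]
  groups <- as.character(groups)[keep]
  if (is.null(weights)) {
    weights <- rep(1, length(rr))
  } else {
    weights <- weights[keep]
    if (any(weights <= 0)) stop("weights must be > 0", call. = FALSE)
  }
  k <- length(rr)
  if (k < 2L) stop("need >= 2 effect sizes", call. = FALSE)
  levels_present <- unique(groups)
  if (length(levels_present) < 2L) {
    stop("need >= 2 non-empty groups", call. = FALSE)
  }

  grand <- sum(weights * rr) / sum(weights)
  q_total <- sum(weights * (rr - grand)^2)
  group_stats <- lapply(split(seq_len(k), groups), function(idx) {
    m <- sum(weights[idx] * rr[idx]) / sum(weights[idx])
    c(k = length(idx), mean = m,
      q = sum(weights[idx] * (rr[idx] - m)^2), w = sum(weights[idx]))
  })
  q_within <- sum(vapply(group_stats, `[[`, numeric(1), "q"))
  q_between <- max(0, q_total - q_within)
  df_between <- length(group_stats) - 1L
  p_value <- pchisq(q_between, df = df_between, lower.tail = FALSE)

  group_table <- data.frame(
    level = names(group_stats),
    k = vapply(group_stats, function(g) as.integer(g[["k"]]), integer(1)),
    mean_rr = vapply(group_stats, `[[`, numeric(1), "mean"),
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(moderator = moderator, q_total = q_total,
                 q_within = q_within, q_between = q_between,
                 df_between = df_between, p_value = p_value, k = k,
                 group_table = group_table),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf(
    "Q decomposition for '%s' (k = %d):\n  Q_total = %.4f, Q_within = %.4f, Q_between = %.4f (df = %d, p = %.4g)\n",
    x$moderator, x$k, x$q_total, x$q_within, x$q_between,
    x$df_between, x$p_value))
  invisible(x)
}

#' Iterative hierarchical moderator selection
#'
#' At each node, tests every remaining candidate moderator with
#' [q_decomposition()], splits the data on the candidate with the largest
#' significant `Q_b` (p < `alpha`), and recurses within each level. The
#' process stops when no candidate is significant or a subgroup falls below
#' the minimum size. Ties in `Q_b` are broken by the fixed order of
#' `candidates`, making the procedure deterministic.
#'
#' @param data data frame with an `rr` column (see [add_effect_sizes()]),
#'   optionally `se_rr`, and one column per candidate moderator.
#' @param candidates character vector of moderator column names, in
#'   tie-break priority order.
#' @param alpha significance level for `Q_b` (default 0.05).
#' @param weighted use inverse-variance weights `1/se_rr^2` (rows lacking
#'   `se_rr` are excluded); `FALSE` runs the unit-weight track on all rows.
#' @param min_group minimum number of effect sizes per subgroup level
#'   (default 3); smaller subgroups become "insufficient data" leaves.
#' @return A `partition_tree`: nested lists with fields `leaf`, `k`,
#'   `moderator`, `result` (the winning `heterogeneity_result`),
#'   `tested` (all candidate results at the node) and `children`
#'   keyed by level; leaves carry a `reason`.
#' @export
hierarchical_partition <- function(data, candidates, alpha = 0.05,
                                   weighted = FALSE, min_group = 3L) {
  stopifnot(length(candidates) >= 1L,
            all(candidates %in% names(data)), "rr" %in% names(data))
  if (weighted) {
    if (!"se_rr" %in% names(data)) {
      stop("weighted partition requires an se_rr column", call. = FALSE)
    }
    data <- data[!is.na(data$se_rr) & data$se_rr > 0, , drop = FALSE]
  }
  data <- data[!is.na(data$rr), , drop = FALSE]
  tree <- partition_node(data, candidates, alpha, weighted, min_group)
  structure(tree, class = "partition_tree")
}

partition_node <- function(data, candidates, alpha, weighted, min_group) {
  k <- nrow(data)
  leaf <- function(reason) list(leaf = TRUE, k = k, reason = reason)
  if (k < 2L * min_group) return(leaf("insufficient data"))
  if (length(candidates) == 0L) return(leaf("no candidates left"))
  w <- if (weighted) 1 / data$se_rr^2 else NULL

  tested <- list()
  for (cand in candidates) {
    lv <- table(as.character(data[[cand]]))
    lv <- lv[lv >= min_group]
    if (length(lv) < 2L) next
    sub <- data[as.character(data[[cand]]) %in% names(lv), , drop = FALSE]
    wsub <- if (weighted) 1 / sub$se_rr^2 else NULL
    res <- q_decomposition(sub$rr, sub[[cand]], weights = wsub,
                           moderator = cand)
    tested[[cand]] <- res
  }
  if (length(tested) == 0L) return(leaf("no testable candidate"))

  qb <- vapply(tested, `[[`, numeric(1), "q_between")
  pv <- vapply(tested, `[[`, numeric(1), "p_value")
  sig <- pv < alpha
  if (!any(sig)) {
    return(c(leaf("no significant moderator"), list(tested = tested)))
  }
  # largest significant Q_b; which.max keeps the first (candidate order)
  winner <- names(tested)[sig][which.max(qb[sig])]

  children <- lapply(split(data, as.character(data[[winner]])), function(sub) {
    if (nrow(sub) < min_group) {
      list(leaf = TRUE, k = nrow(sub), reason = "insufficient data")
    } else {
      partition_node(sub, setdiff(candidates, winner), alpha, weighted,
                     min_group)
    }
  })

  list(leaf = FALSE, k = k, moderator = winner, result = tested[[winner]],
       tested = tested, children = children)
}

#' @export
print.partition_tree <- function(x, ...) {
  recurse <- function(node, label, depth) {
    pad <- strrep("  ", depth)
    if (isTRUE(node$leaf)) {
      cat(sprintf("%s%s: leaf (k = %d, %s)\n", pad, label, node$k, node$reason))
    } else {
      cat(sprintf("%s%s: split on '%s' (k = %d, Q_b = %.2f, p = %.3g)\n",
                  pad, label, node$moderator, node$k,
                  node$result$q_between, node$result$p_value))
      for (lv in names(node$children)) {
        recurse(node$children[[lv]], lv, depth + 1L)
      }
    }
  }
  recurse(x, "root", 0L)
  invisible(x)
}

#' Moderator-by-subgroup heterogeneity table
#'
#' A flat report of `Q_b` (with significance) for each moderator, computed
#' on the full dataset ("ecosystem" row) and within each level of
#' `split_by` (one row per carbon pool by default) — the tabular companion
#' to [hierarchical_partition()].
#'
#' @inheritParams hierarchical_partition
#' @param moderators moderator columns to test.
#' @param split_by column defining the subgroup rows (default `"pool"`);
#'   `NULL` for the overall row only.
#' @return Data frame with `response`, `k`, then one `Q_b` and one p-value
#'   column per moderator.
#' @export
heterogeneity_table <- function(data, moderators, split_by = "pool",
                                weighted = FALSE, min_group = 3L) {
  if (weighted) data <- data[!is.na(data$se_rr) & data$se_rr > 0, , drop = FALSE]
  data <- data[!is.na(data$rr), , drop = FALSE]
  one_row <- function(df, label, mods) {
    row <- list(response = label, k = nrow(df))
    for (m in mods) {
      res <- tryCatch({
        lv <- table(as.character(df[[m]]))
        lv <- lv[lv >= min_group]
        if (length(lv) < 2L) stop("untestable")
        sub <- df[as.character(df[[m]]) %in% names(lv), , drop = FALSE]
        w <- if (weighted) 1 / sub$se_rr^2 else NULL
        q_decomposition(sub$rr, sub[[m]], weights = w, moderator = m)
      }, error = function(e) NULL)
      row[[paste0("qb_", m)]] <- if (is.null(res)) NA_real_ else res$q_between
      row[[paste0("p_", m)]] <- if (is.null(res)) NA_real_ else res$p_value
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- one_row(data, "ecosystem", moderators)
  if (!is.null(split_by)) {
    sub_mods <- setdiff(moderators, split_by)
    for (lv in unique(as.character(data[[split_by]]))) {
      df <- data[as.character(data[[split_by]]) == lv, , drop = FALSE]
      row <- one_row(df, lv, sub_mods)
      row[[paste0("qb_", split_by)]] <- NA_real_
      row[[paste0("p_", split_by)]] <- NA_real_
      out <- rbind(out, row[, names(out)])
    }
  }
  rownames(out) <- NULL
  out
}
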