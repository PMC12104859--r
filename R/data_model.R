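#' Construct a validated carbon-observation dataset
#'
#' A `carbon_dataset` is a data frame with one row per
#' study x unit x pool x treatment x time-point comparison of a harvested
#' stand against an uncut reference. Arm means are carbon stocks in
#' Mg C ha^-1; variance information (SE and replicate count per arm) is
#' optional but must travel together within an arm.
#'
#' Hard invariants (violations are errors, or dropped rows with diagnostics
#' when `on_invalid = "drop"`):
#' * `mean_control > 0` — the reference stand supplies the response-ratio
#'   denominator and always carries carbon;
#' * `mean_treatment >= 0`;
#' * categorical fields drawn from their closed vocabularies
#'   ([CARBON_POOLS], [HARVEST_TREATMENTS], [FOREST_BIOMES],
#'   [REFERENCE_TYPES]);
#' * `se_*` present exactly when `n_*` is present for the same arm;
#' * the key (study_id, unit_id, pool, treatment, time_since_treatment)
#'   is unique.
#'
#' Soft invariants (warnings): `time_since_treatment > 110` years (beyond
#' the longest chronosequence the method is calibrated for) and mineral-soil
#' `sampling_depth` outside 7--150 cm.
#'
#' @param df data frame carrying at least the required columns
#'   (`study_id`, `pool`, `treatment`, `biome`, `reference_type`,
#'   `time_since_treatment`, `mean_treatment`, `mean_control`).
#'   A missing `unit_id` is synthesized as `study_id` plus row ordinal so
#'   the uniqueness invariant can hold.
#' @param provenance free-text source tag stored as an attribute.
#' @param on_invalid `"error"` (default) stops on the first hard violation;
#'   `"drop"` removes offending rows and attaches the row-indexed
#'   diagnostics as the `"validation"` attribute.
#' @return A `carbon_dataset` (data frame subclass).
#' @seealso [read_dataset()], [write_dataset()], [summarize_dataset()]
#' @export
carbon_dataset <- function(df, provenance = "", on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)

  missing_cols <- setdiff(REQUIRED_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(DATASET_COLUMNS, names(df))) df[[col]] <- NA
  if (all(is.na(df$unit_id)) && nrow(df) > 0L) {
    df$unit_id <- paste0(df$study_id, "_u", seq_len(nrow(df)))
  } else if (anyNA(df$unit_id)) {
    idx <- which(is.na(df$unit_id))
    df$unit_id[idx] <- paste0(df$study_id[idx], "_u", idx)
  }

  chr_cols <- c("study_id", "unit_id", "pool", "treatment", "biome", "reference_type")
  num_cols <- c("time_since_treatment", "mean_treatment", "mean_control",
                "se_treatment", "se_control", "sampling_depth")
  int_cols <- c("n_treatment", "n_control")
  for (col in chr_cols) df[[col]] <- as.character(df[[col]])
  for (col in num_cols) df[[col]] <- as.numeric(df[[col]])
  for (col in int_cols) df[[col]] <- as.integer(df[[col]])
  df <- df[, DATASET_COLUMNS]

  report <- validate_observations(df)
  warn_rows <- report[report$severity == "warning", , drop = FALSE]
  if (nrow(warn_rows) > 0L) {
    warning(sprintf("%d soft validation warning(s); first: row %d: %s",
                    nrow(warn_rows), warn_rows$row[1L], warn_rows$message[1L]),
            call. = FALSE)
  }
  bad <- unique(report$row[report$severity == "error"])
  if (length(bad) > 0L) {
    if (on_invalid == "error") {
      err <- report[report$severity == "error", , drop = FALSE]
      stop(sprintf("%d row(s) violate hard invariants; first: row %d [%s]: %s",
                   length(bad), err$row[1L], err$field[1L], err$message[1L]),
           call. = FALSE)
    }
    warning(sprintf("dropping %d invalid row(s); see attr(x, 'validation')",
                    length(bad)), call. = FALSE)
    df <- df[-bad, , drop = FALSE]
    rownames(df) <- NULL
  }

  structure(df,
            provenance = provenance,
            validation = report,
            class = c("carbon_dataset", "data.frame"))
}

#' Row-indexed validation of the observation schema
#'
#' Checks every row of a candidate observation table against the hard and
#' soft invariants of the data model. Validation is total: every malformed
#' row yields a diagnostic rather than a silent drop.
#'
#' @param df data frame in the canonical column layout.
#' @return Data frame with columns `row`, `field`, `severity`
#'   (`"error"`/`"warning"`) and `message`; zero rows when `df` is clean.
#' @export
validate_observations <- function(df) {
  diag <- list()
  note <- function(rows, field, severity, message) {
    if (length(rows) > 0L) {
      diag[[length(diag) + 1L]] <<- data.frame(
        row = rows, field = field, severity = severity, message = message,
        stringsAsFactors = FALSE)
    }
  }

  vocab <- list(pool = CARBON_POOLS, treatment = HARVEST_TREATMENTS,
                biome = FOREST_BIOMES, reference_type = REFERENCE_TYPES)
  for (field in names(vocab)) {
    bad <- which(is.na(df[[field]]) | !(df[[field]] %in% vocab[[field]]))
    note(bad, field, "error",
         paste0("unknown level; allowed: ", paste(vocab[[field]], collapse = ", ")))
  }

  note(which(is.na(df$mean_control) | df$mean_control <= 0),
       "mean_control", "error",
       "reference mean must be > 0 (log response-ratio denominator)")
  note(which(is.na(df$mean_treatment) | df$mean_treatment < 0),
       "mean_treatment", "error", "treatment mean must be >= 0")
  note(which(is.na(df$time_since_treatment) | df$time_since_treatment < 0),
       "time_since_treatment", "error", "time since treatment must be >= 0")
  note(which(!is.na(df$time_since_treatment) & df$time_since_treatment > 110),
       "time_since_treatment", "warning",
       "beyond the 110-year observed horizon")

  for (arm in c("treatment", "control")) {
    se <- df[[paste0("se_", arm)]]
    n <- df[[paste0("n_", arm)]]
    note(which(is.na(se) != is.na(n)), paste0("se_", arm), "error",
         "SE and replicate count must be present or absent together")
    note(which(!is.na(se) & se < 0), paste0("se_", arm), "error",
         "SE must be >= 0")
    note(which(!is.na(n) & n < 1L), paste0("n_", arm), "error",
         "replicate count must be a positive integer")
  }

  note(which(!is.na(df$sampling_depth) &
               (df$sampling_depth < 7 | df$sampling_depth > 150)),
       "sampling_depth", "warning", "outside the reported 7-150 cm range")
  note(which(!is.na(df$sampling_depth) & df$pool != "mineral_soil"),
       "sampling_depth", "warning", "sampling depth given for a non-soil pool")

  key <- paste(df$study_id, df$unit_id, df$pool, df$treatment,
               df$time_since_treatment, sep = "\r")
  note(which(duplicated(key)), "study_id", "error",
       "duplicate (study, unit, pool, treatment, time) key")

  if (length(diag) == 0L) {
    return(data.frame(row = integer(), field = character(),
                      severity = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, diag)
  out[order(out$row), , drop = FALSE]
}

#' Read a carbon-observation CSV
#'
#' Reads a comma-separated, UTF-8, "."-decimal file (empty cell = missing)
#' into a validated [carbon_dataset()]. Source files whose headers differ
#' from the canonical schema are adapted through `mapping`, and files
#' reporting standard deviations instead of standard errors are converted
#' at load via SD/sqrt(n).
#'
#' @param path CSV file path.
#' @param mapping optional named character vector mapping canonical field
#'   names to source column names, e.g.
#'   `c(mean_treatment = "C_cut", mean_control = "C_ref")`.
#' @param variance_as `"se"` (default) or `"sd"`; with `"sd"` the
#'   `se_*` columns of the file are interpreted as standard deviations and
#'   divided by `sqrt(n_*)`.
#' @param provenance source tag; defaults to the file path.
#' @param on_invalid passed to [carbon_dataset()]; default `"drop"` keeps
#'   the clean rows and attaches row-indexed diagnostics.
#' @return A `carbon_dataset`.
#' @export
read_dataset <- function(path, mapping = NULL,
                         variance_as = c("se", "sd"),
                         provenance = path,
                         on_invalid = c("drop", "error")) {
  variance_as <- match.arg(variance_as)
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 na.strings = c("", "NA"), fileEncoding = "UTF-8")

  if (!is.null(mapping)) {
    missing_src <- setdiff(unname(mapping), names(df))
    if (length(missing_src) > 0L) {
      stop("schema error: mapped source column(s) absent from file: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    }
    for (canon in names(mapping)) names(df)[names(df) == mapping[[canon]]] <- canon
  }

  if (variance_as == "sd") {
    for (arm in c("treatment", "control")) {
      se_col <- paste0("se_", arm); n_col <- paste0("n_", arm)
      if (se_col %in% names(df) && n_col %in% names(df)) {
        df[[se_col]] <- as.numeric(df[[se_col]]) / sqrt(as.numeric(df[[n_col]]))
      }
    }
  }

  carbon_dataset(df, provenance = provenance, on_invalid = on_invalid)
}

#' Write a carbon-observation dataset to CSV
#'
#' Output is byte-stable under a fixed column order: numeric fields are
#' printed with 17 significant digits so that `read_dataset()` reproduces
#' the dataset field-for-field, and missing optional fields round-trip as
#' empty cells.
#'
#' @param ds a `carbon_dataset`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "carbon_dataset"))
  out <- as.data.frame(ds)[, DATASET_COLUMNS, drop = FALSE]
  fmt <- function(x) {
    if (is.character(x)) return(as.character(ifelse(is.na(x), "", x)))
    if (is.integer(x)) return(as.character(ifelse(is.na(x), "", as.character(x))))
    as.character(ifelse(is.na(x), "", sprintf("%.17g", x)))
  }
  cells <- vapply(out, fmt, character(nrow(out)))
  if (nrow(out) == 1L) cells <- matrix(cells, nrow = 1L)
  lines <- c(paste(DATASET_COLUMNS, collapse = ","),
             if (nrow(out) > 0L) apply(cells, 1L, paste, collapse = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Dataset composition summary
#'
#' Per-stratum counts and percentages (biome, treatment, pool), quartiles
#' of time since treatment per treatment, and the fraction of observations
#' carrying complete variance information (SE and n for both arms) — the
#' share eligible for the inverse-variance weighted track.
#'
#' @param ds a `carbon_dataset`.
#' @return A `carbon_summary` list; for an empty dataset an explicit empty
#'   summary (`n_obs = 0`), never an error.
#' @export
summarize_dataset <- function(ds) {
  stopifnot(inherits(ds, "carbon_dataset"))
  df <- as.data.frame(ds)
  tab <- function(field) {
    if (nrow(df) == 0L) {
      return(data.frame(level = character(), n = integer(), pct = numeric(),
                        stringsAsFactors = FALSE))
    }
    tt <- table(df[[field]])
    data.frame(level = names(tt), n = as.integer(tt),
               pct = 100 * as.integer(tt) / nrow(df),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  time_summary <- if (nrow(df) == 0L) {
    data.frame(treatment = character(), median = numeric(), q1 = numeric(),
               q3 = numeric(), max = numeric(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(split(df, df$treatment), function(d) {
      q <- quantile(d$time_since_treatment, c(.25, .5, .75), names = FALSE)
      data.frame(treatment = d$treatment[1L], median = q[2L], q1 = q[1L],
                 q3 = q[3L], max = max(d$time_since_treatment),
                 stringsAsFactors = FALSE)
    }))
  }
  rownames(time_summary) <- NULL
  complete_var <- if (nrow(df) == 0L) NA_real_ else {
    mean(complete.cases(df[, c("se_treatment", "se_control",
                               "n_treatment", "n_control")]))
  }
  structure(list(
    n_obs = nrow(df),
    n_studies = length(unique(df$study_id)),
    n_units = length(unique(paste(df$study_id, df$unit_id))),
    by_biome = tab("biome"),
    by_treatment = tab("treatment"),
    by_pool = tab("pool"),
    time_by_treatment = time_summary,
    variance_complete = complete_var,
    provenance = attr(ds, "provenance")
  ), class = "carbon_summary")
}

#' @export
print.carbon_summary <- function(x, ...) {
  cat("Carbon dataset summary\n")
  cat(sprintf("  %d observations, %d studies, %d experimental units\n",
              x$n_obs, x$n_studies, x$n_units))
  if (x$n_obs == 0L) return(invisible(x))
  cat(sprintf("  complete variance info: %.1f%% of rows\n",
              100 * x$variance_complete))
  cat("  by biome:\n")
  print(x$by_biome, row.names = FALSE)
  cat("  by treatment:\n")
  print(x$by_treatment, row.names = FALSE)
  cat("  by pool:\n")
  print(x$by_pool, row.names = FALSE)
  cat("  time since treatment (years):\n")
  print(x$time_by_treatment, row.names = FALSE)
  invisible(x)
}

#' @export
print.carbon_dataset <- function(x, ...) {
  cat(sprintf("<carbon_dataset: %d observations, %d studies>\n",
              nrow(x), length(unique(x$study_id))))
  if (nzchar(attr(x, "provenance") %||% "")) {
    cat("  provenance:", attr(x, "provenance"), "\n")
  }
  print(as.data.frame(head(x, 10L)))
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Assign decade time classes
#'
#' Bins continuous time since treatment into the categorical classes used
#' when time enters a heterogeneity test or a random-effects structure as a
#' grouping factor. Default bins are decades `[0,10), [10,20), ...`.
#'
#' @param t numeric vector of years since treatment.
#' @param width bin width in years (default 10).
#' @param breaks optional explicit break points overriding `width`.
#' @return Factor of time classes labelled `"[a,b)"`.
#' @export
assign_time_class <- function(t, width = 10, breaks = NULL) {
  if (is.null(breaks)) {
    top <- max(width, ceiling(max(t, 0, na.rm = TRUE) / width) * width + width)
    breaks <- seq(0, top, by = width)
  }
  cut(t, breaks = breaks, right = FALSE, include.lowest = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Subsetting keeps the class and provenance.
#' @export
`[.carbon_dataset` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(DATASET_COLUMNS %in% names(out))) {
    attr(out, "provenance") <- attr(x, "provenance")
    class(out) <- c("carbon_dataset", "data.frame")
  }
  out
}
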