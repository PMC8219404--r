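#' @title Trial table schema and I/O
#' @name trial_data
#' @description
#' A trial table is a plain `data.frame` with one row per observer test and
#' the columns listed in [trial_columns()]. Counts are stored, never
#' proportions: the three social predictors are always derived with
#' [trial_proportion()], which keeps the raw visit/peck volumes available
#' for simulation and collinearity analysis.
#'
#' Column semantics:
#' * `trial_id` — opaque unique identifier.
#' * `observer_first_peck_black` — 1 if the observer's first peck was at
#'   the black feeder, 0 otherwise. Only the first peck is modelled;
#'   later pecks may reflect individual learning at the feeders.
#' * `black_side` — 1 if the black feeder was on the left wall of the
#'   observer cage, 0 if on the right (layout covariate).
#' * `birds_black`/`birds_white` — number of demonstrator individuals
#'   assigned to the feeder of each colour.
#' * `visits_black`/`visits_white`, `pecks_black`/`pecks_white` —
#'   demonstrator visit and peck counts at each colour.
#' * `sex` — sex label of the (single-sex) trial; metadata only.
#' * `ratio_label` — design label for the unordered majority:minority
#'   group-size pair, e.g. `"2:4"`.
NULL

#' Canonical trial-table column names
#'
#' @return Character vector of the eleven required columns, in canonical
#'   order.
#' @export
trial_columns <- function() {
  c("trial_id", "observer_first_peck_black", "black_side",
    "birds_black", "birds_white", "visits_black", "visits_white",
    "pecks_black", "pecks_white", "sex", "ratio_label")
}

#' Validate a trial table
#'
#' Checks the schema invariants: all columns present, counts are
#' non-negative integers, the outcome and side covariate are 0/1, at least
#' two demonstrators per trial, trial ids unique, and `ratio_label`
#' consistent with the unordered pair of bird counts. Failures are
#' reported with row numbers.
#'
#' @param trials data.frame in the trial-table schema.
#' @return `trials`, invisibly, if valid; otherwise an error.
#' @export
validate_trials <- function(trials) {
  if (!is.data.frame(trials)) stop("`trials` must be a data.frame")
  missing_cols <- setdiff(trial_columns(), names(trials))
  if (length(missing_cols) > 0) {
    stop("missing trial columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(trials) == 0) return(invisible(trials))

  bad <- function(rows, what) {
    if (length(rows) > 0) {
      stop("invalid trial table: ", what, " (row ",
           paste(rows, collapse = ", "), ")")
    }
  }

  count_cols <- c("birds_black", "birds_white", "visits_black",
                  "visits_white", "pecks_black", "pecks_white")
  for (col in count_cols) {
    v <- trials[[col]]
    if (!is.numeric(v)) stop("column ", col, " must be numeric")
    bad(which(is.na(v) | v < 0 | v != round(v)),
        paste0("non-negative integer required in ", col))
  }
  for (col in c("observer_first_peck_black", "black_side")) {
    v <- trials[[col]]
    bad(which(is.na(v) | !(v %in% c(0, 1))),
        paste0(col, " must be 0 or 1"))
  }
  bad(which(trials$birds_black + trials$birds_white < 2),
      "need at least two demonstrators (birds_black + birds_white >= 2)")

  dup <- which(duplicated(trials$trial_id))
  bad(dup, "duplicated trial_id")

  lab_pair <- function(lab) {
    parts <- suppressWarnings(as.integer(strsplit(lab, ":", fixed = TRUE)[[1]]))
    if (length(parts) != 2 || anyNA(parts)) return(c(NA_integer_, NA_integer_))
    sort(parts)
  }
  bad_ratio <- vapply(seq_len(nrow(trials)), function(i) {
    expected <- lab_pair(as.character(trials$ratio_label[i]))
    actual <- sort(c(trials$birds_black[i], trials$birds_white[i]))
    anyNA(expected) || !identical(as.integer(expected), as.integer(actual))
  }, logical(1))
  bad(which(bad_ratio), "ratio_label inconsistent with bird counts")

  invisible(trials)
}

#' Social-information proportion for a measure
#'
#' Returns the proportion of demonstrator activity at the black feeder for
#' one of the three candidate measures: the proportion of demonstrator
#' `birds`, `visits`, or `pecks` that were at the black (as opposed to
#' white) feeder.
#'
#' @param trials trial table (see [trial_data]).
#' @param measure one of `"birds"`, `"visits"`, `"pecks"`.
#' @param strict if `TRUE` (default) a trial whose black+white total for
#'   the measure is zero raises an undefined-proportion error (the trial is
#'   unanalysable under that measure); if `FALSE` such trials yield `NA`.
#' @return Numeric vector in \[0, 1\], one value per trial.
#' @export
trial_proportion <- function(trials, measure = c("birds", "visits", "pecks"),
                             strict = TRUE) {
  measure <- match.arg(measure)
  black <- trials[[paste0(measure, "_black")]]
  white <- trials[[paste0(measure, "_white")]]
  total <- black + white
  if (strict && any(total == 0)) {
    stop("undefined proportion: zero ", measure, " total in trial(s) ",
         paste(trials$trial_id[total == 0], collapse = ", "))
  }
  ifelse(total == 0, NA_real_, black / total)
}

#' Read a trial table from CSV
#'
#' Expects a comma-separated UTF-8 file whose header names exactly the
#' trial-table columns (any order); the returned data.frame uses canonical
#' column order and preserves row order. The table is validated with
#' [validate_trials()]; failures name the offending rows.
#'
#' @param path file path.
#' @return Validated trial-table data.frame. An empty file (header only)
#'   yields a zero-row table; fitting functions refuse it later.
#' @export
read_trials <- function(path) {
  trials <- read.csv(path, stringsAsFactors = FALSE)
  extra <- setdiff(names(trials), trial_columns())
  if (length(extra) > 0) {
    stop("unexpected column(s) in ", path, ": ", paste(extra, collapse = ", "))
  }
  missing_cols <- setdiff(trial_columns(), names(trials))
  if (length(missing_cols) > 0) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  trials <- trials[trial_columns()]
  trials$trial_id <- as.character(trials$trial_id)
  trials$sex <- as.character(trials$sex)
  trials$ratio_label <- as.character(trials$ratio_label)
  validate_trials(trials)
  trials
}

#' Write a trial table to CSV
#'
#' Inverse of [read_trials()]: `read_trials(write_trials(d, path))`
#' reproduces `d` field-for-field, in the same row order.
#'
#' @param trials validated trial table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  write.csv(trials[trial_columns()], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
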