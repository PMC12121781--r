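# Reading and writing the package's CSV tables. One dialect only: comma
# separated, '.' decimal point, header required, UTF-8, empty cell = missing.

trial_event_cols <- c(
  "subject_id", "day", "trial", "lever_presses", "foodcup_entries",
  "lever_latency", "foodcup_latency", "cs_duration"
)
session_summary_cols <- c(
  "subject_id", "day", "n_trials", "lever_presses", "foodcup_entries",
  "p_lever", "p_foodcup", "mean_lever_latency", "mean_foodcup_latency",
  "cs_duration"
)
score_cols <- c(
  "subject_id", "day", "response_bias", "probability_difference",
  "latency_score", "pavca_index"
)
label_cols <- c("subject_id", "method", "label", "gt_cutoff", "st_cutoff")

require_columns <- function(df, required, path) {
  require_header(names(df), required, path)
}

require_header <- function(present, required, path) {
  missing <- setdiff(required, present)
  if (length(missing) > 0) {
    abort_schema(sprintf(
      "File '%s' is missing required column(s): %s.",
      path, paste(missing, collapse = ", ")
    ))
  }
}

# Collect row-numbered complaints and raise them in one validation error.
raise_row_errors <- function(problems, path) {
  if (length(problems) == 0) {
    return(invisible())
  }
  abort_validation(paste0(
    sprintf("Invalid rows in '%s':\n", path),
    paste("  -", head(problems, 20), collapse = "\n")
  ))
}

#' Read trial-level conditioning events
#'
#' Reads a CSV of per-trial operant events recorded during the conditioned
#' stimulus (CS) window: lever presses and food-cup head entries with their
#' first-response latencies. An empty latency cell means the behavior did not
#' occur on that trial; a latency of 0 means the response occurred at CS
#' onset. Every row is validated (counts/latency consistency, latency within
#' the CS window, unique subject-day-trial keys) and offending rows are
#' reported by row number.
#'
#' @param path Path to a CSV with columns `subject_id`, `day`, `trial`,
#'   `lever_presses`, `foodcup_entries`, `lever_latency`, `foodcup_latency`
#'   and optionally `cs_duration`.
#' @param cs_duration CS duration in seconds used when the file carries no
#'   `cs_duration` column (default 8, the standard PavCA lever presentation).
#' @return A tibble of validated trial events.
#' @export
read_trial_events <- function(path, cs_duration = 8) {
  header <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  require_header(header, setdiff(trial_event_cols, "cs_duration"), path)
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      day = readr::col_integer(),
      trial = readr::col_integer(),
      lever_presses = readr::col_integer(),
      foodcup_entries = readr::col_integer(),
      lever_latency = readr::col_double(),
      foodcup_latency = readr::col_double(),
      .default = readr::col_guess()
    ),
    na = c("", "NA"),
    progress = FALSE,
    show_col_types = FALSE
  )
  require_columns(df, setdiff(trial_event_cols, "cs_duration"), path)
  if (!"cs_duration" %in% names(df)) {
    df$cs_duration <- as.numeric(cs_duration)
  }
  validate_trial_events(df, path)
}

#' Validate a table of trial events
#'
#' Applies the trial-event invariants to an in-memory table; used by
#' [read_trial_events()] and by the simulator's output checks.
#'
#' @param df Data frame of trial events.
#' @param path Label used in error messages (a file path or description).
#' @return The validated tibble, with canonical column order.
#' @export
validate_trial_events <- function(df, path = "<in memory>") {
  df <- as_tibble(df)
  require_columns(df, setdiff(trial_event_cols, "cs_duration"), path)
  if (!"cs_duration" %in% names(df)) df$cs_duration <- 8
  probs <- character()
  note <- function(rows, what) {
    if (length(rows) > 0) {
      probs <<- c(probs, sprintf(
        "row %s: %s", paste(head(rows, 5), collapse = ","), what
      ))
    }
  }
  note(which(is.na(df$subject_id)), "missing subject_id")
  note(which(is.na(df$day) | df$day < 1), "day must be an integer >= 1")
  note(which(is.na(df$trial) | df$trial < 1), "trial must be an integer >= 1")
  note(which(is.na(df$lever_presses) | df$lever_presses < 0),
       "lever_presses must be a count >= 0")
  note(which(is.na(df$foodcup_entries) | df$foodcup_entries < 0),
       "foodcup_entries must be a count >= 0")
  note(which(is.na(df$cs_duration) | df$cs_duration <= 0),
       "cs_duration must be > 0")
  note(which(df$lever_presses == 0 & !is.na(df$lever_latency)),
       "lever_latency present but lever_presses = 0")
  note(which(df$lever_presses > 0 & is.na(df$lever_latency)),
       "lever_latency absent but lever_presses > 0")
  note(which(df$foodcup_entries == 0 & !is.na(df$foodcup_latency)),
       "foodcup_latency present but foodcup_entries = 0")
  note(which(df$foodcup_entries > 0 & is.na(df$foodcup_latency)),
       "foodcup_latency absent but foodcup_entries > 0")
  note(which(!is.na(df$lever_latency) &
               (df$lever_latency < 0 | df$lever_latency > df$cs_duration)),
       "lever_latency outside [0, cs_duration]")
  note(which(!is.na(df$foodcup_latency) &
               (df$foodcup_latency < 0 | df$foodcup_latency > df$cs_duration)),
       "foodcup_latency outside [0, cs_duration]")
  key <- paste(df$subject_id, df$day, df$trial, sep = "\r")
  note(which(duplicated(key)), "duplicate (subject_id, day, trial)")
  raise_row_errors(probs, path)
  df[trial_event_cols]
}

#' Read per-subject-per-day PavCA index scores
#'
#' Reads a CSV of precomputed scores. The three components (response bias,
#' probability difference, latency score) are optional; when present, each
#' row's component mean is checked against the stored index and a warning is
#' issued if they disagree beyond 1e-9.
#'
#' @param path Path to a CSV with columns `subject_id`, `day`, `pavca_index`
#'   and optionally the three component columns.
#' @return A tibble of validated score records; `day` is a character label so
#'   day windows such as `"5-6"` can be represented.
#' @export
read_scores <- function(path) {
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      day = readr::col_character(),
      .default = readr::col_double()
    ),
    na = c("", "NA"),
    progress = FALSE,
    show_col_types = FALSE
  )
  require_columns(df, c("subject_id", "day", "pavca_index"), path)
  probs <- character()
  bad <- which(is.na(df$pavca_index) | df$pavca_index < -1 | df$pavca_index > 1)
  if (length(bad) > 0) {
    probs <- c(probs, sprintf(
      "row %s: pavca_index outside [-1, 1]",
      paste(head(bad, 5), collapse = ",")
    ))
  }
  comps <- intersect(
    c("response_bias", "probability_difference", "latency_score"), names(df)
  )
  for (comp in comps) {
    bad <- which(!is.na(df[[comp]]) & (df[[comp]] < -1 | df[[comp]] > 1))
    if (length(bad) > 0) {
      probs <- c(probs, sprintf(
        "row %s: %s outside [-1, 1]", paste(head(bad, 5), collapse = ","), comp
      ))
    }
  }
  raise_row_errors(probs, path)
  if (length(comps) == 3) {
    m <- (df$response_bias + df$probability_difference + df$latency_score) / 3
    off <- which(!is.na(m) & abs(m - df$pavca_index) > 1e-9)
    if (length(off) > 0) {
      warn(
        sprintf(
          "%d row(s) in '%s' have a component mean that differs from pavca_index by more than 1e-9 (first: row %d).",
          length(off), path, off[1]
        ),
        class = "pavca_component_mismatch"
      )
    }
  }
  df[intersect(score_cols, names(df))]
}

#' Read per-subject-per-day session summaries
#'
#' @param path Path to a CSV with the session summary schema (totals,
#'   response probabilities and mean latencies per subject-day).
#' @return A tibble of validated session summaries.
#' @export
read_session_summaries <- function(path) {
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      day = readr::col_integer(),
      n_trials = readr::col_integer(),
      lever_presses = readr::col_integer(),
      foodcup_entries = readr::col_integer(),
      .default = readr::col_double()
    ),
    na = c("", "NA"),
    progress = FALSE,
    show_col_types = FALSE
  )
  require_columns(df, session_summary_cols, path)
  probs <- character()
  for (p in c("p_lever", "p_foodcup")) {
    bad <- which(is.na(df[[p]]) | df[[p]] < 0 | df[[p]] > 1)
    if (length(bad) > 0) {
      probs <- c(probs, sprintf(
        "row %s: %s outside [0, 1]", paste(head(bad, 5), collapse = ","), p
      ))
    }
  }
  for (l in c("mean_lever_latency", "mean_foodcup_latency")) {
    bad <- which(is.na(df[[l]]) | df[[l]] < 0 | df[[l]] > df$cs_duration)
    if (length(bad) > 0) {
      probs <- c(probs, sprintf(
        "row %s: %s outside [0, cs_duration]",
        paste(head(bad, 5), collapse = ","), l
      ))
    }
  }
  raise_row_errors(probs, path)
  df[session_summary_cols]
}

#' Write a pavca table to CSV
#'
#' Writes any of the package's tables with a deterministic column order, '.'
#' decimal separator, UTF-8 encoding and a terminating newline. Doubles are
#' serialized at 12 significant digits -- far beyond behavioral measurement
#' precision -- which makes write -> read -> write a byte-identical fixed
#' point. Missing values become empty cells.
#'
#' @param table A trial-event, session-summary, score or label tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  table <- as_tibble(table)
  for (canon in list(trial_event_cols, session_summary_cols, score_cols,
                     label_cols)) {
    if (all(names(table) %in% canon)) {
      table <- table[intersect(canon, names(table))]
      break
    }
  }
  table <- dplyr::mutate(
    table,
    dplyr::across(dplyr::where(function(col) {
      is.double(col) && !is.integer(col)
    }), function(col) signif(col, 12))
  )
  readr::write_csv(table, path, na = "")
  invisible(path)
}
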