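# PavCA index scoring: three approach components and their mean, per
# subject-day, plus day-window means.
#
# The index is the equal-weight mean of
#   response bias          (L - F) / (L + F)
#   probability difference P(lever trial) - P(food-cup trial)
#   latency score          (mean food-cup latency - mean lever latency) / cs
# where no-response trials contribute cs_duration to the mean latency. These
# are the standard PavCA component definitions; each lies in [-1, 1], so the
# index does too, with +1 a pure sign-tracker and -1 a pure goal-tracker.

#' Summarize trial events into per-session totals
#'
#' Collapses validated trial events to one row per subject-day: total lever
#' presses and CS food-cup entries, the fraction of trials with at least one
#' response of each kind, and mean first-response latencies with
#' `cs_duration` substituted on no-response trials (the CS ended unanswered).
#'
#' @param events A trial-event tibble (see [read_trial_events()]).
#' @return A session-summary tibble, one row per subject-day.
#' @export
summarize_sessions <- function(events) {
  if (!is.data.frame(events) || nrow(events) == 0) {
    abort_validation("`events` must be a non-empty trial-event table.")
  }
  events <- validate_trial_events(events)
  cs_n <- dplyr::n_distinct(
    paste(events$subject_id, events$day, events$cs_duration)
  )
  if (cs_n != dplyr::n_distinct(paste(events$subject_id, events$day))) {
    abort_validation("`cs_duration` must be constant within each subject-day.")
  }
  events |>
    dplyr::group_by(.data$subject_id, .data$day) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      p_lever = mean(.data$lever_presses > 0),
      p_foodcup = mean(.data$foodcup_entries > 0),
      mean_lever_latency = mean(
        ifelse(is.na(.data$lever_latency), .data$cs_duration,
               .data$lever_latency)
      ),
      mean_foodcup_latency = mean(
        ifelse(is.na(.data$foodcup_latency), .data$cs_duration,
               .data$foodcup_latency)
      ),
      lever_presses = sum(.data$lever_presses),
      foodcup_entries = sum(.data$foodcup_entries),
      cs_duration = .data$cs_duration[1],
      .groups = "drop"
    ) |>
    dplyr::select(dplyr::all_of(session_summary_cols))
}

#' Response bias component
#'
#' Normalized preference for lever contacts over food-cup entries:
#' `(L - F) / (L + F)`. Undefined when no response of either kind occurred.
#'
#' @param lever_presses,foodcup_entries Non-negative total counts (vectors
#'   recycle as usual).
#' @return Scores in `[-1, 1]`.
#' @export
#' @examples
#' response_bias(10, 5) # 1/3
response_bias <- function(lever_presses, foodcup_entries) {
  if (any(lever_presses < 0) || any(foodcup_entries < 0)) {
    abort_validation("Counts must be >= 0.")
  }
  tot <- lever_presses + foodcup_entries
  if (any(tot == 0)) {
    abort(
      "Response bias is undefined when no lever press or food-cup entry occurred.",
      class = c("pavca_undefined_score", "pavca_validation_error")
    )
  }
  (lever_presses - foodcup_entries) / tot
}

#' Probability difference component
#'
#' Difference between the per-trial probability of at least one lever press
#' and of at least one CS food-cup entry.
#'
#' @param p_lever,p_foodcup Probabilities in `[0, 1]`.
#' @return Scores in `[-1, 1]`.
#' @export
probability_difference <- function(p_lever, p_foodcup) {
  if (any(p_lever < 0 | p_lever > 1) || any(p_foodcup < 0 | p_foodcup > 1)) {
    abort_validation("Probabilities must lie in [0, 1].")
  }
  p_lever - p_foodcup
}

#' Latency score component
#'
#' CS-duration-scaled difference between the mean latency to enter the food
#' cup and the mean latency to press the lever; faster lever approach gives a
#' more positive (sign-tracking) score.
#'
#' @param mean_lever_latency,mean_foodcup_latency Mean latencies in seconds,
#'   in `[0, cs_duration]` (no-response trials contribute `cs_duration`).
#' @param cs_duration CS duration in seconds (> 0).
#' @return Scores in `[-1, 1]`.
#' @export
#' @examples
#' latency_score(2, 8, 8) # 0.75
latency_score <- function(mean_lever_latency, mean_foodcup_latency,
                          cs_duration = 8) {
  if (any(cs_duration <= 0)) {
    abort_validation("`cs_duration` must be > 0.")
  }
  if (any(mean_lever_latency < 0 | mean_lever_latency > cs_duration) ||
      any(mean_foodcup_latency < 0 | mean_foodcup_latency > cs_duration)) {
    abort_validation("Mean latencies must lie in [0, cs_duration].")
  }
  (mean_foodcup_latency - mean_lever_latency) / cs_duration
}

#' PavCA index from the three components
#'
#' Equal-weight arithmetic mean of response bias, probability difference and
#' latency score.
#'
#' @param response_bias,probability_difference,latency_score Component
#'   scores in `[-1, 1]`.
#' @return Scores in `[-1, 1]`.
#' @export
pavca_index <- function(response_bias, probability_difference, latency_score) {
  check_unit_interval(response_bias, "response_bias")
  check_unit_interval(probability_difference, "probability_difference")
  check_unit_interval(latency_score, "latency_score")
  (response_bias + probability_difference + latency_score) / 3
}

#' Score session summaries
#'
#' Computes the three components and the PavCA index for each subject-day.
#' Sessions in which neither a lever press nor a food-cup entry occurred have
#' an undefined response bias; by default they are excluded with a message
#' reporting the count, or scored 0 with `undefined = "zero"`.
#'
#' @param summaries Session-summary tibble (see [summarize_sessions()]).
#' @param undefined Either `"exclude"` (default) or `"zero"`.
#' @return A score tibble with one row per scored subject-day; `day` is a
#'   character label.
#' @export
score_sessions <- function(summaries, undefined = c("exclude", "zero")) {
  undefined <- match.arg(undefined)
  if (!is.data.frame(summaries) || nrow(summaries) == 0) {
    abort_validation("`summaries` must be a non-empty session-summary table.")
  }
  key <- paste(summaries$subject_id, summaries$day, sep = "\r")
  if (anyDuplicated(key)) {
    abort_validation("Duplicate subject-day rows in `summaries`.")
  }
  silent <- summaries$lever_presses + summaries$foodcup_entries == 0
  if (any(silent)) {
    if (undefined == "exclude") {
      inform(sprintf(
        "Excluded %d session(s) with no responses of either kind (response bias undefined).",
        sum(silent)
      ))
      summaries <- summaries[!silent, ]
      if (nrow(summaries) == 0) {
        abort_validation("All sessions were unscorable (no responses).")
      }
      silent <- rep(FALSE, nrow(summaries))
    }
  }
  rb <- ifelse(
    silent, 0,
    (summaries$lever_presses - summaries$foodcup_entries) /
      pmax(summaries$lever_presses + summaries$foodcup_entries, 1)
  )
  pd <- probability_difference(summaries$p_lever, summaries$p_foodcup)
  ls <- latency_score(
    summaries$mean_lever_latency, summaries$mean_foodcup_latency,
    summaries$cs_duration
  )
  tibble(
    subject_id = summaries$subject_id,
    day = as.character(summaries$day),
    response_bias = rb,
    probability_difference = pd,
    latency_score = ls,
    pavca_index = pavca_index(rb, pd, ls)
  )
}

#' Score trial events end to end
#'
#' Convenience wrapper: [summarize_sessions()] then [score_sessions()].
#'
#' @inheritParams summarize_sessions
#' @inheritParams score_sessions
#' @return A score tibble.
#' @export
score_trial_events <- function(events, undefined = c("exclude", "zero")) {
  score_sessions(summarize_sessions(events), undefined = match.arg(undefined))
}

#' Day-window mean scores
#'
#' Per-subject arithmetic mean of the PavCA index (and component columns,
#' when present) over a window of training days, e.g. the conventional mean
#' of the last two days. Every subject must have a score on every requested
#' day; nothing is imputed.
#'
#' @param scores Score tibble with a character `day` column.
#' @param days Integer vector of days, e.g. `5:6`.
#' @return A score tibble with one row per subject and `day` set to the
#'   window label (`"5-6"`).
#' @export
day_window_mean <- function(scores, days) {
  if (length(days) < 1) {
    abort_validation("`days` must name at least one day.")
  }
  days <- sort(unique(as.integer(days)))
  scores <- as_tibble(scores)
  require_columns(scores, c("subject_id", "day", "pavca_index"), "<scores>")
  wanted <- scores[scores$day %in% as.character(days), ]
  counts <- table(wanted$subject_id)
  subjects <- unique(scores$subject_id)
  missing <- subjects[!(subjects %in% names(counts)) |
                        counts[subjects] < length(days)]
  if (length(missing) > 0) {
    abort_validation(sprintf(
      "Subject(s) missing scores for day window {%s}: %s.",
      paste(days, collapse = ","), paste(head(missing, 5), collapse = ", ")
    ))
  }
  label <- if (length(days) == 1) {
    as.character(days)
  } else {
    paste0(days[1], "-", days[length(days)])
  }
  value_cols <- intersect(
    c("response_bias", "probability_difference", "latency_score",
      "pavca_index"),
    names(wanted)
  )
  wanted |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(value_cols), mean),
      .groups = "drop"
    ) |>
    dplyr::mutate(day = label, .after = "subject_id")
}
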