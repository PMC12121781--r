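test_that("session summaries aggregate counts, probabilities and latencies", {
  events <- make_session(
    "r1", 3, lever_presses = c(1, 0), foodcup_entries = c(2, 3),
    lever_latency = c(2, NA), foodcup_latency = c(1, 1.5)
  )
  s <- summarize_sessions(events)
  expect_equal(s$n_trials, 2L)
  expect_equal(s$lever_presses, 1L)
  expect_equal(s$foodcup_entries, 5L)
  expect_equal(s$p_lever, 0.5)
  expect_equal(s$p_foodcup, 1)
  expect_equal(s$mean_lever_latency, (2 + 8) / 2) # CS ends unanswered -> 8
  expect_equal(s$mean_foodcup_latency, 1.25)

  silent <- make_session("r1", 1, lever_presses = c(0, 0),
                         foodcup_entries = c(0, 0))
  s0 <- summarize_sessions(silent)
  expect_equal(s0$p_lever, 0)
  expect_equal(s0$mean_lever_latency, 8)
  expect_equal(s0$mean_foodcup_latency, 8)

  expect_error(summarize_sessions(tibble::tibble()),
               class = "pavca_validation_error")
})

test_that("component formulas match hand arithmetic and their symmetries", {
  expect_equal(response_bias(10, 5), 1 / 3)
  expect_equal(response_bias(0, 7), -1)
  expect_error(response_bias(0, 0), class = "pavca_undefined_score")

  expect_equal(probability_difference(1, 0.2), 0.8)
  expect_equal(probability_difference(0.4, 0.4), 0)
  expect_equal(probability_difference(0, 1), -1)
  expect_error(probability_difference(1.2, 0),
               class = "pavca_validation_error")

  expect_equal(latency_score(2, 8, 8), 0.75)
  expect_equal(latency_score(3, 3, 8), 0)
  expect_error(latency_score(2, 4, 0), class = "pavca_validation_error")

  expect_equal(pavca_index(1, 1, 1), 1)
  expect_equal(pavca_index(1 / 3, 0.2, 0.15), mean(c(1 / 3, 0.2, 0.15)))
  expect_equal(pavca_index(-0.2, -0.4, -0.6),
               -pavca_index(0.2, 0.4, 0.6))
  expect_error(pavca_index(1.5, 0, 0), class = "pavca_validation_error")
})

test_that("endpoint sessions score exactly +1 / -1", {
  # Lever response on every trial at CS onset, no food-cup entries.
  st <- make_session(
    "r1", 5, lever_presses = rep(2, 10), foodcup_entries = rep(0, 10),
    lever_latency = rep(0, 10)
  )
  expect_equal(score_trial_events(st)$pavca_index, 1)
  gt <- make_session(
    "r1", 5, lever_presses = rep(0, 10), foodcup_entries = rep(2, 10),
    foodcup_latency = rep(0, 10)
  )
  expect_equal(score_trial_events(gt)$pavca_index, -1)
})

test_that("exchanging event streams negates components and index", {
  withr::with_seed(42, {
    for (i in 1:200) {
      ev <- random_session()
      a <- score_trial_events(ev)
      b <- score_trial_events(swap_streams(ev))
      for (col in c("response_bias", "probability_difference",
                    "latency_score", "pavca_index")) {
        expect_lt(abs(a[[col]] + b[[col]]), 1e-12)
      }
      expect_true(all(abs(a$pavca_index) <= 1))
    }
  })
})

test_that("score_sessions handles cardinality, exclusions and duplicates", {
  withr::with_seed(5, {
    events <- dplyr::bind_rows(lapply(1:6, function(d) {
      dplyr::bind_rows(lapply(sprintf("s%02d", 1:8), function(s) {
        random_session(s, d)
      }))
    }))
  })
  scores <- score_trial_events(events)
  expect_equal(nrow(scores), 48)

  summaries <- summarize_sessions(events)
  silent_row <- summaries[1, ]
  silent_row$subject_id <- "mute"
  silent_row[c("lever_presses", "foodcup_entries", "p_lever",
               "p_foodcup")] <- list(0L, 0L, 0, 0)
  silent_row[c("mean_lever_latency", "mean_foodcup_latency")] <- list(8, 8)
  expect_message(
    out <- score_sessions(dplyr::bind_rows(summaries, silent_row)),
    "Excluded 1 session"
  )
  expect_equal(nrow(out), 48)
  out0 <- score_sessions(dplyr::bind_rows(summaries, silent_row),
                         undefined = "zero")
  expect_equal(nrow(out0), 49)
  expect_equal(out0$pavca_index[out0$subject_id == "mute"], 0)

  expect_error(score_sessions(dplyr::bind_rows(summaries, summaries[1, ])),
               "Duplicate", class = "pavca_validation_error")
})

test_that("day-window means average per subject and refuse missing days", {
  scores <- tibble::tibble(
    subject_id = rep(c("a", "b"), each = 2),
    day = rep(c("5", "6"), 2),
    pavca_index = c(0.2, 0.6, -0.4, -0.2)
  )
  w <- day_window_mean(scores, 5:6)
  expect_equal(w$day, rep("5-6", 2))
  expect_equal(sort(w$pavca_index), c(-0.3, 0.4))

  one <- day_window_mean(scores, 5)
  expect_equal(one$pavca_index[one$subject_id == "a"], 0.2)

  expect_error(day_window_mean(scores[-1, ], 5:6), "missing scores",
               class = "pavca_validation_error")
})

test_that("window means match brute-force recomputation from summaries", {
  withr::with_seed(9, {
    events <- dplyr::bind_rows(lapply(1:5, function(d) {
      dplyr::bind_rows(lapply(c("x", "y", "z"), function(s) {
        random_session(s, d)
      }))
    }))
  })
  scores <- score_trial_events(events)
  w <- day_window_mean(scores, 4:5)
  manual <- vapply(c("x", "y", "z"), function(s) {
    mean(scores$pavca_index[scores$subject_id == s & scores$day %in% c("4", "5")])
  }, numeric(1))
  expect_equal(w$pavca_index[match(c("x", "y", "z"), w$subject_id)],
               unname(manual))
})
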