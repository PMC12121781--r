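# Fixtures and independent oracles used across the suite. Everything is
# built in code; no data files.

# A single subject-day of trial events from parallel vectors; NA latency
# means the behavior did not occur on that trial.
make_session <- function(subject_id = "r1", day = 1,
                         lever_presses, foodcup_entries,
                         lever_latency = NULL, foodcup_latency = NULL,
                         cs_duration = 8) {
  n <- length(lever_presses)
  lever_latency <- lever_latency %||%
    ifelse(lever_presses > 0, cs_duration / 2, NA_real_)
  foodcup_latency <- foodcup_latency %||%
    ifelse(foodcup_entries > 0, cs_duration / 2, NA_real_)
  tibble::tibble(
    subject_id = subject_id, day = as.integer(day), trial = seq_len(n),
    lever_presses = as.integer(lever_presses),
    foodcup_entries = as.integer(foodcup_entries),
    lever_latency = lever_latency, foodcup_latency = foodcup_latency,
    cs_duration = cs_duration
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random well-formed session for property tests: independent counts and
# latencies per trial. Guaranteed scorable (at least one response somewhere).
random_session <- function(subject_id = "r1", day = 1, n_trials = 10,
                           cs_duration = 8) {
  repeat {
    lp <- rpois(n_trials, 1.5)
    fc <- rpois(n_trials, 1.5)
    if (sum(lp) + sum(fc) > 0) break
  }
  make_session(
    subject_id, day, lp, fc,
    lever_latency = ifelse(lp > 0, runif(n_trials, 0, cs_duration), NA_real_),
    foodcup_latency = ifelse(fc > 0, runif(n_trials, 0, cs_duration), NA_real_),
    cs_duration = cs_duration
  )
}

# Swap the lever and food-cup event streams of a session.
swap_streams <- function(events) {
  swapped <- events
  swapped$lever_presses <- events$foodcup_entries
  swapped$foodcup_entries <- events$lever_presses
  swapped$lever_latency <- events$foodcup_latency
  swapped$foodcup_latency <- events$lever_latency
  swapped
}

# Exhaustive 1D k-means oracle: the optimal k-partition of points on a line
# is contiguous in sorted order, so enumerate all contiguous 3-partitions
# and return the minimal total within-cluster sum of squares.
dp_kmeans3_wss <- function(x) {
  x <- sort(x)
  n <- length(x)
  stopifnot(n >= 3)
  seg_wss <- function(i, j) {
    seg <- x[i:j]
    sum((seg - mean(seg))^2)
  }
  best <- Inf
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      w <- seg_wss(1, i) + seg_wss(i + 1, j) + seg_wss(j + 1, n)
      if (w < best) best <- w
    }
  }
  best
}

# Exact two-sided binomial McNemar p by full enumeration of the null.
enumerate_mcnemar_p <- function(b, cc) {
  n <- b + cc
  probs <- vapply(0:n, function(k) choose(n, k) * 0.5^n, numeric(1))
  m <- min(b, cc)
  min(1, 2 * sum(probs[0:m + 1]))
}

# Quadrature oracle: integrate the exact mixture-of-kernels density.
kde_mass_quadrature <- function(x, h, lo, hi) {
  stats::integrate(
    function(t) {
      vapply(t, function(ti) mean(stats::dnorm(ti - x, sd = h)), numeric(1))
    },
    lo, hi, rel.tol = 1e-9
  )$value
}

trapezoid <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

balanced_accuracy <- function(truth, predicted) {
  sens <- mean(predicted[truth])
  spec <- mean(!predicted[!truth])
  (sens + spec) / 2
}
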