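# Seeded generators providing ground truth for the pipeline:
#   * score-level samples from bounded skew-normal mixtures (the shapes a
#     pooled or single-colony PavCA sample shows: bimodal, possibly skewed);
#   * trial-level cohorts with latent phenotypes, a logistic learning curve
#     that starts goal-tracking-biased and relaxes toward the latent bias,
#     Poisson response counts and truncated-exponential latencies.
# The trial model is a package invention; its contract is to reproduce the
# qualitative structure the classification methods assume (bounded bimodal
# end-of-training scores, early GT lean, stable phenotypes by days 4-6), not
# any particular animal dataset.

#' Specify a bounded skew-normal mixture
#'
#' @param components Data frame with columns `weight`, `mean` (location),
#'   `sd` (scale) and `skew` (skew-normal shape; 0 = Gaussian).
#' @param bounds Support bounds, default `c(-1, 1)`; draws are truncated into
#'   them by rejection.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return A `pavca_mixture_spec` list.
#' @export
mixture_spec <- function(components, bounds = c(-1, 1), n = 100, seed = NULL) {
  components <- as_tibble(components)
  require_columns(components, c("weight", "mean", "sd"), "<components>")
  if (!"skew" %in% names(components)) components$skew <- 0
  if (abs(sum(components$weight) - 1) > 1e-8 || any(components$weight < 0)) {
    abort_validation("Component weights must be >= 0 and sum to 1.")
  }
  if (any(components$sd <= 0)) {
    abort_validation("Component `sd` must be > 0.")
  }
  if (length(bounds) != 2 || bounds[1] >= bounds[2]) {
    abort_validation("`bounds` must be c(lo, hi) with lo < hi.")
  }
  structure(
    list(components = components, bounds = bounds, n = n, seed = seed),
    class = "pavca_mixture_spec"
  )
}

# Skew-normal draws via the delta representation:
# Z = delta |U0| + sqrt(1 - delta^2) U1, delta = alpha / sqrt(1 + alpha^2),
# then location-scale. Truncation to [lo, hi] by rejection.
rsn_truncated <- function(n, location, scale, alpha, lo, hi) {
  delta <- alpha / sqrt(1 + alpha^2)
  out <- numeric(0)
  guard <- 0
  while (length(out) < n) {
    m <- max(2 * (n - length(out)), 16)
    u0 <- abs(rnorm(m))
    u1 <- rnorm(m)
    z <- delta * u0 + sqrt(1 - delta^2) * u1
    x <- location + scale * z
    out <- c(out, x[x >= lo & x <= hi])
    guard <- guard + 1
    if (guard > 1000) {
      abort_validation(
        "Mixture component places essentially no mass inside the bounds."
      )
    }
  }
  out[seq_len(n)]
}

rnorm_truncated <- function(n, mean, sd, lo = -1, hi = 1) {
  rsn_truncated(n, mean, sd, alpha = 0, lo = lo, hi = hi)
}

#' Draw scores from a bounded mixture
#'
#' @param spec A `pavca_mixture_spec`.
#' @return Numeric vector of `spec$n` scores inside the bounds;
#'   deterministic given `spec$seed`.
#' @export
simulate_scores <- function(spec) {
  if (!inherits(spec, "pavca_mixture_spec")) {
    abort_validation("`spec` must come from mixture_spec().")
  }
  comp <- spec$components
  with_seed(spec$seed, {
    idx <- sample.int(nrow(comp), spec$n, replace = TRUE, prob = comp$weight)
    counts <- tabulate(idx, nbins = nrow(comp))
    draws <- vector("list", nrow(comp))
    for (j in seq_len(nrow(comp))) {
      if (counts[j] > 0) {
        draws[[j]] <- rsn_truncated(
          counts[j], comp$mean[j], comp$sd[j], comp$skew[j],
          spec$bounds[1], spec$bounds[2]
        )
      } else {
        draws[[j]] <- numeric(0)
      }
    }
    out <- numeric(spec$n)
    for (j in seq_len(nrow(comp))) {
      out[idx == j] <- draws[[j]]
    }
    out
  })
}

#' Specify a trial-level synthetic cohort
#'
#' Each subject carries a latent approach bias `theta` in `[-1, 1]` drawn
#' from its phenotype's truncated normal. The bias expressed on day `d` is
#' `beta(d) = beta0 + (theta - beta0) * s(d)` with the logistic learning
#' curve `s(d) = 1 / (1 + exp(-(d - d0)/tau))`: training starts with a
#' goal-tracking lean (`beta0 < 0`, the food cup is familiar from
#' pre-training) and converges to the latent bias. Per trial, a lever
#' response occurs with probability `(1 + beta)/2` and a food-cup response
#' with probability `(1 - beta)/2`; a responding behavior contributes
#' `1 + Poisson(lambda * p)` events and a latency drawn from an exponential
#' truncated to `(0, cs_duration]` whose rate grows with `p` (stronger
#' tendencies respond faster).
#'
#' @param n_subjects Number of subjects.
#' @param weights Named phenotype weights `c(ST=, IN=, GT=)`, summing to 1.
#' @param theta_mean,theta_sd Named numeric vectors (`ST`, `IN`, `GT`) giving
#'   each phenotype's latent-bias truncated normal.
#' @param n_days Training days (default 6).
#' @param trials_per_day Trials per session (default 25).
#' @param cs_duration CS duration in seconds (default 8).
#' @param d0,tau Learning-curve midpoint day and rate (defaults 2.5, 0.8,
#'   stabilizing expressed bias around days 4-5).
#' @param beta0 Initial expressed bias (default -0.4, a GT lean).
#' @param lambda_lever,lambda_foodcup Poisson rate scale for extra responses
#'   per responding trial (defaults 4).
#' @param latency_rate_base,latency_rate_slope Truncated-exponential latency
#'   rate `base + slope * p` per second (defaults 0.25 and 1.5).
#' @param iti_range Inter-trial interval bounds in seconds, metadata only
#'   (default `c(30, 90)`; ITI behavior is not simulated).
#' @param seed Optional integer seed.
#' @return A `pavca_cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects,
                        weights = c(ST = 1 / 3, IN = 1 / 3, GT = 1 / 3),
                        theta_mean = c(ST = 0.65, IN = 0, GT = -0.65),
                        theta_sd = c(ST = 0.15, IN = 0.12, GT = 0.15),
                        n_days = 6, trials_per_day = 25, cs_duration = 8,
                        d0 = 2.5, tau = 0.8, beta0 = -0.4,
                        lambda_lever = 4, lambda_foodcup = 4,
                        latency_rate_base = 0.25, latency_rate_slope = 1.5,
                        iti_range = c(30, 90), seed = NULL) {
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < 0)) {
    abort_validation("Phenotype weights must be >= 0 and sum to 1.")
  }
  if (!all(phenotype_levels %in% names(weights)) ||
      !all(phenotype_levels %in% names(theta_mean)) ||
      !all(phenotype_levels %in% names(theta_sd))) {
    abort_validation(
      "`weights`, `theta_mean`, `theta_sd` need names ST, IN, GT."
    )
  }
  if (trials_per_day < 1 || n_days < 1 || n_subjects < 1) {
    abort_validation("Cohort dimensions must be >= 1.")
  }
  if (beta0 < -1 || beta0 > 1) {
    abort_validation("`beta0` must lie in [-1, 1].")
  }
  structure(
    list(
      n_subjects = n_subjects, weights = weights,
      theta_mean = theta_mean, theta_sd = theta_sd,
      n_days = n_days, trials_per_day = trials_per_day,
      cs_duration = cs_duration, d0 = d0, tau = tau, beta0 = beta0,
      lambda_lever = lambda_lever, lambda_foodcup = lambda_foodcup,
      latency_rate_base = latency_rate_base,
      latency_rate_slope = latency_rate_slope,
      iti_range = iti_range, seed = seed
    ),
    class = "pavca_cohort_spec"
  )
}

rexp_truncated <- function(n, rate, hi) {
  u <- runif(n)
  -log(1 - u * (1 - exp(-rate * hi))) / rate
}

#' Simulate a trial-level cohort
#'
#' @param spec A `pavca_cohort_spec`.
#' @return A list with `events` (validated trial-event tibble of
#'   `n_subjects * n_days * trials_per_day` rows) and `subjects` (tibble of
#'   `subject_id`, latent `phenotype`, `theta`). Deterministic given
#'   `spec$seed`.
#' @export
simulate_trial_cohort <- function(spec) {
  if (!inherits(spec, "pavca_cohort_spec")) {
    abort_validation("`spec` must come from cohort_spec().")
  }
  with_seed(spec$seed, {
    phen <- sample(
      phenotype_levels, spec$n_subjects, replace = TRUE,
      prob = spec$weights[phenotype_levels]
    )
    theta <- vapply(phen, function(p) {
      rnorm_truncated(1, spec$theta_mean[[p]], spec$theta_sd[[p]])
    }, numeric(1), USE.NAMES = FALSE)
    subjects <- tibble(
      subject_id = sprintf("s%03d", seq_len(spec$n_subjects)),
      phenotype = phen,
      theta = theta
    )
    grid <- tidyr::expand_grid(
      subject_id = subjects$subject_id,
      day = seq_len(spec$n_days),
      trial = seq_len(spec$trials_per_day)
    )
    th <- theta[match(grid$subject_id, subjects$subject_id)]
    s_d <- 1 / (1 + exp(-(grid$day - spec$d0) / spec$tau))
    beta <- spec$beta0 + (th - spec$beta0) * s_d
    p_lever <- (1 + beta) / 2
    p_food <- (1 - beta) / 2
    n <- nrow(grid)
    lever_resp <- rbinom(n, 1, p_lever) == 1
    food_resp <- rbinom(n, 1, p_food) == 1
    lever_presses <- ifelse(
      lever_resp, 1L + rpois(n, spec$lambda_lever * p_lever), 0L
    )
    foodcup_entries <- ifelse(
      food_resp, 1L + rpois(n, spec$lambda_foodcup * p_food), 0L
    )
    lever_rate <- spec$latency_rate_base + spec$latency_rate_slope * p_lever
    food_rate <- spec$latency_rate_base + spec$latency_rate_slope * p_food
    lever_latency <- ifelse(
      lever_resp, rexp_truncated(n, lever_rate, spec$cs_duration), NA_real_
    )
    foodcup_latency <- ifelse(
      food_resp, rexp_truncated(n, food_rate, spec$cs_duration), NA_real_
    )
    events <- tibble(
      subject_id = grid$subject_id,
      day = as.integer(grid$day),
      trial = as.integer(grid$trial),
      lever_presses = as.integer(lever_presses),
      foodcup_entries = as.integer(foodcup_entries),
      lever_latency = lever_latency,
      foodcup_latency = foodcup_latency,
      cs_duration = spec$cs_duration
    )
    list(events = validate_trial_events(events), subjects = subjects)
  })
}

#' Cohort presets emulating the two study-sample shapes
#'
#' `modeling_like` emulates a large pooled sample (189 subjects): broad,
#' mildly sign-tracker-skewed bimodal end-of-training scores.
#' `validation_like` emulates a small single-colony sample (34 subjects)
#' with a narrower, leptokurtic and skewed shape whose goal-tracker mode
#' sits well inside -0.5, the situation in which the fixed rule folds most
#' goal-trackers into the intermediate group.
#'
#' @param name `"modeling_like"` or `"validation_like"`.
#' @param seed Integer seed; defaults keep each preset fully reproducible.
#' @return A `pavca_cohort_spec`.
#' @export
cohort_preset <- function(name = c("modeling_like", "validation_like"),
                          seed = NULL) {
  name <- match.arg(name)
  switch(
    name,
    modeling_like = cohort_spec(
      n_subjects = 189,
      weights = c(ST = 0.42, IN = 0.28, GT = 0.30),
      theta_mean = c(ST = 0.60, IN = 0.05, GT = -0.60),
      theta_sd = c(ST = 0.18, IN = 0.18, GT = 0.16),
      seed = seed %||% 20210601
    ),
    validation_like = cohort_spec(
      n_subjects = 34,
      weights = c(ST = 0.44, IN = 0.23, GT = 0.33),
      theta_mean = c(ST = 0.55, IN = 0.12, GT = -0.42),
      theta_sd = c(ST = 0.12, IN = 0.10, GT = 0.10),
      seed = seed %||% 20220701
    )
  )
}
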