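---
title: "Distribution-driven classification of sign- and goal-tracking: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distribution-driven classification of sign- and goal-tracking: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In Pavlovian conditioned approach (PavCA) experiments, an illuminated lever
(the conditioned stimulus, CS, presented for 8 s) predicts delivery of a food
pellet into a food cup. Rats diverge: *sign-trackers* (ST) approach and press
the lever itself, *goal-trackers* (GT) head for the food cup, and an
*intermediate* (IN) group shows no strong bias. Subjects are conventionally
classified by thresholding the PavCA index at ±0.5, but the shape of the
index distribution varies across colonies, vendors and laboratories —
skewed, leptokurtic, or shifted — and fixed cutoffs then misassign subjects,
most visibly by folding a skewed GT mode into the IN band. This package
implements two distribution-driven alternatives — cutoffs read from the
first derivative of a kernel density estimate, and cutoffs from the decision
boundaries of a 1D k-means clustering — together with the scoring pipeline
that produces the index from trial-level events, McNemar comparisons of the
resulting memberships, and a synthetic cohort simulator that provides ground
truth for every step.

## The PavCA index

For one subject-day session with per-trial lever-press and food-cup-entry
counts and first-response latencies, three components are computed:

* **response bias** $(L - F)/(L + F)$, from the session totals $L$ (lever
  presses) and $F$ (CS food-cup entries);
* **probability difference** $P(\text{lever trial}) - P(\text{food-cup
  trial})$, the difference in the fraction of trials with at least one
  response of each kind;
* **latency score** $(\bar\ell_{food} - \bar\ell_{lever}) / \text{cs}$,
  where each mean latency averages per-trial latencies with the CS duration
  (8 s) substituted on trials without that response — the CS ended
  unanswered.

The index is their equal-weight mean, bounded in $[-1, 1]$: $+1$ is a pure
sign-tracker, $-1$ a pure goal-tracker. Two conventions deserve note:

* A latency of **0 is legal** and means the response occurred at CS onset.
  This makes the endpoints exactly attainable: a subject that presses on
  every trial at onset and never enters the cup scores exactly $+1$, and
  exchanging the two event streams exactly negates every component (the
  package's antisymmetry property).
* A session with **no responses of either kind** has an undefined response
  bias. Such sessions are excluded from scoring with a reported count
  (default), or scored 0 behind the `undefined = "zero"` flag; silently
  inventing a preference is never done.

Classification is performed on per-day scores or, following common practice
after scores stabilize around days 4–5, on the per-subject mean of the last
training days (`day_window_mean()`, e.g. days 5–6).

## The derivative method

`derivative_cutoffs()` proceeds in four steps.

1. **Kernel density estimate.** Exact Gaussian-mixture evaluation on an even
   grid of `n_grid = 100` points spanning $[\min - 3h, \max + 3h]$. The
   bandwidth defaults to the classic robust Silverman rule of thumb
   $h = 0.9\,\min(\hat\sigma, \mathrm{IQR}/1.349)\, n^{-1/5}$ and is always
   reported in the output. Support is unbounded by default — constraining
   the domain condenses and distorts boundary estimates — but
   `support = c(-1, 1)` is available (mass preserved by reflection at the
   bounds) for users focused on the most extreme trackers.
2. **Discrete first derivative.** Forward differences
   $\Delta f / \Delta x$ at interval midpoints.
3. **Extrema with a prominence floor.** Local maxima/minima of the
   derivative by discrete sign change, scanning left to right; adjacent
   extrema pairs whose value gap is below `min_prominence` (default 5%) of
   $\max |df/dx|$ are removed smallest-gap first. This persistence-style
   simplification is monotone in the threshold and suppresses sampling
   wiggles without moving genuine flanks.
4. **Cutoffs.** On a bimodal density the derivative shows the pattern
   max–min–max–min. The **first local minimum** (steepest descent of the GT
   mode) is the GT cutoff; the **second local maximum** (steepest ascent of
   the ST mode) is the ST cutoff. Cutoffs are reported at the interval
   midpoint where the discrete extremum occurs.

A distribution that does not support this reading raises a
`pavca_not_bimodal` error recommending the k-means method or a different
bandwidth — never a silent fallback. The gate requires, beyond the extremum
pattern itself, that the density shows at least two modes whose topographic
prominence clears 5% of the density maximum and that both cutoffs lie
strictly between the outer modes; without the second condition, a wiggly
estimate of a unimodal sample can exhibit the bare max/min/max pattern.

Peak diagnostics (`density_peak_stats()`) report each mode's location and
its width at the half-prominence reference line, the convention of standard
peak-finding tools. One consequence worth knowing: the tallest peak's
prominence is measured from the curve minimum, so when the inter-mode saddle
sits above its half-prominence line the reported width spans past the
neighboring mode. The width is a dispersion diagnostic, not a boundary.

## 1D and 3D k-means

`kmeans_cutoffs_1d()` clusters the scores with $k = 3$ (the three groups the
field uses — $k$ is fixed by design, not selected) and orders clusters by
ascending centroid as GT, IN, ST. In one dimension the nearest-centroid
decision boundary between adjacent clusters is exactly the midpoint of
their centroids, so the two midpoints are the GT and ST cutoffs. This
midpoint rule reproduces published cutoff tables from their printed centroid
triples for two of three single-day rows at two-decimal display rounding
(round-half-away-from-zero); the third printed GT value differs from the
midpoint of its printed centroids by 0.015, and since the underlying raw
data are not deposited the exact edge rule used there cannot be confirmed.
The alternative (extreme member scores) is noted but not implemented.

The clustering engine is Lloyd's algorithm with k-means++ seeding, 10
restarts (best total within-cluster sum of squares kept), an explicit seed,
and farthest-point re-seeding of clusters emptied during iteration. Within-
cluster dispersion (Sum D) is the sum of *squared* point-to-centroid
distances, the common default of the clustering tools used in this
literature; the test suite checks the engine against an exhaustive
dynamic-programming 1D oracle (optimal 1D partitions are contiguous in
sorted order).

`kmeans_labels_3d()` clusters instead on the three raw features behind the
index (latency score, lever presses, food-cup entries) and maps clusters to
phenotypes by ascending mean index of their members. Features are used raw
by default, mirroring the published analysis; because the count dimensions
dominate the latency dimension at raw scale, `standardize = TRUE` is
provided. The 3D boundaries need not be linear in the index.

## Boundary conventions and method comparison

The literature's fixed rule is **inclusive** at its bounds (a score of
exactly 0.5 is ST, −0.5 is GT); data-driven cutoffs are **strict** (a score
equal to a cutoff is IN), matching how cutoff tables print them
(`> 0.34`, `< -0.22`). Both conventions are documented on their classifiers
and configurable.

`compare_methods()` applies each method to the same sample and compares
per-group memberships pairwise with McNemar tests on the paired 2×2 table of
discordant memberships: exact two-sided binomial
$p = \min(1,\, 2\,P(X \le \min(b,c)))$, $X \sim \mathrm{Bin}(b+c, 1/2)$,
when $b + c \le 25$ (the conventional switch point of the statistics
package used in this literature), otherwise the continuity-corrected
$\chi^2 = (|b-c|-1)^2/(b+c)$ on 1 df. Zero discordance yields $p = 1$ with
an explicit "no discordance" flag rather than a statistic. The default
significance level is 0.01, the predefined threshold for repeated testing
on one sample; no further multiplicity correction is applied. A derivative
method that fails its bimodality check is recorded in the report and the
comparison proceeds with the remaining methods.

## The synthetic cohort simulator

No trial-level behavioral data are deposited for the samples that motivated
these methods, so the package ships a generative model whose only contract
is to reproduce the qualitative structure the methods assume. Each subject
draws a latent bias $\theta \in [-1, 1]$ from its phenotype's truncated
normal. The bias expressed on day $d$ is

$$\beta(d) = \beta_0 + (\theta - \beta_0)\, s(d), \qquad
  s(d) = \frac{1}{1 + e^{-(d - d_0)/\tau}},$$

with $\beta_0 = -0.4$ (training starts with a goal-tracking lean — the food
cup is familiar from pre-training), midpoint $d_0 = 2.5$ and rate
$\tau = 0.8$, so expressed bias stabilizes near $\theta$ around days 4–5.
Per trial, a lever response occurs with probability $(1+\beta)/2$ and a
food-cup response with probability $(1-\beta)/2$; a responding behavior
contributes $1 + \mathrm{Poisson}(\lambda p)$ events ($\lambda = 4$) and a
latency from an exponential truncated to $(0, 8]$ with rate
$0.25 + 1.5\,p$ s$^{-1}$ — stronger tendencies respond faster. Sessions are
6 days × 25 trials of an 8-s CS; the 30–90 s inter-trial interval is
metadata only, since no ITI behavior is scored. All draws are seeded.

Two presets emulate the two study-sample shapes at their sample sizes:
`modeling_like` (189 subjects; broad, mildly ST-skewed bimodal scores,
phenotype weights 0.42/0.28/0.30 for ST/IN/GT) and `validation_like`
(34 subjects; narrower, skewed, with the GT mode centered near −0.45 so the
fixed ±0.5 rule folds most goal-trackers into IN). These weights and latent
means were chosen once to realize those qualitative shapes and are not
calibrated to any published table. A score-level generator
(`mixture_spec()` / `simulate_scores()`) draws directly from bounded
skew-normal mixtures (delta-representation sampling, rejection truncation)
when trial-level structure is not needed.

What the simulator does **not** emulate: sex or feeding-schedule effects,
inter-trial-interval behavior, session-to-session autocorrelation beyond
the learning curve, apparatus artifacts, or any mechanistic model of
incentive salience. Passing tests therefore demonstrate correctness of the
*methods* under controlled, realistic-shaped inputs — not that any
particular laboratory's data will be bimodal.

## The regression experiment and known limitations

The end-to-end regression test simulates 200 subjects with well-separated
latent phenotypes ($\theta_{ST} \sim TN(0.65, 0.15)$,
$\theta_{GT} \sim TN(-0.65, 0.15)$, $\theta_{IN} \sim TN(0, 0.12)$, weights
0.4/0.2/0.4), scores them, averages days 5–6, classifies with the
derivative method, and requires balanced accuracy ≥ 0.9 for both ST and GT
membership at a fixed seed. The IN share is kept at 20% deliberately: the
derivative method presumes a *bimodal* distribution, and that is what
"well-separated phenotypes" means distributionally. With a full-sized IN
group the middle of the distribution can form a third mode; the "second
local maximum" of the derivative then sits on the IN mode's rising flank
and the ST cutoff collapses inward. This is the method's main failure mode,
it is seed-visible in simulations, and it is the situation in which the
k-means cutoffs (which do not care about modality) are the better tool —
running both and inspecting where the cutoffs fall on the distribution is
the recommended practice.

Other numerical choices, in brief: scores are never rounded in storage
(display rounding is round-half-away-from-zero at 2 decimals, matching
printed tables); CSV tables serialize doubles at 12 significant digits,
which makes write→read→write byte-identical; ties in discrete extremum
positions resolve to the interval midpoint; duplicate subject-day rows,
out-of-range scores, and latency/count inconsistencies are hard errors with
row-numbered diagnostics, never silent coercions. Problem sizes used in the
test suite (cohorts of 34–200 subjects, mixtures of up to 2000 draws, 100
random k-means instances against the exhaustive oracle) were chosen as the
smallest sizes at which the distributional properties under test are
stable.

## A worked example

```{r, eval = FALSE}
library(pavca)

sim <- simulate_trial_cohort(cohort_preset("modeling_like"))
window <- sim$events |>
  score_trial_events() |>
  day_window_mean(5:6)

ct <- derivative_cutoffs(window)
tidy(ct)
autoplot(ct)

report <- compare_methods(window, seed = 1)
report$frequencies
tidy(report)
```
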