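Package: pavca
Title: Distribution-Driven Classification of Sign- and Goal-Tracking Phenotypes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for objective classification of Pavlovian conditioned
    approach (PavCA) phenotypes. Computes the PavCA Index from trial-level
    operant conditioning events (response bias, probability difference and
    latency score averaged per subject and day), determines sign-tracker and
    goal-tracker cutoff values from the shape of the score distribution --
    either from the first derivative of a kernel density estimate or from the
    decision boundaries of a 1D k-means clustering -- applies the conventional
    fixed +/-0.5 rule, and compares the resulting group memberships with
    McNemar tests. Includes a seeded synthetic cohort simulator with latent
    phenotypes and a learning trajectory so the full pipeline can be exercised
    and validated without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
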