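test_that("fixed classification is inclusive at its bounds", {
  labs <- classify_fixed(c(0.5, -0.5, 0, 0.49, -0.49, 1, -1))
  expect_equal(labs$label, c("ST", "GT", "IN", "IN", "IN", "ST", "GT"))
  expect_error(classify_fixed(0.2, bound = 0), class = "pavca_validation_error")
  expect_error(classify_fixed(0.2, bound = 1), class = "pavca_validation_error")
  expect_error(classify_fixed(1.4), class = "pavca_validation_error")
})

test_that("data-driven classification is strict at its cutoffs", {
  ct <- cutoff_pair(-0.22, 0.34)
  labs <- classify_with_cutoffs(c(0.34, -0.22, 0.341, -0.221, 0), ct)
  expect_equal(labs$label, c("IN", "IN", "ST", "GT", "IN"))
  expect_error(cutoff_pair(0.5, 0.2), class = "pavca_validation_error")

  # labels partition the sample
  withr::with_seed(13, x <- runif(200, -1, 1))
  labs <- classify_with_cutoffs(x, ct)
  expect_equal(nrow(labs), 200)
  expect_true(all(labs$label %in% c("GT", "IN", "ST")))
})

test_that("labels are monotone in score for 1D methods", {
  withr::with_seed(19, x <- runif(300, -1, 1))
  for (labs in list(classify_fixed(x), classify_with_cutoffs(x, cutoff_pair(-0.3, 0.25)))) {
    gt_max <- suppressWarnings(max(labs$pavca_index[labs$label == "GT"]))
    in_rng <- suppressWarnings(range(labs$pavca_index[labs$label == "IN"]))
    st_min <- suppressWarnings(min(labs$pavca_index[labs$label == "ST"]))
    expect_lt(gt_max, in_rng[1])
    expect_lt(in_rng[2], st_min)
  }
})

test_that("group frequencies count every subject exactly once", {
  expect_equal(
    group_frequencies(c("ST", "ST", "GT", "IN")),
    tibble::tibble(n_ST = 2L, n_GT = 1L, n_IN = 1L)
  )
  expect_equal(unlist(group_frequencies(character(0))),
               c(n_ST = 0L, n_GT = 0L, n_IN = 0L))
  withr::with_seed(3, {
    for (i in 1:10) {
      labs <- sample(c("GT", "IN", "ST"), sample(1:50, 1), replace = TRUE)
      expect_equal(sum(unlist(group_frequencies(labs))), length(labs))
    }
  })
})

test_that("McNemar branches match their closed forms", {
  # exact branch: b = 1, c = 5 -> 2 * P(X <= 1 | Bin(6, 1/2)) = 0.21875
  make_labels <- function(b, cc, conc_in = 4, conc_out = 4) {
    a <- c(rep("ST", b), rep("IN", cc), rep("ST", conc_in), rep("IN", conc_out))
    b_ <- c(rep("IN", b), rep("ST", cc), rep("ST", conc_in), rep("IN", conc_out))
    list(a = a, b = b_)
  }
  l <- make_labels(1, 5)
  t1 <- mcnemar_test(l$a, l$b, "ST")
  expect_equal(t1$p_value, 0.21875)
  expect_equal(t1$variant, "exact")
  expect_equal(t1$b + t1$c + t1$concordant, length(l$a))

  l2 <- make_labels(4, 4)
  expect_equal(mcnemar_test(l2$a, l2$b, "ST")$p_value, 1)

  # asymptotic branch: b = 20, c = 40 -> chi2 = 19^2/60
  l3 <- make_labels(20, 40)
  t3 <- mcnemar_test(l3$a, l3$b, "ST")
  expect_equal(t3$statistic, 361 / 60)
  expect_equal(t3$variant, "corrected-chi-square")
  expect_lt(t3$p_value, 0.05)
  # independent cross-check against stats::mcnemar.test
  tab <- table(l3$a == "ST", l3$b == "ST")
  ref <- stats::mcnemar.test(tab, correct = TRUE)
  expect_equal(t3$statistic, unname(ref$statistic))
  expect_equal(t3$p_value, unname(ref$p.value))

  # no discordance -> p = 1 with flag
  t4 <- mcnemar_test(c("ST", "IN"), c("ST", "IN"), "ST")
  expect_equal(t4$p_value, 1)
  expect_equal(t4$variant, "no-discordance")
  expect_true(is.na(t4$statistic))
})

test_that("self-comparison is null and nested fixed bounds order the IN group", {
  withr::with_seed(41, {
    x <- simulate_scores(mixture_spec(
      tibble::tibble(weight = c(0.45, 0.2, 0.35), mean = c(-0.55, 0, 0.55),
                     sd = c(0.18, 0.15, 0.18), skew = 0),
      n = 250, seed = 41
    ))
  })
  labs <- classify_fixed(x)$label
  for (g in c("GT", "IN", "ST")) {
    expect_equal(mcnemar_test(labs, labs, g)$p_value, 1)
  }

  rep <- compare_methods(
    x,
    methods = list(
      wide = list(method = "fixed", bound = 0.5),
      narrow = list(method = "fixed", bound = 0.3)
    )
  )
  f <- rep$frequencies
  expect_gt(f$n_IN[f$method == "wide"], f$n_IN[f$method == "narrow"])
  expect_lte(f$n_ST[f$method == "wide"], f$n_ST[f$method == "narrow"])
  expect_lte(f$n_GT[f$method == "wide"], f$n_GT[f$method == "narrow"])
  expect_true(all(f$n_ST + f$n_GT + f$n_IN == 250))
})

test_that("three-method comparison reports frequencies, tests and cutoffs", {
  x <- simulate_scores(mixture_spec(
    tibble::tibble(weight = c(0.45, 0.2, 0.35), mean = c(-0.55, 0, 0.55),
                   sd = c(0.16, 0.12, 0.16), skew = 0),
    n = 300, seed = 8
  ))
  rep <- compare_methods(x, seed = 8)
  expect_s3_class(rep, "pavca_comparison")
  expect_equal(nrow(rep$frequencies), 3)
  expect_equal(nrow(rep$mcnemar), 3 * 3) # 3 pairs x 3 groups
  expect_equal(rep$alpha, 0.01)
  expect_true(all(c("fixed", "kmeans", "derivative") %in%
                    names(rep$cutoffs)))
  expect_true(all(rep$mcnemar$p_value >= 0 & rep$mcnemar$p_value <= 1))

  expect_error(compare_methods(x, methods = list(fixed = list())),
               class = "pavca_validation_error")
})

test_that("a failed derivative method degrades the comparison gracefully", {
  withr::with_seed(5, uni <- rnorm(120, 0, 0.08))
  rep <- compare_methods(uni, seed = 5)
  expect_true("derivative" %in% names(rep$failures))
  expect_equal(nrow(rep$frequencies), 2)
})

test_that("comparison reports round-trip through JSON", {
  x <- simulate_scores(mixture_spec(
    tibble::tibble(weight = c(0.5, 0.5), mean = c(-0.55, 0.55),
                   sd = 0.15, skew = 0),
    n = 200, seed = 12
  ))
  rep <- compare_methods(x, seed = 12)
  path <- withr::local_tempfile(fileext = ".json")
  comparison_to_json(rep, path)
  back <- comparison_from_json(path)
  expect_equal(as.data.frame(back$frequencies), as.data.frame(rep$frequencies))
  expect_equal(as.data.frame(back$mcnemar), as.data.frame(rep$mcnemar))
  expect_equal(back$alpha, rep$alpha)
  expect_equal(back$cutoffs$kmeans$gt_cutoff, rep$cutoffs$kmeans$gt_cutoff)
})
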