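# Applying cutoffs to scores, tabulating phenotype frequencies, and
# comparing classification methods per group with McNemar tests.
#
# Boundary conventions differ on purpose: the literature's fixed +/-0.5 rule
# is inclusive at the bounds ("between 0.5 and 1 inclusively"), whereas
# data-driven cutoffs are strict, matching how cutoff tables print them
# ("> 0.34", "< -0.22"). Both are documented on their classifiers.

#' Classify scores with fixed symmetric bounds
#'
#' The conventional rule: GT if `score <= -bound`, ST if `score >= bound`,
#' otherwise IN. The bounds are inclusive.
#'
#' @param scores Numeric vector or score tibble, values in `[-1, 1]`.
#' @param bound Positive bound strictly inside (0, 1); default 0.5.
#' @return The score tibble with added `label` and `method` columns.
#' @export
#' @examples
#' classify_fixed(c(-0.7, 0.5, 0.1))$label
classify_fixed <- function(scores, bound = 0.5) {
  if (!is.numeric(bound) || length(bound) != 1 || bound <= 0 || bound >= 1) {
    abort_validation("`bound` must lie strictly inside (0, 1).")
  }
  df <- as_score_frame(scores)
  check_unit_interval(df$pavca_index, "scores")
  df$label <- dplyr::case_when(
    df$pavca_index <= -bound ~ "GT",
    df$pavca_index >= bound ~ "ST",
    .default = "IN"
  )
  df$method <- "fixed"
  df
}

#' Classify scores with a data-driven cutoff pair
#'
#' Strict boundaries: GT if `score < gt_cutoff`, ST if `score > st_cutoff`,
#' otherwise IN (scores equal to a cutoff are IN).
#'
#' @param scores Numeric vector or score tibble.
#' @param cutoffs A `pavca_cutoffs` object (or a list with `gt_cutoff` and
#'   `st_cutoff`).
#' @return The score tibble with added `label` and `method` columns.
#' @export
classify_with_cutoffs <- function(scores, cutoffs) {
  if (is.numeric(cutoffs) && length(cutoffs) == 2) {
    cutoffs <- cutoff_pair(min(cutoffs), max(cutoffs))
  }
  if (is.null(cutoffs$gt_cutoff) || is.null(cutoffs$st_cutoff) ||
      !(cutoffs$gt_cutoff < cutoffs$st_cutoff)) {
    abort_validation("`cutoffs` must provide gt_cutoff < st_cutoff.")
  }
  df <- as_score_frame(scores)
  df$label <- dplyr::case_when(
    df$pavca_index < cutoffs$gt_cutoff ~ "GT",
    df$pavca_index > cutoffs$st_cutoff ~ "ST",
    .default = "IN"
  )
  df$method <- cutoffs$method %||% "manual"
  df
}

#' Phenotype group frequencies
#'
#' @param labels Character vector of labels, or a tibble with a `label`
#'   column.
#' @return A one-row tibble with `n_ST`, `n_GT`, `n_IN` (summing to n).
#' @export
group_frequencies <- function(labels) {
  lab <- if (is.data.frame(labels)) labels$label else labels
  tibble(
    n_ST = sum(lab == "ST"),
    n_GT = sum(lab == "GT"),
    n_IN = sum(lab == "IN")
  )
}

#' McNemar test of paired group membership
#'
#' Compares, for one phenotype group, the membership indicator under two
#' classification methods applied to the same subjects. With `b` subjects in
#' the group under method A only and `c` under method B only, the exact
#' two-sided binomial test `p = min(1, 2 P(X <= min(b, c)))`,
#' `X ~ Binomial(b + c, 1/2)`, is used when `b + c <= 25`; otherwise the
#' continuity-corrected chi-square `(|b - c| - 1)^2 / (b + c)` on 1 df. With
#' no discordant pairs the statistic is undefined and `p = 1` is reported
#' with a flag.
#'
#' @param labels_a,labels_b Label vectors (or tibbles with `label`) over the
#'   same subjects, in the same order.
#' @param group Phenotype group, one of `"ST"`, `"GT"`, `"IN"`.
#' @param alpha Significance level recorded with the result (default 0.01).
#' @return A `pavca_mcnemar` object.
#' @export
#' @examples
#' mcnemar_test(c("ST", "ST", "IN"), c("ST", "IN", "IN"), "ST")
mcnemar_test <- function(labels_a, labels_b, group, alpha = 0.01) {
  a <- if (is.data.frame(labels_a)) labels_a$label else labels_a
  b_lab <- if (is.data.frame(labels_b)) labels_b$label else labels_b
  if (length(a) != length(b_lab)) {
    abort_validation("Label vectors must cover the same subjects.")
  }
  if (!group %in% phenotype_levels) {
    abort_validation("`group` must be one of GT, IN, ST.")
  }
  in_a <- a == group
  in_b <- b_lab == group
  b <- sum(in_a & !in_b)
  cc <- sum(!in_a & in_b)
  concordant <- length(a) - b - cc
  if (b + cc == 0) {
    res <- list(statistic = NA_real_, p_value = 1,
                variant = "no-discordance")
  } else if (b + cc <= 25) {
    res <- list(
      statistic = NA_real_,
      p_value = min(1, 2 * pbinom(min(b, cc), b + cc, 0.5)),
      variant = "exact"
    )
  } else {
    stat <- (abs(b - cc) - 1)^2 / (b + cc)
    res <- list(
      statistic = stat,
      p_value = pchisq(stat, df = 1, lower.tail = FALSE),
      variant = "corrected-chi-square"
    )
  }
  structure(
    list(
      group = group, b = b, c = cc, concordant = concordant,
      n = length(a), statistic = res$statistic, p_value = res$p_value,
      variant = res$variant, alpha = alpha,
      significant = res$p_value < alpha
    ),
    class = "pavca_mcnemar"
  )
}

#' @export
print.pavca_mcnemar <- function(x, ...) {
  stat <- if (is.na(x$statistic)) "" else sprintf("X2 = %.4f, ", x$statistic)
  cat(sprintf(
    "<pavca_mcnemar> group %s: b = %d, c = %d (%s), %sp = %.4g%s\n",
    x$group, x$b, x$c, x$variant, stat, x$p_value,
    if (x$variant == "no-discordance") " [no discordant pairs]" else ""
  ))
  invisible(x)
}

default_method_specs <- function() {
  list(
    fixed = list(bound = 0.5),
    kmeans = list(k = 3, n_init = 10),
    derivative = list(n_grid = 100, min_prominence = 0.05)
  )
}

# `name` labels the results; the method type defaults to the name but can be
# overridden with opts$method, so e.g. two fixed bounds can be compared.
run_method <- function(scores, name, opts, seed) {
  type <- opts$method %||% name
  out <- switch(
    type,
    fixed = {
      bound <- opts$bound %||% 0.5
      labels <- classify_fixed(scores, bound = bound)
      list(
        labels = labels,
        cutoffs = cutoff_pair(-bound, bound, method = "fixed")
      )
    },
    kmeans = {
      cut <- kmeans_cutoffs_1d(
        scores,
        k = opts$k %||% 3,
        n_init = opts$n_init %||% 10,
        seed = opts$seed %||% seed
      )
      list(labels = classify_with_cutoffs(scores, cut), cutoffs = cut)
    },
    derivative = {
      cut <- derivative_cutoffs(
        scores,
        h = opts$h,
        n_grid = opts$n_grid %||% 100,
        support = opts$support,
        min_prominence = opts$min_prominence %||% 0.05
      )
      list(labels = classify_with_cutoffs(scores, cut), cutoffs = cut)
    },
    abort_validation(sprintf("Unknown classification method '%s'.", type))
  )
  out$labels$method <- name
  out
}

#' Compare classification methods on one sample
#'
#' Applies each requested method to the same scores, tabulates phenotype
#' frequencies, and runs all pairwise per-group McNemar tests. A derivative
#' method that fails its bimodality check is recorded in the report's
#' `failures` and the comparison proceeds with the remaining methods.
#'
#' @param scores Numeric vector or score tibble.
#' @param methods Named list of method option lists; names among `"fixed"`,
#'   `"kmeans"`, `"derivative"`. Defaults to all three with standard options.
#' @param alpha Significance level for the McNemar tests (default 0.01, the
#'   predefined threshold for repeated testing on one sample).
#' @param seed Seed passed to stochastic methods (k-means restarts).
#' @return A `pavca_comparison` object with elements `labels` (wide tibble,
#'   one column per method), `frequencies`, `mcnemar` (tidy per-group
#'   pairwise results), `cutoffs`, `failures` and `alpha`.
#' @export
compare_methods <- function(scores, methods = default_method_specs(),
                            alpha = 0.01, seed = NULL) {
  if (length(methods) < 2) {
    abort_validation("Need at least 2 methods to compare.")
  }
  if (is.null(names(methods)) || any(names(methods) == "")) {
    abort_validation("`methods` must be a named list.")
  }
  df <- as_score_frame(scores)
  results <- list()
  failures <- list()
  for (name in names(methods)) {
    res <- tryCatch(
      run_method(df, name, methods[[name]] %||% list(), seed),
      pavca_method_error = function(e) e
    )
    if (inherits(res, "error")) {
      failures[[name]] <- conditionMessage(res)
    } else {
      results[[name]] <- res
    }
  }
  if (length(results) < 2) {
    abort_method(
      "Fewer than 2 methods produced labels; cannot compare.",
      class = "pavca_compare_failure"
    )
  }
  labels_wide <- df["subject_id"]
  labels_wide$pavca_index <- df$pavca_index
  for (name in names(results)) {
    labels_wide[[name]] <- results[[name]]$labels$label
  }
  freqs <- purrr::map_dfr(names(results), function(name) {
    dplyr::bind_cols(
      tibble(method = name), group_frequencies(results[[name]]$labels)
    )
  })
  pairs <- utils::combn(names(results), 2, simplify = FALSE)
  mcn <- purrr::map_dfr(pairs, function(pr) {
    purrr::map_dfr(phenotype_levels, function(g) {
      t <- mcnemar_test(
        results[[pr[1]]]$labels$label, results[[pr[2]]]$labels$label,
        group = g, alpha = alpha
      )
      tibble(
        method_a = pr[1], method_b = pr[2], group = g,
        b = t$b, c = t$c, concordant = t$concordant,
        statistic = t$statistic, p_value = t$p_value,
        variant = t$variant, significant = t$significant
      )
    })
  })
  structure(
    list(
      labels = labels_wide,
      frequencies = freqs,
      mcnemar = mcn,
      cutoffs = purrr::map(results, "cutoffs"),
      failures = failures,
      alpha = alpha,
      n = nrow(df)
    ),
    class = "pavca_comparison"
  )
}

#' @export
print.pavca_comparison <- function(x, ...) {
  cat(sprintf(
    "<pavca_comparison> %d subjects, %d method(s), alpha = %g\n",
    x$n, nrow(x$frequencies), x$alpha
  ))
  print(x$frequencies)
  if (length(x$failures) > 0) {
    cat("Failed methods:", paste(names(x$failures), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a comparison report to JSON
#'
#' Captures labels, frequencies, McNemar results, cutoff values and alpha in
#' a plain JSON document; [comparison_from_json()] reconstructs the tabular
#' parts so a report round-trips.
#'
#' @param report A `pavca_comparison`.
#' @param path Optional file path; when given, writes the JSON there.
#' @return The JSON string (invisibly when `path` is given).
#' @export
comparison_to_json <- function(report, path = NULL) {
  payload <- list(
    alpha = report$alpha,
    n = report$n,
    labels = report$labels,
    frequencies = report$frequencies,
    mcnemar = report$mcnemar,
    cutoffs = purrr::map(report$cutoffs, function(ct) {
      list(method = ct$method, gt_cutoff = ct$gt_cutoff,
           st_cutoff = ct$st_cutoff)
    }),
    failures = report$failures
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(json, path, useBytes = TRUE)
    return(invisible(json))
  }
  json
}

#' Reconstruct a comparison report from JSON
#'
#' @param json A JSON string or file path produced by [comparison_to_json()].
#' @return A `pavca_comparison` (without the heavyweight per-method
#'   diagnostics, which do not serialize).
#' @export
comparison_from_json <- function(json) {
  payload <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  structure(
    list(
      labels = as_tibble(payload$labels),
      frequencies = as_tibble(payload$frequencies),
      mcnemar = as_tibble(payload$mcnemar),
      cutoffs = purrr::map(payload$cutoffs, function(ct) {
        cutoff_pair(ct$gt_cutoff, ct$st_cutoff, method = ct$method)
      }),
      failures = as.list(payload$failures),
      alpha = payload$alpha,
      n = payload$n
    ),
    class = "pavca_comparison"
  )
}
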