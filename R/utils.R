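# Internal helpers shared across modules.

abort_schema <- function(message, ...) {
  abort(message, class = "pavca_schema_error", ...)
}

abort_validation <- function(message, ...) {
  abort(message, class = "pavca_validation_error", ...)
}

abort_method <- function(message, class = NULL, ...) {
  abort(message, class = c(class, "pavca_method_error"), ...)
}

#' Round half away from zero
#'
#' Display rounding used when matching printed cutoff tables: ties go away
#' from zero (so -0.215 prints as -0.22), unlike [round()]'s round-half-even.
#' Stored scores are never rounded; this is output formatting only.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_out(c(-0.215, 0.335), 2)
round_half_out <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards. A NULL seed leaves the RNG stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort_validation("`seed` must be a single non-missing number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Accept either a bare numeric vector of PavCA index scores or a data frame
# holding a `pavca_index` column; always hand back a tibble with at least
# `subject_id` and `pavca_index`.
as_score_frame <- function(scores, arg = "scores") {
  if (is.numeric(scores)) {
    return(tibble(
      subject_id = sprintf("s%03d", seq_along(scores)),
      pavca_index = as.numeric(scores)
    ))
  }
  if (is.data.frame(scores)) {
    if (!"pavca_index" %in% names(scores)) {
      abort_schema(sprintf("`%s` must contain a `pavca_index` column.", arg))
    }
    out <- as_tibble(scores)
    if (!"subject_id" %in% names(out)) {
      out$subject_id <- sprintf("s%03d", seq_len(nrow(out)))
    }
    return(out)
  }
  abort_schema(sprintf(
    "`%s` must be a numeric vector or a data frame with a `pavca_index` column.",
    arg
  ))
}

score_values <- function(scores, arg = "scores") {
  x <- as_score_frame(scores, arg)$pavca_index
  if (anyNA(x)) {
    abort_validation(sprintf("`%s` contains missing PavCA index values.", arg))
  }
  x
}

check_unit_interval <- function(x, arg) {
  bad <- which(!is.na(x) & (x < -1 | x > 1))
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "`%s` must lie in [-1, 1]; offending rows: %s.",
      arg, paste(head(bad, 5), collapse = ", ")
    ))
  }
  invisible(x)
}

phenotype_levels <- c("GT", "IN", "ST")
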