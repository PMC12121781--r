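# The derivative method: Gaussian kernel density estimate of the score
# distribution on an even grid, discrete first derivative, and cutoffs read
# from the derivative's extrema. On a bimodal density the derivative shows
# the pattern max, min, max, min (steepest ascent/descent of each mode); the
# first local minimum marks the falling flank of the goal-tracker mode (GT
# cutoff) and the second local maximum the rising flank of the sign-tracker
# mode (ST cutoff).

#' Silverman rule-of-thumb bandwidth
#'
#' Classic robust form `0.9 * min(sd, IQR/1.349) * n^(-1/5)`. When the IQR is
#' zero but the standard deviation is not, the standard deviation is used.
#'
#' @param scores Numeric vector (or score tibble), n >= 2 with nonzero spread.
#' @return Bandwidth in score units.
#' @export
silverman_bandwidth <- function(scores) {
  x <- score_values(scores)
  if (length(x) < 2) {
    abort_validation("Bandwidth selection needs at least 2 scores.")
  }
  s <- sd(x)
  iqr <- unname(quantile(x, 0.75, type = 7) - quantile(x, 0.25, type = 7))
  robust <- min(s, iqr / 1.349)
  if (robust <= 0) robust <- s
  if (!is.finite(robust) || robust <= 0) {
    abort_validation(
      "Scores have zero spread; supply an explicit bandwidth `h`."
    )
  }
  0.9 * robust * length(x)^(-1 / 5)
}

# Exact mixture-of-Gaussians KDE evaluated at `at`; with bounded support the
# mass leaking past each bound is reflected back inside.
kde_eval <- function(at, x, h, support = NULL) {
  f <- rowMeans(outer(at, x, function(a, b) dnorm(a - b, sd = h)))
  if (!is.null(support)) {
    lo <- support[1]
    hi <- support[2]
    f <- f +
      rowMeans(outer(at, x, function(a, b) dnorm(2 * lo - a - b, sd = h))) +
      rowMeans(outer(at, x, function(a, b) dnorm(2 * hi - a - b, sd = h)))
    f[at < lo | at > hi] <- 0
  }
  f
}

#' Kernel density estimate of a score distribution
#'
#' Gaussian-kernel estimate on an even grid. With unbounded support (the
#' default, matching the recommendation to avoid condensing estimates at the
#' score bounds) the grid spans `[min - 3h, max + 3h]`. With `support =
#' c(-1, 1)` the grid spans the bounds and boundary mass is preserved by
#' reflection.
#'
#' @param scores Numeric vector or score tibble (n >= 2).
#' @param h Bandwidth; `NULL` (default) uses [silverman_bandwidth()].
#' @param n_grid Number of grid points (default 100, minimum 10).
#' @param support `NULL` for unbounded, or a length-2 numeric `c(lo, hi)`.
#' @return A `pavca_density` object: a tibble with columns `x` and `f`, and
#'   attributes `h`, `support` and `n`.
#' @export
estimate_density <- function(scores, h = NULL, n_grid = 100, support = NULL) {
  x <- score_values(scores)
  if (length(x) < 2) {
    abort_validation("Density estimation needs at least 2 scores.")
  }
  if (n_grid < 10) {
    abort_validation("`n_grid` must be at least 10.")
  }
  if (!is.null(support)) {
    if (length(support) != 2 || support[1] >= support[2]) {
      abort_validation("`support` must be c(lo, hi) with lo < hi.")
    }
    if (any(x < support[1] | x > support[2])) {
      abort_validation("All scores must lie within the stated support.")
    }
  }
  h <- h %||% silverman_bandwidth(x)
  if (h <= 0) abort_validation("Bandwidth `h` must be > 0.")
  grid <- if (is.null(support)) {
    seq(min(x) - 3 * h, max(x) + 3 * h, length.out = n_grid)
  } else {
    seq(support[1], support[2], length.out = n_grid)
  }
  f <- kde_eval(grid, x, h, support)
  out <- tibble(x = grid, f = f)
  structure(
    out,
    class = c("pavca_density", class(out)),
    h = h, support = support, n = length(x)
  )
}

#' Discrete first derivative of a density curve
#'
#' Forward differences `diff(f)/diff(x)` reported at interval midpoints.
#'
#' @param curve A `pavca_density` (or any tibble with `x` and `f`).
#' @return A `pavca_derivative` tibble with columns `x` (midpoints) and
#'   `dfdx`.
#' @export
differentiate <- function(curve) {
  if (nrow(curve) < 2) {
    abort_validation("Need at least 2 grid points to differentiate.")
  }
  out <- tibble(
    x = (curve$x[-1] + curve$x[-nrow(curve)]) / 2,
    dfdx = diff(curve$f) / diff(curve$x)
  )
  structure(out, class = c("pavca_derivative", class(out)))
}

# Strict alternating extrema of a discrete series by sign change of its
# forward difference; flat plateaus resolve to their midpoint index.
raw_extrema <- function(v) {
  d <- diff(v)
  nz <- which(d != 0)
  if (length(nz) < 2) {
    return(tibble(index = integer(), value = numeric(), kind = character()))
  }
  idx <- integer()
  kind <- character()
  for (j in seq_len(length(nz) - 1)) {
    a <- nz[j]
    b <- nz[j + 1]
    if (sign(d[a]) != sign(d[b])) {
      mid <- as.integer(round((a + 1 + b) / 2))
      idx <- c(idx, mid)
      kind <- c(kind, if (d[a] > 0) "max" else "min")
    }
  }
  tibble(index = idx, value = v[idx], kind = kind)
}

#' Local extrema of a derivative curve
#'
#' Finds local maxima and minima of `dfdx` by discrete sign change, scanning
#' left to right, then suppresses low-prominence wiggles: adjacent extrema
#' pairs whose height difference is below `min_prominence * max(|dfdx|)` are
#' removed, smallest gap first, until all remaining adjacent pairs clear the
#' threshold. Raising `min_prominence` can only remove extrema.
#'
#' @param dcurve A `pavca_derivative`.
#' @param min_prominence Fraction of `max(|dfdx|)` (default 0.05).
#' @return A tibble with columns `position` (score at the extremum), `value`
#'   and `kind` (`"max"` or `"min"`), ordered left to right.
#' @export
find_extrema <- function(dcurve, min_prominence = 0.05) {
  if (nrow(dcurve) < 3) {
    abort_validation("Need at least 3 derivative points.")
  }
  ext <- raw_extrema(dcurve$dfdx)
  if (nrow(ext) > 0) {
    thr <- min_prominence * max(abs(dcurve$dfdx))
    while (nrow(ext) >= 2) {
      gaps <- abs(diff(ext$value))
      if (all(gaps >= thr)) break
      drop <- which.min(gaps)
      ext <- ext[-c(drop, drop + 1), ]
    }
    if (nrow(ext) == 1 && abs(ext$value[1]) < thr) {
      ext <- ext[0, ]
    }
  }
  tibble(
    position = dcurve$x[ext$index],
    value = ext$value,
    kind = ext$kind
  )
}

#' Peak locations and widths of a density curve
#'
#' Locates each density mode and measures its width at the half-prominence
#' reference line: the prominence of a peak is its height above the higher of
#' the two lowest points separating it from taller terrain (or the curve
#' ends), and the width is the horizontal distance between the curve's
#' crossings of `height - prominence/2`, linearly interpolated.
#'
#' @param curve A `pavca_density`.
#' @return A tibble with columns `location`, `height`, `prominence` and
#'   `width`, ordered by location.
#' @export
density_peak_stats <- function(curve) {
  f <- curve$f
  x <- curve$x
  ext <- raw_extrema(f)
  peaks <- ext[ext$kind == "max", ]
  if (nrow(peaks) == 0) {
    abort_method("Density has no interior mode.", class = "pavca_no_peak")
  }
  stats <- purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    p <- peaks$index[i]
    height <- f[p]
    left_base <- if (any(f[seq_len(p - 1)] > height)) {
      hi <- max(which(f[seq_len(p - 1)] > height))
      min(f[hi:p])
    } else {
      min(f[1:p])
    }
    right_base <- if (any(f[(p + 1):length(f)] > height)) {
      lo <- p + min(which(f[(p + 1):length(f)] > height))
      min(f[p:lo])
    } else {
      min(f[p:length(f)])
    }
    prom <- height - max(left_base, right_base)
    ref <- height - prom / 2
    cross <- function(side) {
      idx <- if (side == "left") seq(p, 1) else seq(p, length(f))
      below <- which(f[idx] < ref)
      if (length(below) == 0) {
        return(x[idx[length(idx)]])
      }
      j <- below[1]
      i1 <- idx[j - 1]
      i2 <- idx[j]
      x[i1] + (ref - f[i1]) * (x[i2] - x[i1]) / (f[i2] - f[i1])
    }
    tibble(
      location = x[p], height = height, prominence = prom,
      width = cross("right") - cross("left")
    )
  })
  dplyr::arrange(stats, .data$location)
}

#' Derivative-method cutoffs
#'
#' Runs the full derivative method on a score distribution: KDE (Silverman
#' bandwidth unless given), discrete first derivative, prominence-filtered
#' extrema, then `gt_cutoff` = position of the first local minimum of the
#' derivative and `st_cutoff` = position of its second local maximum,
#' scanning left to right. A distribution that does not show the bimodal
#' extremum pattern raises a `pavca_not_bimodal` error rather than guessing.
#'
#' @inheritParams estimate_density
#' @inheritParams find_extrema
#' @return A `pavca_cutoffs` object with `gt_cutoff`, `st_cutoff`, the
#'   density and derivative curves, bandwidth, and peak diagnostics.
#' @export
derivative_cutoffs <- function(scores, h = NULL, n_grid = 100, support = NULL,
                               min_prominence = 0.05) {
  dens <- estimate_density(scores, h = h, n_grid = n_grid, support = support)
  deriv <- differentiate(dens)
  ext <- find_extrema(deriv, min_prominence = min_prominence)
  mins <- ext[ext$kind == "min", ]
  maxs <- ext[ext$kind == "max", ]
  fail <- function() {
    abort_method(
      paste(
        "Distribution not bimodal under current bandwidth:",
        "the derivative does not show the max/min/max pattern.",
        "Consider the k-means method or a different bandwidth."
      ),
      class = "pavca_not_bimodal"
    )
  }
  if (nrow(mins) < 1 || nrow(maxs) < 2) fail()
  gt <- mins$position[1]
  st <- maxs$position[2]
  if (!(gt < st)) fail()
  # The density itself must be bimodal: at least two modes whose prominence
  # clears the same fraction of the density maximum, with both cutoffs lying
  # between the outer modes.
  peaks <- tryCatch(density_peak_stats(dens),
                    pavca_no_peak = function(e) NULL)
  if (is.null(peaks)) fail()
  sig <- peaks[peaks$prominence >= min_prominence * max(dens$f), ]
  if (nrow(sig) < 2) fail()
  lo_mode <- sig$location[1]
  hi_mode <- sig$location[nrow(sig)]
  if (gt <= lo_mode || st >= hi_mode) fail()
  new_cutoffs(
    gt_cutoff = gt, st_cutoff = st, method = "derivative",
    diagnostics = list(
      bandwidth = attr(dens, "h"),
      n_grid = n_grid,
      support = support,
      peaks = sig,
      extrema = ext
    ),
    curves = list(density = dens, derivative = deriv)
  )
}

#' Construct a cutoff pair
#'
#' @param gt_cutoff,st_cutoff Cutoff scores with `gt_cutoff < st_cutoff`.
#' @param method Provenance tag (`"fixed"`, `"kmeans"`, `"derivative"`, ...).
#' @param diagnostics,curves Optional method diagnostics.
#' @return A `pavca_cutoffs` object.
#' @export
cutoff_pair <- function(gt_cutoff, st_cutoff, method = "manual",
                        diagnostics = list(), curves = NULL) {
  new_cutoffs(gt_cutoff, st_cutoff, method, diagnostics, curves)
}

new_cutoffs <- function(gt_cutoff, st_cutoff, method, diagnostics = list(),
                        curves = NULL) {
  if (!is.numeric(gt_cutoff) || !is.numeric(st_cutoff) ||
      !(gt_cutoff < st_cutoff)) {
    abort_validation("Cutoffs require gt_cutoff < st_cutoff.")
  }
  structure(
    list(
      gt_cutoff = unname(gt_cutoff), st_cutoff = unname(st_cutoff),
      method = method, diagnostics = diagnostics, curves = curves
    ),
    class = "pavca_cutoffs"
  )
}

#' @export
print.pavca_cutoffs <- function(x, ...) {
  cat(sprintf(
    "<pavca_cutoffs> method = %s: GT < %.4f, ST > %.4f\n",
    x$method, x$gt_cutoff, x$st_cutoff
  ))
  if (!is.null(x$diagnostics$bandwidth)) {
    cat(sprintf("  bandwidth h = %.4f\n", x$diagnostics$bandwidth))
  }
  if (!is.null(x$diagnostics$centroids)) {
    cat(sprintf(
      "  centroids: %s\n",
      paste(sprintf("%.4f", x$diagnostics$centroids), collapse = ", ")
    ))
  }
  invisible(x)
}
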