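# broom-style tidiers for the package's result objects.

#' Tidy a k-means fit
#'
#' @param x A `pavca_kmeans`.
#' @param ... Unused.
#' @return One row per cluster: centroid coordinates, size and `sum_d`.
#' @method tidy pavca_kmeans
#' @export
tidy.pavca_kmeans <- function(x, ...) {
  cent <- x$centroids
  colnames(cent) <- if (ncol(cent) == 1) "centroid" else {
    paste0("centroid_", seq_len(ncol(cent)))
  }
  dplyr::bind_cols(
    tibble(cluster = seq_len(x$k)),
    as_tibble(cent),
    tibble(
      size = tabulate(x$cluster, nbins = x$k),
      sum_d = x$sum_d
    )
  )
}

#' @rdname tidy.pavca_kmeans
#' @method glance pavca_kmeans
#' @export
glance.pavca_kmeans <- function(x, ...) {
  tibble(
    k = x$k, n = x$n, d = x$d, tot_withinss = x$tot_withinss,
    n_init = x$n_init, iter = x$iter
  )
}

#' Tidy a cutoff pair
#'
#' @param x A `pavca_cutoffs`.
#' @param ... Unused.
#' @return A one-row tibble with the method, both cutoffs and the headline
#'   diagnostics (bandwidth or centroids) when available.
#' @method tidy pavca_cutoffs
#' @export
tidy.pavca_cutoffs <- function(x, ...) {
  out <- tibble(
    method = x$method, gt_cutoff = x$gt_cutoff, st_cutoff = x$st_cutoff
  )
  d <- x$diagnostics
  if (!is.null(d$bandwidth)) out$bandwidth <- d$bandwidth
  if (!is.null(d$centroids)) {
    out$centroid_GT <- d$centroids[["GT"]]
    out$centroid_IN <- d$centroids[["IN"]]
    out$centroid_ST <- d$centroids[["ST"]]
    out$sum_d_GT <- d$sum_d[["GT"]]
    out$sum_d_IN <- d$sum_d[["IN"]]
    out$sum_d_ST <- d$sum_d[["ST"]]
  }
  if (!is.null(d$peaks)) {
    out$peak_location_GT <- d$peaks$location[1]
    out$peak_location_ST <- d$peaks$location[nrow(d$peaks)]
    out$peak_width_GT <- d$peaks$width[1]
    out$peak_width_ST <- d$peaks$width[nrow(d$peaks)]
  }
  out
}

#' @rdname tidy.pavca_cutoffs
#' @method glance pavca_cutoffs
#' @export
glance.pavca_cutoffs <- function(x, ...) {
  tibble(
    method = x$method, gt_cutoff = x$gt_cutoff, st_cutoff = x$st_cutoff,
    span = x$st_cutoff - x$gt_cutoff
  )
}

#' Tidy a McNemar result
#'
#' @param x A `pavca_mcnemar`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy pavca_mcnemar
#' @export
tidy.pavca_mcnemar <- function(x, ...) {
  tibble(
    group = x$group, b = x$b, c = x$c, concordant = x$concordant,
    statistic = x$statistic, p_value = x$p_value, variant = x$variant,
    significant = x$significant
  )
}

#' Tidy a method comparison
#'
#' @param x A `pavca_comparison`.
#' @param ... Unused.
#' @return The per-group pairwise McNemar table.
#' @method tidy pavca_comparison
#' @export
tidy.pavca_comparison <- function(x, ...) {
  x$mcnemar
}

#' @rdname tidy.pavca_comparison
#' @method glance pavca_comparison
#' @export
glance.pavca_comparison <- function(x, ...) {
  tibble(
    n = x$n, n_methods = nrow(x$frequencies), alpha = x$alpha,
    n_failures = length(x$failures)
  )
}
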