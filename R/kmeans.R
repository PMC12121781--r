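# k-means clustering of scores (1D) and of the three raw component features
# (3D), with cluster-edge cutoffs. In 1D the nearest-centroid decision
# boundary between two adjacent clusters is exactly the midpoint of their
# centroids, so with k = 3 the two midpoints are the GT and ST cutoffs.

sq_dist_to <- function(X, center) {
  rowSums(sweep(X, 2, center)^2)
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- sq_dist_to(X, centers[1, ])
  for (j in seq_len(k - 1) + 1) {
    if (all(d2 == 0)) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = d2)
    }
    centers[j, ] <- X[pick, ]
    d2 <- pmin(d2, sq_dist_to(X, centers[j, ]))
  }
  centers
}

all_sq_dists <- function(X, centers) {
  matrix(
    vapply(seq_len(nrow(centers)), function(j) sq_dist_to(X, centers[j, ]),
           numeric(nrow(X))),
    nrow = nrow(X)
  )
}

lloyd_once <- function(X, k, max_iter) {
  centers <- kmeanspp_init(X, k)
  assign_old <- rep(0L, nrow(X))
  for (iter in seq_len(max_iter)) {
    d2 <- all_sq_dists(X, centers)
    assign_new <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {
      members <- assign_new == j
      if (!any(members)) {
        # Re-seed an emptied centroid at the point farthest from its centroid.
        far <- which.max(d2[cbind(seq_len(nrow(X)), assign_new)])
        centers[j, ] <- X[far, ]
        assign_new[far] <- j
      } else {
        centers[j, ] <- colMeans(X[members, , drop = FALSE])
      }
    }
    if (identical(assign_new, assign_old)) break
    assign_old <- assign_new
  }
  d2 <- all_sq_dists(X, centers)
  assign_new <- max.col(-d2, ties.method = "first")
  wss <- vapply(seq_len(k), function(j) {
    sum(d2[assign_new == j, j])
  }, numeric(1))
  list(centers = centers, cluster = assign_new, sum_d = wss, iter = iter)
}

#' Lloyd k-means with k-means++ restarts
#'
#' Runs Lloyd's algorithm from `n_init` k-means++ initializations and keeps
#' the solution with the smallest total within-cluster sum of squared
#' distances. A cluster emptied during iteration is re-seeded at the point
#' currently farthest from its assigned centroid. Deterministic given
#' `seed`.
#'
#' @param points Numeric vector (1D) or matrix (n x d) of observations.
#' @param k Number of clusters (`n >= k`).
#' @param n_init Number of random restarts (default 10).
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @param max_iter Lloyd iteration cap per restart (default 100).
#' @return A `pavca_kmeans` object: centroids (k x d matrix), `cluster`
#'   assignments, per-cluster `sum_d` (within-cluster sums of squared
#'   point-to-centroid distances), `tot_withinss`, and reproducibility
#'   metadata.
#' @export
lloyd_kmeans <- function(points, k, n_init = 10, seed = NULL, max_iter = 100) {
  X <- if (is.matrix(points)) points else matrix(as.numeric(points), ncol = 1)
  if (anyNA(X) || any(!is.finite(X))) {
    abort_validation("`points` must be finite and complete.")
  }
  if (nrow(X) < k) {
    abort_validation(sprintf(
      "Need at least k = %d observations, got %d.", k, nrow(X)
    ))
  }
  best <- with_seed(seed, {
    runs <- lapply(seq_len(n_init), function(i) lloyd_once(X, k, max_iter))
    runs[[which.min(vapply(runs, function(r) sum(r$sum_d), numeric(1)))]]
  })
  structure(
    list(
      k = k,
      centroids = best$centers,
      cluster = best$cluster,
      sum_d = best$sum_d,
      tot_withinss = sum(best$sum_d),
      n_init = n_init,
      seed = seed,
      iter = best$iter,
      n = nrow(X),
      d = ncol(X)
    ),
    class = "pavca_kmeans"
  )
}

#' @export
print.pavca_kmeans <- function(x, ...) {
  cat(sprintf(
    "<pavca_kmeans> k = %d on %d observations (%dD), total WSS = %.4f\n",
    x$k, x$n, x$d, x$tot_withinss
  ))
  invisible(x)
}

#' Cutoffs from sorted 1D centroids
#'
#' The nearest-centroid decision boundaries for three clusters on a line:
#' midpoints of adjacent centroids, after sorting. Useful on its own to turn
#' published centroid triples into cutoff pairs.
#'
#' @param centroids Numeric vector of 3 cluster centroids (any order).
#' @return A named numeric vector `c(gt_cutoff, st_cutoff)`.
#' @export
#' @examples
#' centroid_midpoint_cutoffs(c(0.55, -0.55, 0.12)) # -0.215, 0.335
centroid_midpoint_cutoffs <- function(centroids) {
  if (length(centroids) != 3 || anyNA(centroids)) {
    abort_validation("`centroids` must be 3 finite values.")
  }
  cs <- sort(centroids)
  c(gt_cutoff = mean(cs[1:2]), st_cutoff = mean(cs[2:3]))
}

#' 1D k-means cutoffs for PavCA scores
#'
#' Clusters the scores with `k = 3`, orders clusters by ascending centroid
#' (GT, IN, ST), and reports the two nearest-centroid decision boundaries as
#' the GT and ST cutoffs, together with centroids and within-cluster
#' dispersion (Sum D).
#'
#' @param scores Numeric vector or score tibble.
#' @param k Number of clusters; must be 3 for a cutoff pair.
#' @inheritParams lloyd_kmeans
#' @return A `pavca_cutoffs` object whose diagnostics carry the sorted
#'   centroids, per-cluster `sum_d`, cluster sizes and the full
#'   `pavca_kmeans` fit.
#' @export
kmeans_cutoffs_1d <- function(scores, k = 3, n_init = 10, seed = NULL) {
  if (k != 3) {
    abort_validation("Cutoff extraction requires k = 3 (GT, IN, ST).")
  }
  x <- score_values(scores)
  fit <- lloyd_kmeans(x, k = k, n_init = n_init, seed = seed)
  ord <- order(fit$centroids[, 1])
  centroids <- fit$centroids[ord, 1]
  cuts <- centroid_midpoint_cutoffs(centroids)
  relabel <- match(fit$cluster, ord)
  sizes <- tabulate(relabel, nbins = 3)
  new_cutoffs(
    gt_cutoff = cuts[["gt_cutoff"]], st_cutoff = cuts[["st_cutoff"]],
    method = "kmeans",
    diagnostics = list(
      centroids = setNames(centroids, phenotype_levels),
      sum_d = setNames(fit$sum_d[ord], phenotype_levels),
      sizes = setNames(sizes, phenotype_levels),
      n_init = n_init,
      seed = seed,
      fit = fit
    )
  )
}

#' 3D k-means phenotype labels
#'
#' Clusters subjects on the three raw features behind the PavCA index
#' (latency score, lever presses, food-cup entries) and maps the clusters to
#' GT/IN/ST by ascending mean PavCA index of their members. In 3D the
#' resulting boundaries need not be linear in the index. Counts dominate the
#' latency dimension at raw scale, so `standardize = TRUE` (z-scoring each
#' feature) is available; raw features are the default.
#'
#' @param features Tibble with columns `subject_id`, `latency_score`,
#'   `lever_presses`, `foodcup_entries` and `pavca_index` (used only for the
#'   cluster-to-phenotype mapping).
#' @param k Number of clusters (default 3).
#' @param standardize Z-score the three features first (default `FALSE`).
#' @inheritParams lloyd_kmeans
#' @return A list with `labels` (tibble of `subject_id`, `label`) and `fit`
#'   (the `pavca_kmeans` object).
#' @export
kmeans_labels_3d <- function(features, k = 3, standardize = FALSE,
                             n_init = 10, seed = NULL) {
  needed <- c("subject_id", "latency_score", "lever_presses",
              "foodcup_entries", "pavca_index")
  require_columns(features, needed, "<features>")
  feat_cols <- c("latency_score", "lever_presses", "foodcup_entries")
  incomplete <- !stats::complete.cases(features[feat_cols])
  if (any(incomplete)) {
    abort_validation(sprintf(
      "Missing feature value(s) for subject(s): %s.",
      paste(head(features$subject_id[incomplete], 5), collapse = ", ")
    ))
  }
  X <- as.matrix(features[feat_cols])
  if (standardize) {
    X <- scale(X)
    X[, attr(X, "scaled:scale") == 0] <- 0
  }
  fit <- lloyd_kmeans(unclass(X), k = k, n_init = n_init, seed = seed)
  mean_index <- vapply(seq_len(k), function(j) {
    mean(features$pavca_index[fit$cluster == j])
  }, numeric(1))
  ord <- order(mean_index)
  lvl <- if (k == 3) phenotype_levels else paste0("C", seq_len(k))
  labels <- lvl[match(fit$cluster, ord)]
  list(
    labels = tibble(subject_id = features$subject_id, label = labels),
    fit = fit
  )
}
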