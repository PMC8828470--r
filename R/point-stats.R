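#' Ripley F, G and L curves per cluster
#'
#' Point-pattern statistics over the spatial coordinates of each cluster:
#' * `L`: variance-stabilized Ripley K, `L(t) = sqrt(K(t) / pi)` with the
#'   unbiased estimator `K(t) = (A / (n (n - 1))) * sum_{i != j} 1[d_ij < t]`
#'   and `A` the bounding-box area of all coordinates (no edge correction),
#'   so `L(t) ~ t` under complete spatial randomness.
#' * `G`: empirical CDF of within-cluster nearest-neighbour distances.
#' * `F`: empirical CDF of distances from `n_ref` uniform random reference
#'   points in the bounding box to their nearest cluster point (the
#'   empty-space function).
#'
#' @param dataset A [spatial_dataset].
#' @param label_key Categorical column naming the clusters; `NULL` treats all
#'   observations as one cluster `"all"`.
#' @param mode One of `"F"`, `"G"`, `"L"`.
#' @param n_steps Number of support radii (equally spaced from 0 to half the
#'   bounding-box diagonal).
#' @param n_ref Number of uniform reference points for mode F (default: the
#'   cluster size).
#' @param seed Seed for the reference points (required for mode F).
#' @param support Optional explicit vector of radii (overrides `n_steps`).
#' @param area Observation-window area for mode L (default: the bounding-box
#'   area of all coordinates). Supply the true window area when it is known;
#'   note a bounding box is not rotation-invariant, so L computed with the
#'   default area is only translation/scale-equivariant.
#' @return A `ripley_result` tibble: `cluster`, `t`, `value`. Clusters with
#'   fewer than 2 points are skipped with a warning.
#' @export
ripley <- function(dataset, label_key = NULL, mode = c("L", "F", "G"),
                   n_steps = 50, n_ref = NULL, seed = NULL, support = NULL,
                   area = NULL) {
  mode <- match.arg(mode)
  coords <- coords_matrix(dataset)
  labels <- if (is.null(label_key)) {
    factor(rep("all", nrow(coords)))
  } else {
    get_labels(dataset, label_key)
  }
  if (mode == "F" && is.null(seed)) {
    abort("Mode F needs a seed for its uniform reference points.", class = "spomics_error")
  }
  bbox <- apply(coords, 2L, range)
  side <- bbox[2, ] - bbox[1, ]
  area <- area %||% prod(side)
  if (is.null(support)) {
    support <- seq(0, sqrt(sum(side^2)) / 2, length.out = n_steps)
  }
  stopifnot(all(diff(support) > 0), support[1] >= 0)
  rows <- list()
  counts <- integer(0)
  for (cl in levels(labels)) {
    pts <- coords[labels == cl, , drop = FALSE]
    n <- nrow(pts)
    if (n < 2) {
      warn(sprintf("Cluster '%s' has < 2 points; skipped.", cl))
      next
    }
    counts[cl] <- n
    vals <- switch(mode,
      L = {
        d <- as.numeric(dist(pts))
        cnt <- vapply(support, function(t) 2 * sum(d < t), numeric(1))
        sqrt(area * cnt / (n * (n - 1)) / pi)
      },
      G = {
        dm <- as.matrix(dist(pts)); diag(dm) <- Inf
        nnd <- apply(dm, 1L, min)
        vapply(support, function(t) mean(nnd <= t), numeric(1))
      },
      F = {
        m <- n_ref %||% n
        ref <- with_seed(seed, cbind(runif(m, bbox[1, 1], bbox[2, 1]),
                                     runif(m, bbox[1, 2], bbox[2, 2])))
        nnd <- RANN::nn2(pts, ref, k = 1L)$nn.dists[, 1]
        vapply(support, function(t) mean(nnd <= t), numeric(1))
      })
    rows[[cl]] <- tibble(cluster = cl, t = support, value = vals)
  }
  if (!length(rows)) abort("No cluster with >= 2 points.", class = "spomics_error")
  new_spomics_tbl(dplyr::bind_rows(rows), "ripley_result",
                  list(mode = mode, area = area, n_points = counts,
                       seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
}

#' Cluster co-occurrence ratio across distance shells
#'
#' Conditioning on one cluster, pools — over all its member points — the
#' labels of the points falling in each annular distance shell around a
#' member, and reports, per shell and per cluster c, the ratio
#' `p(c | shell) / p(c)` of the within-shell label frequency to the global
#' frequency. Shells with no points give `NaN`.
#'
#' @param dataset A [spatial_dataset].
#' @param label_key Categorical column naming the clusters.
#' @param conditioning Level of `label_key` to condition on.
#' @param n_intervals Number of shells; default edges are `n_intervals`
#'   equal steps from the smallest positive pairwise distance to half the
#'   maximum pairwise distance.
#' @param interval Optional explicit strictly increasing vector of shell
#'   edges (length `n_intervals + 1`).
#' @param cumulative Use cumulative balls `(0, d_high]` instead of annuli.
#' @return A `co_occurrence` tibble: `cluster`, `interval_low`,
#'   `interval_high`, `ratio`.
#' @export
co_occurrence <- function(dataset, label_key, conditioning, n_intervals = 50,
                          interval = NULL, cumulative = FALSE) {
  labels <- get_labels(dataset, label_key)
  lev <- levels(labels)
  if (!conditioning %in% lev) {
    abort(sprintf("Unknown conditioning cluster '%s'.", conditioning),
          class = "spomics_error")
  }
  coords <- coords_matrix(dataset)
  centers <- coords[labels == conditioning, , drop = FALSE]
  dm <- as.matrix(dist(coords))
  dcent <- dm[labels == conditioning, , drop = FALSE]
  if (is.null(interval)) {
    pos <- dm[upper.tri(dm)]
    pos <- pos[pos > 0]
    interval <- seq(min(pos), max(pos) / 2, length.out = n_intervals + 1L)
  }
  stopifnot(all(diff(interval) > 0))
  lo <- interval[-length(interval)]
  hi <- interval[-1]
  if (cumulative) lo <- rep(0, length(hi))
  pglob <- as.numeric(table(labels)) / length(labels)
  k <- length(lev)
  li <- as.integer(labels)
  ratio <- matrix(NA_real_, k, length(hi))
  for (s in seq_along(hi)) {
    sel <- dcent > lo[s] & dcent <= hi[s]
    # a point contributes once per conditioning centre whose shell holds it
    pooled <- tabulate(rep(li, times = colSums(sel)), nbins = k)
    tot <- sum(pooled)
    ratio[, s] <- if (tot > 0) (pooled / tot) / pglob else NaN
  }
  tbl <- tibble(
    cluster = rep(lev, times = length(hi)),
    interval_low = rep(lo, each = k),
    interval_high = rep(hi, each = k),
    ratio = as.numeric(ratio)
  )
  new_spomics_tbl(tbl, "co_occurrence",
                  list(conditioning = conditioning, clusters = lev,
                       cumulative = cumulative))
}
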