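#' Permutation neighbourhood enrichment between cluster labels
#'
#' Counts, for every unordered pair of cluster labels (i, j), the number of
#' graph edges joining a class-i node to a class-j node (each undirected edge
#' counted once, including i = j pairs), then compares the observed count
#' `x_ij` with its null distribution obtained by permuting the labels
#' uniformly while holding the connectivity fixed. The z-score is
#' `Z_ij = (x_ij - mu_ij) / sigma_ij` with `mu`, `sigma` the permutation mean
#' and standard deviation. Pairs whose permutation distribution is degenerate
#' (`sigma = 0`) get `Z = 0` and `sigma_zero = TRUE`.
#'
#' @param dataset A [spatial_dataset].
#' @param graph A [spatial_graph] over the dataset's observations.
#' @param label_key Name of a categorical column in `dataset$obs`.
#' @param n_perms Number of label permutations (>= 1).
#' @param seed Seed for the permutation stream (required; identical seed
#'   gives bit-identical results).
#' @return A `nhood_enrichment` tibble with one row per unordered cluster
#'   pair: `cluster_1`, `cluster_2`, `count`, `perm_mean`, `perm_sd`,
#'   `zscore`, `sigma_zero`. Metadata (`clusters`, `n_perms`, `seed`) is
#'   available through [glance()]; [enrichment_matrix()] returns the k x k
#'   z-score matrix.
#' @examples
#' d <- simulate_points(n_points = 60, pattern = "poisson",
#'                      labels = label_spec("random", k = 3), seed = 1)
#' g <- knn_graph(d, 4)
#' nhood_enrichment(d, g, "cluster", n_perms = 100, seed = 1)
#' @export
nhood_enrichment <- function(dataset, graph, label_key, n_perms = 1000, seed) {
  labels <- get_labels(dataset, label_key)
  lev <- levels(labels)
  k <- length(lev)
  el <- edge_list(graph)
  if (!nrow(el)) abort("Graph has no edges.", class = "spomics_error")
  li <- as.integer(labels)
  counts_of <- function(lab) {
    a <- lab[el$i]; b <- lab[el$j]
    idx <- (pmin(a, b) - 1L) * k + pmax(a, b)
    tabulate(idx, nbins = k * k)
  }
  obs <- counts_of(li)
  perm <- matrix(0L, k * k, n_perms)
  with_seed(seed, for (p in seq_len(n_perms)) {
    perm[, p] <- counts_of(sample(li))
  })
  mu <- rowMeans(perm)
  sdv <- apply(perm, 1L, sd)
  if (n_perms == 1L) sdv <- rep(0, k * k)
  z <- ifelse(sdv > 0, (obs - mu) / sdv, 0)
  pair <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  flat <- (pmin(pair[, 1], pair[, 2]) - 1L) * k + pmax(pair[, 1], pair[, 2])
  tbl <- tibble(
    cluster_1 = lev[pmin(pair[, 1], pair[, 2])],
    cluster_2 = lev[pmax(pair[, 1], pair[, 2])],
    count = obs[flat],
    perm_mean = mu[flat],
    perm_sd = sdv[flat],
    zscore = z[flat],
    sigma_zero = sdv[flat] == 0
  )
  new_spomics_tbl(tbl, "nhood_enrichment",
                  list(clusters = lev, n_perms = as.integer(n_perms),
                       seed = as.integer(seed), degenerate = k == 1L))
}

#' Symmetric matrix view of a neighbourhood-enrichment result
#'
#' @param x A `nhood_enrichment` result.
#' @param value Column to spread into a matrix (`"zscore"` or `"count"`).
#' @return A symmetric k x k matrix with cluster dimnames.
#' @export
enrichment_matrix <- function(x, value = "zscore") {
  lev <- spomics_meta(x)$clusters
  k <- length(lev)
  m <- matrix(0, k, k, dimnames = list(lev, lev))
  i <- match(x$cluster_1, lev); j <- match(x$cluster_2, lev)
  m[cbind(i, j)] <- x[[value]]
  m[cbind(j, i)] <- x[[value]]
  m
}

#' Cluster interaction matrix
#'
#' Entry (i, j) counts ordered node pairs (u, v) with an edge u ~ v,
#' label(u) = i and label(v) = j; the matrix is symmetric and its total
#' equals twice the undirected edge count. Note the convention differs from
#' [nhood_enrichment()], which counts each undirected edge once.
#'
#' @inheritParams nhood_enrichment
#' @param normalized Divide each row by its sum (zero rows stay zero).
#' @return An `interaction_matrix` tibble (`cluster_1`, `cluster_2`, `count`)
#'   with the k x k matrix retrievable via [as.matrix()].
#' @export
interaction_matrix <- function(dataset, graph, label_key, normalized = FALSE) {
  labels <- get_labels(dataset, label_key)
  lev <- levels(labels)
  k <- length(lev)
  n <- length(labels)
  L <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(labels), x = 1,
                            dims = c(n, k))
  A <- (graph$connectivity != 0) * 1
  M <- as.matrix(Matrix::t(L) %*% A %*% L)
  dimnames(M) <- list(lev, lev)
  if (normalized) {
    rs <- rowSums(M)
    M <- sweep(M, 1L, ifelse(rs > 0, rs, 1), "/")
  }
  tbl <- as_tibble(as.data.frame.table(M, responseName = "count",
                                       stringsAsFactors = FALSE))
  names(tbl)[1:2] <- c("cluster_1", "cluster_2")
  out <- new_spomics_tbl(tbl, "interaction_matrix",
                         list(clusters = lev, normalized = normalized))
  attr(out, "matrix") <- M
  out
}

#' @export
as.matrix.interaction_matrix <- function(x, ...) attr(x, "matrix")

# igraph view of the connectivity, unweighted (hop distances by design).
as_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix((graph$connectivity != 0) * 1,
                                      mode = "undirected", diag = FALSE)
}

#' Group centrality scores per cluster
#'
#' For each cluster S on the unweighted connectivity graph:
#' * `degree_centrality`: fraction of non-members adjacent to S,
#'   `|N(S) - S| / (|V| - |S|)`.
#' * `closeness_centrality`: number of non-members reachable from S divided
#'   by the sum of their hop distances `d(S, v) = min_{u in S} d(u, v)`
#'   (unreachable nodes excluded from numerator and denominator; 0 if none
#'   reachable).
#' * `average_clustering`: mean over members of the local clustering
#'   coefficient `2 T(v) / (deg(v) (deg(v) - 1))`, 0 for degree < 2.
#'
#' Clusters equal to the whole vertex set have degree and closeness
#' undefined; they are reported as 0 with `whole_graph = TRUE`.
#'
#' @inheritParams nhood_enrichment
#' @return A `centrality_scores` tibble with one row per cluster.
#' @export
centrality_scores <- function(dataset, graph, label_key) {
  labels <- get_labels(dataset, label_key)
  lev <- levels(labels)
  g <- as_igraph(graph)
  nv <- igraph::vcount(g)
  A <- (graph$connectivity != 0)
  rows <- purrr::map(lev, function(cl) {
    S <- which(labels == cl)
    whole <- length(S) == nv
    if (whole) {
      cdeg <- 0; cclos <- 0
    } else {
      nbr <- which(Matrix::colSums(A[S, , drop = FALSE]) > 0)
      cdeg <- length(setdiff(nbr, S)) / (nv - length(S))
      d <- igraph::distances(g, v = S)
      dSv <- apply(d, 2L, min)[-S]
      reach <- is.finite(dSv)
      cclos <- if (any(reach)) sum(reach) / sum(dSv[reach]) else 0
    }
    lc <- igraph::transitivity(g, type = "localundirected", vids = S,
                               isolates = "zero")
    tibble(cluster = cl, degree_centrality = cdeg,
           closeness_centrality = cclos,
           average_clustering = mean(lc),
           whole_graph = whole)
  })
  new_spomics_tbl(dplyr::bind_rows(rows), "centrality_scores",
                  list(clusters = lev))
}

#' Group betweenness centrality per cluster
#'
#' `C_betw(S) = sum_{u < v, u,v not in S} g_uv(S) / g_uv`, the summed
#' proportion of shortest paths between non-members that pass through the
#' group; disconnected pairs are skipped. Shortest paths are counted on the
#' unweighted connectivity using the identity
#' `g_uv(S) = g_uv - [d_{G-S}(u,v) = d_G(u,v)] g_{G-S}(u,v)`.
#'
#' @inheritParams nhood_enrichment
#' @return A `group_betweenness` tibble (`cluster`, `betweenness`).
#' @export
group_betweenness <- function(dataset, graph, label_key) {
  labels <- get_labels(dataset, label_key)
  lev <- levels(labels)
  adj <- adjacency_list(graph)
  n <- length(adj)
  full <- bfs_path_counts_all(adj)
  rows <- purrr::map(lev, function(cl) {
    S <- which(labels == cl)
    out <- setdiff(seq_len(n), S)
    if (length(out) < 2) return(tibble(cluster = cl, betweenness = 0))
    sub_adj <- induced_adjacency(adj, out)
    sub <- bfs_path_counts_all(sub_adj)
    tot <- 0
    for (a in seq_along(out)) for (b in seq_along(out)) {
      if (b <= a) next
      u <- out[a]; v <- out[b]
      g_uv <- full$sigma[[u]][v]
      if (!is.finite(full$dist[[u]][v]) || g_uv == 0) next
      same_len <- is.finite(sub$dist[[a]][b]) && sub$dist[[a]][b] == full$dist[[u]][v]
      g_avoid <- if (same_len) sub$sigma[[a]][b] else 0
      tot <- tot + (g_uv - g_avoid) / g_uv
    }
    tibble(cluster = cl, betweenness = tot)
  })
  new_spomics_tbl(dplyr::bind_rows(rows), "group_betweenness",
                  list(clusters = lev))
}

adjacency_list <- function(graph) {
  A <- methods::as((graph$connectivity != 0) * 1, "CsparseMatrix")
  n <- nrow(A)
  tr <- Matrix::mat2triplet(A)
  split(tr$i, factor(tr$j, levels = seq_len(n)))
}

induced_adjacency <- function(adj, keep) {
  remap <- integer(length(adj)); remap[keep] <- seq_along(keep)
  lapply(adj[keep], function(nb) remap[nb[nb %in% keep]])
}

# BFS from every source: hop distances and shortest-path counts (sigma).
bfs_path_counts_all <- function(adj) {
  n <- length(adj)
  dist <- vector("list", n); sigma <- vector("list", n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); sg <- numeric(n)
    d[s] <- 0; sg[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        for (w in adj[[u]]) {
          if (!is.finite(d[w])) {
            d[w] <- d[u] + 1
            nxt <- c(nxt, w)
            sg[w] <- sg[w] + sg[u]
          } else if (d[w] == d[u] + 1) {
            sg[w] <- sg[w] + sg[u]
          }
        }
      }
      frontier <- unique(nxt)
    }
    dist[[s]] <- d; sigma[[s]] <- sg
  }
  list(dist = dist, sigma = sigma)
}
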