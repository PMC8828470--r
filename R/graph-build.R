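#' Spatial neighbour graphs
#'
#' A `spatial_graph` holds two sparse symmetric obs x obs matrices over the
#' observations of a dataset: `connectivity` (non-negative weights, zero
#' diagonal; ring ordinals for grid graphs, 1 otherwise) and `distances`
#' (Euclidean distances on the same sparsity pattern; absent edge = structural
#' zero, never an explicit 0 — coincident points get distance
#' `.Machine$double.eps`). `coord_type` is `"grid"` or `"generic"`.
#'
#' @name spatial_graph
NULL

new_spatial_graph <- function(connectivity, distances, coord_type, meta = list()) {
  g <- structure(
    list(connectivity = methods::as(Matrix::drop0(connectivity), "CsparseMatrix"),
         distances = methods::as(Matrix::drop0(distances), "CsparseMatrix"),
         coord_type = coord_type, meta = meta),
    class = "spatial_graph"
  )
  validate_spatial_graph(g)
  g
}

validate_spatial_graph <- function(g, n = NULL) {
  A <- g$connectivity; D <- g$distances
  if (!is.null(n) && nrow(A) != n) abort("Graph size differs from dataset n_obs.", class = "spomics_error")
  if (nrow(A) != ncol(A) || !all(dim(A) == dim(D))) abort("Graph matrices must be square and conformable.", class = "spomics_error")
  if (!Matrix::isSymmetric(A, tol = 0) || !Matrix::isSymmetric(D, tol = 0)) {
    abort("Graph matrices must be symmetric.", class = "spomics_error")
  }
  if (any(Matrix::diag(A) != 0) || any(Matrix::diag(D) != 0)) {
    abort("Graph diagonal must be zero.", class = "spomics_error")
  }
  if (any(A@x < 0)) abort("Connectivity weights must be non-negative.", class = "spomics_error")
  if (any(D@x <= 0)) abort("Stored distances must be positive.", class = "spomics_error")
  invisible(g)
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("<spatial_graph> %d nodes, %d edges, coord_type=%s\n",
              nrow(x$connectivity), n_edges(x), x$coord_type))
  invisible(x)
}

n_edges <- function(graph) length(graph$connectivity@x) / 2L

# Undirected edge list (i < j) with connectivity weight and distance.
edge_list <- function(graph) {
  tr <- Matrix::mat2triplet(Matrix::triu(graph$connectivity))
  d <- graph$distances[cbind(tr$i, tr$j)]
  data.frame(i = tr$i, j = tr$j, weight = tr$x, distance = d)
}

dist_sparse_from_pairs <- function(i, j, coords, n) {
  d <- sqrt((coords[i, 1] - coords[j, 1])^2 + (coords[i, 2] - coords[j, 2])^2)
  dup <- d == 0
  if (any(dup)) {
    warn("Coincident coordinates: zero distances replaced by machine epsilon.")
    d[dup] <- .Machine$double.eps
  }
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(d, d), dims = c(n, n))
}

#' Grid-lattice neighbour graph with ring weights
#'
#' For Visium-style coordinates lying on a triangular (hexagonal-neighbour,
#' `n_neigh = 6`) or square (`n_neigh = 4`) lattice, connects each spot to the
#' spots within `n_rings` rings. Connectivity weights are ring ordinals
#' (1 for immediate neighbours, 2 for the second ring, ...), computed by
#' breadth-first expansion on the ring-1 lattice graph; stored distances are
#' Euclidean. The lattice pitch is inferred as the modal nearest-neighbour
#' distance.
#'
#' @param dataset A [spatial_dataset].
#' @param n_neigh 6 (triangular/hex lattice) or 4 (square lattice).
#' @param n_rings Number of rings to connect (>= 1).
#' @return A [spatial_graph] with `coord_type = "grid"`.
#' @export
grid_graph <- function(dataset, n_neigh = 6, n_rings = 1) {
  stopifnot(n_neigh %in% c(4L, 6L), n_rings >= 1)
  coords <- coords_matrix(dataset)
  n <- nrow(coords)
  if (n < 2) abort("Need at least 2 observations.", class = "spomics_error")
  nn <- RANN::nn2(coords, k = 2L)
  pitch <- modal_value(nn$nn.dists[, 2])
  tol <- 0.1 * pitch
  k_cap <- min(n, 3L * n_neigh + 1L)
  cand <- RANN::nn2(coords, k = k_cap)
  in_ring1 <- abs(cand$nn.dists - pitch) <= tol & cand$nn.dists > 0
  deg1 <- rowSums(in_ring1)
  if (mean(deg1 == 0) > 0.05) {
    abort("Coordinates do not look lattice-like; use a generic graph (knn/radius/delaunay).",
          class = "spomics_structure_error")
  }
  ii <- rep(seq_len(n), times = rowSums(in_ring1))
  jj <- t(cand$nn.idx)[t(in_ring1)]
  A1 <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1, dims = c(n, n))
  A1 <- methods::as(A1 > 0, "dMatrix") * 1

  # BFS ring expansion: ring r nodes are neighbours of ring r-1 not yet seen.
  ring <- methods::as(A1, "CsparseMatrix")
  seen <- ring + Matrix::Diagonal(n)
  conn <- ring
  if (n_rings > 1) {
    frontier <- ring
    for (r in 2:n_rings) {
      nxt <- frontier %*% A1
      nxt <- Matrix::drop0((nxt > 0) - ((seen > 0) * 1) > 0) * 1
      if (!length(nxt@x)) break
      conn <- conn + nxt * r
      seen <- seen + nxt
      frontier <- nxt
    }
  }
  tr <- Matrix::mat2triplet(Matrix::triu(conn))
  D <- dist_sparse_from_pairs(tr$i, tr$j, coords, n)
  new_spatial_graph(conn, D, "grid",
                    list(type = "grid", n_neigh = n_neigh, n_rings = n_rings, pitch = pitch))
}

modal_value <- function(x, digits = 6) {
  r <- signif(x, digits)
  as.numeric(names(sort(table(r), decreasing = TRUE))[1])
}

#' k-nearest-neighbour graph
#'
#' Directed kNN relation symmetrized by union; self-matches excluded;
#' distance ties broken toward the lower observation index.
#'
#' @param dataset A [spatial_dataset].
#' @param n_neigh Number of neighbours per observation (`< n_obs`).
#' @return A [spatial_graph] with `coord_type = "generic"`.
#' @export
knn_graph <- function(dataset, n_neigh = 6) {
  coords <- coords_matrix(dataset)
  n <- nrow(coords)
  if (n_neigh >= n) abort("n_neigh must be smaller than n_obs.", class = "spomics_error")
  k_query <- min(n, n_neigh + 5L)
  nn <- RANN::nn2(coords, k = k_query)
  pick <- matrix(0L, n, n_neigh)
  for (u in seq_len(n)) {
    idx <- nn$nn.idx[u, ]
    d <- nn$nn.dists[u, ]
    keep <- idx != u
    idx <- idx[keep]; d <- d[keep]
    ord <- order(d, idx)
    pick[u, ] <- idx[ord][seq_len(n_neigh)]
  }
  ii <- rep(seq_len(n), each = n_neigh)
  jj <- as.vector(t(pick))
  A <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1, dims = c(n, n))
  A <- (A > 0) * 1
  tr <- Matrix::mat2triplet(Matrix::triu(A))
  D <- dist_sparse_from_pairs(tr$i, tr$j, coords, n)
  new_spatial_graph(A, D, "generic", list(type = "knn", n_neigh = n_neigh))
}

#' Fixed-radius neighbour graph
#'
#' Connects every pair of observations at Euclidean distance in
#' `(0, radius]`.
#'
#' @param dataset A [spatial_dataset].
#' @param radius Positive finite radius in coordinate units.
#' @return A [spatial_graph] with `coord_type = "generic"`.
#' @export
radius_graph <- function(dataset, radius) {
  stopifnot(is.finite(radius), radius > 0)
  coords <- coords_matrix(dataset)
  n <- nrow(coords)
  dm <- as.matrix(dist(coords))
  sel <- which(upper.tri(dm) & dm <= radius, arr.ind = TRUE)
  A <- Matrix::sparseMatrix(i = c(sel[, 1], sel[, 2]), j = c(sel[, 2], sel[, 1]),
                            x = 1, dims = c(n, n))
  D <- if (nrow(sel)) dist_sparse_from_pairs(sel[, 1], sel[, 2], coords, n) else
    Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(), dims = c(n, n))
  new_spatial_graph(A, D, "generic", list(type = "radius", radius = radius))
}

#' Delaunay-triangulation neighbour graph
#'
#' @param dataset A [spatial_dataset] with at least 3 non-collinear points.
#' @return A [spatial_graph] with `coord_type = "generic"`.
#' @export
delaunay_graph <- function(dataset) {
  coords <- coords_matrix(dataset)
  n <- nrow(coords)
  if (n < 3) abort("Delaunay triangulation needs >= 3 points.", class = "spomics_error")
  if (qr(sweep(coords, 2, colMeans(coords)))$rank < 2) {
    abort("Degenerate (collinear) coordinates: no triangulation exists.",
          class = "spomics_structure_error")
  }
  tri <- tryCatch(
    deldir::deldir(coords[, 1], coords[, 2], suppressMsge = TRUE),
    error = function(e) abort(paste0("Triangulation failed: ", conditionMessage(e)),
                              class = "spomics_structure_error")
  )
  del <- tri$delsgs
  if (is.null(del) || !nrow(del)) {
    abort("Degenerate (collinear/duplicate) input: no triangulation.",
          class = "spomics_structure_error")
  }
  i <- pmin(del$ind1, del$ind2); j <- pmax(del$ind1, del$ind2)
  keep <- !duplicated(cbind(i, j))
  i <- i[keep]; j <- j[keep]
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1, dims = c(n, n))
  D <- dist_sparse_from_pairs(i, j, coords, n)
  new_spatial_graph(A, D, "generic", list(type = "delaunay"))
}

#' Spectral or cosine transform of a graph adjacency
#'
#' `spectral` returns the symmetrically normalized adjacency
#' `D^(-1/2) A D^(-1/2)` (degree-diagonal `D`; isolated nodes keep zero
#' rows). `cosine` returns pairwise cosine similarity between adjacency rows
#' (nonzero wherever two nodes share a neighbour) with the diagonal removed.
#'
#' @param graph A [spatial_graph].
#' @param mode `"spectral"` or `"cosine"`.
#' @return A [spatial_graph] with transformed connectivity (distances kept).
#' @export
transform_graph <- function(graph, mode = c("spectral", "cosine")) {
  mode <- match.arg(mode)
  A <- graph$connectivity
  if (mode == "spectral") {
    deg <- Matrix::rowSums(A)
    s <- ifelse(deg > 0, 1 / sqrt(deg), 0)
    newA <- Matrix::Diagonal(x = s) %*% A %*% Matrix::Diagonal(x = s)
  } else {
    # full pairwise cosine similarity of adjacency rows (nodes with identical
    # neighbourhoods score 1 even when not adjacent); diagonal removed below
    nrm <- sqrt(Matrix::rowSums(A^2))
    s <- ifelse(nrm > 0, 1 / nrm, 0)
    newA <- Matrix::tcrossprod(Matrix::Diagonal(x = s) %*% A)
  }
  newA <- Matrix::drop0(newA)
  Matrix::diag(newA) <- 0
  out <- graph
  out$connectivity <- methods::as(Matrix::drop0(newA), "CsparseMatrix")
  out$meta$transform <- mode
  out
}

#' Export / import a graph as MatrixMarket files
#'
#' Writes `<prefix>.connectivity.mtx` and `<prefix>.distances.mtx`.
#'
#' @param graph A [spatial_graph].
#' @param prefix Output path prefix.
#' @return The two file paths, invisibly.
#' @export
write_graph_mtx <- function(graph, prefix) {
  pc <- paste0(prefix, ".connectivity.mtx")
  pd <- paste0(prefix, ".distances.mtx")
  Matrix::writeMM(methods::as(graph$connectivity, "generalMatrix"), pc)
  Matrix::writeMM(methods::as(graph$distances, "generalMatrix"), pd)
  invisible(c(pc, pd))
}

#' @rdname write_graph_mtx
#' @param coord_type Coordinate type recorded on the reloaded graph.
#' @export
read_graph_mtx <- function(prefix, coord_type = "generic") {
  # readMM may return pattern/symmetric classes; normalize to numeric general
  norm <- function(m) {
    methods::as(methods::as(Matrix::drop0(m * 1), "generalMatrix"), "CsparseMatrix")
  }
  A <- norm(Matrix::readMM(paste0(prefix, ".connectivity.mtx")))
  D <- norm(Matrix::readMM(paste0(prefix, ".distances.mtx")))
  new_spatial_graph(A, D, coord_type, list(type = "imported"))
}
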