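# Shared fixture builders: everything is generated in code at test time.

# Dataset from explicit coordinates (and optional labels / expression).
make_dataset <- function(coords, labels = NULL, X = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(X)) X <- matrix(1, n, 2, dimnames = list(NULL, c("g1", "g2")))
  lab <- if (is.null(labels)) NULL else data.frame(cluster = labels)
  spatial_dataset(X, data.frame(x = coords[, 1], y = coords[, 2]), labels = lab)
}

# Graph from an undirected edge list over given coordinates.
make_graph <- function(edges, coords, coord_type = "generic") {
  n <- nrow(coords)
  i <- pmin(edges[, 1], edges[, 2]); j <- pmax(edges[, 1], edges[, 2])
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1, dims = c(n, n))
  d <- sqrt((coords[i, 1] - coords[j, 1])^2 + (coords[i, 2] - coords[j, 2])^2)
  d[d == 0] <- 1
  D <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(d, d), dims = c(n, n))
  spomics:::new_spatial_graph((A > 0) * 1, D, coord_type, list(type = "manual"))
}

# Two k-node cliques with no between-edges, clique id as label.
make_two_cliques <- function(k = 10) {
  coords <- rbind(cbind(runif(k), runif(k)), cbind(10 + runif(k), runif(k)))
  edges <- rbind(t(utils::combn(1:k, 2)), t(utils::combn(k + 1:k, 2)))
  d <- make_dataset(coords, labels = rep(c("A", "B"), each = k))
  list(dataset = d, graph = make_graph(edges, coords))
}

# Erdos-Renyi graph over random coordinates.
make_random_graph <- function(n, p, seed) {
  set.seed(seed)
  coords <- cbind(runif(n), runif(n))
  pairs <- t(utils::combn(seq_len(n), 2))
  edges <- pairs[runif(nrow(pairs)) < p, , drop = FALSE]
  list(dataset = make_dataset(coords), graph = make_graph(edges, coords),
       coords = coords, edges = edges)
}

# Independent hex/square lattice ring oracle: BFS on the pitch-threshold
# adjacency using plain dense matrices.
brute_force_rings <- function(coords, pitch, n_rings) {
  dm <- as.matrix(dist(coords))
  A <- dm > 0 & abs(dm - pitch) <= 0.1 * pitch
  n <- nrow(A)
  rings <- matrix(0L, n, n)
  reach <- diag(n) > 0
  frontier <- reach
  for (r in seq_len(n_rings)) {
    nxt <- (frontier %*% A) > 0 & !reach
    rings[nxt] <- r
    reach <- reach | nxt
    frontier <- nxt
  }
  rings
}

# Dense-matrix Moran's I / Geary's C oracle (direct formula evaluation).
dense_autocorr <- function(x, W, mode) {
  W <- as.matrix(W)
  n <- length(x)
  z <- x - mean(x)
  S0 <- sum(W)
  if (mode == "moran") {
    (n / S0) * sum(W * outer(z, z)) / sum(z^2)
  } else {
    (n - 1) * sum(W * outer(x, x, function(a, b) (a - b)^2)) / (2 * S0 * sum(z^2))
  }
}

expect_valid_graph <- function(g) {
  expect_true(Matrix::isSymmetric(g$connectivity, tol = 0))
  expect_true(Matrix::isSymmetric(g$distances, tol = 0))
  expect_true(all(Matrix::diag(g$connectivity) == 0))
  expect_true(all(g$distances@x > 0))
}
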