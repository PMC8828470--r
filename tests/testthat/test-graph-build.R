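hex_lattice <- function(nx = 9, ny = 9, pitch = 1, seed = 1) {
  simulate_points(pattern = "lattice", lattice_type = "hex",
                  nx = nx, ny = ny, pitch = pitch, seed = seed)
}

interior_index <- function(d) {
  which.min((d$obs$x - mean(d$obs$x))^2 + (d$obs$y - mean(d$obs$y))^2)
}

test_that("hex lattice ring neighbourhoods match geometry and brute force", {
  d <- hex_lattice()
  ctr <- interior_index(d)
  g1 <- grid_graph(d, n_neigh = 6, n_rings = 1)
  expect_equal(g1$coord_type, "grid")
  w <- g1$connectivity[ctr, ]
  expect_equal(sum(w != 0), 6)
  expect_true(all(w[w != 0] == 1))

  g2 <- grid_graph(d, n_neigh = 6, n_rings = 2)
  w2 <- g2$connectivity[ctr, ]
  expect_equal(sum(w2 != 0), 18)
  expect_equal(sum(w2 == 1), 6)
  expect_equal(sum(w2 == 2), 12)

  oracle <- brute_force_rings(cbind(d$obs$x, d$obs$y), pitch = 1, n_rings = 2)
  expect_equal(unname(as.matrix(g2$connectivity)), oracle)
})

test_that("square lattice ring-1 gives 4 neighbours and matches brute force", {
  d <- simulate_points(pattern = "lattice", lattice_type = "square",
                       nx = 7, ny = 7, seed = 1)
  g <- grid_graph(d, n_neigh = 4, n_rings = 1)
  ctr <- interior_index(d)
  expect_equal(sum(g$connectivity[ctr, ] != 0), 4)
  oracle <- brute_force_rings(cbind(d$obs$x, d$obs$y), pitch = 1, n_rings = 1)
  expect_equal(unname(as.matrix(g$connectivity)), oracle)
})

test_that("non-lattice coordinates are rejected with a structure error", {
  d <- simulate_points(n_points = 100, pattern = "poisson", seed = 2)
  expect_error(grid_graph(d, 6, 1), class = "spomics_structure_error")
})

test_that("knn graph: hand cases and union symmetrization", {
  d <- make_dataset(cbind(c(0, 1, 3), 0))
  g <- knn_graph(d, 1)
  A <- as.matrix(g$connectivity)
  expect_equal(A[1, 2], 1)  # 0 and 1 mutually nearest
  expect_equal(A[2, 3], 1)  # 3's nearest is 1 -> union keeps it
  expect_equal(A[1, 3], 0)

  d10 <- simulate_points(n_points = 10, seed = 3)
  gc <- knn_graph(d10, 9)
  expect_equal(sum(gc$connectivity != 0), 10 * 9)  # complete graph
  g3 <- knn_graph(d10, 3)
  expect_true(all(Matrix::rowSums(g3$connectivity != 0) >= 3))
  # stored distances equal recomputed Euclidean distances
  el <- spomics:::edge_list(g3)
  co <- cbind(d10$obs$x, d10$obs$y)
  expect_equal(el$distance,
               sqrt(rowSums((co[el$i, ] - co[el$j, ])^2)), tolerance = 1e-9)
})

test_that("radius graph thresholds and is monotone in the radius", {
  sq <- make_dataset(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  expect_equal(sum(radius_graph(sq, 0.5)$connectivity), 0)
  expect_equal(sum(radius_graph(sq, 1)$connectivity != 0) / 2, 4)  # sides only
  expect_equal(sum(radius_graph(sq, 2)$connectivity != 0) / 2, 6)  # complete

  d <- simulate_points(n_points = 60, seed = 4)
  radii <- c(0.1, 0.2, 0.35, 0.6)
  sets <- lapply(radii, function(r) {
    el <- spomics:::edge_list(radius_graph(d, r))
    paste(el$i, el$j)
  })
  for (k in seq_len(length(radii) - 1)) {
    expect_true(all(sets[[k]] %in% sets[[k + 1]]))
  }
})

test_that("delaunay graph edge counts follow triangulation geometry", {
  tri <- make_dataset(cbind(c(0, 1, 0.5), c(0, 0, 1)))
  expect_equal(spomics:::n_edges(delaunay_graph(tri)), 3)
  quad <- make_dataset(cbind(c(0, 2, 2.1, -0.2), c(0, 0.1, 2, 1.9)))
  expect_equal(spomics:::n_edges(delaunay_graph(quad)), 5)
  set.seed(9)
  pts <- cbind(runif(20), runif(20))
  h <- length(grDevices::chull(pts))
  g <- delaunay_graph(make_dataset(pts))
  expect_equal(spomics:::n_edges(g), 3 * 20 - 3 - h)  # Euler relation
  expect_error(delaunay_graph(make_dataset(cbind(0:3, 0:3))),
               class = "spomics_structure_error")
})

test_that("spectral and cosine transforms match dense linear algebra", {
  # cycle C4: regular of degree 2
  co <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  g <- make_graph(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)), co)
  gs <- transform_graph(g, "spectral")
  expect_true(all(abs(gs$connectivity@x - 0.5) < 1e-12))

  # path P3 spectral against dense D^{-1/2} A D^{-1/2}
  co3 <- cbind(0:2, 0)
  p3 <- make_graph(rbind(c(1, 2), c(2, 3)), co3)
  A <- as.matrix(p3$connectivity)
  Dm <- diag(1 / sqrt(rowSums(A)))
  expect_equal(as.matrix(transform_graph(p3, "spectral")$connectivity),
               Dm %*% A %*% Dm, ignore_attr = TRUE, tolerance = 1e-12)

  # cosine of identical adjacency rows is 1
  gc <- transform_graph(g, "cosine")
  Ac <- as.matrix(gc$connectivity)
  expect_equal(Ac[1, 3], 1)  # opposite corners share both neighbours
  expect_true(all(diag(Ac) == 0))
})

test_that("all constructors produce valid symmetric zero-diagonal graphs", {
  d <- simulate_points(n_points = 50, seed = 11)
  dl <- hex_lattice(6, 6)
  for (g in list(knn_graph(d, 4), radius_graph(d, 0.25), delaunay_graph(d),
                 grid_graph(dl, 6, 2))) {
    expect_valid_graph(g)
  }
})
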