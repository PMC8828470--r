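test_that("segregated cliques enrich on the diagonal and deplete across", {
  set.seed(1)
  fx <- make_two_cliques(10)
  res <- nhood_enrichment(fx$dataset, fx$graph, "cluster",
                          n_perms = 10000, seed = 7)
  Z <- enrichment_matrix(res)
  expect_gt(Z["A", "A"], 0)
  expect_gt(Z["B", "B"], 0)
  expect_lt(Z["A", "B"], 0)
  # permutation oracle: recount x_AA by hand
  el <- spomics:::edge_list(fx$graph)
  lab <- fx$dataset$obs$cluster
  x_AA <- sum(lab[el$i] == "A" & lab[el$j] == "A")
  expect_equal(enrichment_matrix(res, "count")["A", "A"], x_AA)
})

test_that("single-label datasets give flagged zero z-scores", {
  set.seed(2)
  fx <- make_random_graph(20, 0.3, seed = 2)
  d <- fx$dataset
  d$obs$cluster <- factor(rep("only", 20))
  res <- nhood_enrichment(d, fx$graph, "cluster", n_perms = 50, seed = 1)
  expect_equal(res$zscore, 0)
  expect_true(all(res$sigma_zero))
})

test_that("identical seeds reproduce enrichment bit-for-bit", {
  fx <- make_random_graph(40, 0.15, seed = 3)
  d <- fx$dataset
  set.seed(99); d$obs$cluster <- factor(sample(c("a", "b", "c"), 40, TRUE))
  r1 <- nhood_enrichment(d, fx$graph, "cluster", n_perms = 300, seed = 5)
  r2 <- nhood_enrichment(d, fx$graph, "cluster", n_perms = 300, seed = 5)
  expect_identical(tidy(r1), tidy(r2))
})

test_that("interaction matrix uses ordered-pair counting", {
  co <- cbind(0:2, 0)
  g <- make_graph(rbind(c(1, 2), c(2, 3)), co)
  d <- make_dataset(co, labels = c("A", "B", "B"))
  M <- as.matrix(interaction_matrix(d, g, "cluster"))
  expect_equal(M["A", "B"], 1)
  expect_equal(M["B", "A"], 1)
  expect_equal(M["B", "B"], 2)
  expect_equal(M["A", "A"], 0)

  fx <- make_random_graph(30, 0.2, seed = 4)
  dd <- fx$dataset
  set.seed(4); dd$obs$cluster <- factor(sample(c("x", "y"), 30, TRUE))
  Mr <- as.matrix(interaction_matrix(dd, fx$graph, "cluster"))
  expect_equal(sum(Mr), 2 * nrow(fx$edges))
  Mn <- as.matrix(interaction_matrix(dd, fx$graph, "cluster", normalized = TRUE))
  expect_equal(unname(rowSums(Mn)), rep(1, 2))
})

test_that("centralities match hand computations on canonical graphs", {
  # star K1,3 with the centre its own cluster
  co <- cbind(c(0, 1, -1, 0), c(0, 0, 0, 1))
  star <- make_graph(rbind(c(1, 2), c(1, 3), c(1, 4)), co)
  d <- make_dataset(co, labels = c("hub", "leaf", "leaf", "leaf"))
  cs <- centrality_scores(d, star, "cluster")
  hub <- dplyr::filter(cs, cluster == "hub")
  expect_equal(hub$degree_centrality, 1)
  expect_equal(hub$closeness_centrality, 1)

  # triangle: every node has clustering coefficient 1
  cot <- cbind(c(0, 1, 0.5), c(0, 0, 1))
  tri <- make_graph(rbind(c(1, 2), c(2, 3), c(1, 3)), cot)
  dt <- make_dataset(cot, labels = c("a", "b", "b"))
  cst <- centrality_scores(dt, tri, "cluster")
  expect_equal(cst$average_clustering, c(1, 1))

  # cluster covering the whole graph is flagged and zeroed
  dall <- make_dataset(cot, labels = rep("all", 3))
  call <- centrality_scores(dall, tri, "cluster")
  expect_true(call$whole_graph)
  expect_equal(call$degree_centrality, 0)
})

test_that("group betweenness matches hand counts and path enumeration", {
  # path a-b-c: S={b} intercepts the single a-c shortest path
  co <- cbind(0:2, 0)
  p3 <- make_graph(rbind(c(1, 2), c(2, 3)), co)
  d <- make_dataset(co, labels = c("A", "B", "A"))
  gb <- group_betweenness(d, p3, "cluster")
  expect_equal(dplyr::filter(gb, cluster == "B")$betweenness, 1)

  # complete graph: no shortest path passes through any proper subset
  co4 <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  k4 <- make_graph(t(utils::combn(1:4, 2)), co4)
  d4 <- make_dataset(co4, labels = c("s", "s", "t", "t"))
  expect_equal(group_betweenness(d4, k4, "cluster")$betweenness, c(0, 0))

  # random graph vs igraph all_shortest_paths enumeration oracle
  fx <- make_random_graph(15, 0.25, seed = 6)
  d15 <- fx$dataset
  set.seed(6); d15$obs$cluster <- factor(sample(c("u", "v", "w"), 15, TRUE))
  mine <- group_betweenness(d15, fx$graph, "cluster")
  ig <- igraph::graph_from_adjacency_matrix(
    (fx$graph$connectivity != 0) * 1, mode = "undirected", diag = FALSE)
  for (cl in levels(d15$obs$cluster)) {
    S <- which(d15$obs$cluster == cl)
    out <- setdiff(1:15, S)
    tot <- 0
    for (a in seq_along(out)) for (b in seq_along(out)) {
      if (b <= a) next
      paths <- suppressWarnings(
        igraph::all_shortest_paths(ig, out[a], out[b])$vpaths)
      if (!length(paths)) next
      hit <- vapply(paths, function(p) any(as.integer(p) %in% S), logical(1))
      tot <- tot + mean(hit)
    }
    expect_equal(dplyr::filter(mine, cluster == cl)$betweenness, tot,
                 tolerance = 1e-12)
  }
})

test_that("closeness matches an independent multi-source BFS oracle", {
  fx <- make_random_graph(25, 0.12, seed = 8)
  d <- fx$dataset
  set.seed(8); d$obs$cluster <- factor(sample(c("p", "q"), 25, TRUE))
  cs <- centrality_scores(d, fx$graph, "cluster")
  A <- as.matrix(fx$graph$connectivity) != 0
  bfs_dist <- function(src) {
    dvec <- rep(Inf, 25); dvec[src] <- 0; frontier <- src
    while (length(frontier)) {
      nxt <- setdiff(which(colSums(A[frontier, , drop = FALSE]) > 0),
                     which(is.finite(dvec)))
      dvec[nxt] <- min(dvec[frontier]) + 1
      frontier <- nxt
    }
    dvec
  }
  for (cl in levels(d$obs$cluster)) {
    S <- which(d$obs$cluster == cl)
    dS <- do.call(pmin, lapply(S, bfs_dist))[-S]
    reach <- is.finite(dS)
    want <- if (any(reach)) sum(reach) / sum(dS[reach]) else 0
    expect_equal(dplyr::filter(cs, cluster == cl)$closeness_centrality, want)
  }
})

test_that("centrality ranges hold on random labelled graphs", {
  fx <- make_random_graph(40, 0.1, seed = 10)
  d <- fx$dataset
  set.seed(10); d$obs$cluster <- factor(sample(letters[1:4], 40, TRUE))
  cs <- centrality_scores(d, fx$graph, "cluster")
  expect_true(all(cs$degree_centrality >= 0 & cs$degree_centrality <= 1))
  expect_true(all(cs$closeness_centrality >= 0 & cs$closeness_centrality <= 1))
  expect_true(all(cs$average_clustering >= 0 & cs$average_clustering <= 1))
  expect_true(all(group_betweenness(d, fx$graph, "cluster")$betweenness >= 0))
})
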