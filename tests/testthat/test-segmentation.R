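test_that("RV coefficient matches the covariance-block oracle", {
  set.seed(1)
  X <- matrix(rnorm(12), 4, 3)
  Y <- matrix(rnorm(12), 4, 3) + 0.5 * X
  # brute-force oracle: explicit covariance blocks and the trace formula
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  Sxy <- crossprod(Xc, Yc) / 3; Sxx <- crossprod(Xc) / 3; Syy <- crossprod(Yc) / 3
  oracle <- sum(diag(Sxy %*% t(Sxy))) /
    sqrt(sum(diag(Sxx %*% Sxx)) * sum(diag(Syy %*% Syy)))
  expect_equal(rv_coefficient(X, Y), oracle, tolerance = 1e-12)
  # self-similarity and range
  expect_equal(rv_coefficient(X, X), 1)
  expect_gte(rv_coefficient(X, Y), 0)
  expect_lte(rv_coefficient(X, Y), 1)
  # invariance to orthogonal rotation of one block
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  expect_equal(rv_coefficient(X, Y %*% Q), rv_coefficient(X, Y),
               tolerance = 1e-12)
  # zero-variance block
  expect_warning(rv0 <- rv_coefficient(X, matrix(1, 4, 2)), "zero-variance")
  expect_equal(rv0, 0)
})

test_that("RV similarity matrix separates planted covariation blocks", {
  set.seed(2)
  n <- 200; L <- 20
  f1 <- rnorm(n); f2 <- rnorm(n)
  X <- matrix(rnorm(n * 3 * L, sd = 0.5), n, 3 * L)
  for (l in 1:10) X[, (3 * l - 2):(3 * l)] <- X[, (3 * l - 2):(3 * l)] + f1 %o% c(1, 0.5, -0.3)
  for (l in 11:20) X[, (3 * l - 2):(3 * l)] <- X[, (3 * l - 2):(3 * l)] + f2 %o% c(-0.4, 1, 0.6)
  rv <- build_similarity(X)
  expect_equal(dim(rv), c(L, L))
  expect_equal(unname(diag(rv)), rep(1, L))
  expect_true(isSymmetric(unclass(rv)))
  within1 <- rv[1:10, 1:10][upper.tri(matrix(0, 10, 10))]
  within2 <- rv[11:20, 11:20][upper.tri(matrix(0, 10, 10))]
  between <- rv[1:10, 11:20]
  expect_gt(mean(c(within1, within2)), 2 * mean(between))
  expect_error(build_similarity(matrix(c(1, NA, 3, 4, 5, 6), 2, 3)), "non-finite")
})

test_that("hierarchical segmentation yields the full binary tree structure", {
  tpl <- tiny_template(200, seed = 3)
  panel <- noise_panel(tpl, 80, sd = 1, seed = 4)
  X <- segcca:::flatten_coords(panel$coords)
  rv <- build_similarity(X)
  tree <- hierarchical_spectral_cluster(rv, tpl$adjacency, depth = 5, seed = 1)
  counts <- table(tree$nodes$level)
  expect_equal(nrow(tree$nodes), 63L)
  expect_equal(as.integer(counts[as.character(0:5)]), c(1L, 2L, 4L, 8L, 16L, 32L))
  # children partition their parent at every internal node
  for (pid in tree$nodes$node_id[tree$nodes$level < 5]) {
    p <- tree$landmarks[[as.character(pid)]]
    c1 <- tree$landmarks[[as.character(2 * pid)]]
    c2 <- tree$landmarks[[as.character(2 * pid + 1)]]
    expect_identical(sort(c(c1, c2)), p)
    expect_length(intersect(c1, c2), 0)
  }
  # every segment induces a connected subgraph
  for (key in as.character(tree$nodes$node_id)) {
    idx <- tree$landmarks[[key]]
    g <- igraph::graph_from_adjacency_matrix(
      tpl$adjacency[idx, idx, drop = FALSE], mode = "undirected")
    expect_equal(igraph::components(g)$no, 1L)
  }
  # a shallow tree has 4 leaves
  tree2 <- hierarchical_spectral_cluster(rv, tpl$adjacency, depth = 2, seed = 1)
  expect_equal(nrow(tree2$nodes), 7L)
  expect_equal(sum(tree2$nodes$level == 2), 4L)
  # a depth too large for the landmark count is refused
  small <- tiny_template(24, seed = 5)
  rvs <- build_similarity(segcca:::flatten_coords(noise_panel(small, 40, seed = 6)$coords))
  expect_error(hierarchical_spectral_cluster(rvs, small$adjacency, depth = 4),
               "smaller tree depth")
})

test_that("a planted two-blob structure is recovered exactly at depth one", {
  # two spatially separated blobs with independent covariation
  set.seed(7)
  c1 <- matrix(rnorm(30, sd = 1), 10, 3)
  c2 <- matrix(rnorm(30, sd = 1), 10, 3) + 50
  coords <- rbind(c1, c2)
  adj <- segcca:::knn_adjacency(coords, 4)
  n <- 150
  f1 <- rnorm(n); f2 <- rnorm(n)
  X <- matrix(rnorm(n * 60, sd = 0.3), n, 60)
  for (l in 1:10) X[, (3 * l - 2):(3 * l)] <- X[, (3 * l - 2):(3 * l)] + f1 %o% c(1, 1, 0)
  for (l in 11:20) X[, (3 * l - 2):(3 * l)] <- X[, (3 * l - 2):(3 * l)] + f2 %o% c(0, 1, 1)
  rv <- build_similarity(X)
  tree <- hierarchical_spectral_cluster(rv, adj, depth = 1, seed = 1)
  kids <- list(tree$landmarks[["2"]], tree$landmarks[["3"]])
  blobs <- list(1:10, 11:20)
  expect_true((identical(kids[[1]], blobs[[1]]) && identical(kids[[2]], blobs[[2]])) ||
                (identical(kids[[1]], blobs[[2]]) && identical(kids[[2]], blobs[[1]])))
})

test_that("parallel analysis keeps planted factors and drops noise", {
  tpl <- tiny_template(24, seed = 5)
  k <- 24
  tree <- single_node_tree(k)
  # pure iid noise around the template: at most 2 components retained in
  # nearly all seeded runs
  over <- 0
  for (s in 1:10) {
    panel <- noise_panel(tpl, 150, sd = 1, seed = 100 + s)
    sp <- suppressWarnings(
      segment_pca(panel$coords, tree, rep("c1", 150), pa_reps = 40, seed = s))
    if (sp$segments[["1"]]$retained > 2) over <- over + 1
  }
  expect_lte(over, 1)
  # three strong planted factors are retained exactly
  set.seed(11)
  n <- 200
  F3 <- matrix(rnorm(n * 3), n, 3)
  dirs <- qr.Q(qr(matrix(rnorm(3 * k * 3), 3 * k, 3)))
  A <- array(rep(tpl$coords, each = n), dim = c(n, k, 3))
  flat <- segcca:::flatten_coords(A) + 10 * F3 %*% t(dirs) +
    matrix(rnorm(n * 3 * k), n, 3 * k)
  sp3 <- segment_pca(segcca:::unflatten_coords(flat), tree, rep("c1", n),
                     pa_reps = 60, seed = 12)
  expect_equal(sp3$segments[["1"]]$retained, 3L)
  # loadings orthonormal
  B <- sp3$segments[["1"]]$basis
  expect_equal(crossprod(B), diag(ncol(B)), tolerance = 1e-8)
  # scores are consistent with the stored eigenvalues
  sc <- sp3$segments[["1"]]$scores
  expect_equal(unname(diag(crossprod(sc)) / (n - 1)),
               sp3$segments[["1"]]$eigenvalues[1:3], tolerance = 1e-8)
  # the retained-PC cap binds
  spc <- segment_pca(segcca:::unflatten_coords(flat), tree, rep("c1", n),
                     pa_reps = 60, seed = 12, max_pc = 2)
  expect_equal(spc$segments[["1"]]$retained, 2L)
})
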