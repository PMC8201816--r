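test_that("laplacian matches its definition on forced cases", {
  g0 <- laplacian_from_weights(matrix(0, 2, 2))
  expect_equal(g0$laplacian, matrix(0, 2, 2))

  g1 <- laplacian_from_weights(matrix(c(0, 1, 1, 0), 2))
  expect_equal(g1$laplacian, matrix(c(1, -1, -1, 1), 2))
})

test_that("laplacian of random weighted graphs has zero row sums and is PSD", {
  set.seed(11)
  for (rep in 1:20) {
    w <- random_symmetric_weights(6)
    g <- laplacian_from_weights(w)
    expect_lt(max(abs(rowSums(g$laplacian))), 1e-10)
    ev <- eigen(g$laplacian, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-9)
  }
})

test_that("laplacian_from_weights rejects malformed input, naming the offender", {
  expect_error(laplacian_from_weights(matrix(0, 2, 3)), "square")
  asym <- matrix(c(0, 1, 0.5, 0), 2)
  expect_error(laplacian_from_weights(asym), "W\\[1,2\\]|W\\[2,1\\]")
  neg <- matrix(c(0, -1, -1, 0), 2)
  expect_error(laplacian_from_weights(neg), "negative")
})

test_that("self-loops are stripped and do not change the laplacian", {
  w <- matrix(c(3, 1, 1, 7), 2)
  g <- laplacian_from_weights(w)
  expect_equal(diag(g$weights), c(0, 0))
  expect_equal(g$laplacian, matrix(c(1, -1, -1, 1), 2))
})

test_that("gsr_penalty annihilates constants and matches the single-edge case", {
  g <- laplacian_from_weights(matrix(c(0, 1, 1, 0), 2))
  expect_equal(gsr_penalty(c(5, 5), g), 0)
  expect_equal(gsr_penalty(c(1, 0), g), 1)
  gg <- grid_graph(3, 4)
  expect_equal(gsr_penalty(rep(2.5, 12), gg), 0)
})

test_that("quadratic-form penalty equals the brute-force pairwise sum", {
  set.seed(23)
  for (rep in 1:100) {
    n <- sample(2:20, 1)
    w <- random_symmetric_weights(n)
    g <- laplacian_from_weights(w)
    z <- matrix(rnorm(sample(1:10, 1) * n), ncol = n)
    expect_equal(gsr_penalty(z, g), pairwise_penalty_oracle(z, g$weights),
                 tolerance = 1e-8)
  }
})

test_that("penalty is nonnegative and scales quadratically", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(2:15, 1)
    g <- laplacian_from_weights(random_symmetric_weights(n))
    z <- matrix(rnorm(5 * n), ncol = n)
    p <- gsr_penalty(z, g)
    expect_gte(p, 0)
    c_ <- runif(1, 0.1, 10)
    expect_equal(gsr_penalty(c_ * z, g), c_^2 * p, tolerance = 1e-8 * c_^2 * p + 1e-12)
  }
})

test_that("gsr_penalty rejects a column/node mismatch", {
  g <- complete_graph(4)
  expect_error(gsr_penalty(matrix(0, 2, 3), g), "match graph nodes|nodes")
})

test_that("grid graphs have lattice structure", {
  g11 <- grid_graph(1, 1)
  expect_equal(g11$n_nodes, 1)
  expect_equal(sum(g11$weights), 0)

  g88 <- grid_graph(8, 8)
  expect_equal(g88$n_nodes, 64)
  expect_equal(sum(g88$weights[upper.tri(g88$weights)] > 0), 112)
  degrees <- rowSums(g88$weights)
  expect_true(all(degrees %in% c(2, 3, 4)))

  g23 <- grid_graph(2, 3)
  expect_equal(sort(rowSums(g23$weights)), c(2, 2, 2, 2, 3, 3))
  expect_error(grid_graph(0, 3), "positive")
})

test_that("disjoint pairs graph is a block-diagonal union of edges", {
  g3 <- disjoint_pairs_graph(3)
  expect_equal(g3$n_nodes, 6)
  expect_equal(sum(g3$weights) / 2, 3)
  expect_equal(connected_components(g3, 0)$n_components, 3)

  g1 <- disjoint_pairs_graph(1)
  expect_equal(g1$laplacian, matrix(c(1, -1, -1, 1), 2))

  g4 <- disjoint_pairs_graph(4)
  block <- matrix(c(1, -1, -1, 1), 2)
  for (p in 1:4) {
    idx <- (2 * p - 1):(2 * p)
    expect_equal(g4$laplacian[idx, idx], block)
    expect_equal(sum(abs(g4$laplacian[idx, -idx])), 0)
  }
  expect_error(disjoint_pairs_graph(0), "positive")
})

test_that("complete graph matches its closed forms", {
  g2 <- complete_graph(2)
  expect_equal(sum(g2$weights) / 2, 1)

  g10 <- complete_graph(10)
  expect_equal(rowSums(g10$weights), rep(9, 10))
  expect_equal(sum(g10$weights[upper.tri(g10$weights)] > 0), 45)
  expect_equal(g10$laplacian, 10 * diag(10) - matrix(1, 10, 10))

  for (n in c(3, 5, 8)) {
    z <- c(1, -1, rep(0, n - 2))
    expect_equal(gsr_penalty(z, complete_graph(n)), 2 * n)
  }
})

test_that("adaptive kernel matches the closed form for two features", {
  x <- rbind(c(0, 0, 0), c(2, 0, 0))
  g <- adaptive_gaussian_kernel(x, kernel_params(k = 1))
  expect_equal(g$weights[1, 2], exp(-1 / 2), tolerance = 1e-12)
  expect_equal(g$weights[1, 1], 0)
})

test_that("adaptive kernel agrees with a scalar-loop oracle", {
  set.seed(47)
  for (k in 1:3) {
    x <- matrix(rnorm(5 * 20), 5, 20)
    g <- adaptive_gaussian_kernel(x, kernel_params(k = k))
    expect_equal(g$weights, kernel_oracle(x, k), tolerance = 1e-12)
    expect_identical(g$weights, t(g$weights))
    expect_true(all(g$weights >= 0 & g$weights <= 1))
    expect_lt(max(abs(rowSums(g$laplacian))), 1e-10)
  }
})

test_that("adaptive kernel guards its degenerate cases", {
  x <- matrix(1, 3, 10)  # all features identical
  expect_warning(g <- adaptive_gaussian_kernel(x, kernel_params(k = 1)),
                 "floor")
  expect_true(all(is.finite(g$weights)))
  expect_error(adaptive_gaussian_kernel(matrix(rnorm(20), 2, 10),
                                        kernel_params(k = 2)),
               "k \\+ 1")
})

test_that("connected components follow strict-threshold semantics", {
  expect_equal(connected_components(disjoint_pairs_graph(3), 0)$n_components, 3)
  k5 <- complete_graph(5)
  expect_equal(connected_components(k5, 0)$n_components, 1)
  expect_equal(connected_components(k5, 1.0)$n_components, 5)
})

test_that("component labels match a union-find oracle and are deterministic", {
  set.seed(59)
  for (rep in 1:25) {
    n <- sample(3:15, 1)
    w <- random_symmetric_weights(n, density = 0.25)
    g <- laplacian_from_weights(w)
    thr <- runif(1, 0, 0.8)
    got <- connected_components(g, thr)
    want <- union_find_components(g$weights, thr)
    expect_identical(got$labels, want)
    expect_equal(got$n_components, length(unique(want)))
  }
  # lowest node index in a component carries the smallest label
  g <- laplacian_from_weights(rbind(c(0, 0, 1), c(0, 0, 0), c(1, 0, 0)))
  expect_identical(connected_components(g, 0)$labels, c(0L, 1L, 0L))
})

test_that("edge-list TSV round-trips a weighted graph", {
  set.seed(61)
  g <- laplacian_from_weights(random_symmetric_weights(7, density = 0.4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_true(all(tab$node_i < tab$node_j))
  g2 <- read_edge_list(path, n_nodes = 7)
  expect_equal(g2$weights, g$weights, tolerance = 1e-12)
  expect_equal(g2$laplacian, g$laplacian, tolerance = 1e-12)
})

test_that("graphml export is readable by a graph library", {
  g <- grid_graph(2, 3)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, path)
  ig <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(ig), 6)
  expect_equal(igraph::ecount(ig), 7)
})

test_that("laplacian CSV export is dense and labeled", {
  g <- disjoint_pairs_graph(2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_laplacian_csv(g, path)
  m <- as.matrix(read.csv(path))
  dimnames(m) <- NULL
  expect_equal(m, g$laplacian)
})
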