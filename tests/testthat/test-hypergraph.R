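test_that("hypergraph construction validates its invariants", {
  g <- hypergraph(3, list(c(1, 2), 3))
  expect_equal(g$weights, c(1, 1))
  expect_error(hypergraph(3, list(integer(0))),
               class = "wpinjury_invalid_hypergraph")
  expect_error(hypergraph(3, list(c(1, 4))),
               class = "wpinjury_invalid_hypergraph")
  expect_error(hypergraph(3, list(c(1, 2)), weights = -1),
               class = "wpinjury_invalid_hypergraph")
  h <- incidence_matrix(g)
  expect_true(all(h %in% c(0, 1)))
  expect_equal(colSums(h), lengths(g$hyperedges))
})

test_that("KNN hyperedges contain each vertex plus its nearest neighbours", {
  g <- build_knn_hypergraph(matrix(c(0, 1, 10), ncol = 1), k = 1)
  expect_equal(g$hyperedges, list(c(1L, 2L), c(1L, 2L), c(2L, 3L)))
  expect_equal(g$weights, rep(1, 3))

  # k = n - 1: every hyperedge is the full vertex set
  g_full <- build_knn_hypergraph(matrix(rnorm(12), 4), k = 3)
  expect_true(all(vapply(g_full$hyperedges, identical, logical(1), 1:4)))

  # equidistant duplicates: the tie goes to the lower vertex index
  g_tie <- build_knn_hypergraph(matrix(c(0, 0, 0), ncol = 1), k = 1)
  expect_equal(g_tie$hyperedges, list(c(1L, 2L), c(1L, 2L), c(1L, 3L)))

  expect_error(build_knn_hypergraph(matrix(rnorm(4), 2), k = 2),
               class = "wpinjury_invalid_parameter")
  expect_error(build_knn_hypergraph(matrix(c(1, NA), 1), k = 1),
               class = "wpinjury_invalid_parameter")
})

test_that("KNN builds exactly n hyperedges of size k + 1", {
  withr::with_seed(3, x <- matrix(rnorm(60), 12))
  g <- build_knn_hypergraph(x, k = 4)
  expect_length(g$hyperedges, 12)
  expect_true(all(lengths(g$hyperedges) == 5))
  expect_true(all(vapply(seq_len(12), function(v) v %in% g$hyperedges[[v]],
                         logical(1))))
})

test_that("vertex and hyperedge degrees sum weighted incidences", {
  d1 <- hypergraph_degrees(hypergraph(3, list(c(1, 2, 3))))
  expect_equal(d1$Dv, c(1, 1, 1))
  expect_equal(d1$De, 3)

  d2 <- hypergraph_degrees(hypergraph(3, list(c(1, 2))))
  expect_equal(d2$Dv[3], 0)

  d3 <- hypergraph_degrees(hypergraph(3, list(c(1, 2), c(2, 3)),
                                      weights = c(2, 3)))
  expect_equal(d3$Dv[2], 5)
})

test_that("the clique-expansion Laplacian matches hand-derived values", {
  b <- hypergraph_laplacian(hypergraph(2, list(c(1, 2))))
  expect_equal(b$A, matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(b$L, matrix(c(0.5, -0.5, -0.5, 0.5), 2))

  singletons <- hypergraph_laplacian(hypergraph(3, list(1, 2, 3)))
  expect_equal(singletons$A, matrix(0, 3, 3))
  expect_equal(singletons$L, matrix(0, 3, 3))
})

test_that("L is symmetric PSD with zero row sums on random hypergraphs", {
  for (seed in 1:25) {
    b <- hypergraph_laplacian(random_hypergraph(seed))
    expect_equal(b$L, t(b$L))
    expect_true(all(abs(rowSums(b$L)) < 1e-10))
    expect_gte(min(eigen(b$L, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
    expect_true(all(b$A >= 0))
  }
})

test_that("smoothness equals the brute-force pairwise sum", {
  b <- hypergraph_laplacian(hypergraph(2, list(c(1, 2))))
  expect_equal(smoothness(matrix(c(0, 1)), b), 0.25)
  expect_equal(smoothness(matrix(1, 5, 3),
                          hypergraph_laplacian(random_hypergraph(4, 5, 4))), 0,
               tolerance = 1e-12)
  for (seed in 1:30) {
    g <- random_hypergraph(seed)
    b <- hypergraph_laplacian(g)
    withr::with_seed(seed + 100, x <- matrix(rnorm(g$n_vertices * 3),
                                             g$n_vertices))
    s1 <- smoothness(x, b)
    s2 <- brute_smoothness(x, b$A)
    expect_equal(s1, s2, tolerance = 1e-8)
    # quadratic homogeneity
    expect_equal(smoothness(2.5 * x, b), 2.5^2 * s1, tolerance = 1e-10)
  }
  expect_error(smoothness(matrix(0, 3, 2),
                          hypergraph_laplacian(hypergraph(2, list(c(1, 2))))),
               class = "wpinjury_shape_error")
})

test_that("the edge-space operator equals De - H'H on hyperedge space", {
  g <- random_hypergraph(9)
  le <- edge_space_laplacian(g)
  h <- incidence_matrix(g)
  expect_equal(dim(le), rep(length(g$hyperedges), 2))
  expect_equal(le, diag(lengths(g$hyperedges), length(g$hyperedges)) -
                 t(h) %*% h)
  # diagonal: De(e) - |e| = 0 under unit vertex weights
  expect_true(all(abs(diag(le)) < 1e-12))
})

test_that("hypergraph JSON round trip is lossless", {
  g <- random_hypergraph(17)
  path <- withr::local_tempfile(fileext = ".json")
  write_hypergraph_json(g, path)
  g2 <- read_hypergraph_json(path)
  expect_equal(g2$n_vertices, g$n_vertices)
  expect_identical(g2$hyperedges, g$hyperedges)
  expect_equal(g2$weights, g$weights)
})
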