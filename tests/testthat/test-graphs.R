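test_that("cell-gene graph weights are within-cell expression fractions", {
  ds <- sc_dataset(matrix(c(1, 3), 1, 2),
                   cell_ids = "c1", gene_ids = c("g0", "g1"))
  g <- cell_gene_graph(ds)
  expect_true(g$bipartite)
  expect_equal(sort(g$edges$w), c(0.25, 0.75))
  # zero entries produce no edge
  ds2 <- sc_dataset(rbind(c(2, 0), c(1, 1)))
  g2 <- cell_gene_graph(ds2)
  expect_equal(nrow(g2$edges), 3)
  expect_error(cell_gene_graph(sc_dataset(rbind(c(1, 1), c(0, 0)))),
               "all-zero cell")
  # invariant: incident weights of every cell sum to 1 on random sparse input
  for (rep in 1:20) {
    X <- matrix(rpois(12 * 9, 0.8), 12, 9)
    X[rowSums(X) == 0, 1] <- 1
    gr <- cell_gene_graph(sc_dataset(X))
    A <- graph_adjacency(gr)
    expect_equal(Matrix::rowSums(A)[1:12], rep(1, 12), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("bipartite graphs refuse same-role edges", {
  expect_error(sc_graph(c("a", "b"), c("cell", "cell"),
                        data.frame(u = 1, v = 2, w = 1), bipartite = TRUE),
               "same role")
  expect_error(sc_graph("a", "cell", data.frame(u = 1, v = 1, w = -1)),
               "non-negative")
})

test_that("knn graph mutualizes neighbours with deterministic tie-breaks", {
  emb <- matrix(c(0, 1, 10), 3, 1)    # collinear points
  g <- knn_graph(emb, 1)
  e <- g$edges[order(g$edges$u, g$edges$v), ]
  expect_equal(unname(as.matrix(e[, 1:2])), rbind(c(1, 2), c(2, 3)))
  # k = n-1 gives the complete graph
  gk <- knn_graph(matrix(rnorm(10), 5, 2), 4)
  expect_equal(nrow(gk$edges), choose(5, 2))
  # duplicated points: stable tie-break by index across runs
  dup <- matrix(c(0, 0, 0, 1), 4, 1)
  g1 <- knn_graph(dup, 1); g2 <- knn_graph(dup, 1)
  expect_identical(g1$edges, g2$edges)
  # translation invariance
  emb2 <- matrix(rnorm(20), 10, 2)
  ga <- knn_graph(emb2, 3)
  gb <- knn_graph(emb2 + 5, 3)
  expect_identical(ga$edges, gb$edges)
  expect_error(knn_graph(emb2, 10), "k must satisfy")
})

test_that("adjacency normalization follows the degree formulas", {
  # single node with a self-loop keeps weight 1
  g <- sc_graph("a", "cell", data.frame(u = 1, v = 1, w = 1))
  gn <- normalize_adjacency(g, "sym", add_self_loops = FALSE)
  expect_equal(gn$edges$w, 1)
  # two nodes, one unit edge, no self-loops: degrees 1 and 1 -> weight 1
  g2 <- sc_graph(c("a", "b"), c("cell", "cell"),
                 data.frame(u = 1, v = 2, w = 1))
  gn2 <- normalize_adjacency(g2, "sym", add_self_loops = FALSE)
  expect_equal(gn2$edges$w[gn2$edges$u != gn2$edges$v], 1)
  # row mode: every non-isolated row of the implied matrix sums to 1
  g3 <- knn_graph(matrix(rnorm(12), 6, 2), 2)
  gn3 <- normalize_adjacency(g3, "row", add_self_loops = TRUE)
  rs <- tapply(gn3$edges$w, gn3$edges$u, sum)
  expect_equal(as.vector(rs), rep(1, 6), tolerance = 1e-12)
  # isolated node without self-loops is undefined in row mode
  iso <- sc_graph(c("a", "b"), c("cell", "cell"),
                  data.frame(u = integer(0), v = integer(0), w = numeric(0)))
  expect_error(normalize_adjacency(iso, "row", add_self_loops = FALSE),
               "isolated")
})

test_that("propagate is the normalized weighted neighbourhood sum", {
  # identity graph: self-loops only
  g <- sc_graph(c("a", "b"), c("cell", "cell"),
                data.frame(u = 1:2, v = 1:2, w = 1))
  gn <- normalize_adjacency(g, "sym", add_self_loops = FALSE)
  f <- matrix(rnorm(4), 2, 2)
  expect_equal(propagate(f, gn), f, ignore_attr = TRUE)
  # row-normalized complete 2-graph with self-loops averages the rows
  g2 <- sc_graph(c("a", "b"), c("cell", "cell"),
                 data.frame(u = 1, v = 2, w = 1))
  gn2 <- normalize_adjacency(g2, "row", add_self_loops = TRUE)
  out <- propagate(f, gn2)
  expect_equal(out[1, ], colMeans(f), ignore_attr = TRUE)
  expect_equal(out[2, ], colMeans(f), ignore_attr = TRUE)
  # linearity
  g3 <- normalize_adjacency(knn_graph(matrix(rnorm(16), 8, 2), 3), "sym")
  F1 <- matrix(rnorm(24), 8, 3); F2 <- matrix(rnorm(24), 8, 3)
  expect_equal(propagate(2 * F1 - 3 * F2, g3),
               2 * propagate(F1, g3) - 3 * propagate(F2, g3),
               tolerance = 1e-9)
  expect_equal(propagate(F1 * 0, g3), F1 * 0, ignore_attr = TRUE)
  expect_error(propagate(matrix(0, 3, 2), g3), "nodes")
  expect_error(propagate(F1, knn_graph(matrix(rnorm(16), 8, 2), 3)),
               "normalized")
})

test_that("edge list export writes ids and weights", {
  g <- cell_gene_graph(sc_dataset(matrix(c(1, 3), 1, 2)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, path)
  tab <- read.delim(path)
  expect_equal(sort(tab$w), c(0.25, 0.75))
})
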