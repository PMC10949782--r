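make_ds <- function(X, ...) sc_dataset(X, ...)

# permute cells while keeping ids/tables aligned (test-local helper)
subset_cells_for_test <- function(ds, idx) {
  ds$X <- ds$X[idx, , drop = FALSE]
  ds$layers <- lapply(ds$layers, function(m) m[idx, , drop = FALSE])
  ds$cell_ids <- ds$cell_ids[idx]
  ds$cell_table <- ds$cell_table[idx, , drop = FALSE]
  ds
}

test_that("filter_features keeps genes by expression support", {
  # hand count: columns expressed in [2, 1, 1] cells
  X <- rbind(c(1, 0, 0), c(2, 0, 0), c(0, 3, 0), c(0, 0, 0) + c(0, 0, 1))
  ds <- make_ds(X)
  out <- filter_features(ds, min_cells_expressing = 2)
  expect_identical(out$gene_ids, ds$gene_ids[1])
  expect_equal(as.matrix(out$X), X[, 1, drop = FALSE], ignore_attr = TRUE)
  # thresholds zero: identity on the gene set
  expect_identical(filter_features(ds, 0)$gene_ids, ds$gene_ids)
  # dropping everything is an error
  expect_error(filter_features(ds, 10), "empty dataset")
  # cells axis is symmetric
  outc <- filter_features(ds, min_cells_expressing = 1, axis = "cells")
  expect_equal(n_cells(outc), 4)
})

test_that("normalize_total puts every cell at the target and records a layer", {
  ds <- make_ds(rbind(c(1, 3), c(5, 5)))
  out <- normalize_total(ds, 4)
  expect_equal(as.vector(out$X[1, ]), c(1, 3))
  expect_equal(rowSums(as.matrix(out$X)), c(4, 4))
  expect_true("normalized" %in% names(out$layers))
  out1 <- normalize_total(ds, 1)
  expect_equal(as.vector(out1$X[1, ]), c(0.25, 0.75))
  expect_error(normalize_total(make_ds(rbind(c(1, 1), c(0, 0)))),
               "all-zero cell")
  # property: random non-degenerate inputs
  for (rep in 1:5) {
    X <- matrix(rexp(30), 5, 6) + 1e-3
    rs <- rowSums(as.matrix(normalize_total(make_ds(X), 123.4)$X))
    expect_equal(rs, rep(123.4, 5), tolerance = 1e-9)
  }
})

test_that("log1p transform is exact and monotone", {
  ds <- make_ds(rbind(c(0, exp(1) - 1), c(2, 7)))
  out <- log1p_transform(ds)
  expect_equal(as.vector(out$X[1, ]), c(0, 1))
  X <- matrix(rexp(40), 5, 8)
  ord_before <- order(X)
  ord_after <- order(as.matrix(log1p_transform(make_ds(X))$X))
  expect_identical(ord_before, ord_after)
})

test_that("select_top_genes ranks by totals with id tie-break", {
  X <- rbind(c(5, 9, 9, 1), c(0, 0, 0, 0) + 0)
  ds <- make_ds(X, gene_ids = c("g0", "g1", "g2", "g3"))
  out <- select_top_genes(ds, 2)
  expect_identical(out$gene_ids, c("g1", "g2"))
  expect_identical(select_top_genes(ds, 10)$gene_ids, ds$gene_ids)
  expect_equal(formals(select_top_genes)$k, 3000L)
  # invariance to cell permutation
  dsx <- tiny_labeled_dataset()
  perm <- sample(n_cells(dsx))
  a <- select_top_genes(dsx, 7)$gene_ids
  b <- select_top_genes(subset_cells_for_test(dsx, perm), 7)$gene_ids
  expect_identical(a, b)
})

test_that("zscore scaling centers, scales and clips per gene", {
  ds <- make_ds(rbind(c(0, 5), c(2, 5)))
  out <- zscore_scale(ds)
  Z <- out$layers$scaled
  expect_equal(Z[, 1], c(-1, 1), ignore_attr = TRUE)   # population sd
  expect_equal(Z[, 2], c(0, 0), ignore_attr = TRUE)    # constant gene
  X <- matrix(c(0, 0, 0, 0, 0, 30), 6, 1)              # outlier beyond clip
  Zc <- zscore_scale(make_ds(X), clip = 1)$layers$scaled
  expect_equal(max(Zc), 1)
})

test_that("pca embedding preserves geometry and is sign-deterministic", {
  # rank-1 case: points on a line
  t_par <- seq(0, 1, length.out = 8)
  X <- cbind(1 + 2 * t_par, 3 + 4 * t_par)
  emb <- pca_embed(make_ds(X), 1)
  expect_equal(as.matrix(dist(emb)), as.matrix(dist(X)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # full-rank rotation preserves all pairwise distances
  Xf <- matrix(rexp(60), 10, 6)
  embf <- pca_embed(make_ds(Xf), 6)
  expect_equal(as.matrix(dist(embf)), as.matrix(dist(scale(Xf, scale = FALSE))),
               tolerance = 1e-8, ignore_attr = TRUE)
  # determinism under the sign convention, any seeds
  expect_identical(pca_embed(make_ds(Xf), 3, seed = 1),
                   pca_embed(make_ds(Xf), 3, seed = 99))
  expect_error(pca_embed(make_ds(Xf), 11), "must be in")
})

test_that("pipelines serialize bit-exactly and equal sequential application", {
  p <- sc_pipeline(list(transform_step("normalize_total", target_sum = 1),
                        transform_step("log1p")))
  ds <- make_ds(matrix(c(1, 3), 1, 2))
  out <- apply_pipeline(p, ds)
  expect_equal(as.vector(out$X), c(log(1.25), log(1.75)))
  # empty pipeline is the identity
  expect_equal(as.matrix(apply_pipeline(sc_pipeline(), ds)$X),
               as.matrix(ds$X))
  # JSON round trip: identical steps and identical application
  json <- pipeline_to_json(p)
  p2 <- pipeline_from_json(json)
  expect_identical(pipeline_to_json(p2), json)
  expect_equal(as.matrix(apply_pipeline(p2, ds)$X), as.matrix(out$X))
  # failing step reports its index
  bad <- sc_pipeline(list(transform_step("log1p"),
                          transform_step("nope")))
  expect_error(apply_pipeline(bad, ds), "step 2")
  # purity: the input object is never modified
  before <- as.matrix(ds$X)
  invisible(apply_pipeline(p, ds))
  expect_identical(as.matrix(ds$X), before)
})

test_that("default pipelines exist per model and unknown models error", {
  p <- default_pipeline("zinb_dec")
  nm <- vapply(p$steps, `[[`, "", "name")
  expect_identical(nm, c("filter_features", "normalize_total", "log1p",
                         "select_top_genes"))
  expect_equal(p$steps[[4]]$params$k, 3000L)
  # linear-scale deconvolution pipeline omits the log transform
  expect_false("log1p" %in%
                 vapply(default_pipeline("nnls_deconv")$steps, `[[`, "",
                        "name"))
  expect_error(default_pipeline("nope"), "unknown model")
})
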