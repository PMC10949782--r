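test_that("dataset constructor enforces its invariants", {
  X <- matrix(c(1, 0, 2, 3), 2, 2)
  ds <- sc_dataset(X, layers = list(raw = X))
  expect_s3_class(ds, "sc_dataset")
  expect_equal(dim(ds), c(2, 2))
  expect_error(sc_dataset(matrix(-1, 1, 1)), "negative")
  expect_error(sc_dataset(matrix(NaN, 1, 1)), "non-finite")
  expect_error(sc_dataset(X, cell_ids = c("a", "a")), "unique")
  expect_error(sc_dataset(X, layers = list(raw = matrix(0.5, 2, 2))),
               "integers")
  expect_error(sc_dataset(X, layers = list(z = matrix(0, 3, 3))), "shape")
})

test_that("bundle write/read round-trips integer data exactly and floats to 1e-12", {
  X <- matrix(rpois(12, 4), 3, 4)
  storage.mode(X) <- "double"
  lay <- matrix(runif(12), 3, 4)
  ds <- sc_dataset(X, cell_ids = paste0("c", 1:3),
                   gene_ids = paste0("g", 1:4),
                   cell_table = data.frame(cell_id = paste0("c", 1:3),
                                           cell_type = c("a", "b", "a")),
                   layers = list(raw = X, normalized = lay))
  ds <- log_append(ds, "made_up", list(k = 2))
  dir <- withr::local_tempdir()
  write_bundle(ds, dir)
  back <- read_bundle(dir)
  expect_equal(as.matrix(back$X), X, ignore_attr = TRUE)
  expect_equal(as.matrix(get_layer(back, "raw")), X, ignore_attr = TRUE)
  expect_equal(as.matrix(get_layer(back, "normalized")), lay,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$cell_ids, ds$cell_ids)
  expect_identical(back$cell_table$cell_type, c("a", "b", "a"))
  expect_identical(vapply(back$log, `[[`, "", "name"),
                   vapply(ds$log, `[[`, "", "name"))
  expect_error(read_bundle(withr::local_tempdir()), "meta.json")
})

test_that("matrix market loader validates dimensions and keeps empty cells", {
  dir <- withr::local_tempdir()
  X <- matrix(c(1, 0, 0, 2, 3, 0), 2, 3)    # second row has zeros only at end
  ds0 <- sc_dataset(X, cell_ids = c("b1", "b2"),
                    gene_ids = c("g1", "g2", "g3"), layers = list(raw = X))
  write_bundle(ds0, dir)
  ds <- load_matrix_market(dir)
  expect_equal(as.matrix(ds$X), X, ignore_attr = TRUE)
  # dimension mismatch: truncate features.tsv
  writeLines(c("g1", "g2"), file.path(dir, "features.tsv"))
  expect_error(load_matrix_market(dir), "dimension mismatch")
  expect_error(load_matrix_market(withr::local_tempdir()), "missing file")
  # an all-zero cell is retained by the reader (filtering is a transform)
  dir2 <- withr::local_tempdir()
  X2 <- rbind(c(1, 2), c(0, 0))
  write_bundle(sc_dataset(X2, layers = list(raw = X2)), dir2)
  expect_equal(nrow(load_matrix_market(dir2)$X), 2)
})

test_that("csv loader handles orientation and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,g1,g2", "c1,1,0", "c2,2,3"), path)
  ds <- load_csv_matrix(path)
  expect_equal(as.matrix(ds$X), matrix(c(1, 2, 0, 3), 2, 2),
               ignore_attr = TRUE)
  expect_identical(ds$cell_ids, c("c1", "c2"))
  dst <- load_csv_matrix(path, cells_in_rows = FALSE)
  expect_equal(as.matrix(dst$X), t(matrix(c(1, 2, 0, 3), 2, 2)),
               ignore_attr = TRUE)
  writeLines(c("id,g1,g2", "c1,1,-1", "c2,2,3"), path)
  expect_error(load_csv_matrix(path), "negative")
})

test_that("dataset registry is deterministic and lists names on error", {
  expect_error(get_dataset("pbmc"), "synth_blobs4")
  ds1 <- get_dataset("synth_blobs4")
  ds2 <- get_dataset("synth_blobs4")
  expect_identical(as.matrix(ds1$X), as.matrix(ds2$X))
  expect_equal(dim(ds1), c(400, 200))
  expect_equal(length(unique(ds1$cell_table$cell_type)), 4)
  register_dataset("tmp_fixture", function() tiny_labeled_dataset())
  expect_true("tmp_fixture" %in% list_datasets())
  expect_s3_class(get_dataset("tmp_fixture"), "sc_dataset")
})

test_that("split partitions are disjoint, exhaustive and stratified within one cell", {
  ds <- tiny_labeled_dataset(n_cells = 10)
  parts <- split_dataset(ds, 0.2, seed = 0)
  expect_equal(n_cells(parts$train) + n_cells(parts$test), 10)
  expect_length(intersect(parts$train$cell_ids, parts$test$cell_ids), 0)
  expect_equal(n_cells(parts$test), 2)
  # property over random sizes and fractions
  for (rep in 1:10) {
    n <- sample(4:80, 1)
    frac <- runif(1, 0.1, 0.9)
    ds_r <- simulate_counts(synthetic_spec(n_cells = n, n_genes = 12,
                                           K = 2, depth = 300, seed = rep))
    pr <- split_dataset(ds_r, frac, seed = rep)
    expect_setequal(c(pr$train$cell_ids, pr$test$cell_ids), ds_r$cell_ids)
    expect_length(intersect(pr$train$cell_ids, pr$test$cell_ids), 0)
  }
  # stratified: balanced 2-class, fraction 0.5 -> each class split 50/50 +-1
  dsb <- tiny_labeled_dataset(n_cells = 40)
  pb <- split_dataset(dsb, 0.5, stratify_by = "cell_type", seed = 1)
  for (cl in unique(dsb$cell_table$cell_type)) {
    n_tr <- sum(pb$train$cell_table$cell_type == cl)
    n_te <- sum(pb$test$cell_table$cell_type == cl)
    expect_lte(abs(n_tr - n_te), 1)
  }
  # determinism
  p1 <- split_dataset(ds, 0.3, seed = 5)
  p2 <- split_dataset(ds, 0.3, seed = 5)
  expect_identical(p1$test$cell_ids, p2$test$cell_ids)
  # singleton class refuses stratification
  ds1 <- ds
  ds1$cell_table$cell_type[1] <- "rare"
  expect_error(split_dataset(ds1, 0.5, stratify_by = "cell_type"),
               "single member")
})

test_that("derivations append exactly one log entry each", {
  ds <- tiny_labeled_dataset()
  n0 <- length(ds$log)
  for (op in list(function(d) filter_features(d, 1),
                  function(d) normalize_total(d),
                  function(d) log1p_transform(d),
                  function(d) select_top_genes(d, 10),
                  function(d) zscore_scale(d))) {
    out <- op(ds)
    expect_equal(length(out$log), n0 + 1)
  }
})
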