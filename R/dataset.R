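#' Single-cell dataset container
#'
#' `sc_dataset()` bundles a cells x genes expression matrix with per-cell and
#' per-gene annotation tables, optional named layers sharing the matrix shape,
#' and an append-only log of the transforms that produced it.  The orientation
#' convention is fixed package-wide: cells are rows, genes are columns.
#'
#' @param X numeric matrix (dense `matrix` or a `Matrix` sparse matrix),
#'   cells as rows, genes as columns, non-negative and finite.
#' @param cell_ids character vector of unique cell identifiers (barcodes).
#' @param gene_ids character vector of unique gene identifiers.
#' @param cell_table data.frame of per-cell annotations.  Recognised columns:
#'   `cell_type` (character/factor), `batch`, `split` ("train"/"test"),
#'   `x_coord`, `y_coord` (numeric, for spatial spots).
#' @param gene_table data.frame of per-gene annotations.
#' @param layers named list of matrices with the same shape as `X`.  The layer
#'   `"raw"` is reserved for untouched counts and must be integer-valued.
#' @param log list of transform records, each `list(name=, params=)`.
#'
#' @return An object of class `sc_dataset`.
#' @export
sc_dataset <- function(X, cell_ids = NULL, gene_ids = NULL,
                       cell_table = NULL, gene_table = NULL,
                       layers = list(), log = list()) {
  if (is.null(dim(X)) || length(dim(X)) != 2L)
    stop("X must be a two-dimensional matrix")
  if (is.null(cell_ids)) cell_ids <- rownames(X)
  if (is.null(gene_ids)) gene_ids <- colnames(X)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(X)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(X)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (is.null(cell_table)) cell_table <- data.frame(cell_id = cell_ids,
                                                   stringsAsFactors = FALSE)
  if (is.null(gene_table)) gene_table <- data.frame(gene_id = gene_ids,
                                                    stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(cell_table)) cell_table$cell_id <- cell_ids
  if (!"gene_id" %in% names(gene_table)) gene_table$gene_id <- gene_ids
  rownames(cell_table) <- NULL
  rownames(gene_table) <- NULL
  ds <- structure(list(X = X, layers = layers,
                       cell_ids = cell_ids, gene_ids = gene_ids,
                       cell_table = cell_table, gene_table = gene_table,
                       log = log),
                  class = "sc_dataset")
  validate_sc_dataset(ds)
  ds
}

#' @keywords internal
validate_sc_dataset <- function(ds) {
  X <- ds$X
  if (length(ds$cell_ids) != nrow(X))
    stop("length(cell_ids) must equal nrow(X)")
  if (length(ds$gene_ids) != ncol(X))
    stop("length(gene_ids) must equal ncol(X)")
  if (anyDuplicated(ds$cell_ids)) stop("cell_ids must be unique")
  if (anyDuplicated(ds$gene_ids)) stop("gene_ids must be unique")
  check_mat <- function(m, label) {
    v <- mat_values(m)
    if (any(!is.finite(v))) stop("non-finite entries in ", label)
    if (any(v < 0)) stop("negative entries in ", label)
  }
  check_mat(X, "X")
  for (nm in names(ds$layers)) {
    lay <- ds$layers[[nm]]
    if (!all(dim(lay) == dim(X)))
      stop("layer '", nm, "' shape differs from X")
    check_mat(lay, paste0("layer '", nm, "'"))
    if (identical(nm, "raw")) {
      v <- mat_values(lay)
      if (any(abs(v - round(v)) > 1e-8))
        stop("layer 'raw' must contain non-negative integers")
    }
  }
  if (nrow(ds$cell_table) != nrow(X)) stop("cell_table rows must match cells")
  if (nrow(ds$gene_table) != ncol(X)) stop("gene_table rows must match genes")
  invisible(ds)
}

## Nonzero (sparse) or all (dense) values of a matrix -- enough for
## sign/finiteness checks because implicit sparse entries are exact zeros.
#' @keywords internal
mat_values <- function(m) {
  if (inherits(m, "sparseMatrix")) {
    v <- methods::slot(methods::as(m, "generalMatrix"), "x")
    if (length(v) == 0) numeric(1) else v
  } else {
    as.vector(m)
  }
}

#' @keywords internal
as_dense <- function(m) {
  if (inherits(m, "Matrix")) as.matrix(m) else m
}

#' Number of cells / genes in a dataset
#' @param ds an `sc_dataset`.
#' @return integer count.
#' @export
n_cells <- function(ds) nrow(ds$X)

#' @rdname n_cells
#' @export
n_genes <- function(ds) ncol(ds$X)

#' @export
dim.sc_dataset <- function(x) dim(x$X)

#' Retrieve a named layer
#' @param ds an `sc_dataset`.
#' @param name layer name, e.g. `"raw"` or `"normalized"`.
#' @return the layer matrix.
#' @export
get_layer <- function(ds, name) {
  if (!name %in% names(ds$layers))
    stop("no layer '", name, "'; available: ",
         paste(names(ds$layers), collapse = ", "))
  ds$layers[[name]]
}

#' Append a transform record to a dataset's log
#' @param ds an `sc_dataset`.
#' @param name transform name.
#' @param params named list of parameters (serializable scalars).
#' @return the dataset with one more log entry.
#' @export
log_append <- function(ds, name, params = list()) {
  ds$log[[length(ds$log) + 1L]] <- list(name = name, params = params)
  ds
}

## Subset helpers keep ids, tables and every layer consistent.
#' @keywords internal
subset_cells <- function(ds, idx) {
  ds$X <- ds$X[idx, , drop = FALSE]
  ds$layers <- lapply(ds$layers, function(m) m[idx, , drop = FALSE])
  ds$cell_ids <- ds$cell_ids[idx]
  ds$cell_table <- ds$cell_table[idx, , drop = FALSE]
  rownames(ds$cell_table) <- NULL
  ds
}

#' @keywords internal
subset_genes <- function(ds, idx) {
  ds$X <- ds$X[, idx, drop = FALSE]
  ds$layers <- lapply(ds$layers, function(m) m[, idx, drop = FALSE])
  ds$gene_ids <- ds$gene_ids[idx]
  ds$gene_table <- ds$gene_table[idx, , drop = FALSE]
  rownames(ds$gene_table) <- NULL
  ds
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat("sc_dataset:", nrow(x$X), "cells x", ncol(x$X), "genes\n")
  if (length(x$layers))
    cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  extra <- setdiff(names(x$cell_table), "cell_id")
  if (length(extra))
    cat("  cell annotations:", paste(extra, collapse = ", "), "\n")
  if (length(x$log)) {
    nm <- vapply(x$log, function(e) e$name, character(1))
    cat("  log:", paste(nm, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Train/test split of a dataset by cells
#'
#' Partitions the cells of a dataset into disjoint, exhaustive train and test
#' subsets, optionally stratifying by an annotation column so that class
#' proportions in both parts match the full dataset to within one cell.
#'
#' @param ds an `sc_dataset` with at least 2 cells.
#' @param test_fraction fraction of cells assigned to the test part, in (0,1).
#' @param stratify_by optional name of a `cell_table` column to stratify on.
#' @param seed integer seed; identical seeds give identical index sets.
#' @return list with elements `train` and `test` (both `sc_dataset`).
#' @export
split_dataset <- function(ds, test_fraction, stratify_by = NULL, seed = 0L) {
  stopifnot(inherits(ds, "sc_dataset"))
  n <- n_cells(ds)
  if (n < 2) stop("need at least 2 cells to split")
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0,1)")
  pick <- function(idx, frac) {
    k <- round(length(idx) * frac)
    k <- max(0L, min(length(idx), k))
    if (length(idx) == 1L) return(integer(0))  # never empty a singleton group
    sample(idx, k)
  }
  test_idx <- withr::with_seed(seed, {
    if (is.null(stratify_by)) {
      k <- max(1L, min(n - 1L, round(n * test_fraction)))
      sample.int(n, k)
    } else {
      if (!stratify_by %in% names(ds$cell_table))
        stop("no cell_table column '", stratify_by, "'")
      cls <- as.character(ds$cell_table[[stratify_by]])
      counts <- table(cls)
      if (any(counts < 2))
        stop("stratified class with a single member; use an unstratified split")
      unlist(lapply(split(seq_len(n), cls), pick, frac = test_fraction),
             use.names = FALSE)
    }
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n), test_idx)
  if (!length(test_idx) || !length(train_idx))
    stop("split produced an empty part; adjust test_fraction")
  tr <- log_append(subset_cells(ds, train_idx), "split",
                   list(part = "train", test_fraction = test_fraction,
                        seed = seed))
  te <- log_append(subset_cells(ds, test_idx), "split",
                   list(part = "test", test_fraction = test_fraction,
                        seed = seed))
  tr$cell_table$split <- "train"
  te$cell_table$split <- "test"
  list(train = tr, test = te)
}
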