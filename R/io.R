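#' Read a CellRanger-style Matrix Market bundle
#'
#' Loads `matrix.mtx`, `barcodes.tsv` and `features.tsv` from a directory into
#' an [sc_dataset].  The 10x triplet on disk is genes x cells; it is transposed
#' on load so that cells are rows, the package-wide orientation.  The loaded
#' counts are stored both as the working matrix and as layer `"raw"`.
#'
#' @param directory path containing `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv`.
#' @param genes_in_rows orientation of the mtx file on disk; `TRUE` (the 10x
#'   convention, default) means rows are genes.
#' @return an [sc_dataset] with layer `"raw"` and one log entry.
#' @export
load_matrix_market <- function(directory, genes_in_rows = TRUE) {
  paths <- file.path(directory, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  for (p in paths)
    if (!file.exists(p)) stop("missing file: ", p)
  m <- Matrix::readMM(paths[1])
  barcodes <- readLines(paths[2])
  features <- readLines(paths[3])
  ## features.tsv may carry extra tab-separated columns (10x writes id\tname)
  gene_ids <- vapply(strsplit(features, "\t"), `[[`, character(1), 1L)
  if (genes_in_rows) m <- Matrix::t(m)
  if (nrow(m) != length(barcodes))
    stop("dimension mismatch: matrix has ", nrow(m),
         " cells but barcodes.tsv has ", length(barcodes), " lines")
  if (ncol(m) != length(gene_ids))
    stop("dimension mismatch: matrix has ", ncol(m),
         " genes but features.tsv has ", length(gene_ids), " lines")
  m <- methods::as(m, "CsparseMatrix")
  ## the raw-counts layer only applies to integer-valued matrices (a bundle
  ## may legitimately store an already-normalized working matrix)
  vals <- mat_values(m)
  layers <- if (all(abs(vals - round(vals)) <= 1e-8)) list(raw = m)
  else list()
  ds <- sc_dataset(m, cell_ids = barcodes, gene_ids = gene_ids,
                   layers = layers)
  log_append(ds, "load_matrix_market",
             list(directory = as.character(directory)))
}

#' Read a dense CSV/TSV expression matrix
#'
#' @param path file with a header row of ids and a first column of ids.
#' @param cells_in_rows if `FALSE`, the file is genes x cells and is transposed
#'   on load.
#' @param delimiter field delimiter; no auto-detection.
#' @return an [sc_dataset] with layer `"raw"` when counts are integer-valued.
#' @export
load_csv_matrix <- function(path, cells_in_rows = TRUE, delimiter = ",") {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          row.names = 1, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  if (any(!is.finite(m))) stop("non-finite entries in ", path)
  if (any(m < 0)) stop("negative entries in ", path)
  if (!cells_in_rows) m <- t(m)
  layers <- if (all(abs(m - round(m)) <= 1e-8)) list(raw = m) else list()
  ds <- sc_dataset(m, cell_ids = rownames(m), gene_ids = colnames(m),
                   layers = layers)
  log_append(ds, "load_csv_matrix",
             list(path = as.character(path), cells_in_rows = cells_in_rows))
}

#' Write / read a dataset bundle
#'
#' `write_bundle()` serializes a dataset to a directory as plain-text files:
#' `matrix.mtx` (genes x cells, 10x orientation), `barcodes.tsv`,
#' `features.tsv`, `cell_table.tsv`, layer matrices as `layer_<name>.mtx`, and
#' `meta.json` (layer names and the transform log).  `read_bundle()` is its
#' inverse: exact on integer data, within relative 1e-12 on float layers.
#'
#' @param ds an [sc_dataset].
#' @param directory target directory (created if absent).
#' @return `write_bundle` returns the directory path invisibly; `read_bundle`
#'   returns an [sc_dataset].
#' @export
write_bundle <- function(ds, directory) {
  stopifnot(inherits(ds, "sc_dataset"))
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE,
                                            showWarnings = FALSE)
  if (!ok || file.access(directory, mode = 2) != 0)
    stop("cannot write to directory: ", directory)
  write_mm <- function(m, path) {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(
      Matrix::t(m), sparse = TRUE), "generalMatrix"), "CsparseMatrix"), path)
  }
  write_mm(ds$X, file.path(directory, "matrix.mtx"))
  writeLines(ds$cell_ids, file.path(directory, "barcodes.tsv"))
  writeLines(ds$gene_ids, file.path(directory, "features.tsv"))
  utils::write.table(ds$cell_table, file.path(directory, "cell_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$gene_table, file.path(directory, "gene_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(ds$layers))
    write_mm(ds$layers[[nm]], file.path(directory, paste0("layer_", nm, ".mtx")))
  meta <- list(layers = as.list(names(ds$layers)), log = ds$log)
  jsonlite::write_json(meta, file.path(directory, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(directory)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(directory) {
  meta_path <- file.path(directory, "meta.json")
  if (!file.exists(meta_path)) stop("not a bundle directory (no meta.json): ",
                                    directory)
  ds <- load_matrix_market(directory)
  meta <- jsonlite::read_json(meta_path, simplifyVector = FALSE)
  layers <- list()
  for (nm in unlist(meta$layers)) {
    m <- Matrix::t(Matrix::readMM(file.path(directory,
                                            paste0("layer_", nm, ".mtx"))))
    layers[[nm]] <- methods::as(m, "CsparseMatrix")
  }
  ct_path <- file.path(directory, "cell_table.tsv")
  cell_table <- utils::read.table(ct_path, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE,
                                  colClasses = c(cell_id = "character"))
  gt_path <- file.path(directory, "gene_table.tsv")
  gene_table <- utils::read.table(gt_path, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE,
                                  colClasses = c(gene_id = "character"))
  log <- lapply(meta$log, function(e)
    list(name = e$name, params = lapply(e$params, identity)))
  sc_dataset(ds$X, cell_ids = ds$cell_ids, gene_ids = ds$gene_ids,
             cell_table = cell_table, gene_table = gene_table,
             layers = layers, log = log)
}

## ---- named fixture registry ------------------------------------------------

the_registry <- new.env(parent = emptyenv())
the_registry$datasets <- list()   # name -> generator function()
the_registry$cache <- list()      # name -> memoised sc_dataset

#' Register a named dataset
#'
#' The registry maps dataset names to generator functions, mirroring
#' load-by-name data access.  Built-in synthetic fixtures embed their seeds,
#' so the same name always yields an identical dataset; results are memoised
#' per session.
#'
#' @param name dataset name.
#' @param generator zero-argument function returning the dataset object.
#' @return `name`, invisibly.
#' @export
register_dataset <- function(name, generator) {
  stopifnot(is.character(name), length(name) == 1, is.function(generator))
  the_registry$datasets[[name]] <- generator
  the_registry$cache[[name]] <- NULL
  invisible(name)
}

#' Fetch a registered dataset by name
#'
#' @param name a registered dataset name; see [list_datasets()].
#' @return the registered object (an [sc_dataset], or an `sc_mixture` for
#'   deconvolution fixtures).
#' @export
get_dataset <- function(name) {
  if (!name %in% names(the_registry$datasets))
    stop("unknown dataset '", name, "'; available: ",
         paste(sort(names(the_registry$datasets)), collapse = ", "))
  if (is.null(the_registry$cache[[name]]))
    the_registry$cache[[name]] <- the_registry$datasets[[name]]()
  the_registry$cache[[name]]
}

#' List registered dataset names
#' @return character vector of names.
#' @export
list_datasets <- function() sort(names(the_registry$datasets))
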