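#' Preprocessing transforms and pipelines
#'
#' Transforms are pure functions `sc_dataset -> sc_dataset`; a [sc_pipeline]
#' is an ordered list of named transform steps that serializes losslessly to
#' JSON, so a model's preprocessing is reproducible from its run record alone.
#'
#' @name transforms
NULL

#' Filter rarely expressed genes (or empty cells)
#'
#' Keeps, along the chosen axis, the features expressed (count > 0) in at
#' least `min_cells_expressing` observations and with total counts at least
#' `min_counts`.  The default threshold of 3 expressing cells quantifies
#' "rarely expressed"; it is configurable.
#'
#' @param ds an [sc_dataset].
#' @param min_cells_expressing minimum number of cells with a nonzero value
#'   (for `axis = "genes"`); symmetric meaning for cells.
#' @param axis `"genes"` (default) or `"cells"`.
#' @param min_counts minimum total count.
#' @return filtered [sc_dataset] with ids and tables subset consistently.
#' @export
filter_features <- function(ds, min_cells_expressing = 3L, axis = "genes",
                            min_counts = 0L) {
  stopifnot(inherits(ds, "sc_dataset"))
  axis <- match.arg(axis, c("genes", "cells"))
  if (min_cells_expressing < 0 || min_counts < 0)
    stop("thresholds must be >= 0")
  X <- ds$X
  if (axis == "genes") {
    nnz <- Matrix::colSums(X > 0)
    tot <- Matrix::colSums(X)
  } else {
    nnz <- Matrix::rowSums(X > 0)
    tot <- Matrix::rowSums(X)
  }
  keep <- which(nnz >= min_cells_expressing & tot >= min_counts)
  if (!length(keep))
    stop("filter_features would remove every ", axis,
         "; an empty dataset is invalid")
  out <- if (axis == "genes") subset_genes(ds, keep) else subset_cells(ds, keep)
  log_append(out, "filter_features",
             list(min_cells_expressing = min_cells_expressing, axis = axis,
                  min_counts = min_counts))
}

#' Normalize each cell to the same total count
#'
#' Scales every cell (row) so its entries sum to `target_sum`, the library-size
#' normalization preceding most models here.  The result also becomes layer
#' `"normalized"`.
#'
#' @param ds an [sc_dataset] without all-zero cells.
#' @param target_sum positive row total after scaling (default 1e4).
#' @return normalized [sc_dataset].
#' @export
normalize_total <- function(ds, target_sum = 1e4) {
  stopifnot(inherits(ds, "sc_dataset"))
  if (!is.numeric(target_sum) || target_sum <= 0)
    stop("target_sum must be a positive real")
  rs <- Matrix::rowSums(ds$X)
  if (any(rs == 0))
    stop("all-zero cell present; run filter_features(axis = 'cells') first")
  ds$X <- ds$X * (target_sum / rs)  # row-wise recycling over columns
  ds$layers[["normalized"]] <- ds$X
  log_append(ds, "normalize_total", list(target_sum = target_sum))
}

#' Entrywise log(1 + x)
#'
#' @param ds an [sc_dataset] (non-negative by invariant).
#' @return transformed [sc_dataset].
#' @export
log1p_transform <- function(ds) {
  stopifnot(inherits(ds, "sc_dataset"))
  ds$X <- if (inherits(ds$X, "sparseMatrix")) {
    m <- methods::as(methods::as(ds$X, "generalMatrix"), "CsparseMatrix")
    m@x <- log1p(m@x)
    m
  } else log1p(ds$X)
  log_append(ds, "log1p", list())
}

#' Keep the most highly expressed genes
#'
#' Retains the `k` genes with the largest total raw-scale counts across cells
#' (all genes when `k >= n_genes`).  Ranking uses total expression, not
#' dispersion; ties break deterministically by ascending gene id.  The default
#' `k = 3000` follows the usual clustering preprocessing.
#'
#' @param ds an [sc_dataset].
#' @param k number of genes to keep, `>= 1`.
#' @return gene-subset [sc_dataset].
#' @export
select_top_genes <- function(ds, k = 3000L) {
  stopifnot(inherits(ds, "sc_dataset"))
  if (k < 1) stop("k must be >= 1")
  tot <- Matrix::colSums(ds$X)
  ord <- order(-tot, ds$gene_ids)
  keep <- sort(ord[seq_len(min(k, length(tot)))])
  out <- subset_genes(ds, keep)
  log_append(out, "select_top_genes", list(k = k))
}

#' Per-gene z-score scaling with clipping
#'
#' Centers each gene to mean 0 and population (divide-by-n) unit variance;
#' zero-variance genes become all zeros; entries are clipped to
#' `[-clip, clip]`.  Result is dense.
#'
#' @param ds an [sc_dataset] with at least 2 cells.
#' @param clip positive clipping bound (default 10).
#' @return scaled [sc_dataset].
#' @export
zscore_scale <- function(ds, clip = 10) {
  stopifnot(inherits(ds, "sc_dataset"))
  if (n_cells(ds) < 2) stop("zscore_scale needs at least 2 cells")
  if (!is.numeric(clip) || clip <= 0) stop("clip must be positive")
  X <- as_dense(ds$X)
  mu <- colMeans(X)
  sd_pop <- sqrt(pmax(colMeans(X^2) - mu^2, 0))
  Z <- sweep(X, 2, mu, "-")
  nz <- sd_pop > 0
  Z[, nz] <- sweep(Z[, nz, drop = FALSE], 2, sd_pop[nz], "/")
  Z[, !nz] <- 0
  Z <- pmin(pmax(Z, -clip), clip)
  ## z-scores are signed, outside the non-negative dataset contract: shift is
  ## not wanted, so scaled data lives in a layer and X stays untouched.
  ds$layers[["scaled"]] <- Z
  log_append(ds, "zscore_scale", list(clip = clip))
}

#' PCA embedding of cells
#'
#' Centered (never whitened) principal components of the working matrix, with
#' a deterministic sign convention: within each component the loading of
#' largest magnitude is positive.  Randomness plays no role; `seed` is
#' accepted for pipeline-signature uniformity.
#'
#' @param ds an [sc_dataset].
#' @param d number of components, `1 <= d <= min(n_cells, n_genes)`.
#' @param seed ignored (deterministic), kept for interface uniformity.
#' @return numeric matrix, cells x `d`.
#' @export
pca_embed <- function(ds, d, seed = 0L) {
  stopifnot(inherits(ds, "sc_dataset"))
  p <- min(n_cells(ds), n_genes(ds))
  if (d < 1 || d > p) stop("d must be in [1, ", p, "]")
  pr <- stats::prcomp(as_dense(ds$X), center = TRUE, scale. = FALSE, rank. = d)
  flip <- vapply(seq_len(ncol(pr$rotation)), function(j) {
    v <- pr$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  emb <- sweep(pr$x[, seq_len(d), drop = FALSE], 2, flip[seq_len(d)], "*")
  rownames(emb) <- ds$cell_ids
  emb
}

## ---- pipeline machinery ----------------------------------------------------

## transform name -> function(ds, params...) used by apply_pipeline()
transform_fns <- function() list(
  filter_features = filter_features,
  normalize_total = normalize_total,
  log1p           = function(ds) log1p_transform(ds),
  select_top_genes = select_top_genes,
  zscore_scale    = zscore_scale
)

#' Construct a preprocessing pipeline
#'
#' @param steps list of steps, each created by [transform_step()].
#' @return object of class `sc_pipeline`.
#' @export
sc_pipeline <- function(steps = list()) {
  for (s in steps)
    if (!inherits(s, "transform_step")) stop("steps must be transform_step()s")
  structure(list(steps = steps), class = "sc_pipeline")
}

#' @rdname sc_pipeline
#' @param name registered transform name (see [apply_pipeline()]).
#' @param ... flat, serializable transform parameters.
#' @export
transform_step <- function(name, ...) {
  params <- list(...)
  if (length(params) && is.null(names(params)))
    stop("transform parameters must be named")
  structure(list(name = name, params = params), class = "transform_step")
}

#' @export
print.sc_pipeline <- function(x, ...) {
  cat("sc_pipeline with", length(x$steps), "step(s)\n")
  for (s in x$steps) {
    p <- if (length(s$params))
      paste0("(", paste(names(s$params), unlist(s$params), sep = "=",
                        collapse = ", "), ")")
    else "()"
    cat("  -", s$name, p, "\n")
  }
  invisible(x)
}

#' Apply a pipeline to a dataset
#'
#' Equivalent to applying each step in order; the input object is never
#' modified.  A failing step reports its 1-based index.
#'
#' @param p an [sc_pipeline].
#' @param ds an [sc_dataset].
#' @return transformed [sc_dataset].
#' @export
apply_pipeline <- function(p, ds) {
  stopifnot(inherits(p, "sc_pipeline"), inherits(ds, "sc_dataset"))
  fns <- transform_fns()
  for (i in seq_along(p$steps)) {
    s <- p$steps[[i]]
    fn <- fns[[s$name]]
    if (is.null(fn)) stop("pipeline step ", i, ": unknown transform '",
                          s$name, "'")
    ds <- tryCatch(do.call(fn, c(list(ds), s$params)),
                   error = function(e)
                     stop("pipeline step ", i, " (", s$name, "): ",
                          conditionMessage(e), call. = FALSE))
  }
  ds
}

#' Serialize / deserialize a pipeline as JSON
#'
#' The JSON schema is `{"steps": [{"name": ..., "params": {...}}]}` and the
#' round trip is bit-exact.
#'
#' @param p an [sc_pipeline].
#' @return `pipeline_to_json` a JSON string; `pipeline_from_json` an
#'   [sc_pipeline].
#' @export
pipeline_to_json <- function(p) {
  stopifnot(inherits(p, "sc_pipeline"))
  steps <- lapply(p$steps, function(s)
    list(name = s$name,
         params = if (length(s$params)) s$params else structure(list(),
                                                                names = character(0))))
  jsonlite::toJSON(list(steps = steps), auto_unbox = TRUE, digits = NA)
}

#' @rdname pipeline_to_json
#' @param json JSON string produced by `pipeline_to_json`.
#' @export
pipeline_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  steps <- lapply(obj$steps, function(s) {
    params <- lapply(s$params, function(v) {
      # JSON numbers for whole values come back as doubles; keep as given
      v
    })
    do.call(transform_step, c(list(name = s$name), params))
  })
  sc_pipeline(steps)
}

#' A model's documented default preprocessing pipeline
#'
#' Every registered model declares the preprocessing it expects; this returns
#' that pipeline so a benchmark run is reproducible without per-model lore.
#' Clustering and annotation models use
#' filter -> normalize -> log1p -> top-genes; the linear-scale deconvolution
#' solvers omit the log transform.
#'
#' @param model_name a registered model name (see [list_models()]).
#' @return an [sc_pipeline].
#' @export
default_pipeline <- function(model_name) {
  info <- model_info(model_name)
  info$pipeline
}
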