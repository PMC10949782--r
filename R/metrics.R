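#' Task-aligned evaluation metrics
#'
#' Each benchmark task scores with one primary metric: clustering with the
#' adjusted Rand index, annotation with accuracy, imputation with mean squared
#' error on masked entries, deconvolution with mean squared error on
#' proportions.  Degenerate-case conventions are fixed here and documented,
#' because library implementations differ on them.
#'
#' @name metrics
NULL

#' @keywords internal
label_contingency <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred))
    stop("label vectors differ in length (", length(labels_true), " vs ",
         length(labels_pred), ")")
  table(as.character(labels_true), as.character(labels_pred))
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions from their contingency
#' table; invariant to relabeling of either argument.  When the adjustment
#' denominator vanishes (both partitions a single cluster, or both all
#' singletons) the index is defined as 1.0 if the partitions are identical up
#' to relabeling and 0.0 otherwise.
#'
#' @param labels_true,labels_pred label vectors of equal length `>= 2`.
#' @return a real in `[-1, 1]`.
#' @export
ari <- function(labels_true, labels_pred) {
  ct <- label_contingency(labels_true, labels_pred)
  n <- sum(ct)
  if (n < 2) stop("need at least 2 items")
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(ct))
  a <- sum(choose2(rowSums(ct)))
  b <- sum(choose2(colSums(ct)))
  expected <- a * b / choose2(n)
  denom <- (a + b) / 2 - expected
  if (abs(denom) < .Machine$double.eps * 8) {
    ## both single-cluster or both all-singletons: identical partitions -> 1
    same <- all(rowSums(ct > 0) == 1) && all(colSums(ct > 0) == 1)
    return(if (same) 1.0 else 0.0)
  }
  (sum_ij - expected) / denom
}

#' Normalized mutual information
#'
#' Mutual information of the two labelings (natural logs) normalized by the
#' arithmetic mean of their entropies (default) or their geometric mean.
#' If either labeling has zero entropy the value is defined as 0, except that
#' two identical degenerate labelings still score 0 (no information).
#'
#' @param labels_true,labels_pred label vectors of equal length `>= 2`.
#' @param normalization `"arithmetic"` (default) or `"geometric"` mean of the
#'   two entropies.
#' @return a real in `[0, 1]`, symmetric in its arguments.
#' @export
nmi <- function(labels_true, labels_pred,
                normalization = c("arithmetic", "geometric")) {
  normalization <- match.arg(normalization)
  ct <- label_contingency(labels_true, labels_pred)
  n <- sum(ct)
  if (n < 2) stop("need at least 2 items")
  pij <- ct / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / (pi_[row(pij)[nz]] * pj_[col(pij)[nz]])))
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  h1 <- h(pi_); h2 <- h(pj_)
  if (h1 == 0 || h2 == 0) return(0)
  norm <- if (normalization == "arithmetic") (h1 + h2) / 2 else sqrt(h1 * h2)
  val <- mi / norm
  min(max(val, 0), 1)
}

#' Classification accuracy
#'
#' Fraction of positions where the two label vectors match exactly (string
#' comparison).
#'
#' @param labels_true,labels_pred label vectors of equal length `>= 1`.
#' @return a real in `[0, 1]`.
#' @export
accuracy <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred))
    stop("label vectors differ in length")
  if (!length(labels_true)) stop("need at least 1 item")
  mean(as.character(labels_true) == as.character(labels_pred))
}

#' Mean squared error over (optionally masked) matrix entries
#'
#' @param truth,pred numeric matrices of identical shape.
#' @param mask optional logical matrix selecting the entries to average over;
#'   all entries when absent.  An empty mask is an error.
#' @return non-negative real.
#' @export
masked_mse <- function(truth, pred, mask = NULL) {
  truth <- as_dense(truth); pred <- as_dense(pred)
  if (!all(dim(truth) == dim(pred))) stop("shape mismatch between truth and pred")
  if (is.null(mask)) return(mean((truth - pred)^2))
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(truth))) stop("mask shape mismatch")
  if (!any(mask)) stop("mask selects no entries")
  mean((truth[mask] - pred[mask])^2)
}

#' Root mean squared error
#'
#' @param truth,pred numeric matrices (or vectors) of identical shape.
#' @return `sqrt(masked_mse(truth, pred))`.
#' @export
rmse <- function(truth, pred) {
  sqrt(masked_mse(as.matrix(truth), as.matrix(pred)))
}

#' Bundle metric values into a report
#'
#' @param task task name.
#' @param values named numeric vector or list of metric values.
#' @param n_items number of scored items (cells, entries, spots).
#' @return object of class `metric_report`, JSON-serializable via
#'   [report_to_json()].
#' @export
metric_report <- function(task, values, n_items) {
  values <- as.list(values)
  structure(list(task = task, values = values,
                 n_items = as.integer(n_items)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("metric_report [", x$task, "], n =", x$n_items, "\n")
  for (nm in names(x$values))
    cat(sprintf("  %s = %.6g\n", nm, x$values[[nm]]))
  invisible(x)
}

#' @rdname metric_report
#' @param report a `metric_report`.
#' @export
report_to_json <- function(report) {
  jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA)
}
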