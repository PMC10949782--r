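#' Signature matrix from a labeled scRNA reference
#'
#' Per-type mean of library-size-normalized expression, restricted to the
#' union over types of the `n_markers` genes with highest fold change
#' (type mean over mean of the other types, epsilon-stabilized).  Ties break
#' deterministically by ascending gene id.
#'
#' @param reference an [sc_dataset] with `cell_type` labels; at least 2
#'   types with at least 3 cells each.
#' @param n_markers marker genes per type (default 20); `n_markers >=
#'   n_genes` keeps all genes.
#' @param target_sum normalization total (default 1e4).
#' @return object of class `signature_matrix`: fields `S` (genes x types),
#'   `gene_ids`, `type_names`.
#' @export
build_signature <- function(reference, n_markers = 20L, target_sum = 1e4) {
  stopifnot(inherits(reference, "sc_dataset"))
  y <- reference$cell_table$cell_type
  if (is.null(y)) stop("reference has no cell_type labels")
  y <- as.character(y)
  tab <- table(y)
  if (length(tab) < 2) stop("need at least 2 cell types")
  if (any(tab < 3))
    stop("cell type(s) with fewer than 3 cells: ",
         paste(names(tab)[tab < 3], collapse = ", "))
  types <- sort(names(tab))
  X <- as_dense(reference$X)
  rs <- rowSums(X); rs[rs == 0] <- 1
  Xn <- X * (target_sum / rs)
  means <- vapply(types, function(t) colMeans(Xn[y == t, , drop = FALSE]),
                  numeric(ncol(Xn)))           # genes x types
  eps <- 1e-8
  G <- nrow(means)
  if (n_markers >= G) {
    keep <- seq_len(G)
  } else {
    keep <- sort(unique(unlist(lapply(seq_along(types), function(j) {
      other <- rowMeans(means[, -j, drop = FALSE])
      fc <- (means[, j] + eps) / (other + eps)
      order(-fc, reference$gene_ids)[seq_len(n_markers)]
    }))))
  }
  S <- means[keep, , drop = FALSE]
  if (any(colSums(S) == 0)) stop("signature has an all-zero type column")
  structure(list(S = S, gene_ids = reference$gene_ids[keep],
                 type_names = types),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat("signature_matrix:", nrow(x$S), "genes x", length(x$type_names),
      "types (", paste(x$type_names, collapse = ", "), ")\n")
  invisible(x)
}

#' @keywords internal
align_spots_to_signature <- function(spots, sig) {
  spots <- as_dense(spots)
  if (!is.null(colnames(spots))) {
    missing <- setdiff(sig$gene_ids, colnames(spots))
    if (length(missing))
      stop("spot matrix lacks signature genes: ",
           paste(utils::head(missing, 5), collapse = ", "))
    spots <- spots[, sig$gene_ids, drop = FALSE]
  } else if (ncol(spots) != nrow(sig$S)) {
    stop("unnamed spot matrix must have exactly the signature's ",
         nrow(sig$S), " genes")
  }
  spots
}

## solve per spot row; always returns an n_spots x K matrix
#' @keywords internal
nnls_rows <- function(Y, S, solver) {
  out <- matrix(0, nrow(Y), ncol(S))
  for (i in seq_len(nrow(Y))) out[i, ] <- solver(Y[i, ])
  out
}

#' @keywords internal
as_proportion_matrix <- function(P, type_names, spot_ids = NULL) {
  P <- pmax(P, 0)
  rs <- rowSums(P)
  flat <- rs <= 0
  if (any(flat)) {
    warning(sum(flat), " spot(s) with an all-zero solution; set to uniform")
    P[flat, ] <- 1 / ncol(P)
    rs[flat] <- 1
  }
  P <- P / rowSums(P)
  colnames(P) <- type_names
  if (!is.null(spot_ids)) rownames(P) <- spot_ids
  class(P) <- c("proportion_matrix", class(P))
  P
}

#' Per-spot NNLS deconvolution
#'
#' Solves, for each spot y, `min_{beta >= 0} ||y - S beta||^2` with the
#' Lawson-Hanson active-set method, then renormalizes beta to the simplex.
#' With `log_weighting = TRUE` the solve is iteratively reweighted with
#' per-gene weights `1 / (fitted + eps)^2` (3 reweights, initialized from
#' the unweighted solution), approximating a log-normal multiplicative error
#' model.
#'
#' @param spots non-negative spots x genes matrix; columns aligned to the
#'   signature's genes (by name when the matrix has column names).
#' @param sig a [build_signature()] result.
#' @param log_weighting use the log-normal weighting scheme (default FALSE).
#' @return a `proportion_matrix` (spots x types, rows on the simplex).
#' @export
nnls_deconvolve <- function(spots, sig, log_weighting = FALSE) {
  stopifnot(inherits(sig, "signature_matrix"))
  Y <- align_spots_to_signature(spots, sig)
  S <- sig$S
  eps <- 1
  P <- nnls_rows(Y, S, function(y) {
    beta <- pracma::lsqnonneg(S, y)$x
    if (log_weighting) {
      for (it in 1:3) {
        w <- 1 / (pmax(as.vector(S %*% beta), 0) + eps)
        beta <- pracma::lsqnonneg(S * w, y * w)$x
      }
    }
    beta
  })
  as_proportion_matrix(P, sig$type_names, rownames(Y))
}

#' Seeded NMF deconvolution
#'
#' Factorizes the normalized reference (restricted to signature genes) as
#' `V ~ W H` at rank K = number of types by Frobenius multiplicative
#' updates.  W (genes x K) is initialized from the signature columns
#' (epsilon-floored) and H from the NNLS projection of the reference onto W,
#' so topic j stays identified with type j throughout.  Spot proportions are
#' the simplex-normalized NNLS coefficients of each spot on the final W.
#' The Frobenius objective is non-increasing over updates.
#'
#' @param reference labeled [sc_dataset] used to refine the factors.
#' @param spots spots x genes matrix as in [nnls_deconvolve()].
#' @param sig a [build_signature()] result.
#' Refinement trades seed fidelity for reference fit: with a noisy
#' reference, Frobenius-optimal topics shrink toward the data centroid and
#' pure-type spots lose probability mass to other topics, so the default
#' number of updates is kept moderate.
#'
#' @param cfg list of options: `n_iter` (20), `target_sum` (1e4),
#'   `eps` (1e-8).
#' @return a `proportion_matrix` with attribute `"objective"` (the per-
#'   iteration Frobenius objective trace).
#' @export
seeded_nmf_deconvolve <- function(reference, spots, sig, cfg = list()) {
  stopifnot(inherits(reference, "sc_dataset"),
            inherits(sig, "signature_matrix"))
  defaults <- list(n_iter = 20L, target_sum = 1e4, eps = 1e-8)
  cfg <- utils::modifyList(defaults, cfg)
  eps <- cfg$eps
  gi <- match(sig$gene_ids, reference$gene_ids)
  if (anyNA(gi)) stop("signature genes missing from reference")
  X <- as_dense(reference$X)
  rs <- rowSums(X); rs[rs == 0] <- 1
  V <- t(X * (cfg$target_sum / rs))[gi, , drop = FALSE]  # genes x cells
  W <- pmax(sig$S, eps)
  K <- ncol(W)
  H <- vapply(seq_len(ncol(V)), function(j)
    pracma::lsqnonneg(W, V[, j])$x, numeric(K))
  H <- matrix(pmax(H, eps), K, ncol(V))
  objective <- numeric(cfg$n_iter)
  for (it in seq_len(cfg$n_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W, W) %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% (H %*% t(H)) + eps)
    objective[it] <- norm(V - W %*% H, "F")^2
  }
  Y <- align_spots_to_signature(spots, sig)
  P <- nnls_rows(Y, W, function(y) pracma::lsqnonneg(W, y)$x)
  out <- as_proportion_matrix(P, sig$type_names, rownames(Y))
  attr(out, "objective") <- objective
  attr(out, "W") <- W
  out
}

#' Deconvolution score: proportion MSE
#'
#' Mean squared error over all spot x type entries between predicted and
#' true proportion matrices (aligned type order required); symmetric in its
#' arguments.
#'
#' @param pred,truth spots x types matrices with matching type columns.
#' @return non-negative real.
#' @export
score_deconvolution <- function(pred, truth) {
  pm <- unclass(pred); tm <- unclass(truth)
  if (!all(dim(pm) == dim(tm))) stop("shape mismatch")
  if (!is.null(colnames(pm)) && !is.null(colnames(tm)) &&
      !identical(colnames(pm), colnames(tm)))
    stop("misaligned type names: ", paste(colnames(pm), collapse = ","),
         " vs ", paste(colnames(tm), collapse = ","))
  mean((pm - tm)^2)
}

#' Export proportions as CSV
#' @param P a `proportion_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_proportions <- function(P, path) {
  df <- data.frame(spot_id = if (is.null(rownames(P)))
    paste0("spot", seq_len(nrow(P))) else rownames(P),
    unclass(P), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
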