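#' Simulated-dropout masking for imputation benchmarks
#'
#' Uniformly samples `floor(fraction * nnz)` (at least 1) distinct nonzero
#' positions of the dataset's raw counts, zeroes them in the working matrix
#' and in every layer, and stores the original values so a model can later be
#' scored on exactly the held-out entries.  Masked positions never intersect
#' original zeros, and the held-out store is keyed by the true mask
#' positions.
#'
#' @param ds an [sc_dataset] with at least one nonzero entry.
#' @param fraction fraction of nonzero entries to mask, in (0,1).
#' @param seed integer seed; identical seeds give identical masks.
#' @return object of class `masked_dataset`: fields `base` (the masked
#'   [sc_dataset]), `mask` (logical cells x genes), `held_out` (data.frame
#'   `cell`, `gene`, `value` of original raw values).
#' @export
mask_nonzero_entries <- function(ds, fraction = 0.1, seed = 0L) {
  stopifnot(inherits(ds, "sc_dataset"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0,1)")
  raw <- if ("raw" %in% names(ds$layers)) get_layer(ds, "raw") else ds$X
  raw <- as_dense(raw)
  nz <- which(raw > 0)
  if (!length(nz)) stop("all-zero matrix cannot be masked")
  k <- max(1L, min(length(nz), floor(fraction * length(nz))))
  sel <- withr::with_seed(seed, sample(nz, k))
  sel <- sort(sel)
  mask <- matrix(FALSE, nrow(raw), ncol(raw))
  mask[sel] <- TRUE
  cells <- ((sel - 1L) %% nrow(raw)) + 1L
  genes <- ((sel - 1L) %/% nrow(raw)) + 1L
  held_out <- data.frame(cell = cells, gene = genes, value = raw[sel])
  base <- ds
  zero_at <- function(m) { m <- as_dense(m); m[sel] <- 0; m }
  base$X <- zero_at(base$X)
  base$layers <- lapply(base$layers, zero_at)
  base <- log_append(base, "mask_nonzero_entries",
                     list(fraction = fraction, seed = seed, n_masked = k))
  structure(list(base = base, mask = mask, held_out = held_out),
            class = "masked_dataset")
}

#' @export
print.masked_dataset <- function(x, ...) {
  cat("masked_dataset:", nrow(x$held_out), "held-out entries over",
      nrow(x$base$X), "cells x", ncol(x$base$X), "genes\n")
  invisible(x)
}

## evaluation scale: normalize_total + log1p of a raw matrix
#' @keywords internal
imputation_working <- function(raw, target_sum = 1e4) {
  rs <- rowSums(raw)
  rs[rs == 0] <- 1
  log1p(raw * (target_sum / rs))
}

#' Prepare working and truth matrices for an imputation run
#'
#' The benchmark scale is library-size-normalized, log1p-transformed
#' expression: the model trains on the transform of the masked raw counts and
#' is evaluated against the transform of the original raw counts at masked
#' positions.
#'
#' @param mds a [mask_nonzero_entries()] result.
#' @param original the unmasked [sc_dataset] the mask was drawn from.
#' @param target_sum per-cell total used by the normalization (default 1e4).
#' @return list with `working` (masked, transformed), `truth` (unmasked,
#'   transformed) and `mask`.
#' @export
imputation_matrices <- function(mds, original, target_sum = 1e4) {
  stopifnot(inherits(mds, "masked_dataset"), inherits(original, "sc_dataset"))
  raw_masked <- as_dense(if ("raw" %in% names(mds$base$layers))
    get_layer(mds$base, "raw") else mds$base$X)
  raw_full <- as_dense(if ("raw" %in% names(original$layers))
    get_layer(original, "raw") else original$X)
  list(working = imputation_working(raw_masked, target_sum),
       truth = imputation_working(raw_full, target_sum),
       mask = mds$mask)
}

#' Gene-mean baseline imputation
#'
#' Replaces every entry of gene g by the mean of g's observed (unmasked)
#' values on the working scale; a gene with every value masked imputes 0.
#' The floor any trainable imputer must beat.
#'
#' @param mds a [mask_nonzero_entries()] result.
#' @param target_sum normalization total for the working scale.
#' @return cells x genes matrix of imputed values.
#' @export
baseline_gene_mean_impute <- function(mds, target_sum = 1e4) {
  stopifnot(inherits(mds, "masked_dataset"))
  raw_masked <- as_dense(if ("raw" %in% names(mds$base$layers))
    get_layer(mds$base, "raw") else mds$base$X)
  W <- imputation_working(raw_masked, target_sum)
  obs <- !mds$mask
  means <- vapply(seq_len(ncol(W)), function(j) {
    o <- obs[, j]
    if (!any(o)) 0 else mean(W[o, j])
  }, numeric(1))
  matrix(means, nrow(W), ncol(W), byrow = TRUE)
}

#' @export
print.sc_imputer <- function(x, ...) {
  cat("imputer [", x$method, "] over", nrow(x$imputed), "cells x",
      ncol(x$imputed), "genes\n")
  invisible(x)
}

#' Imputed expression matrix of a fitted imputer
#' @param object a fitted imputer.
#' @param ... unused.
#' @return non-negative cells x genes matrix on the working scale.
#' @export
impute <- function(object, ...) UseMethod("impute")

#' @export
impute.sc_imputer <- function(object, ...) object$imputed

#' @export
predict.sc_imputer <- function(object, ...) object$imputed

#' @export
score.sc_imputer <- function(object, ds = NULL, ...) {
  if (is.null(object$truth_matrix))
    stop("no truth matrix stored; pass the original dataset to the fitter")
  masked_mse(object$truth_matrix, object$imputed, object$mask)
}

#' Parallel block-MLP imputer
#'
#' Target genes are partitioned into blocks (deterministic gene order,
#' default size 256).  Within a block, each target contributes its top-5
#' absolute-Pearson-correlation predictor genes (computed on unmasked entries
#' only, the target itself excluded); the block's predictor union feeds one
#' single-hidden-layer network predicting all block targets, trained with
#' value-weighted squared error (weight = target value, so zeros carry no
#' loss) over unmasked entries only.  Blocks are independent.
#'
#' @param mds a [mask_nonzero_entries()] result.
#' @param original the unmasked [sc_dataset] (supplies the evaluation truth;
#'   its masked values are never used in training).
#' @param cfg list of options: `seed` (0), `block_size` (256), `n_pred` (5),
#'   `hidden` (64), `epochs` (200), `lr` (1e-3), `target_sum` (1e4).
#' @return object of classes `sc_block_mlp_imputer`, `sc_imputer`.
#' @export
fit_block_mlp_imputer <- function(mds, original = NULL, cfg = list()) {
  stopifnot(inherits(mds, "masked_dataset"))
  defaults <- list(seed = 0L, block_size = 256L, n_pred = 5L, hidden = 64L,
                   epochs = 200L, lr = 1e-3, target_sum = 1e4)
  cfg <- utils::modifyList(defaults, cfg)
  raw_masked <- as_dense(if ("raw" %in% names(mds$base$layers))
    get_layer(mds$base, "raw") else mds$base$X)
  G <- ncol(raw_masked)
  if (G < cfg$n_pred + 1L)
    stop("fewer than ", cfg$n_pred + 1L, " genes: no predictors available")
  W <- imputation_working(raw_masked, cfg$target_sum)
  obs <- !mds$mask
  n <- nrow(W)

  ## per-gene standardization of inputs (observed entries define the scale)
  gmean <- colSums(W * obs) / pmax(colSums(obs), 1)
  Wc <- W
  Wc[!obs] <- NA

  ## |Pearson| on pairwise-complete unmasked entries; missing treated as
  ## absent, not zero, so the mask never leaks into predictor selection
  cors <- suppressWarnings(stats::cor(Wc, use = "pairwise.complete.obs"))
  cors[!is.finite(cors)] <- 0
  diag(cors) <- 0

  blocks <- split(seq_len(G), ceiling(seq_len(G) / cfg$block_size))
  imputed <- matrix(0, n, G)
  withr::with_seed(cfg$seed, {
    for (bl in blocks) {
      preds <- sort(unique(unlist(lapply(bl, function(gi) {
        ord <- order(-abs(cors[, gi]), seq_len(G))
        setdiff(ord, gi)[seq_len(cfg$n_pred)]
      }))))
      Xb <- W[, preds, drop = FALSE]
      ## masked predictor entries are zero in W already (mask zeroed them)
      Yb <- W[, bl, drop = FALSE]
      wts <- Yb * obs[, bl, drop = FALSE]   # value weights, masked excluded
      params <- nn_init_mlp(c(length(preds), cfg$hidden, length(bl)))
      state <- adam_init(params)
      for (ep in seq_len(cfg$epochs)) {
        fw <- nn_forward(params, Xb)
        r <- fw$out - Yb
        sw <- sum(wts)
        if (sw == 0) break
        dout <- 2 * r * wts / sw
        bd <- nn_backward(params, fw$cache, dout)
        st <- adam_step(params, bd$grads, state, lr = cfg$lr)
        params <- st$params; state <- st$state
      }
      imputed[, bl] <- pmax(nn_forward(params, Xb)$out, 0)
    }
  })

  truth <- NULL
  if (!is.null(original)) {
    mats <- imputation_matrices(mds, original, cfg$target_sum)
    truth <- mats$truth
  }
  structure(list(method = "block_mlp", cfg = cfg, imputed = imputed,
                 mask = mds$mask, truth_matrix = truth),
            class = c("sc_block_mlp_imputer", "sc_imputer"))
}

#' Graph-autoencoder imputer on the cell-gene graph
#'
#' Builds the weighted cell-gene graph from the masked working matrix,
#' embeds cells and genes with two propagation layers, and reconstructs
#' every expression value as `softplus(z_cell . z_gene + b_cell + b_gene)`
#' (the bias terms carry per-cell depth and per-gene baseline level, the
#' bilinear term the type structure).  The squared-error
#' loss runs over observed unmasked nonzero entries plus an equal-count
#' sample of observed zeros, resampled each epoch from the run seed; masked
#' positions never enter training.
#'
#' @inheritParams fit_block_mlp_imputer
#' @param cfg list of options: `seed` (0), `feat_dim` (64), `hidden` (64),
#'   `latent_dim` (32), `epochs` (200), `lr` (1e-2), `target_sum` (1e4).
#' @return object of classes `sc_graph_ae_imputer`, `sc_imputer`.
#' @export
fit_graph_ae_imputer <- function(mds, original = NULL, cfg = list()) {
  stopifnot(inherits(mds, "masked_dataset"))
  defaults <- list(seed = 0L, feat_dim = 64L, hidden = 64L, latent_dim = 32L,
                   epochs = 200L, lr = 1e-2, target_sum = 1e4)
  cfg <- utils::modifyList(defaults, cfg)
  raw_masked <- as_dense(if ("raw" %in% names(mds$base$layers))
    get_layer(mds$base, "raw") else mds$base$X)
  W <- imputation_working(raw_masked, cfg$target_sum)
  n_c <- nrow(W); n_g <- ncol(W)
  wds <- sc_dataset(W, cell_ids = mds$base$cell_ids,
                    gene_ids = mds$base$gene_ids)
  g <- cell_gene_graph(wds)
  A <- norm_adjacency_matrix(normalize_adjacency(g, "sym", TRUE))
  obs <- !mds$mask
  pos_idx <- which(W > 0 & obs)          # observed nonzero entries
  zero_idx <- which(W == 0 & obs)        # observed zeros (candidate sample)
  m_pos <- length(pos_idx)

  res <- withr::with_seed(cfg$seed, {
    f <- cfg$feat_dim
    Fmat <- rbind(matrix(0, n_c, f),
                  matrix(stats::rnorm(n_g * f, sd = 1 / sqrt(f)), n_g, f))
    params <- list(W1 = nn_init_mat(f, cfg$hidden),
                   W2 = nn_init_mat(cfg$hidden, cfg$latent_dim),
                   b_cell = matrix(0, n_c, 1),
                   b_gene = matrix(0, n_g, 1))
    state <- adam_init(params)
    AF <- as.matrix(A %*% Fmat)
    losses <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      A1 <- AF %*% params$W1
      H1 <- nn_relu(A1)
      AH <- as.matrix(A %*% H1)
      Z <- AH %*% params$W2
      zi <- sample(zero_idx, min(m_pos, length(zero_idx)))
      idx <- c(pos_idx, zi)
      cu <- ((idx - 1L) %% n_c) + 1L
      gg <- ((idx - 1L) %/% n_c) + 1L
      gv <- n_c + gg
      tgt <- W[idx]
      s <- rowSums(Z[cu, , drop = FALSE] * Z[gv, , drop = FALSE]) +
        params$b_cell[cu] + params$b_gene[gg]
      pred <- nn_softplus(s)
      r <- pred - tgt
      m_all <- length(r)
      losses[ep] <- mean(r^2)
      dS <- 2 * r * nn_sigmoid(s) / m_all
      R <- Matrix::sparseMatrix(i = cu, j = gv, x = dS,
                                dims = c(n_c + n_g, n_c + n_g))
      dZ <- as.matrix(R %*% Z + Matrix::t(R) %*% Z)
      db_cell <- matrix(Matrix::rowSums(R)[seq_len(n_c)], n_c, 1)
      db_gene <- matrix(Matrix::colSums(R)[n_c + seq_len(n_g)], n_g, 1)
      dW2 <- crossprod(AH, dZ)
      dAH <- dZ %*% t(params$W2)
      dH1 <- as.matrix(A %*% dAH)
      dA1 <- dH1 * (A1 > 0)
      dW1 <- crossprod(AF, dA1)
      st <- adam_step(params, list(W1 = dW1, W2 = dW2, b_cell = db_cell,
                                   b_gene = db_gene), state, lr = cfg$lr)
      params <- st$params; state <- st$state
    }
    A1 <- AF %*% params$W1
    Z <- as.matrix(A %*% nn_relu(A1)) %*% params$W2
    S <- Z[seq_len(n_c), , drop = FALSE] %*%
      t(Z[n_c + seq_len(n_g), , drop = FALSE])
    S <- S + matrix(params$b_cell, n_c, n_g) +
      matrix(params$b_gene, n_c, n_g, byrow = TRUE)
    Xhat <- nn_softplus(S)
    list(params = params, Xhat = Xhat, losses = losses)
  })

  truth <- NULL
  if (!is.null(original)) {
    mats <- imputation_matrices(mds, original, cfg$target_sum)
    truth <- mats$truth
  }
  structure(list(method = "graph_ae_imputer", cfg = cfg,
                 imputed = res$Xhat, mask = mds$mask, truth_matrix = truth,
                 losses = res$losses),
            class = c("sc_graph_ae_imputer", "sc_imputer"))
}
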