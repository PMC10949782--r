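#' Supervised cell-type annotation models
#'
#' Three annotators share one contract: `fit_*` learns from a labeled
#' training dataset, `predict()` returns one vocabulary label per cell (with
#' per-cell class probabilities on the simplex as attribute `"prob"`), and
#' `score()` is accuracy against ground truth.  The vocabulary is closed: a
#' label unseen in training is never predicted.
#'
#' @name annotation
NULL

#' @keywords internal
annotator_features <- function(ds, gene_ids, fmean, fsd) {
  if (!identical(ds$gene_ids, gene_ids)) {
    missing <- setdiff(gene_ids, ds$gene_ids)
    if (length(missing))
      stop("gene vocabulary mismatch; missing genes: ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) " ..." else "")
    ds <- subset_genes(ds, match(gene_ids, ds$gene_ids))
  }
  X <- as_dense(ds$X)
  pmin(pmax(sweep(sweep(X, 2, fmean), 2, fsd, "/"), -10), 10)
}

#' @keywords internal
check_train_labels <- function(train, allow_single = FALSE) {
  y <- train$cell_table$cell_type
  if (is.null(y)) stop("training dataset has no cell_type labels")
  y <- as.character(y)
  tab <- table(y)
  if (!allow_single) {
    if (length(tab) < 2) stop("need at least 2 classes to train an annotator")
    if (any(tab < 2)) stop("every class needs at least 2 cells")
  }
  y
}

#' @export
print.sc_annotator <- function(x, ...) {
  cat("annotator [", x$method, "],", length(x$vocab), "types:",
      paste(utils::head(x$vocab, 6), collapse = ", "),
      if (length(x$vocab) > 6) "..." else "", "\n")
  invisible(x)
}

#' @export
score.sc_annotator <- function(object, ds = NULL, ...) {
  if (is.null(ds)) stop("score() for annotators needs a labeled dataset")
  truth <- as.character(ds$cell_table$cell_type)
  if (is.null(truth)) stop("dataset has no cell_type labels")
  pred <- predict(object, ds)
  keep <- truth %in% object$vocab
  if (!all(keep))
    message(sum(!keep), " cell(s) with a type absent from training excluded")
  accuracy(truth[keep], pred[keep])
}

## shared softmax-head training loop for logreg (no hidden layers) and the
## MLP; minibatch SGD-style updates via Adam, inverse-frequency class weights
## optional.
#' @keywords internal
fit_softmax_net <- function(train, cfg, hidden) {
  y <- check_train_labels(train)
  vocab <- sort(unique(y))
  X <- as_dense(train$X)
  fmean <- colMeans(X)
  fsd <- sqrt(pmax(colMeans(X^2) - fmean^2, 0)); fsd[fsd == 0] <- 1
  Xin <- pmin(pmax(sweep(sweep(X, 2, fmean), 2, fsd, "/"), -10), 10)
  Y <- one_hot(y, vocab)
  n <- nrow(Xin)
  rw <- NULL
  if (isTRUE(cfg$class_weights)) {
    freq <- table(factor(y, levels = vocab))
    rw <- as.vector((1 / freq)[y]) * n / length(vocab)
  }
  withr::with_seed(cfg$seed, {
    params <- nn_init_mlp(c(ncol(Xin), hidden, length(vocab)))
    state <- adam_init(params)
    bs <- min(cfg$batch_size, n)
    losses <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      idx <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1, n, by = bs)) {
        b <- idx[start:min(start + bs - 1L, n)]
        fw <- nn_forward(params, Xin[b, , drop = FALSE])
        ce <- nn_softmax_xent(fw$out, Y[b, , drop = FALSE],
                              row_weights = rw[b])
        bd <- nn_backward(params, fw$cache, ce$dlogits)
        st <- adam_step(params, bd$grads, state, lr = cfg$lr,
                        weight_decay = cfg$l2)
        params <- st$params; state <- st$state
        ep_loss <- ep_loss + ce$loss; nb <- nb + 1L
      }
      losses[ep] <- ep_loss / nb
    }
    list(params = params, vocab = vocab, fmean = fmean, fsd = fsd,
         gene_ids = train$gene_ids, losses = losses)
  })
}

#' Multinomial logistic regression annotator
#'
#' A softmax-linear classifier trained by minibatch stochastic gradient
#' descent (Adam updates) with an L2 penalty, on per-gene standardized
#' features.
#'
#' @param train an [sc_dataset] with `cell_type` labels, `>= 2` classes with
#'   `>= 2` cells each, preprocessed features.
#' @param cfg list of options: `seed` (0), `epochs` (100), `batch_size` (64),
#'   `lr` (1e-2), `l2` (1e-4), `class_weights` (FALSE, inverse-frequency loss
#'   weights when TRUE).
#' @return object of classes `sc_logreg_annotator`, `sc_annotator`.
#' @export
fit_logreg_annotator <- function(train, cfg = list()) {
  stopifnot(inherits(train, "sc_dataset"))
  defaults <- list(seed = 0L, epochs = 100L, batch_size = 64L, lr = 1e-2,
                   l2 = 1e-4, class_weights = FALSE)
  cfg <- utils::modifyList(defaults, cfg)
  res <- fit_softmax_net(train, cfg, hidden = integer(0))
  structure(c(res, list(method = "logreg", cfg = cfg)),
            class = c("sc_mlp_annotator", "sc_annotator"))
}

#' Multilayer-perceptron annotator
#'
#' A fully connected network with ReLU hidden layers (default sizes
#' 100-50-25), softmax output and cross-entropy loss.  `hidden = integer(0)`
#' reduces to the logistic-regression architecture.
#'
#' @inheritParams fit_logreg_annotator
#' @param cfg as in [fit_logreg_annotator()], plus `hidden`
#'   (default `c(100, 50, 25)`).
#' @return object of classes `sc_mlp_annotator`, `sc_annotator`.
#' @export
fit_mlp_annotator <- function(train, cfg = list()) {
  stopifnot(inherits(train, "sc_dataset"))
  defaults <- list(seed = 0L, epochs = 100L, batch_size = 64L, lr = 1e-3,
                   l2 = 1e-4, class_weights = FALSE,
                   hidden = c(100L, 50L, 25L))
  cfg <- utils::modifyList(defaults, cfg)
  res <- fit_softmax_net(train, cfg, hidden = cfg$hidden)
  structure(c(res, list(method = "mlp", cfg = cfg)),
            class = c("sc_mlp_annotator", "sc_annotator"))
}

#' @export
predict.sc_mlp_annotator <- function(object, ds, type = c("class", "prob"),
                                     ...) {
  type <- match.arg(type)
  stopifnot(inherits(ds, "sc_dataset"))
  Xin <- annotator_features(ds, object$gene_ids, object$fmean, object$fsd)
  prob <- nn_softmax(nn_forward(object$params, Xin)$out)
  colnames(prob) <- object$vocab
  if (type == "prob") return(prob)
  labels <- object$vocab[max.col(prob, ties.method = "first")]
  attr(labels, "prob") <- prob
  labels
}

#' Transductive GNN annotator on the cell-gene graph
#'
#' Builds one bipartite cell-gene graph over the union of training and test
#' cells (they must share the gene vocabulary), applies two propagation
#' layers over the symmetric-normalized adjacency with learned linear maps,
#' and a linear softmax head on the cell embeddings.  The cross-entropy loss
#' is masked to training cells only; prediction reads the test-cell outputs
#' of the same forward pass.  No pre-trained atlas is involved: training is
#' single-graph and transductive.
#'
#' @param train labeled [sc_dataset].
#' @param test_unlabeled [sc_dataset] sharing `train`'s gene vocabulary
#'   (labels, if present, are ignored during training).
#' @param cfg list of options: `seed` (0), `feat_dim` (64), `hidden` (64),
#'   `epochs` (150), `lr` (1e-2), `l2` (1e-4).
#' @return object of classes `sc_gnn_annotator`, `sc_annotator`; `predict()`
#'   with no new data returns test-cell labels.
#' @export
fit_gnn_annotator <- function(train, test_unlabeled, cfg = list()) {
  stopifnot(inherits(train, "sc_dataset"),
            inherits(test_unlabeled, "sc_dataset"))
  defaults <- list(seed = 0L, feat_dim = 64L, hidden = 64L, epochs = 150L,
                   lr = 1e-2, l2 = 1e-4)
  cfg <- utils::modifyList(defaults, cfg)
  if (!identical(train$gene_ids, test_unlabeled$gene_ids)) {
    off <- union(setdiff(train$gene_ids, test_unlabeled$gene_ids),
                 setdiff(test_unlabeled$gene_ids, train$gene_ids))
    stop("gene vocabulary mismatch between train and test; offending genes: ",
         paste(utils::head(off, 5), collapse = ", "),
         if (length(off) > 5) " ..." else "")
  }
  ## a single training class is legal here: the head then predicts that
  ## label everywhere (closed vocabulary)
  y <- check_train_labels(train, allow_single = TRUE)
  vocab <- sort(unique(y))
  n_tr <- n_cells(train); n_te <- n_cells(test_unlabeled)
  n_g <- n_genes(train)
  Xall <- rbind(as_dense(train$X), as_dense(test_unlabeled$X))
  all_ids <- make.unique(c(train$cell_ids, test_unlabeled$cell_ids))
  combined <- sc_dataset(Xall, cell_ids = all_ids, gene_ids = train$gene_ids)
  g <- cell_gene_graph(combined)
  A <- norm_adjacency_matrix(normalize_adjacency(g, "sym", TRUE))
  n_cells_all <- n_tr + n_te
  Y <- one_hot(y, vocab)

  res <- withr::with_seed(cfg$seed, {
    f <- cfg$feat_dim
    Fmat <- rbind(matrix(0, n_cells_all, f),
                  matrix(stats::rnorm(n_g * f, sd = 1 / sqrt(f)), n_g, f))
    params <- list(W1 = nn_init_mat(f, cfg$hidden),
                   W2 = nn_init_mat(cfg$hidden, length(vocab)),
                   b2 = matrix(0, 1, length(vocab)))
    state <- adam_init(params)
    AF <- as.matrix(A %*% Fmat)
    tr_idx <- seq_len(n_tr)
    losses <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      A1 <- AF %*% params$W1
      H1 <- nn_relu(A1)
      AH <- as.matrix(A %*% H1)
      logits <- sweep(AH %*% params$W2, 2, as.vector(params$b2), "+")
      ce <- nn_softmax_xent(logits[tr_idx, , drop = FALSE], Y)
      losses[ep] <- ce$loss
      dlogits <- matrix(0, nrow(logits), ncol(logits))
      dlogits[tr_idx, ] <- ce$dlogits
      dW2 <- crossprod(AH, dlogits)
      db2 <- matrix(colSums(dlogits), 1)
      dAH <- dlogits %*% t(params$W2)
      dH1 <- as.matrix(A %*% dAH)
      dA1 <- dH1 * (A1 > 0)
      dW1 <- crossprod(AF, dA1)
      st <- adam_step(params, list(W1 = dW1, W2 = dW2, b2 = db2), state,
                      lr = cfg$lr, weight_decay = cfg$l2)
      params <- st$params; state <- st$state
    }
    A1 <- AF %*% params$W1
    AH <- as.matrix(A %*% nn_relu(A1))
    logits <- sweep(AH %*% params$W2, 2, as.vector(params$b2), "+")
    prob <- nn_softmax(logits[seq_len(n_cells_all), , drop = FALSE])
    list(params = params, prob = prob, losses = losses,
         Fgenes = Fmat[n_cells_all + seq_len(n_g), , drop = FALSE])
  })

  test_prob <- res$prob[n_tr + seq_len(n_te), , drop = FALSE]
  colnames(test_prob) <- vocab
  structure(list(method = "gnn", cfg = cfg, vocab = vocab,
                 gene_ids = train$gene_ids,
                 params = res$params, gene_features = res$Fgenes,
                 test_cell_ids = test_unlabeled$cell_ids,
                 test_prob = test_prob, losses = res$losses),
            class = c("sc_gnn_annotator", "sc_annotator"))
}

#' @export
predict.sc_gnn_annotator <- function(object, ds = NULL,
                                     type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.null(ds)) {
    prob <- object$test_prob
  } else {
    stopifnot(inherits(ds, "sc_dataset"))
    if (!identical(ds$gene_ids, object$gene_ids))
      stop("gene vocabulary mismatch")
    g <- cell_gene_graph(ds)
    A <- norm_adjacency_matrix(normalize_adjacency(g, "sym", TRUE))
    nc <- n_cells(ds)
    Fmat <- rbind(matrix(0, nc, ncol(object$gene_features)),
                  object$gene_features)
    AF <- as.matrix(A %*% Fmat)
    AH <- as.matrix(A %*% nn_relu(AF %*% object$params$W1))
    logits <- sweep(AH %*% object$params$W2, 2,
                    as.vector(object$params$b2), "+")
    prob <- nn_softmax(logits[seq_len(nc), , drop = FALSE])
    colnames(prob) <- object$vocab
  }
  if (type == "prob") return(prob)
  labels <- object$vocab[max.col(prob, ties.method = "first")]
  attr(labels, "prob") <- prob
  labels
}

#' Export annotation predictions as TSV
#'
#' Writes `cell_id`, `predicted_type` and `max_probability` columns.
#'
#' @param object a fitted annotator.
#' @param ds dataset to predict on.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(object, ds, path) {
  labels <- predict(object, ds)
  prob <- attr(labels, "prob")
  out <- data.frame(cell_id = ds$cell_ids,
                    predicted_type = as.character(labels),
                    max_probability = apply(prob, 1, max))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
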