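#' Zero-inflated negative binomial negative log-likelihood
#'
#' Mean NLL over entries of the ZINB model: a zero observation arises either
#' from the dropout component (probability `pi`) or from the negative
#' binomial; a positive count only from the negative binomial.  With
#' `NB(x; mu, theta) = Gamma(x+theta)/(Gamma(theta) x!) *
#' (theta/(theta+mu))^theta (mu/(theta+mu))^x`:
#' for `x = 0` the NLL is `-log(pi + (1-pi) NB(0))`, for `x > 0` it is
#' `-log(1-pi) - log NB(x)`.  Logs are epsilon-stabilized.
#'
#' @param x non-negative count matrix (cells x genes) or vector.
#' @param mu positive mean, same shape as `x` (recycled if scalar).
#' @param theta positive dispersion, per gene: scalar, length-`ncol` vector,
#'   or full matrix.
#' @param pi dropout probability in `[0,1]`, same shape as `x` (or scalar).
#' @param reduce return the mean over entries (default) or the entrywise
#'   matrix.
#' @return mean NLL (scalar) or entrywise NLL.
#' @export
zinb_nll <- function(x, mu, theta, pi = 0, reduce = TRUE) {
  x <- as_dense(x)
  if (!all(is.finite(mu)) || !all(is.finite(theta)) || !all(is.finite(pi)))
    stop("non-finite ZINB parameters")
  if (any(mu <= 0) || any(theta <= 0)) stop("mu and theta must be positive")
  if (any(pi < 0) || any(pi > 1)) stop("pi must lie in [0,1]")
  shp <- if (is.matrix(x)) dim(x) else c(1L, length(x))
  bc <- function(v) {
    if (length(v) == 1) array(v, shp)
    else if (is.matrix(v)) v
    else matrix(v, shp[1], shp[2], byrow = TRUE)   # per-gene vector
  }
  xm <- matrix(x, shp[1], shp[2])
  mu <- bc(mu); theta <- bc(theta); pi <- bc(pi)
  eps <- 1e-12
  pi <- pmin(pi, 1 - eps)
  log_nb <- lgamma(xm + theta) - lgamma(theta) - lgamma(xm + 1) +
    theta * (log(theta) - log(theta + mu)) +
    xm * (log(mu + eps) - log(theta + mu))
  nll_pos <- -log1p(-pi) - log_nb
  ## zero branch via log-sum-exp: log(pi + (1-pi) * NB(0)) computed without
  ## additive stabilizers so the pi = 0 limit is the exact NB value
  la <- log(pi)                               # -Inf at pi = 0 is fine
  lb <- log1p(-pi) + theta * (log(theta) - log(theta + mu))
  mx <- pmax(la, lb)
  nll_zero <- -(mx + log(exp(la - mx) + exp(lb - mx)))
  out <- ifelse(xm == 0, nll_zero, nll_pos)
  if (reduce) mean(out) else out
}

## Entrywise gradients of the mean ZINB NLL w.r.t. mu, theta, pi.
## Returned gradients are d(mean NLL)/d(param at entry) * (n*p), i.e. the
## per-entry contribution; callers divide by the entry count.
#' @keywords internal
zinb_nll_grad <- function(x, mu, theta, pi) {
  eps <- 1e-10
  zero <- x == 0
  p0 <- exp(theta * (log(theta) - log(theta + mu)))
  L0 <- pi + (1 - pi) * p0 + eps
  ## x > 0 branch
  dmu_pos <- -x / (mu + eps) + (x + theta) / (theta + mu)
  dth_pos <- -(digamma(x + theta) - digamma(theta) +
                 log(theta) - log(theta + mu) + (mu - x) / (theta + mu))
  dpi_pos <- 1 / (1 - pi + eps)
  ## x == 0 branch
  dp0_dmu <- -p0 * theta / (theta + mu)
  dp0_dth <- p0 * (log(theta) - log(theta + mu) + mu / (theta + mu))
  dmu_zero <- -(1 - pi) * dp0_dmu / L0
  dth_zero <- -(1 - pi) * dp0_dth / L0
  dpi_zero <- -(1 - p0) / L0
  list(dmu = ifelse(zero, dmu_zero, dmu_pos),
       dtheta = ifelse(zero, dth_zero, dth_pos),
       dpi = ifelse(zero, dpi_zero, dpi_pos))
}

#' Student-t soft cluster assignments
#'
#' `q_ij` is proportional to `(1 + ||z_i - mu_j||^2 / alpha)^(-(alpha+1)/2)`,
#' rows normalized to the simplex — the kernel of deep embedded clustering.
#'
#' @param Z numeric matrix, cells x d.
#' @param centroids numeric matrix, K x d.
#' @param alpha positive degrees of freedom (default 1).
#' @return matrix Q, cells x K, rows summing to 1.
#' @export
soft_assignments <- function(Z, centroids, alpha = 1) {
  Z <- as.matrix(Z); centroids <- as.matrix(centroids)
  stopifnot(ncol(Z) == ncol(centroids), alpha > 0)
  d2 <- outer(rowSums(Z^2), rep(1, nrow(centroids))) +
    outer(rep(1, nrow(Z)), rowSums(centroids^2)) -
    2 * Z %*% t(centroids)
  d2 <- pmax(d2, 0)
  u <- (1 + d2 / alpha)^(-(alpha + 1) / 2)
  u / rowSums(u)
}

#' Self-training target distribution
#'
#' Sharpened targets `p_ij = (q_ij^2 / f_j) / sum_j' (q_ij'^2 / f_j')` with
#' cluster frequencies `f_j = sum_i q_ij`; a vanishing frequency is
#' epsilon-stabilized with a warning.
#'
#' @param Q soft-assignment matrix with rows on the simplex.
#' @return matrix P of the same shape, rows on the simplex.
#' @export
target_distribution <- function(Q) {
  Q <- as.matrix(Q)
  f <- colSums(Q)
  if (any(f < 1e-12)) {
    warning("cluster frequency numerically zero; epsilon-stabilized")
    f <- pmax(f, 1e-12)
  }
  w <- sweep(Q^2, 2, f, "/")
  w / rowSums(w)
}

#' Pairwise must-link / cannot-link constraint set
#'
#' @param must_link,cannot_link two-column integer matrices of unordered cell
#'   index pairs (1-based); members of a pair must differ and no pair may
#'   appear in both sets.
#' @return object of class `constraint_set`.
#' @export
constraint_set <- function(must_link = NULL, cannot_link = NULL) {
  canon <- function(m) {
    if (is.null(m) || !length(m)) return(matrix(integer(0), 0, 2))
    m <- matrix(as.integer(m), ncol = 2)
    if (any(m[, 1] == m[, 2])) stop("constraint pair with identical members")
    cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  }
  ml <- canon(must_link); cl <- canon(cannot_link)
  key <- function(m) paste(m[, 1], m[, 2])
  if (length(intersect(key(ml), key(cl))))
    stop("a pair appears in both must_link and cannot_link")
  structure(list(must_link = ml, cannot_link = cl), class = "constraint_set")
}

#' Pairwise constraint loss on soft assignments
#'
#' For must-links the loss is `-log` of the assignment inner product
#' `sum_k q_ak q_bk` (probability the pair lands in the same cluster); for
#' cannot-links `-log` of its complement.  Logs are epsilon-clamped; an empty
#' constraint set contributes 0.
#'
#' @param Q soft-assignment matrix, cells x K.
#' @param constraints a [constraint_set].
#' @return non-negative real.
#' @export
pairwise_constraint_loss <- function(Q, constraints) {
  stopifnot(inherits(constraints, "constraint_set"))
  Q <- as.matrix(Q)
  idx <- rbind(constraints$must_link, constraints$cannot_link)
  if (nrow(idx) && any(idx < 1 | idx > nrow(Q)))
    stop("constraint index out of range")
  eps <- 1e-10
  loss <- 0
  ml <- constraints$must_link
  if (nrow(ml)) {
    s <- rowSums(Q[ml[, 1], , drop = FALSE] * Q[ml[, 2], , drop = FALSE])
    loss <- loss - sum(log(pmin(pmax(s, eps), 1)))
  }
  cl <- constraints$cannot_link
  if (nrow(cl)) {
    s <- rowSums(Q[cl[, 1], , drop = FALSE] * Q[cl[, 2], , drop = FALSE])
    loss <- loss - sum(log(pmin(pmax(1 - s, eps), 1)))
  }
  loss
}

## dL/dQ of the constraint loss (same epsilon conventions).
#' @keywords internal
constraint_loss_grad_q <- function(Q, constraints) {
  dQ <- Q * 0
  eps <- 1e-10
  ml <- constraints$must_link
  if (nrow(ml)) {
    qa <- Q[ml[, 1], , drop = FALSE]; qb <- Q[ml[, 2], , drop = FALSE]
    s <- pmax(rowSums(qa * qb), eps)
    for (r in seq_len(nrow(ml))) {
      dQ[ml[r, 1], ] <- dQ[ml[r, 1], ] - qb[r, ] / s[r]
      dQ[ml[r, 2], ] <- dQ[ml[r, 2], ] - qa[r, ] / s[r]
    }
  }
  cl <- constraints$cannot_link
  if (nrow(cl)) {
    qa <- Q[cl[, 1], , drop = FALSE]; qb <- Q[cl[, 2], , drop = FALSE]
    s <- pmin(rowSums(qa * qb), 1 - eps)
    for (r in seq_len(nrow(cl))) {
      dQ[cl[r, 1], ] <- dQ[cl[r, 1], ] + qb[r, ] / (1 - s[r])
      dQ[cl[r, 2], ] <- dQ[cl[r, 2], ] + qa[r, ] / (1 - s[r])
    }
  }
  dQ
}

## Backward through the Student-t assignment kernel: given dL/dQ, return
## dL/dZ and dL/dcentroids.  Uses q_ij = u_ij / sum_j u_ij with
## du_ij/dz_i = -((alpha+1)/alpha) u_ij (1 + d2/alpha)^(-1) (z_i - mu_j).
#' @keywords internal
soft_assign_backward <- function(Z, centroids, alpha, dLdQ) {
  n <- nrow(Z); K <- nrow(centroids)
  d2 <- outer(rowSums(Z^2), rep(1, K)) +
    outer(rep(1, n), rowSums(centroids^2)) - 2 * Z %*% t(centroids)
  d2 <- pmax(d2, 0)
  base <- 1 + d2 / alpha
  u <- base^(-(alpha + 1) / 2)
  su <- rowSums(u)
  Q <- u / su
  ## dL/du_ij = (dLdQ_ij - sum_j' dLdQ_ij' q_ij') / su_i
  dLdu <- (dLdQ - rowSums(dLdQ * Q)) / su
  coef <- -((alpha + 1) / alpha) * dLdu * u / base   # multiplies (z_i - mu_j)
  dZ <- (rowSums(coef) * Z) - coef %*% centroids
  dC <- (colSums(coef) * centroids) - crossprod(coef, Z)
  list(dZ = dZ, dC = dC)
}

## ---- model objects ---------------------------------------------------------

#' Fit-predict-score generic
#'
#' All models in the package honour one contract: a `fit_*` function returns a
#' classed model, `predict()` produces labels / values for a dataset, and
#' `score()` evaluates the task's primary metric against the dataset's ground
#' truth.
#'
#' @param object a fitted model.
#' @param ds an [sc_dataset] (defaults to the training data where stored).
#' @param ... passed to methods.
#' @return the task's primary metric value.
#' @export
score <- function(object, ds = NULL, ...) UseMethod("score")

#' @export
score.sc_clustering <- function(object, ds = NULL, ...) {
  truth <- if (is.null(ds)) object$truth else ds$cell_table$cell_type
  if (is.null(truth)) stop("no cell_type labels available to score against")
  ari(truth, predict(object, ds))
}

#' @export
print.sc_clustering <- function(x, ...) {
  cat("clustering model [", x$method, "], K =", x$K, ",",
      length(x$labels), "cells\n")
  if (!is.null(x$train_ari))
    cat(sprintf("  training ARI vs provided labels: %.3f\n", x$train_ari))
  invisible(x)
}

## default preprocessing guard: models expect the normalized/log pipeline
#' @keywords internal
ensure_preprocessed <- function(ds, model_name) {
  ops <- vapply(ds$log, function(e) e$name, character(1))
  if (!"normalize_total" %in% ops) {
    warning("dataset looks unpreprocessed; applying default_pipeline('",
            model_name, "')")
    ds <- apply_pipeline(default_pipeline(model_name), ds)
  }
  ds
}

#' ZINB autoencoder with deep-embedded-clustering self-training
#'
#' Three training stages: (1) an autoencoder is pretrained with the ZINB
#' reconstruction likelihood on the raw counts (per-cell size factors from raw
#' totals); (2) cluster centroids are initialised by Lloyd's algorithm on the
#' latent embedding; (3) the joint loss
#' `zinb_nll + gamma * KL(P || Q) (+ lambda * constraint loss)` is minimised,
#' with the target distribution P refreshed every `refresh_interval` epochs,
#' stopping when fewer than `tol` of the labels change between refreshes.
#' Supplying `constraints` gives the pairwise-constrained variant of the same
#' architecture.
#'
#' @param ds an [sc_dataset], preprocessed by the model's default pipeline
#'   (an unpreprocessed dataset triggers a warning and automatic
#'   preprocessing); layer `"raw"` supplies the reconstruction targets.
#' @param K number of clusters, `1 <= K <= n_cells`.
#' @param cfg list of training options: `seed` (0), `hidden` (c(256, 64)),
#'   `latent_dim` (32), `pretrain_epochs` (120), `dec_epochs` (80),
#'   `lr` (1e-3), `gamma` (1), `lambda` (1), `refresh_interval` (10),
#'   `tol` (0.001), `alpha` (1), `kmeans_restarts` (20).
#' @param constraints optional [constraint_set] of must-link / cannot-link
#'   cell pairs.
#' @return object of classes `sc_zinb_dec`, `sc_clustering`.
#' @export
fit_zinb_dec <- function(ds, K, cfg = list(), constraints = NULL) {
  stopifnot(inherits(ds, "sc_dataset"))
  defaults <- list(seed = 0L, hidden = c(256L, 64L), latent_dim = 32L,
                   pretrain_epochs = 120L, dec_epochs = 80L, lr = 1e-3,
                   gamma = 1, lambda = 1, refresh_interval = 10L,
                   tol = 0.001, alpha = 1, kmeans_restarts = 20L)
  cfg <- utils::modifyList(defaults, cfg)
  if (K < 1) stop("K must be >= 1")
  if (n_cells(ds) < K) stop("n_cells < K")
  ds <- ensure_preprocessed(ds, "zinb_dec")
  if (!is.null(constraints)) stopifnot(inherits(constraints, "constraint_set"))

  raw <- as_dense(get_layer(ds, "raw"))
  n <- nrow(raw); G <- ncol(raw)
  tot <- rowSums(raw)
  sf <- tot / stats::median(tot)
  Xw <- as_dense(ds$X)
  fmean <- colMeans(Xw)
  fsd <- sqrt(pmax(colMeans(Xw^2) - fmean^2, 0)); fsd[fsd == 0] <- 1
  Xin <- pmin(pmax(sweep(sweep(Xw, 2, fmean), 2, fsd, "/"), -10), 10)

  alpha <- cfg$alpha
  nml <- if (is.null(constraints)) 0L else nrow(constraints$must_link) +
    nrow(constraints$cannot_link)

  res <- withr::with_seed(cfg$seed, {
    enc <- nn_init_mlp(c(G, cfg$hidden, cfg$latent_dim))
    dec <- nn_init_mlp(c(cfg$latent_dim, rev(cfg$hidden)))
    Hd <- rev(cfg$hidden)[length(cfg$hidden)]
    params <- list(enc = enc, dec = dec,
                   W_mu = nn_init_mat(Hd, G), b_mu = matrix(0, 1, G),
                   W_pi = nn_init_mat(Hd, G), b_pi = matrix(-2, 1, G),
                   theta = matrix(0.5413, 1, G))
    state <- adam_init(params)

    recon_pass <- function(params) {
      ef <- nn_forward(params$enc, Xin)
      Z <- ef$out
      df <- nn_forward(params$dec, Z)
      H <- nn_relu(df$out)
      a_mu <- pmin(pmax(sweep(H %*% params$W_mu, 2,
                              as.vector(params$b_mu), "+"), -12), 12)
      mu <- sf * exp(a_mu)
      a_pi <- sweep(H %*% params$W_pi, 2, as.vector(params$b_pi), "+")
      pi_ <- nn_sigmoid(a_pi)
      th_g <- pmin(pmax(nn_softplus(as.vector(params$theta)), 1e-4), 1e4)
      theta <- matrix(th_g, n, G, byrow = TRUE)
      loss <- zinb_nll(raw, mu, theta, pi_)
      list(ef = ef, Z = Z, df = df, H = H, a_mu = a_mu, mu = mu,
           pi_ = pi_, theta = theta, loss = loss)
    }

    recon_grads <- function(params, fw, extra_dZ = NULL) {
      N <- n * G
      gz <- zinb_nll_grad(raw, fw$mu, fw$theta, fw$pi_)
      clip_mask <- (fw$a_mu > -12) & (fw$a_mu < 12)
      dA_mu <- gz$dmu * fw$mu * clip_mask / N
      dA_pi <- gz$dpi * fw$pi_ * (1 - fw$pi_) / N
      dtheta <- matrix(colSums(gz$dtheta) / N *
                         nn_sigmoid(as.vector(params$theta)), 1, G)
      dH <- dA_mu %*% t(params$W_mu) + dA_pi %*% t(params$W_pi)
      dDecOut <- dH * (fw$df$out > 0)
      bd <- nn_backward(params$dec, fw$df$cache, dDecOut)
      dZ <- bd$dinput
      if (!is.null(extra_dZ)) dZ <- dZ + extra_dZ
      be <- nn_backward(params$enc, fw$ef$cache, dZ)
      list(grads = list(enc = be$grads, dec = bd$grads,
                        W_mu = crossprod(fw$H, dA_mu),
                        b_mu = matrix(colSums(dA_mu), 1),
                        W_pi = crossprod(fw$H, dA_pi),
                        b_pi = matrix(colSums(dA_pi), 1),
                        theta = dtheta))
    }

    ## stage 1: ZINB autoencoder pretraining
    pre_losses <- numeric(cfg$pretrain_epochs)
    for (ep in seq_len(cfg$pretrain_epochs)) {
      fw <- recon_pass(params)
      pre_losses[ep] <- fw$loss
      gr <- recon_grads(params, fw)
      st <- adam_step(params, gr$grads, state, lr = cfg$lr)
      params <- st$params; state <- st$state
    }

    ## stage 2: centroid initialisation on the latent embedding
    Z <- nn_forward(params$enc, Xin)$out
    km <- lloyd_kmeans(Z, K, seed = cfg$seed + 1L,
                       nstart = cfg$kmeans_restarts)
    C <- km$centers
    labels <- km$cluster

    ## stage 3: joint self-training
    params$C <- C
    state <- adam_init(params)
    P <- NULL
    dec_losses <- numeric(0)
    for (ep in seq_len(cfg$dec_epochs)) {
      fw <- recon_pass(params)
      Q <- soft_assignments(fw$Z, params$C, alpha)
      if (ep %% cfg$refresh_interval == 1L || cfg$refresh_interval == 1L ||
          is.null(P)) {
        P <- target_distribution(Q)
        new_labels <- max.col(Q, ties.method = "first")
        changed <- mean(new_labels != labels)
        labels <- new_labels
        if (ep > 1L && changed < cfg$tol) break
      }
      kl <- sum(P * log(pmax(P, 1e-12) / pmax(Q, 1e-12))) / n
      dQ <- cfg$gamma * (-(P / pmax(Q, 1e-12)) / n)
      closs <- 0
      if (nml > 0) {
        closs <- pairwise_constraint_loss(Q, constraints) / nml
        dQ <- dQ + cfg$lambda * constraint_loss_grad_q(Q, constraints) / nml
      }
      sb <- soft_assign_backward(fw$Z, params$C, alpha, dQ)
      dec_losses <- c(dec_losses,
                      fw$loss + cfg$gamma * kl + cfg$lambda * closs)
      gr <- recon_grads(params, fw, extra_dZ = sb$dZ)
      gr$grads$C <- sb$dC
      st <- adam_step(params, gr$grads, state, lr = cfg$lr)
      params <- st$params; state <- st$state
    }
    Zfin <- nn_forward(params$enc, Xin)$out
    Qfin <- soft_assignments(Zfin, params$C, alpha)
    list(params = params, labels = max.col(Qfin, ties.method = "first"),
         pre_losses = pre_losses, dec_losses = dec_losses)
  })

  obj <- structure(list(method = if (is.null(constraints)) "zinb_dec"
                        else "zinb_dec_constrained",
                        K = K, alpha = alpha, cfg = cfg,
                        params = res$params,
                        gene_ids = ds$gene_ids,
                        feat_mean = fmean, feat_sd = fsd,
                        labels = res$labels,
                        truth = ds$cell_table$cell_type,
                        pretrain_losses = res$pre_losses,
                        joint_losses = res$dec_losses),
                   class = c("sc_zinb_dec", "sc_clustering"))
  if (!is.null(obj$truth)) obj$train_ari <- ari(obj$truth, obj$labels)
  obj
}

#' @export
predict.sc_zinb_dec <- function(object, ds = NULL, ...) {
  if (is.null(ds)) return(object$labels)
  stopifnot(inherits(ds, "sc_dataset"))
  if (!identical(ds$gene_ids, object$gene_ids))
    stop("gene vocabulary differs from the training data")
  Xw <- as_dense(ds$X)
  Xin <- pmin(pmax(sweep(sweep(Xw, 2, object$feat_mean), 2,
                         object$feat_sd, "/"), -10), 10)
  Z <- nn_forward(object$params$enc, Xin)$out
  Q <- soft_assignments(Z, object$params$C, object$alpha)
  max.col(Q, ties.method = "first")
}

#' Graph-autoencoder clustering on the cell-gene graph
#'
#' Builds the weighted bipartite cell-gene graph of the (preprocessed)
#' dataset, encodes all nodes with two propagation layers over the
#' symmetric-normalized adjacency (gene nodes carry fixed random features,
#' cell nodes aggregate them), and trains the linear maps so that inner
#' products of cell and gene embeddings reconstruct the observed edge weights
#' (squared error over observed edges plus an equal-count per-epoch sample of
#' non-edges).  Final labels come from Lloyd's algorithm with `K` clusters on
#' the cell embeddings.
#'
#' @inheritParams fit_zinb_dec
#' @param cfg list of options: `seed` (0), `feat_dim` (128), `hidden` (64),
#'   `latent_dim` (32), `epochs` (200), `lr` (1e-2), `kmeans_restarts` (20).
#' @return object of classes `sc_graph_ae_cluster`, `sc_clustering`.
#' @export
fit_graph_ae_cluster <- function(ds, K, cfg = list()) {
  stopifnot(inherits(ds, "sc_dataset"))
  defaults <- list(seed = 0L, feat_dim = 128L, hidden = 64L, latent_dim = 32L,
                   epochs = 200L, lr = 1e-2, kmeans_restarts = 20L)
  cfg <- utils::modifyList(defaults, cfg)
  if (K < 1) stop("K must be >= 1")
  if (n_cells(ds) < K) stop("n_cells < K")
  ds <- ensure_preprocessed(ds, "graph_ae_cluster")
  n_c <- n_cells(ds); n_g <- n_genes(ds)
  g <- cell_gene_graph(ds)
  gn <- normalize_adjacency(g, mode = "sym", add_self_loops = TRUE)
  A <- norm_adjacency_matrix(gn)
  obs <- g$edges                       # u: cell node, v: gene node, w weight
  m_obs <- nrow(obs)
  Xd <- as_dense(ds$X)

  res <- withr::with_seed(cfg$seed, {
    f <- cfg$feat_dim
    Fmat <- rbind(matrix(0, n_c, f),
                  matrix(stats::rnorm(n_g * f, sd = 1 / sqrt(f)), n_g, f))
    params <- list(W1 = nn_init_mat(f, cfg$hidden),
                   W2 = nn_init_mat(cfg$hidden, cfg$latent_dim))
    state <- adam_init(params)
    AF <- as.matrix(A %*% Fmat)        # constant across epochs
    losses <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      A1 <- AF %*% params$W1
      H1 <- nn_relu(A1)
      AH <- as.matrix(A %*% H1)
      Z <- AH %*% params$W2
      ## equal-count sample of non-edges (cell, gene) with zero target
      neg_u <- integer(0); neg_v <- integer(0)
      tries <- 0L
      while (length(neg_u) < m_obs && tries < 20L) {
        need <- m_obs - length(neg_u)
        cu <- sample.int(n_c, need, replace = TRUE)
        gv <- sample.int(n_g, need, replace = TRUE)
        ok <- Xd[cbind(cu, gv)] == 0
        neg_u <- c(neg_u, cu[ok]); neg_v <- c(neg_v, gv[ok])
        tries <- tries + 1L
      }
      pu <- c(obs$u, neg_u)
      pv <- c(obs$v, n_c + neg_v)
      tgt <- c(obs$w, numeric(length(neg_u)))
      s <- rowSums(Z[pu, , drop = FALSE] * Z[pv, , drop = FALSE])
      r <- s - tgt
      m_all <- length(r)
      losses[ep] <- mean(r^2)
      R <- Matrix::sparseMatrix(i = pu, j = pv, x = 2 * r / m_all,
                                dims = c(n_c + n_g, n_c + n_g))
      dZ <- as.matrix(R %*% Z + Matrix::t(R) %*% Z)
      dW2 <- crossprod(AH, dZ)
      dAH <- dZ %*% t(params$W2)
      dH1 <- as.matrix(A %*% dAH)
      dA1 <- dH1 * (A1 > 0)
      dW1 <- crossprod(AF, dA1)
      st <- adam_step(params, list(W1 = dW1, W2 = dW2), state, lr = cfg$lr)
      params <- st$params; state <- st$state
    }
    A1 <- AF %*% params$W1
    Z <- as.matrix(A %*% nn_relu(A1)) %*% params$W2
    Zc <- Z[seq_len(n_c), , drop = FALSE]
    km <- lloyd_kmeans(Zc, K, seed = cfg$seed + 1L,
                       nstart = cfg$kmeans_restarts)
    list(params = params, Fmat = Fmat, labels = km$cluster,
         centers = km$centers, losses = losses, Zc = Zc)
  })

  obj <- structure(list(method = "graph_ae_cluster", K = K, cfg = cfg,
                        params = res$params, gene_features =
                          res$Fmat[n_c + seq_len(n_g), , drop = FALSE],
                        gene_ids = ds$gene_ids,
                        centers = res$centers,
                        labels = res$labels,
                        embedding = res$Zc,
                        truth = ds$cell_table$cell_type,
                        losses = res$losses),
                   class = c("sc_graph_ae_cluster", "sc_clustering"))
  if (!is.null(obj$truth)) obj$train_ari <- ari(obj$truth, obj$labels)
  obj
}

#' @export
predict.sc_graph_ae_cluster <- function(object, ds = NULL, ...) {
  if (is.null(ds)) return(object$labels)
  stopifnot(inherits(ds, "sc_dataset"))
  if (!identical(ds$gene_ids, object$gene_ids))
    stop("gene vocabulary differs from the training data")
  n_c <- n_cells(ds); n_g <- n_genes(ds)
  g <- cell_gene_graph(ds)
  gn <- normalize_adjacency(g, mode = "sym", add_self_loops = TRUE)
  A <- norm_adjacency_matrix(gn)
  Fmat <- rbind(matrix(0, n_c, ncol(object$gene_features)),
                object$gene_features)
  AF <- as.matrix(A %*% Fmat)
  Z <- as.matrix(A %*% nn_relu(AF %*% object$params$W1)) %*% object$params$W2
  Zc <- Z[seq_len(n_c), , drop = FALSE]
  d2 <- outer(rowSums(Zc^2), rep(1, nrow(object$centers))) +
    outer(rep(1, n_c), rowSums(object$centers^2)) -
    2 * Zc %*% t(object$centers)
  max.col(-d2, ties.method = "first")
}
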