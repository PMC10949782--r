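## Minimal dense-network machinery shared by the autoencoder, MLP and GNN
## models: Glorot initialisation, forward/backward passes for affine+ReLU
## stacks, softmax cross-entropy, and an Adam optimizer over a flat list of
## parameter matrices.  Everything is plain matrix algebra; determinism comes
## from seeding R's RNG around initialisation and minibatch sampling.

#' @keywords internal
nn_init_mat <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

## params: list of list(W=, b=) per layer
#' @keywords internal
nn_init_mlp <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L), function(i)
    list(W = nn_init_mat(sizes[i], sizes[i + 1L]),
         b = matrix(0, 1, sizes[i + 1L])))
}

#' @keywords internal
nn_relu <- function(x) pmax(x, 0)

#' @keywords internal
nn_sigmoid <- function(x) 1 / (1 + exp(-pmin(pmax(x, -30), 30)))

#' @keywords internal
nn_softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

#' @keywords internal
nn_softmax <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

## Forward through affine+ReLU hidden layers; the last layer is affine only.
## Returns list(out=, cache=) where cache holds per-layer inputs and
## pre-activations for the backward pass.
#' @keywords internal
nn_forward <- function(params, x) {
  L <- length(params)
  cache <- vector("list", L)
  h <- x
  for (i in seq_len(L)) {
    a <- h %*% params[[i]]$W
    a <- sweep(a, 2, as.vector(params[[i]]$b), "+")
    cache[[i]] <- list(input = h, pre = a)
    h <- if (i < L) nn_relu(a) else a
  }
  list(out = h, cache = cache)
}

## Backward given dL/d(out).  Returns list(grads = per-layer list(W,b),
## dinput = dL/dx).
#' @keywords internal
nn_backward <- function(params, cache, dout) {
  L <- length(params)
  grads <- vector("list", L)
  delta <- dout
  for (i in rev(seq_len(L))) {
    if (i < L) delta <- delta * (cache[[i + 1L]]$input > 0)  # ReLU mask
    grads[[i]] <- list(W = crossprod(cache[[i]]$input, delta),
                       b = matrix(colSums(delta), 1))
    delta <- delta %*% t(params[[i]]$W)
  }
  list(grads = grads, dinput = delta)
}

## ---- Adam over an arbitrary nested list of matrices ------------------------

#' @keywords internal
adam_init <- function(params) {
  zeros <- rapply(params, function(p) p * 0, how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

#' @keywords internal
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (weight_decay > 0) g <- g + weight_decay * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else upd(p, g, m, v)
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = t))
}

## softmax cross-entropy: y is a one-hot matrix (or row weights), returns
## list(loss=, dlogits=) with gradients averaged over rows.
#' @keywords internal
nn_softmax_xent <- function(logits, y_onehot, row_weights = NULL) {
  p <- nn_softmax(logits)
  n <- nrow(logits)
  w <- if (is.null(row_weights)) rep(1, n) else row_weights
  eps <- 1e-12
  loss <- -sum(w * rowSums(y_onehot * log(p + eps))) / sum(w)
  dlogits <- (p - y_onehot) * (w / sum(w))
  list(loss = loss, dlogits = dlogits, prob = p)
}

#' @keywords internal
one_hot <- function(labels, vocab) {
  m <- matrix(0, length(labels), length(vocab))
  m[cbind(seq_along(labels), match(as.character(labels), vocab))] <- 1
  m
}

## Seeded Lloyd k-means with restarts; wraps stats::kmeans (Lloyd algorithm,
## best of `nstart` seeded restarts by total within-cluster sum of squares).
#' @keywords internal
lloyd_kmeans <- function(Z, K, seed, nstart = 20L, iter_max = 100L) {
  if (K == 1L)
    return(list(cluster = rep(1L, nrow(Z)),
                centers = matrix(colMeans(Z), 1)))
  withr::with_seed(seed, {
    km <- suppressWarnings(
      stats::kmeans(Z, centers = K, iter.max = iter_max, nstart = nstart,
                    algorithm = "Lloyd"))
    list(cluster = km$cluster, centers = km$centers)
  })
}
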