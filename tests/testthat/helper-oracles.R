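# Independent oracles used to cross-check the package implementations.
# These deliberately use different formulations (pair counting, subset
# enumeration) than the code under test.

# ARI by explicit pair counting (Hubert-Arabie pair form).
brute_ari <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa && !sb) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  denom <- (s11 + s10) * (s10 + s00) + (s11 + s01) * (s01 + s00)
  if (denom == 0) {
    # both partitions degenerate in the same way
    return(if (s10 + s01 == 0) 1.0 else 0.0)
  }
  2 * (s11 * s00 - s10 * s01) / denom
}

# NMI by explicit double loops over class values, arithmetic-mean norm.
brute_nmi <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  mi <- 0
  for (x in ua) for (y in ub) {
    nij <- sum(a == x & b == y)
    if (nij > 0)
      mi <- mi + (nij / n) * log(nij * n / (sum(a == x) * sum(b == y)))
  }
  ha <- 0
  for (x in ua) { p <- sum(a == x) / n; ha <- ha - p * log(p) }
  hb <- 0
  for (y in ub) { p <- sum(b == y) / n; hb <- hb - p * log(p) }
  if (ha == 0 || hb == 0) return(0)
  max(min(mi / ((ha + hb) / 2), 1), 0)
}

# NNLS by brute-force enumeration of active sets with a KKT check.
brute_nnls <- function(S, y) {
  p <- ncol(S)
  best <- NULL; best_obj <- Inf
  for (mask in 0:(2^p - 1)) {
    act <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    beta <- numeric(p)
    if (length(act)) {
      Sa <- S[, act, drop = FALSE]
      coef <- tryCatch(qr.solve(crossprod(Sa), crossprod(Sa, y)),
                       error = function(e) NULL)
      if (is.null(coef) || any(coef < -1e-9)) next
      beta[act] <- pmax(as.vector(coef), 0)
    }
    grad <- -2 * as.vector(crossprod(S, y - S %*% beta))
    if (any(grad < -1e-6)) next           # KKT: inactive gradients >= 0
    obj <- sum((y - S %*% beta)^2)
    if (obj < best_obj - 1e-12) { best_obj <- obj; best <- beta }
  }
  list(beta = best, objective = best_obj)
}

# Small labeled count dataset for fast model tests.
tiny_labeled_dataset <- function(n_cells = 60, n_genes = 30, K = 2,
                                 lfc = 2, seed = 7) {
  simulate_counts(synthetic_spec(n_cells = n_cells, n_genes = n_genes,
                                 K = K, lfc_scale = lfc, dropout_rate = 0.1,
                                 depth = 500, seed = seed))
}

# All 3x3 contingency tables with total n (non-negative integer matrices).
enumerate_tables <- function(n) {
  out <- list()
  idx <- 0
  counts <- integer(9)
  rec <- function(pos, remaining) {
    if (pos == 9) {
      counts[9] <<- remaining
      idx <<- idx + 1
      out[[idx]] <<- matrix(counts, 3, 3)
      return(invisible())
    }
    for (v in 0:remaining) {
      counts[pos] <<- v
      rec(pos + 1, remaining - v)
    }
  }
  rec(1, n)
  out
}

# Reconstruct a pair of label vectors realizing a contingency table.
labels_from_table <- function(ct) {
  a <- character(0); b <- character(0)
  for (i in 1:nrow(ct)) for (j in 1:ncol(ct)) {
    if (ct[i, j] > 0) {
      a <- c(a, rep(paste0("r", i), ct[i, j]))
      b <- c(b, rep(paste0("c", j), ct[i, j]))
    }
  }
  list(a = a, b = b)
}
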