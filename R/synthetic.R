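#' Specification for a synthetic labeled count dataset
#'
#' The generator emulates the structure of droplet scRNA-seq benchmark data:
#' log-normal baseline gene means, per-type differential expression on
#' disjoint gene sets, negative-binomial counts at a target sequencing depth,
#' and uniform technical dropout.
#'
#' @param n_cells,n_genes dataset dimensions.
#' @param K number of cell types.
#' @param type_proportions simplex vector of length K (default uniform).
#' @param de_fraction fraction of genes differential per type (each type gets
#'   its own disjoint set).
#' @param lfc_scale log-fold-change magnitude of differential genes (natural
#'   log; genes are up- or down-regulated by `exp(±lfc_scale)`).
#' @param base_mean_log_mu,base_mean_log_sd parameters of the log-normal
#'   baseline gene means.
#' @param dispersion negative-binomial dispersion theta (size).
#' @param dropout_rate probability an observed count is zeroed (uniform,
#'   mean-independent).
#' @param depth target total counts per cell.
#' @param seed integer seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cells = 400L, n_genes = 200L, K = 4L,
                           type_proportions = NULL, de_fraction = 0.1,
                           lfc_scale = 1, base_mean_log_mu = 0,
                           base_mean_log_sd = 1, dispersion = 2,
                           dropout_rate = 0.1, depth = 2000, seed = 0L) {
  if (is.null(type_proportions)) type_proportions <- rep(1 / K, K)
  stopifnot(n_cells >= 1, n_genes >= 1, K >= 1,
            length(type_proportions) == K,
            abs(sum(type_proportions) - 1) < 1e-8,
            all(type_proportions > 0),
            de_fraction >= 0, de_fraction <= 1, lfc_scale >= 0,
            base_mean_log_sd > 0, dispersion > 0,
            dropout_rate >= 0, dropout_rate < 1, depth > 0)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Simulate a labeled count dataset
#'
#' Per gene, a baseline mean is drawn log-normal; each type up- or
#' down-regulates its own disjoint random `de_fraction` of genes by
#' `exp(±lfc_scale)` (sign random per gene); each cell's expected profile is
#' scaled to the target depth, counts drawn negative binomial with the given
#' dispersion, then zeroed independently with the dropout probability.
#' Deterministic given the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return an [sc_dataset] with `cell_type` labels and layer `"raw"`.
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    G <- spec$n_genes; n <- spec$n_cells; K <- spec$K
    base <- exp(stats::rnorm(G, spec$base_mean_log_mu, spec$base_mean_log_sd))
    n_de <- floor(spec$de_fraction * G)
    if (n_de * K > G)
      stop("de_fraction too large for disjoint per-type gene sets")
    de_pool <- sample.int(G, n_de * K)
    profiles <- matrix(base, G, K)
    for (t in seq_len(K)) {
      g_t <- de_pool[((t - 1L) * n_de + 1L):(t * n_de)]
      if (n_de > 0) {
        sign_t <- sample(c(-1, 1), n_de, replace = TRUE)
        profiles[g_t, t] <- profiles[g_t, t] * exp(sign_t * spec$lfc_scale)
      }
    }
    labels <- sample.int(K, n, replace = TRUE, prob = spec$type_proportions)
    lam <- t(profiles[, labels])                       # cells x genes
    lam <- lam * (spec$depth / rowSums(lam))
    counts <- matrix(stats::rnbinom(n * G, size = spec$dispersion,
                                    mu = as.vector(lam)), n, G)
    if (spec$dropout_rate > 0) {
      drop <- matrix(stats::runif(n * G) < spec$dropout_rate, n, G)
      counts[drop] <- 0L
    }
    keep <- rowSums(counts) > 0        # guard: depth makes this ~never fire
    counts <- counts[keep, , drop = FALSE]
    storage.mode(counts) <- "double"
    ds <- sc_dataset(counts,
                     cell_ids = paste0("cell", seq_len(nrow(counts))),
                     gene_ids = sprintf("gene%03d", seq_len(G)),
                     cell_table = data.frame(
                       cell_id = paste0("cell", seq_len(nrow(counts))),
                       cell_type = paste0("type", labels[keep]),
                       stringsAsFactors = FALSE),
                     layers = list(raw = counts))
    ds$type_profiles <- profiles
    log_append(ds, "simulate_counts", list(seed = spec$seed, K = K,
                                           lfc_scale = spec$lfc_scale))
  })
}

#' Specification for spot mixtures with known proportions
#'
#' @param n_spots number of spatial capture spots.
#' @param dirichlet_alpha positive concentration vector (length = number of
#'   reference types).
#' @param depth target total counts per spot.
#' @param seed integer seed.
#' @return object of class `mixture_spec`.
#' @export
mixture_spec <- function(n_spots = 100L, dirichlet_alpha = rep(1, 4),
                         depth = 1e4, seed = 0L) {
  stopifnot(n_spots >= 1, all(dirichlet_alpha > 0), depth > 0)
  structure(as.list(environment()), class = "mixture_spec")
}

#' Simulate spot mixtures from a labeled reference
#'
#' Per spot, mixing proportions beta are drawn Dirichlet; the expected
#' profile is the beta-weighted combination of the reference's per-type mean
#' profiles, scaled to the target depth; observed counts are Poisson around
#' that expectation.  The true beta per spot is returned alongside.
#'
#' @param reference an [sc_dataset] with at least 2 cell types (e.g. from
#'   [simulate_counts()]).
#' @param mspec a [mixture_spec()]; `dirichlet_alpha` must match the number
#'   of reference types.
#' @return object of class `sc_mixture`: fields `spots` (spots x genes count
#'   matrix), `truth` (`proportion_matrix`, spots x types), `reference`.
#' @export
simulate_mixtures <- function(reference, mspec) {
  stopifnot(inherits(reference, "sc_dataset"), inherits(mspec, "mixture_spec"))
  y <- as.character(reference$cell_table$cell_type)
  if (is.null(y) || length(unique(y)) < 2)
    stop("reference needs at least 2 cell types")
  types <- sort(unique(y))
  K <- length(types)
  if (length(mspec$dirichlet_alpha) != K)
    stop("dirichlet_alpha length must equal the number of reference types")
  X <- as_dense(reference$X)
  profiles <- vapply(types, function(t) colMeans(X[y == t, , drop = FALSE]),
                     numeric(ncol(X)))                 # genes x types
  withr::with_seed(mspec$seed, {
    gm <- matrix(stats::rgamma(mspec$n_spots * K,
                               shape = rep(mspec$dirichlet_alpha,
                                           each = mspec$n_spots)),
                 mspec$n_spots, K)
    beta <- gm / rowSums(gm)
    expected <- beta %*% t(profiles)                   # spots x genes
    expected <- expected * (mspec$depth / rowSums(expected))
    spots <- matrix(stats::rpois(length(expected), as.vector(expected)),
                    nrow(expected), ncol(expected))
    storage.mode(spots) <- "double"
    colnames(spots) <- reference$gene_ids
    rownames(spots) <- paste0("spot", seq_len(nrow(spots)))
    colnames(beta) <- types
    rownames(beta) <- rownames(spots)
    class(beta) <- c("proportion_matrix", class(beta))
    structure(list(spots = spots, truth = beta, reference = reference),
              class = "sc_mixture")
  })
}

#' @export
print.sc_mixture <- function(x, ...) {
  cat("sc_mixture:", nrow(x$spots), "spots x", ncol(x$spots), "genes,",
      ncol(x$truth), "types\n")
  invisible(x)
}

#' Sample must-link / cannot-link constraints from true labels
#'
#' Must-links are drawn uniformly without replacement from same-label pairs,
#' cannot-links from different-label pairs.
#'
#' @param labels label vector.
#' @param n_must,n_cannot numbers of pairs to draw.
#' @param seed integer seed.
#' @return a [constraint_set].
#' @export
sample_constraints <- function(labels, n_must, n_cannot, seed = 0L) {
  labels <- as.character(labels)
  n <- length(labels)
  idx_by_class <- split(seq_len(n), labels)
  max_must <- sum(vapply(idx_by_class, function(i)
    choose(length(i), 2), numeric(1)))
  max_cannot <- choose(n, 2) - max_must
  if (n_must > max_must)
    stop("requested ", n_must, " must-links but only ", max_must,
         " same-label pairs exist")
  if (n_cannot > max_cannot)
    stop("requested ", n_cannot, " cannot-links but only ", max_cannot,
         " different-label pairs exist")
  withr::with_seed(seed, {
    ## enumerate candidate pairs lazily by rejection-free sampling from the
    ## full pair list (n is small in benchmark settings)
    all_pairs <- t(utils::combn(n, 2))
    same <- labels[all_pairs[, 1]] == labels[all_pairs[, 2]]
    ml <- all_pairs[same, , drop = FALSE]
    cl <- all_pairs[!same, , drop = FALSE]
    ml <- ml[sample.int(nrow(ml), n_must), , drop = FALSE]
    cl <- cl[sample.int(nrow(cl), n_cannot), , drop = FALSE]
    constraint_set(must_link = ml, cannot_link = cl)
  })
}

## ---- built-in fixtures -----------------------------------------------------

## Standard named fixtures; all seed 0.  "synth_blobs4" is the easy
## well-separated case (lfc 2, dropout 0.1), "synth_hard4" the hard one
## (lfc 1, dropout 0.3), "synth_sep2" a linearly separable 2-type annotation
## fixture, and "synth_mix4" a deconvolution benchmark (100 spots, uniform
## Dirichlet, depth 1e4) built on a blobs-style reference.
#' @keywords internal
register_builtin_fixtures <- function() {
  register_dataset("synth_blobs4", function()
    simulate_counts(synthetic_spec(n_cells = 400L, n_genes = 200L, K = 4L,
                                   lfc_scale = 2, dropout_rate = 0.1,
                                   seed = 0L)))
  register_dataset("synth_hard4", function()
    simulate_counts(synthetic_spec(n_cells = 400L, n_genes = 200L, K = 4L,
                                   lfc_scale = 1, dropout_rate = 0.3,
                                   seed = 0L)))
  register_dataset("synth_sep2", function()
    simulate_counts(synthetic_spec(n_cells = 300L, n_genes = 150L, K = 2L,
                                   lfc_scale = 2, dropout_rate = 0.1,
                                   seed = 0L)))
  register_dataset("synth_mix4", function() {
    ref <- simulate_counts(synthetic_spec(n_cells = 400L, n_genes = 200L,
                                          K = 4L, lfc_scale = 2,
                                          dropout_rate = 0.1, seed = 0L))
    simulate_mixtures(ref, mixture_spec(n_spots = 100L,
                                        dirichlet_alpha = rep(1, 4),
                                        depth = 1e4, seed = 0L))
  })
  invisible(NULL)
}
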