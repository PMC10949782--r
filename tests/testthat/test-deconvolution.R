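ref_fixture <- function(seed = 21)
  simulate_counts(synthetic_spec(n_cells = 120, n_genes = 60, K = 3,
                                 lfc_scale = 2, dropout_rate = 0.1,
                                 depth = 1000, seed = seed))

test_that("signature construction selects markers by fold change", {
  # two types with disjoint constant profiles reproduce themselves
  X <- rbind(matrix(rep(c(8, 8, 0, 0), each = 4), 4, 4),
             matrix(rep(c(0, 0, 8, 8), each = 4), 4, 4))
  ds <- sc_dataset(X, cell_table = data.frame(
    cell_id = paste0("c", 1:8),
    cell_type = rep(c("A", "B"), each = 4)))
  sig <- build_signature(ds, n_markers = 2)
  expect_identical(sig$type_names, c("A", "B"))
  SA <- sig$S[, "A"]
  expect_true(all(SA[sig$gene_ids %in% ds$gene_ids[1:2]] > 0))
  expect_true(all(SA[sig$gene_ids %in% ds$gene_ids[3:4]] == 0))
  # n_markers >= n_genes keeps every gene
  expect_equal(nrow(build_signature(ds, n_markers = 100)$S), 4)
  # a type-exclusive gene outranks a uniform gene
  Xr <- cbind(c(rep(6, 4), rep(0, 4)), matrix(5, 8, 3))
  dsr <- sc_dataset(Xr, cell_table = ds$cell_table)
  sigr <- build_signature(dsr, n_markers = 1)
  expect_true(dsr$gene_ids[1] %in% sigr$gene_ids)
  # minimum cells per type
  small <- sc_dataset(X[1:5, ], cell_table = data.frame(
    cell_id = paste0("c", 1:5), cell_type = c("A", "A", "A", "A", "B")))
  expect_error(build_signature(small), "fewer than 3")
})

test_that("nnls recovers exact mixtures and hand-solved active sets", {
  ref <- ref_fixture()
  sig <- build_signature(ref, n_markers = 10)
  set.seed(1)
  beta <- matrix(rgamma(15 * 3, 1), 15, 3)
  beta <- beta / rowSums(beta)
  Y <- beta %*% t(sig$S)
  colnames(Y) <- sig$gene_ids
  P <- nnls_deconvolve(Y, sig)
  expect_equal(unclass(P), beta, tolerance = 1e-8, ignore_attr = TRUE)
  expect_lte(score_deconvolution(
    P, structure(beta, dimnames = list(NULL, sig$type_names))), 1e-6)
  # S columns (1,1) and (1,0), y = (0,1): active set {1}, beta = (0.5, 0)
  sig2 <- structure(list(S = cbind(c(1, 1), c(1, 0)),
                         gene_ids = c("g1", "g2"),
                         type_names = c("t1", "t2")),
                    class = "signature_matrix")
  P2 <- nnls_deconvolve(matrix(c(0, 1), 1, 2), sig2)
  expect_equal(as.vector(unclass(P2)), c(1, 0))
  # orthogonal signature columns: clipped per-column projections
  sig3 <- structure(list(S = cbind(c(2, 0), c(0, 1)),
                         gene_ids = c("g1", "g2"),
                         type_names = c("t1", "t2")),
                    class = "signature_matrix")
  y <- matrix(c(4, 3), 1, 2)
  P3 <- nnls_deconvolve(y, sig3)
  expect_equal(as.vector(unclass(P3)), c(2, 3) / 5)   # beta = (2, 3)
})

test_that("nnls solutions satisfy KKT and match active-set enumeration", {
  set.seed(5)
  for (rep in 1:40) {
    K <- sample(2:5, 1); G <- K + sample(2:6, 1)
    S <- matrix(rexp(G * K), G, K)
    y <- as.vector(S %*% rexp(K)) + rexp(G, 10)
    beta <- pracma::lsqnonneg(S, y)$x
    grad <- -2 * as.vector(crossprod(S, y - S %*% beta))
    expect_true(all(grad[beta > 1e-8] < 1e-6))
    expect_true(all(grad >= -1e-6))
    oracle <- brute_nnls(S, y)
    expect_lte(sum((y - S %*% beta)^2) - oracle$objective, 1e-8)
  }
})

test_that("log-weighted nnls stays on the simplex and near the truth", {
  ref <- ref_fixture()
  sig <- build_signature(ref, n_markers = 10)
  set.seed(2)
  beta <- matrix(rgamma(8 * 3, 1), 8, 3); beta <- beta / rowSums(beta)
  Y <- beta %*% t(sig$S) * 50
  colnames(Y) <- sig$gene_ids
  P <- nnls_deconvolve(Y, sig, log_weighting = TRUE)
  expect_equal(rowSums(unclass(P)), rep(1, 8), tolerance = 1e-9)
  expect_lte(mean((unclass(P) - beta)^2), 1e-4)
})

test_that("seeded NMF keeps a non-increasing objective and type identity", {
  ref <- ref_fixture()
  sig <- build_signature(ref, n_markers = 10)
  mix <- simulate_mixtures(ref, mixture_spec(n_spots = 20,
                                             dirichlet_alpha = rep(1, 3),
                                             depth = 1e4, seed = 3))
  P <- seeded_nmf_deconvolve(ref, mix$spots, sig)
  obj <- attr(P, "objective")
  expect_true(all(diff(obj) <= 1e-8 * pmax(obj[-length(obj)], 1)))
  expect_equal(rowSums(unclass(P)), rep(1, 20), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(colnames(P), sig$type_names)
  # dominant predicted type matches the dominant true type for clear spots
  clear <- apply(unclass(mix$truth), 1, max) > 0.6
  expect_gte(mean(max.col(unclass(P))[clear] ==
                    max.col(unclass(mix$truth))[clear]), 0.9)
  # K = 1: all proportions are 1
  sig1 <- structure(list(S = sig$S[, 1, drop = FALSE],
                         gene_ids = sig$gene_ids, type_names = "t"),
                    class = "signature_matrix")
  P1 <- seeded_nmf_deconvolve(ref, mix$spots, sig1, list(n_iter = 5L))
  expect_equal(as.vector(unclass(P1)), rep(1, 20))
})

test_that("deconvolution scoring is a symmetric proportion MSE", {
  A <- matrix(c(0.5, 0.5, 1, 0), 2, 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b")))
  B <- matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b")))
  expect_equal(score_deconvolution(A, A), 0)
  expect_equal(score_deconvolution(A[1, , drop = FALSE],
                                   B[1, , drop = FALSE]), 0.25)
  expect_equal(score_deconvolution(A, B), score_deconvolution(B, A))
  bad <- B; colnames(bad) <- c("b", "a")
  expect_error(score_deconvolution(A, bad), "misaligned")
  # proportions export
  path <- withr::local_tempfile(fileext = ".csv")
  write_proportions(structure(A, class = c("proportion_matrix", "matrix")),
                    path)
  tab <- read.csv(path)
  expect_identical(names(tab), c("spot_id", "a", "b"))
})
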