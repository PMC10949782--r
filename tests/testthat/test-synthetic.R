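test_that("generators are pure functions of their spec", {
  sp <- synthetic_spec(n_cells = 50, n_genes = 20, seed = 9)
  d1 <- simulate_counts(sp); d2 <- simulate_counts(sp)
  expect_identical(as.matrix(d1$X), as.matrix(d2$X))
  expect_identical(d1$cell_table$cell_type, d2$cell_table$cell_type)
  ref <- simulate_counts(synthetic_spec(n_cells = 60, n_genes = 30, K = 3,
                                        seed = 1))
  ms <- mixture_spec(n_spots = 12, dirichlet_alpha = rep(1, 3), seed = 4)
  m1 <- simulate_mixtures(ref, ms); m2 <- simulate_mixtures(ref, ms)
  expect_identical(m1$spots, m2$spots)
  expect_identical(unclass(m1$truth), unclass(m2$truth))
})

test_that("spec validation rejects impossible settings", {
  expect_error(synthetic_spec(K = 4, type_proportions = c(1, 1, 1, 1)))
  expect_error(synthetic_spec(dropout_rate = 1))
  expect_error(simulate_counts(synthetic_spec(n_genes = 10, K = 4,
                                              de_fraction = 0.5)),
               "disjoint")
})

test_that("count moments match the configured means without dropout", {
  # large dispersion, no dropout: per-gene sample means track expectations
  sp <- synthetic_spec(n_cells = 2000, n_genes = 60, K = 2,
                       de_fraction = 0.1, lfc_scale = 1, dispersion = 1e4,
                       dropout_rate = 0, depth = 1500, seed = 13)
  ds <- simulate_counts(sp)
  X <- as.matrix(ds$X)
  prof <- ds$type_profiles
  labels <- as.integer(sub("type", "", ds$cell_table$cell_type))
  lam <- t(prof[, labels])
  lam <- lam * (sp$depth / rowSums(lam))
  exp_mean <- colMeans(lam)
  obs_mean <- colMeans(X)
  se <- sqrt(colMeans(lam + lam^2 / sp$dispersion) / nrow(X))
  frac_in <- mean(abs(obs_mean - exp_mean) <= 3 * se)
  expect_gte(frac_in, 0.97)   # ~99.7% expected; slack for 60 parallel tests
})

test_that("label frequencies match the type proportions", {
  sp <- synthetic_spec(n_cells = 2000, n_genes = 20, K = 2,
                       type_proportions = c(0.3, 0.7), seed = 5)
  ds <- simulate_counts(sp)
  n1 <- sum(ds$cell_table$cell_type == "type1")
  pv <- binom.test(n1, n_cells(ds), p = 0.3)$p.value
  expect_gt(pv, 0.001)
})

test_that("mixtures honour the Dirichlet truth and concentration limits", {
  ref <- simulate_counts(synthetic_spec(n_cells = 90, n_genes = 40, K = 3,
                                        lfc_scale = 2, seed = 2))
  mix <- simulate_mixtures(ref, mixture_spec(n_spots = 30,
                                             dirichlet_alpha = rep(1, 3),
                                             depth = 1e4, seed = 0))
  expect_equal(rowSums(unclass(mix$truth)), rep(1, 30), tolerance = 1e-9,
               ignore_attr = TRUE)
  # concentrated alpha: spots approach the scaled type profile
  conc <- simulate_mixtures(ref, mixture_spec(
    n_spots = 5, dirichlet_alpha = c(2000, 0.001, 0.001), depth = 1e6,
    seed = 1))
  X <- as.matrix(ref$X)
  p1 <- colMeans(X[ref$cell_table$cell_type == "type1", ])
  p1 <- p1 / sum(p1)
  spot1 <- conc$spots[1, ] / sum(conc$spots[1, ])
  expect_gt(cor(p1, spot1), 0.999)
  expect_error(simulate_mixtures(ref, mixture_spec(dirichlet_alpha = 1:2)),
               "length")
})

test_that("nnls on generated spots is consistent at high depth", {
  # low technical noise isolates the depth limit: near-constant per-cell
  # totals make the signature's normalized means match the mixture
  # generator's raw means
  ref <- simulate_counts(synthetic_spec(n_cells = 400, n_genes = 60, K = 3,
                                        lfc_scale = 2, dropout_rate = 0,
                                        dispersion = 100, seed = 6))
  mix <- simulate_mixtures(ref, mixture_spec(n_spots = 25,
                                             dirichlet_alpha = rep(1, 3),
                                             depth = 1e6, seed = 7))
  sig <- build_signature(ref, n_markers = 20)
  P <- nnls_deconvolve(mix$spots, sig)
  expect_lte(score_deconvolution(P, mix$truth), 1e-3)
})

test_that("constraint sampling respects labels, bounds and seeds", {
  labs <- c("a", "a", "b")
  expect_error(sample_constraints(labs, 2, 1), "1 same-label")
  expect_error(sample_constraints(labs, 1, 3), "2 different-label")
  cs <- sample_constraints(labs, 1, 2, seed = 0)
  expect_equal(nrow(cs$must_link), 1)
  expect_equal(nrow(cs$cannot_link), 2)
  labs2 <- rep(c("x", "y", "z"), each = 8)
  cs2 <- sample_constraints(labs2, 20, 20, seed = 3)
  expect_true(all(labs2[cs2$must_link[, 1]] == labs2[cs2$must_link[, 2]]))
  expect_true(all(labs2[cs2$cannot_link[, 1]] != labs2[cs2$cannot_link[, 2]]))
  cs3 <- sample_constraints(labs2, 20, 20, seed = 3)
  expect_identical(cs2, cs3)
})
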