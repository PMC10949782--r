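test_that("zinb nll matches closed forms and the plain NB limit", {
  expect_equal(zinb_nll(0, 1, 1, 0), log(2), tolerance = 1e-9)
  # pi = 0 equals the NB negative log-likelihood over a parameter grid
  for (x in c(0, 1, 3, 10)) for (mu in c(0.3, 1, 5)) for (th in c(0.5, 2, 10))
    expect_equal(zinb_nll(x, mu, th, 0),
                 -dnbinom(x, size = th, mu = mu, log = TRUE),
                 tolerance = 1e-6)
  # pi -> 1 at x = 0 drives the NLL to 0
  expect_lt(zinb_nll(0, 1, 1, 1 - 1e-12), 1e-9)
  expect_error(zinb_nll(1, -1, 1, 0), "positive")
  expect_error(zinb_nll(1, 1, 1, 2), "0,1")
  expect_error(zinb_nll(1, Inf, 1, 0), "non-finite")
})

test_that("zinb gradients agree with numerical differentiation", {
  set.seed(3)
  x <- matrix(rpois(8, 2), 2, 4); x[1, 2] <- 0
  mu <- matrix(runif(8, 0.5, 3), 2, 4)
  th <- matrix(runif(8, 0.5, 2), 2, 4)
  pi_ <- matrix(runif(8, 0.1, 0.5), 2, 4)
  g <- scbench:::zinb_nll_grad(x, mu, th, pi_)
  nd <- function(f, m) {
    out <- m * 0; eps <- 1e-6
    for (i in seq_along(m)) {
      mp <- m; mm <- m; mp[i] <- m[i] + eps; mm[i] <- m[i] - eps
      out[i] <- (f(mp) - f(mm)) / (2 * eps)
    }
    out
  }
  expect_equal(g$dmu,
               nd(function(m) sum(zinb_nll(x, m, th, pi_, reduce = FALSE)), mu),
               tolerance = 1e-5)
  expect_equal(g$dtheta,
               nd(function(m) sum(zinb_nll(x, mu, m, pi_, reduce = FALSE)), th),
               tolerance = 1e-5)
  expect_equal(g$dpi,
               nd(function(m) sum(zinb_nll(x, mu, th, m, reduce = FALSE)), pi_),
               tolerance = 1e-5)
})

test_that("soft assignments follow the Student-t kernel", {
  # single centroid: all mass on it
  expect_equal(as.vector(soft_assignments(matrix(rnorm(6), 3, 2),
                                          matrix(0, 1, 2))),
               rep(1, 3))
  # equidistant point splits evenly
  Q <- soft_assignments(matrix(c(0.5, 0), 1, 2),
                        rbind(c(0, 0), c(1, 0)))
  expect_equal(as.vector(Q), c(0.5, 0.5))
  # z at centroid 1, centroid 2 at distance 1, alpha 1 -> (2/3, 1/3)
  Q2 <- soft_assignments(matrix(c(0, 0), 1, 2), rbind(c(0, 0), c(1, 0)))
  expect_equal(as.vector(Q2), c(2 / 3, 1 / 3))
  # rows on the simplex
  Q3 <- soft_assignments(matrix(rnorm(40), 20, 2), matrix(rnorm(8), 4, 2))
  expect_equal(rowSums(Q3), rep(1, 20), tolerance = 1e-9)
})

test_that("target distribution sharpens with the frequency correction", {
  expect_equal(as.vector(target_distribution(matrix(c(0.5, 0.5), 1))),
               c(0.5, 0.5))
  P <- target_distribution(rbind(c(0.9, 0.1), c(0.5, 0.5)))
  expect_equal(P, rbind(c(0.81 / 1.4, 0.01 / 0.6) / (0.81 / 1.4 + 0.01 / 0.6),
                        c(0.25 / 1.4, 0.25 / 0.6) / (0.25 / 1.4 + 0.25 / 0.6)),
               tolerance = 1e-9)
  expect_equal(round(P, 3), rbind(c(0.972, 0.028), c(0.300, 0.700)))
  # uniform Q is a fixed point
  U <- matrix(1 / 3, 6, 3)
  expect_equal(target_distribution(U), U)
  q0 <- matrix(runif(30), 10, 3) + 0.1
  q0 <- q0 / rowSums(q0)
  expect_equal(rowSums(target_distribution(q0)), rep(1, 10),
               tolerance = 1e-9)
})

test_that("sharpening holds under uniform cluster frequencies", {
  set.seed(4)
  K <- 4
  base <- matrix(rexp(250 * K), 250, K)
  base <- base / rowSums(base)
  # stack all cyclic column rotations so the column sums are exactly uniform
  Q <- do.call(rbind, lapply(0:(K - 1), function(s)
    base[, ((seq_len(K) - 1 + s) %% K) + 1]))
  expect_equal(max(abs(colSums(Q) - nrow(Q) / K)), 0, tolerance = 1e-9)
  P <- target_distribution(Q)
  expect_equal(max.col(P), max.col(Q))
  expect_true(all(apply(P, 1, max) >= apply(Q, 1, max) - 1e-12))
})

test_that("constraint sets validate and the loss matches hand values", {
  expect_error(constraint_set(must_link = rbind(c(1, 1))), "identical")
  expect_error(constraint_set(must_link = rbind(c(1, 2)),
                              cannot_link = rbind(c(2, 1))), "both")
  Q <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0.5, 0.5))
  # identical one-hot rows, must-link: zero loss
  expect_equal(pairwise_constraint_loss(
    Q, constraint_set(must_link = rbind(c(1, 2)))), 0, tolerance = 1e-8)
  # orthogonal one-hot rows, cannot-link: zero loss
  expect_equal(pairwise_constraint_loss(
    Q, constraint_set(cannot_link = rbind(c(1, 3)))), 0, tolerance = 1e-8)
  # two uniform rows, must-link: inner product 1/2 -> log 2
  expect_equal(pairwise_constraint_loss(
    rbind(c(0.5, 0.5), c(0.5, 0.5)),
    constraint_set(must_link = rbind(c(1, 2)))), log(2), tolerance = 1e-9)
  expect_equal(pairwise_constraint_loss(Q, constraint_set()), 0)
  expect_error(pairwise_constraint_loss(
    Q, constraint_set(must_link = rbind(c(1, 9)))), "out of range")
})
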