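test_that("log multivariate gamma matches its defining decomposition", {
  expect_equal(log_multigamma(1, 0.5), lgamma(0.5))
  expect_equal(log_multigamma(2, 1.5),
               0.5 * log(pi) + lgamma(1.5) + lgamma(1.0))
  # independent oracle: Gamma_d(a) = pi^((d-1)/2) Gamma(a) Gamma_{d-1}(a-1/2)
  for (case in list(c(3, 4.2), c(2, 1.5), c(5, 7.3), c(4, 2.1)))
    expect_equal(log_multigamma(case[1], case[2]),
                 recursive_log_multigamma(as.integer(case[1]), case[2]),
                 tolerance = 1e-12)
  expect_error(log_multigamma(3, 1), "degrees of freedom")
  expect_error(log_multigamma(2, 0.5), "degrees of freedom")
})

test_that("prior construction follows the reference configurations", {
  pr <- make_prior(niw_prior_spec("proper", scale = 0.5, kappa_offset = 2,
                                  mean = 0, nu = 4), dim = 3)
  expect_equal(pr$kappa, 5)
  expect_equal(pr$S, diag(0.5, 3))
  expect_equal(pr$m, rep(0, 3))
  # kappa = dim + 2 makes the prior mean of Sigma equal S exactly:
  # E(Sigma) = S / (kappa - dim - 1)
  expect_equal(pr$S / (pr$kappa - 3 - 1), 0.5 * diag(3))

  jp <- make_prior("jeffreys", dim = 2)
  expect_equal(jp$S, matrix(0, 2, 2))
  expect_equal(jp$kappa, 0)
  expect_equal(jp$nu, 0)
  expect_equal(jp$logK, 0)
  expect_equal(jp$logL, 0)

  expect_error(niw_prior_spec("proper", scale = -1), "scale")
  expect_error(niw_prior_spec("proper", nu = 0), "nu")
})

test_that("conjugate updates reproduce the closed-form hyperparameters", {
  set.seed(1)
  x <- rnorm(5)
  post <- niw_update(make_prior("jeffreys", 1), matrix(x, ncol = 1))
  expect_equal(post$kappa, 5)
  expect_equal(post$nu, 5)
  expect_equal(drop(post$S), 4 * var(x))
  expect_equal(drop(post$m), mean(x))

  post2 <- niw_update(make_prior(niw_prior_spec("proper", kappa_offset = 3,
                                                nu = 4), 1),
                      matrix(rnorm(10), ncol = 1))
  expect_equal(post2$kappa, 14)  # kappa = 1 + 3 then + 10
  expect_equal(post2$nu, 14)

  # 2-D proper prior, fixed 3-row block, hand-computed scatter:
  # S* = S + 2*Sigma-hat + (4*3/7) mu-hat mu-hat^T  (m = 0)
  Xb <- matrix(c(1, 2, 4,
                 0, 1, -1), nrow = 3)
  pr <- make_prior(niw_prior_spec("proper", scale = 0.5, kappa_offset = 2,
                                  mean = 0, nu = 4), 2)
  post3 <- niw_update(pr, Xb)
  mu <- colMeans(Xb)
  expected <- diag(0.5, 2) + 2 * cov(Xb) + (4 * 3 / 7) * tcrossprod(mu)
  expect_equal(post3$S, expected, tolerance = 1e-12)
  expect_equal(post3$m, (4 * 0 + 3 * mu) / 7)
})

test_that("updating in one batch equals updating sequentially", {
  set.seed(2)
  X <- matrix(rnorm(24), 8, 3)
  for (kind in c("jeffreys", "proper")) {
    pr <- make_prior(kind, 3)
    batch <- niw_update(pr, X)
    seq2 <- niw_update(niw_update(pr, X[1:3, ]), X[4:8, ])
    expect_equal(batch$kappa, seq2$kappa)
    expect_equal(batch$nu, seq2$nu)
    expect_equal(batch$m, seq2$m, tolerance = 1e-12)
    expect_equal(batch$S, seq2$S, tolerance = 1e-12)
  }
  # n = 0 returns the prior unchanged
  pr <- make_prior("jeffreys", 2)
  expect_identical(niw_update(pr, matrix(numeric(0), 0, 2)), pr)
})

test_that("1-D block evidences match numerical quadrature", {
  s <- make_sample(matrix(c(0, 1, 2), ncol = 1), matrix(c(0, 2, 4), ncol = 1))
  # good block: product of per-class integrals
  expect_equal(log_good_block_evidence(s, 1, "jeffreys"),
               quad_log_evidence_1d(c(0, 1, 2), "jeffreys") +
                 quad_log_evidence_1d(c(0, 2, 4), "jeffreys"),
               tolerance = 1e-7)
  # bad block: pooled integral
  expect_equal(log_bad_block_evidence(s, 1, "jeffreys"),
               quad_log_evidence_1d(c(0, 1, 2, 0, 2, 4), "jeffreys"),
               tolerance = 1e-7)
  # proper prior
  pp <- niw_prior_spec("proper")
  expect_equal(log_good_block_evidence(s, 1, pp),
               quad_log_evidence_1d(c(0, 1, 2), "proper") +
                 quad_log_evidence_1d(c(0, 2, 4), "proper"),
               tolerance = 1e-7)
  expect_equal(log_bad_block_evidence(s, 1, pp),
               quad_log_evidence_1d(c(0, 1, 2, 0, 2, 4), "proper"),
               tolerance = 1e-7)
})

test_that("evidences are permutation invariant and scale predictably", {
  set.seed(3)
  s <- null_sample(20, 4)
  blk <- c(2, 4, 1)
  expect_equal(log_good_block_evidence(s, blk),
               log_good_block_evidence(s, rev(blk)))
  expect_equal(log_bad_block_evidence(s, blk),
               log_bad_block_evidence(s, sample(blk)))
  # x -> c*x rescales the good evidence by -0.5*(kappa*_0+kappa*_1)*d*2*log c
  cc <- 3
  s2 <- labeled_sample(s$X * cc, s$y)
  d <- length(blk)
  expect_equal(log_good_block_evidence(s2, blk) -
                 log_good_block_evidence(s, blk),
               -0.5 * (10 + 10) * d * 2 * log(cc), tolerance = 1e-9)
})

test_that("log H is affine invariant under the Jeffreys prior", {
  set.seed(4)
  s <- null_sample(16, 5)
  a <- c(2, 0.5, 4, 1, 8)           # exact powers of two
  b <- c(0.3, -1.2, 0, 5, -0.7)
  s2 <- labeled_sample(sweep(sweep(s$X, 2, a, "*"), 2, b, "+"), s$y)
  for (blk in list(1, c(1, 2), c(3, 5), c(2, 4, 5)))
    expect_equal(log_H(s2, blk), log_H(s, blk), tolerance = 1e-9)
  # sample reordering leaves H unchanged
  ord <- sample(s$n)
  s3 <- labeled_sample(s$X[ord, ], s$y[ord])
  expect_equal(log_H(s3, c(1, 3)), log_H(s, c(1, 3)))
})

test_that("log H separates strong blocks from null blocks", {
  set.seed(5)
  diffs <- replicate(40, {
    s <- one_marker_sample(40, 2, delta = 5)
    log_H(s, 1) - log_H(s, 2)
  })
  expect_gt(mean(diffs > 0), 0.95)
  # bad - good evidence gap shrinks under strong signal (Bayes factor flips)
  set.seed(6)
  gap <- function(delta) mean(replicate(30, {
    s <- one_marker_sample(30, 1, delta = delta)
    log_bad_block_evidence(s, 1) - log_good_block_evidence(s, 1)
  }))
  expect_gt(gap(0), gap(4))
})

test_that("degenerate Jeffreys configurations raise rank errors", {
  set.seed(7)
  s <- null_sample(6, 7)
  # bad block of size n has scatter rank at most n-1
  expect_error(log_bad_block_evidence(s, 1:6), "sample size > block size")
  expect_error(log_good_block_evidence(s, 1:3), "sample size > block size")
  # constant feature: zero scatter
  sc <- labeled_sample(cbind(rep(1, 6), matrix(rnorm(12), 6, 2)),
                       rep(0:1, each = 3))
  expect_error(log_H(sc, 1), "rank-deficient")
  # n = 1 in a class
  s1 <- labeled_sample(matrix(rnorm(8), 4, 2), c(0, 1, 1, 1))
  expect_error(log_H(s1, 1), "sample size > block size")
})

test_that("partition posterior composes block evidences", {
  set.seed(8)
  s <- null_sample(12, 3)
  part <- feature_partition(list(c(1L, 3L)), list(2L), 3)
  expect_equal(
    log_partition_posterior(s, part, "jeffreys", log_prior = -1.7),
    -1.7 + log_good_block_evidence(s, c(1, 3)) + log_bad_block_evidence(s, 2))
  # block order is immaterial
  p1 <- feature_partition(list(1L, 2L), list(3L), 3)
  p2 <- feature_partition(list(2L, 1L), list(3L), 3)
  expect_equal(log_partition_posterior(s, p1), log_partition_posterior(s, p2))
  # all-good vs all-bad singleton partitions: the log difference is the sum
  # of per-feature good/bad Bayes factors, each verified by quadrature
  pg <- feature_partition(list(1L, 2L, 3L), list(), 3)
  pb <- feature_partition(list(), list(1L, 2L, 3L), 3)
  lbf_quad <- sum(vapply(1:3, function(f) {
    x0 <- s$X[s$y == 0, f]; x1 <- s$X[s$y == 1, f]
    (quad_log_evidence_1d(x0, "jeffreys") +
       quad_log_evidence_1d(x1, "jeffreys")) -
      quad_log_evidence_1d(c(x0, x1), "jeffreys")
  }, numeric(1)))
  expect_equal(log_partition_posterior(s, pg) - log_partition_posterior(s, pb),
               lbf_quad, tolerance = 1e-6)
  # enumerating one-good-block/one-bad-block partitions of |F| = 3 and
  # normalizing gives a distribution
  splits <- list(list(1L, 2:3), list(2L, c(1L, 3L)), list(3L, 1:2),
                 list(1:2, 3L), list(c(1L, 3L), 2L), list(2:3, 1L))
  lp <- vapply(splits, function(sp)
    log_partition_posterior(s, feature_partition(list(sp[[1]]),
                                                 list(sp[[2]]), 3)),
    numeric(1))
  post <- exp(lp - max(lp)); post <- post / sum(post)
  expect_equal(sum(post), 1)
  expect_error(feature_partition(list(1:2), list(2:3), 3), "overlap")
  expect_error(feature_partition(list(1L), list(3L), 3), "cover")
})
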