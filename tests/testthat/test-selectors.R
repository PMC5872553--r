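test_that("CMNC-OBF posteriors behave like posterior probabilities", {
  set.seed(20)
  s <- one_marker_sample(40, 12, delta = 3)
  res <- cmnc_obf(s, D = 3)
  expect_length(res$selected, 3)
  expect_true(all(res$scores > 0 & res$scores < 1))
  expect_equal(res$selected[1], "f1")   # the planted marker dominates
  # ranking is invariant to the good-feature prior probability
  r3 <- cmnc_obf(s, D = 12, p_good = 0.3)
  r7 <- cmnc_obf(s, D = 12, p_good = 0.7)
  expect_identical(r3$selected, r7$selected)
  expect_true(all(r7$scores >= r3$scores))  # monotone in prior odds
  expect_error(cmnc_obf(s, D = 20), "exceeds")
  expect_error(cmnc_obf(s, D = 2, p_good = 1.2), "p_good")
})

test_that("CMNC-OBF recovery improves with sample size", {
  set.seed(21)
  found <- sapply(c(10, 100), function(n) {
    mean(replicate(50, {
      X0 <- matrix(rnorm(n / 2 * 30), n / 2, 30)
      X1 <- matrix(rnorm(n / 2 * 30), n / 2, 30)
      X1[, 1:5] <- X1[, 1:5] + 1
      s <- make_sample(X0, X1)
      sum(cmnc_obf(s, D = 5)$selected %in% paste0("f", 1:5))
    }))
  })
  expect_gt(found[2], found[1])
})

test_that("2MNC-Robust ranks by normalized pair marginals", {
  set.seed(22)
  s2 <- null_sample(20, 2)
  r <- two_mnc_robust(s2, D = 2)
  expect_equal(unname(r$scores), c(1, 1), tolerance = 1e-12)

  # brute-force reference ranking on |F| = 10
  s <- one_marker_sample(30, 10, delta = 2)
  H <- pairwise_logH(s)
  m <- max(H, na.rm = TRUE)
  P <- exp(H - m); diag(P) <- 0
  marg <- rowSums(P) / (sum(P) / 2)
  ref_order <- s$feature_ids[order(-marg, seq_along(marg))]
  r <- two_mnc_robust(s, D = 10)
  expect_identical(r$selected, ref_order)
  expect_equal(unname(r$scores), unname(marg), tolerance = 1e-9)

  # permutation equivariance of the selection
  perm <- sample(10)
  sp <- labeled_sample(s$X[, perm], s$y,
                       feature_ids = s$feature_ids[perm])
  rp <- two_mnc_robust(sp, D = 4)
  expect_identical(rp$selected, two_mnc_robust(s, D = 4)$selected)
})

test_that("MAIN stops on unreachable thresholds", {
  set.seed(23)
  s <- null_sample(20, 8)
  # T1 = 1: marginals over >= 3 working features cannot exceed 1
  r <- main_subroutine(s, F_t = s$feature_ids, T1 = 1, T2 = s$n)
  expect_length(r$selected, 0)
  # T2 = +Inf: the pair-score floor fires immediately
  r2 <- main_subroutine(s, F_t = s$feature_ids, T1 = 0.01, T2 = Inf)
  expect_length(r2$selected, 0)
  expect_match(r2$trace[[1]]$stop, "T2")
  # fewer than two working features: empty
  expect_length(main_subroutine(s, F_t = "f1", T1 = 0.1)$selected, 0)
})

test_that("MAIN captures a correlated strong pair in its first iteration", {
  set.seed(24)
  hits <- replicate(100, {
    s <- block_sample(40, 2, 0.95, 48, shift = c(2, 1))
    r <- main_subroutine(s, F_t = s$feature_ids, T1 = 0.3, T2 = s$n)
    all(c("f1", "f2") %in% r$selected[r$config$iteration == 1])
  })
  expect_gte(mean(hits), 0.9)
})

test_that("REMAIN recovers independent blocks, the weaker one via later calls", {
  set.seed(25)
  res <- replicate(100, {
    # two independent marker blocks, the second weaker
    n <- 60
    R <- equicorr_chol(3, 0.9)
    X <- cbind(matrix(rnorm(n * 3), n, 3) %*% R,
               matrix(rnorm(n * 3), n, 3) %*% R,
               matrix(rnorm(n * 114), n, 114))
    rows1 <- (n / 2 + 1):n
    X[rows1, 1:3] <- sweep(X[rows1, 1:3], 2, c(2, 1.5, 1), "+")
    X[rows1, 4:6] <- sweep(X[rows1, 4:6], 2, c(1.2, 0.9, 0.6), "+")
    s <- labeled_sample(X, rep(c(0L, 1L), each = n / 2))
    r <- remain(s, T1 = 0.3, T2 = "auto")
    calls2 <- r$config$call[match(paste0("f", 4:6), r$selected)]
    c(strong = all(paste0("f", 1:3) %in% r$selected),
      weak_n = sum(!is.na(calls2)),
      weak_later = any(calls2 > 1, na.rm = TRUE))
  })
  # the strong block is always recovered
  expect_gte(mean(res["strong", ]), 0.99)
  # the weaker independent block is partially recovered on average ...
  expect_gte(mean(res["weak_n", ]), 1.5)
  # ... and in a substantial share of runs only by MAIN calls after the
  # strong block was removed from the working set
  expect_gte(mean(res["weak_later", ]), 0.25)
})

test_that("REMAIN false selections on null data stay O(1) in high dimension", {
  set.seed(26)
  counts <- replicate(60, {
    s <- null_sample(100, 500)
    length(remain(s, T1 = 0.3)$selected)
  })
  # spurious selections are limited to the best few random pairs; they do
  # not scale with the 500-feature working set
  expect_lte(max(counts), 10)
  expect_lte(mean(counts), 3)
  expect_lte(median(counts), 2)
})

test_that("REMAIN output size is nonincreasing in T1 on a fixed dataset", {
  set.seed(27)
  ds <- simulate_microarray_dataset(
    microarray_config(n_features = 150, n_gm = 10, n_hm = 20, n_hv = 50,
                      k = 5), n = 40)
  e <- score_engine(ds$sample)
  sizes <- vapply(c(0.3, 0.2, 0.1, 0.05, 0.01),
                  function(T1) length(remain(ds$sample, T1 = T1,
                                             engine = e)$selected),
                  numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("POFAC matches the explicit posterior-factor ranking", {
  set.seed(28)
  s <- one_marker_sample(30, 15, delta = 2)
  beta <- posterior_factor(s)
  ref <- s$feature_ids[order(-beta, seq_along(beta))]
  r <- pofac(s, D = 15)
  expect_identical(r$selected, ref)
  expect_identical(pofac(s, D = 1)$selected,
                   s$feature_ids[which.max(beta)])
})

test_that("the block-merge criterion C1 behaves as an evidence of dependence", {
  set.seed(29)
  s <- null_sample(40, 6)
  # prior odds of 1 contribute exactly zero
  expect_equal(log_C1(s, 1, 2, prior_odds = 1) -
                 log_C1(s, 1, 2, prior_odds = exp(1)), -1)
  # symmetric in its arguments
  expect_equal(log_C1(s, c(1, 3), c(2, 5)), log_C1(s, c(2, 5), c(1, 3)),
               tolerance = 1e-10)
  expect_error(log_C1(s, 1, 1), "disjoint")

  # dependence raises C1: correlated pairs vs independent pairs
  set.seed(30)
  c1 <- function(rho) replicate(100, {
    Z <- matrix(rnorm(200), 100, 2)
    if (rho > 0) Z[, 2] <- rho * Z[, 1] + sqrt(1 - rho^2) * Z[, 2]
    s <- labeled_sample(Z, rep(0:1, each = 50))
    log_C1(s, 1, 2)
  })
  expect_gt(mean(c1(0.9)), mean(c1(0)))
})

test_that("GSG grows exactly the planted block and audits its threshold", {
  set.seed(31)
  s <- block_sample(100, 5, 0.95, 20)
  U <- gsg(s, seed_feature = "f2", t1 = 100, t2 = 0.5)
  expect_setequal(as.character(U), paste0("f", 1:5))
  tr <- attr(U, "trace")
  n <- 100
  for (i in seq_along(tr))
    expect_equal(tr[[i]]$log_T3, log(100) + 0.5 * tr[[i]]$size * log(n))
  # an infinite t1 never admits a candidate
  U0 <- gsg(s, seed_feature = "f1", t1 = Inf, t2 = 1)
  expect_identical(as.character(U0), "f1")
  # growth stops before the Jeffreys identifiability limit
  set.seed(32)
  sbig <- block_sample(8, 3, 0.9, 2)
  expect_warning(gsg(sbig, "f1", t1 = 1e-12, t2 = 0.01),
                 "not identifiable")
})

test_that("SPM partitions its selection into disjoint blocks", {
  set.seed(33)
  ds <- simulate_microarray_dataset(
    microarray_config(n_features = 150, n_gm = 10, n_hm = 20, n_hv = 50,
                      k = 5), n = 60)
  r <- spm(ds$sample, t1 = 100, t2 = 2, T4 = 1e4)
  expect_gt(length(r$blocks), 0)
  all_members <- unlist(r$blocks)
  expect_identical(sort(all_members), sort(unique(all_members)))
  expect_setequal(r$selected, all_members)
  # T4 = +Inf terminates immediately
  expect_length(spm(ds$sample, t1 = 100, t2 = 2, T4 = Inf)$selected, 0)
})

test_that("selectors are equivariant under feature permutation", {
  set.seed(34)
  ds <- simulate_microarray_dataset(
    microarray_config(n_features = 100, n_gm = 10, n_hm = 10, n_hv = 30,
                      k = 5), n = 40)
  s <- ds$sample
  perm <- sample(100)
  sp <- labeled_sample(s$X[, perm], s$y, feature_ids = s$feature_ids[perm])
  expect_identical(cmnc_obf(sp, D = 10)$selected,
                   cmnc_obf(s, D = 10)$selected)
  expect_identical(pofac(sp, D = 10)$selected, pofac(s, D = 10)$selected)
  expect_setequal(remain(sp, T1 = 0.1)$selected,
                  remain(s, T1 = 0.1)$selected)
  expect_setequal(spm(sp, t1 = 100, t2 = 2, T4 = 1e4)$selected,
                  spm(s, t1 = 100, t2 = 2, T4 = 1e4)$selected)
})
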