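test_that("NIW parameter draws match their prior moments", {
  pr <- make_prior(niw_prior_spec("proper", scale = 0.5, kappa_offset = 2,
                                  mean = 0, nu = 4), 2)
  set.seed(40)
  draws <- replicate(5000, sample_block_params(pr)$cov)
  # E(Sigma) = S / (kappa - d - 1) = 0.5 I; check within 3 SE per entry
  m11 <- mean(draws[1, 1, ]); se11 <- sd(draws[1, 1, ]) / sqrt(5000)
  m12 <- mean(draws[1, 2, ]); se12 <- sd(draws[1, 2, ]) / sqrt(5000)
  expect_lt(abs(m11 - 0.5), 3 * se11)
  expect_lt(abs(m12 - 0), 3 * se12)
  # every draw positive-definite
  expect_true(all(apply(draws[, , 1:100], 3,
                        function(S) all(eigen(S)$values > 0))))
  # mean draws concentrate around m as nu grows
  set.seed(41)
  mu4 <- replicate(2000, sample_block_params(pr)$mean[1])
  pr400 <- make_prior(niw_prior_spec("proper", nu = 400), 2)
  mu400 <- replicate(2000, sample_block_params(pr400)$mean[1])
  expect_lt(var(mu400), var(mu4))
  expect_error(sample_block_params(make_prior("jeffreys", 2)), "proper")
})

test_that("the NIW block simulator reproduces its declared structure", {
  ds <- simulate_bayesian_dataset(n = 20, seed = 42)
  expect_equal(dim(ds$sample$X), c(20, 4100))
  expect_equal(sum(ds$truth), 100)
  expect_equal(ds$sample$n0, 10)
  expect_equal(ds$sample$n1, 10)
  expect_equal(length(ds$partition$good_blocks), 4)
  expect_equal(length(ds$partition$bad_blocks), 120)
  expect_setequal(lengths(ds$partition$good_blocks), c(10, 20, 30, 40))
  # truth agrees with the partition
  expect_setequal(which(ds$truth), unlist(ds$partition$good_blocks))
  # seeded reproducibility is bit-exact
  ds2 <- simulate_bayesian_dataset(n = 20, seed = 42)
  expect_identical(ds$sample$X, ds2$sample$X)
  expect_error(simulate_bayesian_dataset(n = 15), "even")
  expect_error(simulate_bayesian_dataset(n = 10, prior = "jeffreys"),
               "proper")
})

test_that("features in different blocks are independent", {
  small <- block_structure(good_sizes = c(5, 10), bad_sizes = rep(c(5, 10), 5))
  ds <- simulate_bayesian_dataset(small, n = 200, seed = 43)
  blocks <- c(ds$partition$good_blocks, ds$partition$bad_blocks)
  block_of <- integer(ds$partition$n_features)
  for (i in seq_along(blocks)) block_of[blocks[[i]]] <- i
  X0 <- ds$sample$X[ds$sample$y == 0, ]
  set.seed(44)
  pairs <- matrix(sample(ncol(X0), 4000, replace = TRUE), ncol = 2)
  pairs <- pairs[block_of[pairs[, 1]] != block_of[pairs[, 2]], ][1:1000, ]
  r <- vapply(seq_len(nrow(pairs)),
              function(i) cor(X0[, pairs[i, 1]], X0[, pairs[i, 2]]),
              numeric(1))
  expect_lt(mean(abs(r)), 3 / sqrt(nrow(X0)))
})

test_that("the microarray model produces its declared feature roles", {
  cfg <- microarray_config()
  ds <- simulate_microarray_dataset(cfg, n = 20, seed = 45)
  expect_equal(length(ds$truth), 5000)
  expect_equal(sum(ds$truth), 100)
  expect_equal(sum(!ds$truth), 4900)
  types <- vapply(ds$blocks, `[[`, character(1), "type")
  expect_equal(sum(types == "GM"), 4)
  expect_equal(sum(types == "HM"), 16)
  expect_equal(sum(types == "LV"), 580)
  ds2 <- simulate_microarray_dataset(cfg, n = 20, seed = 45)
  expect_identical(ds$sample$X, ds2$sample$X)
  expect_error(simulate_microarray_dataset(cfg, n = 21), "even")
  expect_error(simulate_microarray_dataset(cfg, n = 22), "divisible")
  expect_error(microarray_config(n_features = 101, n_gm = 20, n_hm = 80,
                                 n_hv = 0, k = 5), "divide")
})

test_that("marker block means follow the configured mean type", {
  n <- 1000
  for (mt in c("redundant", "synergetic", "marginal")) {
    cfg <- microarray_config(n_features = 40, n_gm = 20, n_hm = 0,
                             n_hv = 10, k = 5, mean_type = mt)
    ds <- simulate_microarray_dataset(cfg, n = n, seed = 46)
    mu_expect <- switch(mt, redundant = rep(1, 5),
                        synergetic = 1 / (1:5),
                        marginal = c(1, rep(0, 4)))
    gm <- ds$blocks[[1]]
    # block columns are stored in generation order: position i carries mu1[i]
    X1 <- ds$sample$X[ds$sample$y == 1, gm$cols]
    se <- apply(X1, 2, sd) / sqrt(n / 2)
    expect_true(all(abs(colMeans(X1) - mu_expect) < 3 * se))
  }
})

test_that("heterogeneous markers shift only their subclass", {
  cfg <- microarray_config(n_features = 60, n_gm = 0, n_hm = 40, n_hv = 10,
                           k = 5, c_subclasses = 2, mean_type = "redundant",
                           rho0 = 0.5, rho1 = 0.5)
  ds <- simulate_microarray_dataset(cfg, n = 400, seed = 47)
  hm <- ds$blocks[[1]]
  X1 <- ds$sample$X[ds$sample$y == 1, hm$cols]
  n1 <- 200
  sub <- rep(1:2, each = n1 / 2)
  hot <- colMeans(X1[sub == hm$subclass, ])
  cold <- colMeans(X1[sub != hm$subclass, ])
  expect_true(all(hot > 0.5))    # shifted toward mu1 = 1
  expect_true(all(abs(cold) < 0.5))
})

test_that("HV non-markers are over-dispersed mixtures", {
  cfg <- microarray_config(n_features = 2100, n_gm = 20, n_hm = 80,
                           n_hv = 2000, k = 5)
  ds <- simulate_microarray_dataset(cfg, n = 100, seed = 48)
  hv_cols <- ds$blocks[[length(ds$blocks)]]$cols
  v <- apply(ds$sample$X[, hv_cols], 2, var)
  # the two-component mixture inflates the variance beyond sigma0 on average
  expect_gt(mean(v), 0.25)
})

test_that("within-block correlations concentrate near rho", {
  cfg <- microarray_config(n_features = 40, n_gm = 20, n_hm = 0, n_hv = 0,
                           k = 5, rho0 = 0.9, rho1 = 0.9)
  ds <- simulate_microarray_dataset(cfg, n = 400, seed = 49)
  X0 <- ds$sample$X[ds$sample$y == 0, ]
  blk <- ds$blocks[[1]]$cols
  cors <- cor(X0[, blk])[upper.tri(diag(5))]
  expect_true(all(abs(cors - 0.9) < 3 / sqrt(200)))
  other <- ds$blocks[[2]]$cols
  cross <- cor(X0[, blk], X0[, other])
  expect_lt(mean(abs(cross)), 3 / sqrt(200))
})
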