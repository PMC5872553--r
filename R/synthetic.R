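#' Block structure for the NIW block-model simulator
#'
#' Describes how many good and bad blocks of which sizes make up the feature
#' set. The defaults are the reference configuration of the simulation
#' study: one good block of each size 10, 20, 30, 40 (100 good features) and
#' twenty bad blocks of each size 5, 10, 15, 20, 50, 100, for 4100 features
#' in total.
#'
#' @param good_sizes Integer vector of good block sizes.
#' @param bad_sizes Integer vector of bad block sizes.
#' @return An object of class `block_structure`.
#' @export
block_structure <- function(good_sizes = c(10L, 20L, 30L, 40L),
                            bad_sizes = rep(c(5L, 10L, 15L, 20L, 50L, 100L),
                                            each = 20L)) {
  good_sizes <- as.integer(good_sizes); bad_sizes <- as.integer(bad_sizes)
  if (any(c(good_sizes, bad_sizes) < 1L)) stop("block sizes must be >= 1")
  structure(list(good_sizes = good_sizes, bad_sizes = bad_sizes,
                 n_features = sum(good_sizes) + sum(bad_sizes)),
            class = "block_structure")
}

#' Draw Gaussian block parameters from an NIW prior
#'
#' Draws \eqn{\Sigma \sim} Inverse-Wishart\eqn{(S, \kappa)} (via
#' [stats::rWishart()] on the precision) and \eqn{\mu | \Sigma \sim
#' N(m, \Sigma/\nu)}. Requires a proper prior; a finite prior mean of
#' \eqn{\Sigma} additionally needs \eqn{\kappa > d + 1}, under which
#' \eqn{E(\Sigma) = S / (\kappa - d - 1)}.
#'
#' @param prior A `niw_params` from [make_prior()]; must be proper.
#' @return List with elements `mean` (length-d vector) and `cov`
#'   (d x d symmetric positive-definite matrix). Uses the R RNG.
#' @export
sample_block_params <- function(prior) {
  if (!inherits(prior, "niw_params")) stop("`prior` must be a niw_params")
  d <- prior$dim
  if (prior$nu <= 0 || prior$kappa <= d - 1 ||
      inherits(try(chol(prior$S), silent = TRUE), "try-error"))
    stop("sampling block parameters requires a proper NIW prior ",
         "(S positive-definite, kappa > dim - 1, nu > 0)")
  W <- rWishart(1L, df = prior$kappa, Sigma = chol2inv(chol(prior$S)))[, , 1L]
  Sigma <- chol2inv(chol(W))
  Sigma <- (Sigma + t(Sigma)) / 2
  mu <- prior$m + drop(rnorm(d) %*% chol(Sigma / prior$nu))
  list(mean = mu, cov = Sigma)
}

# n x d Gaussian draws with given mean vector and upper Cholesky factor
.rmvn_chol <- function(n, mean, R) {
  d <- ncol(R)
  Z <- matrix(rnorm(n * d), n, d) %*% R
  sweep(Z, 2L, mean, "+")
}

#' Simulate from the NIW block model
#'
#' The hierarchical generator the Bayesian selectors are calibrated against:
#' features are randomly permuted into the blocks of `structure`; each good
#' block draws class-0 and class-1 parameters independently from the NIW
#' prior, each bad block draws a single set of parameters; a stratified
#' sample of size `n` (n/2 per class) is drawn with blocks mutually
#' independent and features within a block jointly Gaussian.
#'
#' @param structure A [block_structure()].
#' @param n Total sample size (even; n/2 per class).
#' @param prior A [niw_prior_spec()] (proper) used for every block; the
#'   default is the reference configuration `S = 0.5 I`, `kappa = |A| + 2`,
#'   `m = 0`, `nu = 4`.
#' @param seed Optional integer seed (sets the R RNG).
#' @return An object of class `simulated_dataset`: list with `sample` (a
#'   [labeled_sample()]), `truth` (named logical, `TRUE` = good/marker),
#'   `partition` (the generating [feature_partition()]), and `params`.
#' @export
simulate_bayesian_dataset <- function(structure = block_structure(), n,
                                      prior = niw_prior_spec("proper"),
                                      seed = NULL) {
  if (!inherits(structure, "block_structure"))
    stop("`structure` must be a block_structure")
  if (n %% 2L != 0L) stop("`n` must be even (stratified sampling)")
  if (!is.null(seed)) set.seed(seed)
  spec <- .as_prior_spec(prior)
  if (spec$kind != "proper") stop("the block-model simulator needs a proper prior")
  p <- structure$n_features
  n_half <- n %/% 2L
  y <- rep(c(0L, 1L), each = n_half)
  X <- matrix(0, n, p)
  perm <- sample.int(p)   # random feature-to-block assignment
  pos <- 0L
  good_blocks <- list(); bad_blocks <- list()
  for (sz in structure$good_sizes) {
    cols <- perm[pos + seq_len(sz)]; pos <- pos + sz
    pr <- make_prior(spec, sz)
    for (cls in 0:1) {
      par <- sample_block_params(pr)
      X[y == cls, cols] <- .rmvn_chol(n_half, par$mean, chol(par$cov))
    }
    good_blocks[[length(good_blocks) + 1L]] <- sort(cols)
  }
  for (sz in structure$bad_sizes) {
    cols <- perm[pos + seq_len(sz)]; pos <- pos + sz
    par <- sample_block_params(make_prior(spec, sz))
    X[, cols] <- .rmvn_chol(n, par$mean, chol(par$cov))
    bad_blocks[[length(bad_blocks) + 1L]] <- sort(cols)
  }
  ids <- paste0("f", seq_len(p))
  truth <- rep(FALSE, p)
  truth[unlist(good_blocks)] <- TRUE
  names(truth) <- ids
  # NB: the `structure` argument shadows base::structure here
  out <- list(sample = labeled_sample(X, y, ids), truth = truth,
              partition = feature_partition(good_blocks, bad_blocks, p),
              params = list(model = "bayesian", n = n, prior = spec))
  class(out) <- "simulated_dataset"
  out
}

#' Configuration of the synthetic microarray model
#'
#' The two-class expression model with four feature roles. Global markers
#' (GM) shift all class-1 samples; heterogeneous markers (HM) shift only one
#' of `c_subclasses` equal subgroups of the class-1 samples. Markers and
#' low-variance (LV) non-markers form blocks of `k` equicorrelated features
#' (correlation `rho0` in the class-0/null law, `rho1` in the class-1
#' marker law); high-variance (HV) non-markers are independent two-component
#' Gaussian mixtures. `sigma0`, `sigma1` are the per-feature variances of
#' the two laws (defaults 0.25 and 0.64, the "large and unequal variance"
#' setting), and the class-1 marker block mean is `[1, ..., 1]`
#' (`"redundant"`), `[1, 1/2, ..., 1/k]` (`"synergetic"`) or
#' `[1, 0, ..., 0]` (`"marginal"`). Defaults are the reference study
#' conditions: 5000 features with 20 GM + 80 HM markers, 2000 HV, blocks of
#' `k = 5` with `rho0 = rho1 = 0.9`, synergetic means.
#'
#' @param n_features,n_gm,n_hm,n_hv Feature counts (LV count is the
#'   remainder).
#' @param c_subclasses Number of heterogeneous subclasses within class 1.
#' @param k Block size; must divide `n_gm`, `n_hm` and the LV count.
#' @param rho0,rho1 Within-block correlations of the two laws.
#' @param sigma0,sigma1 Per-feature variances of the two laws.
#' @param mean_type `"redundant"`, `"synergetic"` or `"marginal"`.
#' @return An object of class `microarray_config`.
#' @export
microarray_config <- function(n_features = 5000L, n_gm = 20L, n_hm = 80L,
                              n_hv = 2000L, c_subclasses = 2L, k = 5L,
                              rho0 = 0.9, rho1 = 0.9, sigma0 = 0.25,
                              sigma1 = 0.64,
                              mean_type = c("synergetic", "redundant",
                                            "marginal")) {
  mean_type <- match.arg(mean_type)
  n_lv <- n_features - n_gm - n_hm - n_hv
  if (n_lv < 0L) stop("n_gm + n_hm + n_hv exceeds n_features")
  if (n_gm %% k || n_hm %% k || n_lv %% k)
    stop("`k` must divide the GM (", n_gm, "), HM (", n_hm, ") and LV (",
         n_lv, ") feature counts")
  if (abs(rho0) >= 1 || abs(rho1) >= 1) stop("correlations must be in (-1, 1)")
  if (sigma0 <= 0 || sigma1 <= 0) stop("variances must be positive")
  structure(list(n_features = as.integer(n_features), n_gm = as.integer(n_gm),
                 n_hm = as.integer(n_hm), n_hv = as.integer(n_hv),
                 n_lv = as.integer(n_lv),
                 c_subclasses = as.integer(c_subclasses), k = as.integer(k),
                 rho0 = rho0, rho1 = rho1, sigma0 = sigma0, sigma1 = sigma1,
                 mean_type = mean_type),
            class = "microarray_config")
}

.class1_block_mean <- function(mean_type, k) {
  switch(mean_type,
         redundant = rep(1, k),
         synergetic = 1 / seq_len(k),
         marginal = c(1, rep(0, k - 1L)))
}

#' Simulate from the synthetic microarray model
#'
#' Generates a stratified two-class sample (n/2 per class) under the model
#' described in [microarray_config()]. Features are assigned to blocks by a
#' uniform random permutation, so block members are scattered across
#' columns. The class-1 samples are partitioned into `c_subclasses` equal
#' groups; each HM block is assigned one subclass (round-robin) and only
#' that subclass's samples draw from the marker law. Markers (GM and HM) are
#' the ground-truth good features.
#'
#' @param config A [microarray_config()].
#' @param n Total sample size; even, with `n/2` divisible by
#'   `c_subclasses`.
#' @param seed Optional integer seed (sets the R RNG).
#' @return A `simulated_dataset` (see [simulate_bayesian_dataset()]); its
#'   `blocks` element lists the marker/LV block column sets, each in
#'   generation order (position i of a marker block carries mean `mu1[i]`
#'   in the class-1 law).
#' @export
simulate_microarray_dataset <- function(config = microarray_config(), n,
                                        seed = NULL) {
  if (!inherits(config, "microarray_config"))
    stop("`config` must be a microarray_config")
  if (n %% 2L != 0L) stop("`n` must be even (stratified sampling)")
  n1 <- n %/% 2L
  if (n1 %% config$c_subclasses)
    stop("class-1 sample size ", n1, " must be divisible by c_subclasses = ",
         config$c_subclasses)
  if (!is.null(seed)) set.seed(seed)
  p <- config$n_features; k <- config$k
  y <- rep(c(0L, 1L), each = n1)
  rows1 <- which(y == 1L)
  subclass_of <- rep(seq_len(config$c_subclasses), each = n1 %/%
                       config$c_subclasses)
  corr <- function(rho) {
    M <- matrix(rho, k, k); diag(M) <- 1; M
  }
  R0 <- chol(config$sigma0 * corr(config$rho0))
  R1 <- chol(config$sigma1 * corr(config$rho1))
  mu1 <- .class1_block_mean(config$mean_type, k)
  perm <- sample.int(p)
  pos <- 0L
  take <- function(m) {
    cols <- perm[pos + seq_len(m)]; pos <<- pos + m; cols
  }
  X <- matrix(0, n, p)
  blocks <- list()
  n_gm_b <- config$n_gm %/% k; n_hm_b <- config$n_hm %/% k
  n_lv_b <- config$n_lv %/% k
  gm_cols <- hm_cols <- integer(0)
  for (b in seq_len(n_gm_b)) {
    cols <- take(k)
    X[y == 0L, cols] <- .rmvn_chol(n1, rep(0, k), R0)
    X[rows1, cols] <- .rmvn_chol(n1, mu1, R1)
    gm_cols <- c(gm_cols, cols)
    blocks[[length(blocks) + 1L]] <- list(type = "GM", cols = cols)
  }
  for (b in seq_len(n_hm_b)) {
    cols <- take(k)
    sub <- ((b - 1L) %% config$c_subclasses) + 1L
    hot <- rows1[subclass_of == sub]
    cold <- rows1[subclass_of != sub]
    X[y == 0L, cols] <- .rmvn_chol(n1, rep(0, k), R0)
    X[hot, cols] <- .rmvn_chol(length(hot), mu1, R1)
    if (length(cold))
      X[cold, cols] <- .rmvn_chol(length(cold), rep(0, k), R0)
    hm_cols <- c(hm_cols, cols)
    blocks[[length(blocks) + 1L]] <- list(type = "HM", subclass = sub,
                                          cols = cols)
  }
  for (b in seq_len(n_lv_b)) {
    cols <- take(k)
    X[, cols] <- .rmvn_chol(n, rep(0, k), R0)
    blocks[[length(blocks) + 1L]] <- list(type = "LV", cols = cols)
  }
  hv_cols <- take(config$n_hv)
  if (length(hv_cols)) {
    # per-feature mixture weight, component drawn i.i.d. per sample
    pmix <- runif(length(hv_cols))
    comp <- matrix(rbinom(n * length(hv_cols), 1L, rep(1 - pmix, each = n)),
                   n, length(hv_cols))
    X[, hv_cols] <- (1 - comp) * rnorm(n * length(hv_cols), 0,
                                       sqrt(config$sigma0)) +
      comp * rnorm(n * length(hv_cols), 1, sqrt(config$sigma1))
    blocks[[length(blocks) + 1L]] <- list(type = "HV", cols = sort(hv_cols),
                                          p_mix = pmix)
  }
  ids <- paste0("f", seq_len(p))
  truth <- rep(FALSE, p)
  truth[c(gm_cols, hm_cols)] <- TRUE
  names(truth) <- ids
  structure(list(sample = labeled_sample(X, y, ids), truth = truth,
                 blocks = blocks,
                 params = list(model = "microarray", n = n, config = config)),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated_dataset (%s model): %d x %d, %d marker(s)\n",
              x$params$model, x$sample$n, length(x$truth), sum(x$truth)))
  invisible(x)
}
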