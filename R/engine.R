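#' Precomputed scoring engine for a labeled sample
#'
#' Builds, once, everything the vectorized scores and selectors need: the
#' class-wise and pooled centered cross-product (scatter) matrices, the
#' mean-offset vectors entering the NIW rank-one update, and the per-dimension
#' posterior degrees of freedom. Singleton and pairwise log-H tables and the
#' posterior factor are computed lazily and cached, so several selectors run
#' on the same dataset share one O(p^2) computation. Memory is O(p^2) doubles
#' per cached matrix.
#'
#' All user-facing functions build an engine automatically; pass one
#' explicitly (argument `engine`) when running several selectors on the same
#' data.
#'
#' @param sample A [labeled_sample()].
#' @param prior A [niw_prior_spec()] (or `"jeffreys"`/`"proper"`).
#' @param features Optional subset of feature ids/indices forming the working
#'   set (default: all features).
#' @return An environment of class `score_engine`.
#' @export
score_engine <- function(sample, prior = niw_prior_spec("jeffreys"),
                         features = NULL) {
  spec <- .as_prior_spec(prior)
  idx <- .resolve_features(sample, features)
  e <- new.env(parent = emptyenv())
  e$sample <- sample
  e$spec <- spec
  e$idx <- idx
  e$ids <- sample$feature_ids[idx]
  e$p <- length(idx)
  e$n0 <- sample$n0; e$n1 <- sample$n1; e$n <- sample$n

  X <- sample$X[, idx, drop = FALSE]
  X0 <- X[sample$y == 0L, , drop = FALSE]
  X1 <- X[sample$y == 1L, , drop = FALSE]
  mu0 <- colMeans(X0); mu1 <- colMeans(X1); mup <- colMeans(X)
  e$C0 <- scatter_kernel(sweep(X0, 2L, mu0, "-"))
  e$C1 <- scatter_kernel(sweep(X1, 2L, mu1, "-"))
  e$Cp <- scatter_kernel(sweep(X, 2L, mup, "-"))
  if (spec$kind == "proper") {
    e$u0 <- mu0 - spec$mean; e$u1 <- mu1 - spec$mean; e$up <- mup - spec$mean
    e$w0 <- spec$nu * e$n0 / (spec$nu + e$n0)
    e$w1 <- spec$nu * e$n1 / (spec$nu + e$n1)
    e$wp <- spec$nu * e$n / (spec$nu + e$n)
    e$s <- spec$scale
  } else {
    e$u0 <- e$u1 <- e$up <- numeric(e$p)
    e$w0 <- e$w1 <- e$wp <- 0
    e$s <- 0
  }
  # posterior degrees of freedom kappa*(d) for a block of dimension d
  e$kappa0 <- function(d) .kappa_dim(spec, d) + e$n0
  e$kappa1 <- function(d) .kappa_dim(spec, d) + e$n1
  e$kappap <- function(d) .kappa_dim(spec, d) + e$n
  class(e) <- "score_engine"
  e
}

.kappa_dim <- function(spec, d) {
  if (spec$kind == "jeffreys") 0 else d + spec$kappa_offset
}

#' @export
print.score_engine <- function(x, ...) {
  cat(sprintf("score_engine: %d features, n = %d (%s prior)%s\n", x$p, x$n,
              x$spec$kind,
              if (!is.null(x$logH2)) ", pairwise table cached" else ""))
  invisible(x)
}

.engine_for <- function(sample, prior, features, engine) {
  if (!is.null(engine)) {
    if (!inherits(engine, "score_engine")) stop("`engine` must be a score_engine")
    return(engine)
  }
  score_engine(sample, prior, features)
}

# adjusted per-class diagonal entries (1x1 posterior scatters); errors name
# the first degenerate feature
.engine_diag <- function(e, group = c("c0", "c1", "pool")) {
  group <- match.arg(group)
  key <- paste0("diag_", group)
  if (!is.null(e[[key]])) return(e[[key]])
  v <- switch(group,
    c0 = diag(e$C0) + e$w0 * (e$u0 * e$u0) + e$s,
    c1 = diag(e$C1) + e$w1 * (e$u1 * e$u1) + e$s,
    pool = diag(e$Cp) + e$wp * (e$up * e$up) + e$s)
  e[[key]] <- v
  v
}

.engine_check_singletons <- function(e) {
  if (e$spec$kind == "jeffreys" && min(e$n0, e$n1) < 2L)
    stop("Jeffreys prior requires at least 2 samples per class for ",
         "singleton scores")
  for (group in c("c0", "c1", "pool")) {
    v <- .engine_diag(e, group)
    if (any(v <= 0))
      stop("rank-deficient singleton scatter (zero variance) for feature ",
           e$ids[which(v <= 0)[1L]], " (", group, ")")
  }
}

.engine_logH1 <- function(e) {
  if (!is.null(e$logH1)) return(e$logH1)
  .engine_check_singletons(e)
  a0 <- .engine_diag(e, "c0"); a1 <- .engine_diag(e, "c1")
  ap <- .engine_diag(e, "pool")
  v <- -0.5 * (e$kappa0(1) * log(a0) + e$kappa1(1) * log(a1) -
                 e$kappap(1) * log(ap))
  names(v) <- e$ids
  e$logH1 <- v
  v
}

# one fused pass computes the pairwise log-H upper triangle, the full-set
# row log-sum-exp state, and the per-row top-k partner lists
.engine_tables <- function(e) {
  if (!is.null(e$logH2)) return(invisible(e))
  if (e$spec$kind == "jeffreys" && min(e$n0, e$n1) < 3L)
    stop("Jeffreys prior requires at least 3 samples per class for ",
         "pairwise scores")
  tab <- pair_tables_kernel(e$C0, e$C1, e$Cp, e$u0, e$u1, e$up,
                            e$w0, e$w1, e$wp, e$s,
                            e$kappa0(2), e$kappa1(2), e$kappap(2),
                            ktop = 64L)
  H <- tab$H
  bad <- first_nan_pair(H)
  if (length(bad))
    stop("rank-deficient pairwise scatter for pair {",
         e$ids[bad[1L]], ", ", e$ids[bad[2L]], "}")
  dimnames(H) <- list(e$ids, e$ids)
  e$logH2 <- H
  e$lse_state <- list(mx = tab$mx, acc = tab$acc, s = tab$s)
  e$topk <- list(val = tab$topval, arg = tab$toparg)
  invisible(e)
}

# pairwise log-H table with only the upper triangle filled (all internal
# kernels are triangle readers); use .engine_logH2_full for a symmetric copy
.engine_logH2 <- function(e) {
  .engine_tables(e)
  e$logH2
}

.engine_logH2_full <- function(e) {
  if (!is.null(e$logH2_full)) return(e$logH2_full)
  H <- .engine_logH2(e)
  tH <- t(H)
  low <- lower.tri(H)
  H[low] <- tH[low]
  e$logH2_full <- H
  H
}

# log of the Q-constant ratio between the good (class-split) and bad
# (pooled) model for a block of dimension d: turns the bare determinant
# ratio H into a calibrated good-vs-bad Bayes factor BF(G) = H(G) * exp(dq)
.engine_delta_q <- function(e, d) {
  pr <- make_prior(e$spec, d)
  (.log_Q(pr, e$n0) + .log_Q(pr, e$n1)) - .log_Q(pr, e$n)
}

.engine_beta <- function(e) {
  if (!is.null(e$beta)) return(e$beta)
  h1 <- .engine_logH1(e)
  H <- .engine_logH2(e)
  if (e$p < 2L) stop("posterior factor needs at least 2 features")
  # beta(f) = mean_g BF({f,g}) / BF({g}); the pair/singleton Q constants do
  # not cancel across set sizes and put beta on the Bayes-factor scale the
  # T4 threshold expects (approximately 1 for a bad feature)
  shift <- .engine_delta_q(e, 2L) - .engine_delta_q(e, 1L)
  b <- beta_tilde_kernel(H, unname(h1) - shift, 700)
  if (attr(b, "capped") > 0)
    warning("posterior factor: ", attr(b, "capped"),
            " ratio exponent(s) capped at 700 to avoid overflow")
  b <- as.numeric(b)
  names(b) <- e$ids
  e$beta <- b
  b
}

# full-working-set row log-sum-exp state (shared by 2MNC, REMAIN's first
# MAIN call, and the pair-posterior normalization)
.engine_lse_state <- function(e) {
  .engine_tables(e)
  e$lse_state
}

# per-row top-k pair partners over the full working set
.engine_topk <- function(e) {
  .engine_tables(e)
  e$topk
}

# log-sum-exp of a plain vector
.lse <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# subblock of the class-y adjusted scatter, rows `ri` x cols `ci`
# (local engine indices); diagonal adjustment applied where row == col
.engine_block <- function(e, y, ri, ci = ri) {
  C <- if (y == 0) e$C0 else e$C1
  u <- if (y == 0) e$u0 else e$u1
  w <- if (y == 0) e$w0 else e$w1
  M <- C[ri, ci, drop = FALSE] + w * (u[ri] %o% u[ci])
  same <- outer(ri, ci, "==")
  if (any(same)) M[same] <- M[same] + e$s
  M
}
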