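# Independent numerical oracles and small data builders shared by the tests.

# log marginal likelihood of a 1-D Gaussian sample under an NIW prior, by
# nested numerical integration over (mu, sigma^2). Entirely independent of
# the package's conjugate closed forms.
quad_log_evidence_1d <- function(x, kind = c("jeffreys", "proper"),
                                 scale = 0.5, kappa_offset = 2, m = 0,
                                 nu = 4) {
  kind <- match.arg(kind)
  n <- length(x)
  log_integrand <- function(mu, v) {
    ll <- sum(dnorm(x, mu, sqrt(v), log = TRUE))
    if (kind == "jeffreys") {
      # K = L = 1: pi(v) = v^-1, pi(mu | v) = v^-1/2
      ll - 1.5 * log(v)
    } else {
      kap <- 1 + kappa_offset
      logK <- 0.5 * kap * log(scale) - 0.5 * kap * log(2) - lgamma(kap / 2)
      ll + logK - 0.5 * (kap + 2) * log(v) - scale / (2 * v) +
        0.5 * (log(nu) - log(2 * pi) - log(v)) - nu * (mu - m)^2 / (2 * v)
    }
  }
  v_hat <- max(mean((x - mean(x))^2), 1e-3)
  M <- log_integrand(mean(x), v_hat)
  inner <- function(v) {
    vapply(v, function(vi) {
      stats::integrate(function(mu)
        exp(vapply(mu, log_integrand, numeric(1), v = vi) - M),
        -Inf, Inf, rel.tol = 1e-10, abs.tol = 0)$value
    }, numeric(1))
  }
  I <- stats::integrate(inner, 0, Inf, rel.tol = 1e-9, abs.tol = 0)$value
  M + log(I)
}

# multivariate gamma by the standard recursion
# Gamma_d(a) = pi^((d-1)/2) * Gamma(a) * Gamma_{d-1}(a - 1/2)
recursive_log_multigamma <- function(d, a) {
  if (d == 1L) return(lgamma(a))
  (d - 1) / 2 * log(pi) + lgamma(a) + recursive_log_multigamma(d - 1L,
                                                               a - 0.5)
}

# two-class sample with given per-class feature matrices
make_sample <- function(X0, X1, ids = NULL) {
  labeled_sample(rbind(X0, X1), rep(c(0L, 1L), c(nrow(X0), nrow(X1))),
                 feature_ids = ids)
}

# n x p standard-normal null sample, stratified
null_sample <- function(n, p) {
  make_sample(matrix(rnorm(n / 2 * p), n / 2, p),
              matrix(rnorm(n / 2 * p), n / 2, p))
}

# sample with one strong good feature (class-1 mean shift `delta`) among
# p - 1 null features
one_marker_sample <- function(n, p, delta = 2) {
  X0 <- matrix(rnorm(n / 2 * p), n / 2, p)
  X1 <- matrix(rnorm(n / 2 * p), n / 2, p)
  X1[, 1] <- X1[, 1] + delta
  make_sample(X0, X1)
}

# equicorrelated Gaussian block generator (upper Cholesky reused)
equicorr_chol <- function(k, rho, var = 1) chol(var * ((1 - rho) * diag(k) +
                                                         rho))

# sample whose first `k` features form a correlated block (same law in both
# classes), remaining features independent; optional class-1 mean shift
# (scalar or per-feature vector) on the block to make it a marker block
block_sample <- function(n, k, rho, p_null, shift = 0) {
  R <- equicorr_chol(k, rho)
  Xb <- matrix(rnorm(n * k), n, k) %*% R
  rows1 <- (n / 2 + 1):n
  Xb[rows1, ] <- sweep(Xb[rows1, , drop = FALSE], 2, rep_len(shift, k), "+")
  X <- cbind(Xb, matrix(rnorm(n * p_null), n, p_null))
  labeled_sample(X, rep(c(0L, 1L), each = n / 2))
}
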