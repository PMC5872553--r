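#' Singleton log-H scores
#'
#' Vectorized [log_H()] over 1-feature blocks: per feature, the class-split
#' versus pooled log evidence ratio computed from scalar posterior variances.
#' Agrees with the scalar implementation bit for bit.
#'
#' @inheritParams score_engine
#' @param engine Optional precomputed [score_engine()].
#' @return Named numeric vector of `log H({f})` over the working set.
#' @export
singleton_logH <- function(sample, features = NULL,
                           prior = niw_prior_spec("jeffreys"),
                           engine = NULL) {
  e <- .engine_for(sample, prior, features, engine)
  .engine_logH1(e)
}

#' Pairwise log-H scores
#'
#' Vectorized [log_H()] over all unordered feature pairs of the working set,
#' computed from class-wise and pooled cross-product matrices so the cost is
#' O(p^2) closed-form 2x2 determinant evaluations. Bit-equal to the scalar
#' implementation per pair. The diagonal is `NA` (undefined).
#'
#' @inheritParams singleton_logH
#' @return Symmetric `p x p` matrix of `log H({f, f'})` with `NA` diagonal.
#' @export
pairwise_logH <- function(sample, features = NULL,
                          prior = niw_prior_spec("jeffreys"),
                          engine = NULL) {
  e <- .engine_for(sample, prior, features, engine)
  .engine_logH2_full(e)
}

#' Score table over a working feature set
#'
#' Bundles the singleton and pairwise log-H evidences (and, after
#' [normalize_size2()], the approximate marginal posteriors) for a working
#' feature set.
#'
#' @inheritParams singleton_logH
#' @param pairwise Compute the pairwise table (default `TRUE`).
#' @return An object of class `score_table`: list with `feature_set`,
#'   `logH1`, `logH2`, and (after normalization) `marginals` and
#'   `log_normalizer`; the engine is attached for reuse.
#' @export
score_table <- function(sample, features = NULL,
                        prior = niw_prior_spec("jeffreys"),
                        pairwise = TRUE, engine = NULL) {
  e <- .engine_for(sample, prior, features, engine)
  out <- list(feature_set = e$ids,
              logH1 = .engine_logH1(e),
              logH2 = if (pairwise) .engine_logH2_full(e) else NULL,
              marginals = NULL, log_normalizer = NULL)
  attr(out, "engine") <- e
  class(out) <- "score_table"
  out
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("score_table: %d features%s%s\n", length(x$feature_set),
              if (!is.null(x$logH2)) ", pairwise" else ", singleton only",
              if (!is.null(x$marginals)) ", normalized" else ""))
  invisible(x)
}

#' Normalize pair posteriors and compute feature marginals
#'
#' Normalizes the size-2 set scores so the approximate set posteriors sum to
#' one over all pairs of the working set,
#' \eqn{\tilde\pi^*(G) = H(G) / \sum_{|G'|=2} H(G')}, and accumulates the
#' per-feature marginals \eqn{\tilde\pi^*(f) = \sum_{G \ni f}
#' \tilde\pi^*(G)}. By construction the marginals sum to 2. All sums are
#' carried out with shifted exponentials in log space.
#'
#' @param table A [score_table()] with the pairwise table present.
#' @return The table with `marginals` (named, summing to 2) and
#'   `log_normalizer` filled in.
#' @export
normalize_size2 <- function(table) {
  if (!inherits(table, "score_table")) stop("`table` must be a score_table")
  if (is.null(table$logH2)) stop("pairwise scores missing; rebuild with pairwise = TRUE")
  p <- length(table$feature_set)
  if (p < 2L) stop("need at least 2 features to normalize over pairs")
  e <- attr(table, "engine")
  s <- if (!is.null(e)) .engine_lse_state(e)$s
       else row_lse_kernel(table$logH2, seq_len(p))
  logZ <- .lse(s) - log(2)   # log sum over unordered pairs
  marg <- exp(s - logZ)
  names(marg) <- table$feature_set
  table$marginals <- marg
  table$log_normalizer <- logZ
  table
}

#' Approximate posterior factor
#'
#' A Bayes-factor-like score of each feature's contribution: the average,
#' over all other features f', of the posterior ratio of the pair to the
#' singleton,
#' \deqn{\tilde\beta(f) = \frac{1}{|F|-1} \sum_{f' \ne f}
#'   \frac{\tilde\pi^*(\{f, f'\})}{\tilde\pi^*(\{f'\})}
#'   = \frac{1}{|F|-1} \sum_{f' \ne f} \frac{H(\{f,f'\})}{H(\{f'\})},}
#' the second equality holding because the joint normalizer over sets of
#' sizes 1 and 2 and the uniform set prior cancel in the ratio. Ratios are
#' computed as exponentials of log differences with the exponent capped at
#' 700 (a warning reports capping). Large values flag features that improve
#' many models when added; values at or below 1 flag likely bad features.
#'
#' @inheritParams singleton_logH
#' @return Named vector of strictly positive posterior factors.
#' @export
posterior_factor <- function(sample, features = NULL,
                             prior = niw_prior_spec("jeffreys"),
                             engine = NULL) {
  e <- .engine_for(sample, prior, features, engine)
  .engine_beta(e)
}

#' Write a score table to disk
#'
#' Writes the per-feature scores as TSV (`<prefix>_scores.tsv` with columns
#' feature_id, logH1, marginal, beta_tilde) and, optionally, the pairwise
#' upper triangle as a MatrixMarket sparse file (`<prefix>_pairs.mtx`).
#'
#' @param table A [score_table()].
#' @param prefix Output path prefix.
#' @param pairs Also write the pairwise matrix (default `FALSE`; requires the
#'   Matrix package).
#' @return Invisibly, the paths written.
#' @export
write_score_table <- function(table, prefix, pairs = FALSE) {
  if (!inherits(table, "score_table")) stop("`table` must be a score_table")
  e <- attr(table, "engine")
  beta <- tryCatch(.engine_beta(e), error = function(err) NULL)
  df <- data.table::data.table(
    feature_id = table$feature_set,
    logH1 = as.numeric(table$logH1),
    marginal = if (is.null(table$marginals)) NA_real_
               else as.numeric(table$marginals),
    beta_tilde = if (is.null(beta)) NA_real_ else as.numeric(beta))
  scores_path <- paste0(prefix, "_scores.tsv")
  data.table::fwrite(df, scores_path, sep = "\t")
  paths <- scores_path
  if (pairs) {
    if (!requireNamespace("Matrix", quietly = TRUE))
      stop("writing the pairwise matrix requires the Matrix package")
    H <- table$logH2
    H[lower.tri(H, diag = TRUE)] <- 0
    mtx_path <- paste0(prefix, "_pairs.mtx")
    Matrix::writeMM(Matrix::Matrix(H, sparse = TRUE), mtx_path)
    paths <- c(paths, mtx_path)
  }
  invisible(paths)
}
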