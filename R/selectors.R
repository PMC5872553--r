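#' Selection results
#'
#' All selectors return a `selection_result`: the selected feature ids (in
#' rank order where the method defines one), the per-feature score used for
#' ranking, the detected blocks (SPM only), and a structured per-iteration
#' trace.
#'
#' @param method Selector name.
#' @param selected Character vector of selected feature ids, rank order.
#' @param scores Named numeric vector of the ranking score.
#' @param blocks List of character vectors (SPM), detection order.
#' @param trace List of per-iteration records.
#' @param config List echoing the thresholds used.
#' @return An object of class `selection_result`.
#' @keywords internal
selection_result <- function(method, selected, scores = NULL, blocks = NULL,
                             trace = NULL, config = list()) {
  structure(list(method = method, selected = selected, scores = scores,
                 blocks = blocks, trace = trace, config = config),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("%s: %d feature(s) selected", x$method, length(x$selected)))
  if (!is.null(x$blocks)) cat(sprintf(" in %d block(s)", length(x$blocks)))
  cat("\n")
  if (length(x$selected))
    cat("  top: ", paste(head(x$selected, 10L), collapse = ", "),
        if (length(x$selected) > 10L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# rank indices by score descending, ties by ascending index
.rank_desc <- function(score) order(-score, seq_along(score))

#' CMNC optimal Bayesian filter
#'
#' Assumes every block has size one (independent features) and that the
#' events "feature f is good" are a-priori independent with probability
#' `p_good`. The per-feature posterior is then available in closed form from
#' the singleton evidences,
#' \deqn{\pi^*(f) = \frac{p\,E_g(f)}{p\,E_g(f) + (1-p)\,E_b(f)},}
#' with \eqn{E_g, E_b} the good (class-split) and bad (pooled) marginal
#' likelihoods including their Q constants (which differ between the two
#' models and do not cancel). The top `D` features by posterior are
#' returned; the ranking does not depend on `p_good` (a monotone transform
#' of the evidence ratio).
#'
#' @inheritParams singleton_logH
#' @param D Number of features to select.
#' @param p_good Prior probability that a feature is good (default 0.5).
#' @return A `selection_result` with `scores` = posterior probabilities
#'   `pi*(f)` for all features.
#' @export
cmnc_obf <- function(sample, prior = niw_prior_spec("jeffreys"), D,
                     p_good = 0.5, engine = NULL) {
  if (p_good <= 0 || p_good >= 1) stop("`p_good` must be in (0, 1)")
  e <- .engine_for(sample, prior, NULL, engine)
  if (D > e$p) stop("D = ", D, " exceeds the number of features ", e$p)
  .engine_check_singletons(e)
  pr1 <- make_prior(e$spec, 1L)
  a0 <- .engine_diag(e, "c0"); a1 <- .engine_diag(e, "c1")
  ap <- .engine_diag(e, "pool")
  log_Eg <- (.log_Q(pr1, e$n0) + .log_Q(pr1, e$n1)) -
    0.5 * (e$kappa0(1) * log(a0) + e$kappa1(1) * log(a1))
  log_Eb <- .log_Q(pr1, e$n) - 0.5 * e$kappap(1) * log(ap)
  # the (2*pi)^(-n/2) data constants cancel in the odds
  post <- plogis(log(p_good / (1 - p_good)) + log_Eg - log_Eb)
  names(post) <- e$ids
  ord <- .rank_desc(post)
  selection_result("cmnc_obf", e$ids[ord[seq_len(D)]], scores = post,
                   config = list(D = D, p_good = p_good,
                                 prior = e$spec$kind))
}

#' 2MNC-Robust pairwise marginal ranking
#'
#' Computes the approximate set posterior over all feature pairs, normalizes
#' it over the working set, and ranks features by the marginal
#' \eqn{\tilde\pi^*(f) = \sum_{G \ni f} \tilde\pi^*(G)} (which sums to 2
#' across features). Returns the top `D` features; ties broken by ascending
#' feature index.
#'
#' @inheritParams cmnc_obf
#' @return A `selection_result` with `scores` = marginals.
#' @export
two_mnc_robust <- function(sample, prior = niw_prior_spec("jeffreys"), D,
                           engine = NULL) {
  e <- .engine_for(sample, prior, NULL, engine)
  if (D > e$p) stop("D = ", D, " exceeds the number of features ", e$p)
  s <- .engine_lse_state(e)$s
  marg <- 2 * exp(s - .lse(s))
  names(marg) <- e$ids
  ord <- .rank_desc(marg)
  selection_result("two_mnc_robust", e$ids[ord[seq_len(D)]], scores = marg,
                   config = list(D = D, prior = e$spec$kind))
}

#' POFAC posterior-factor ranking
#'
#' Ranks features by the approximate posterior factor
#' [posterior_factor()] and returns the top `D`; ties broken by ascending
#' feature index.
#'
#' @inheritParams cmnc_obf
#' @return A `selection_result` with `scores` = posterior factors.
#' @export
pofac <- function(sample, prior = niw_prior_spec("jeffreys"), D,
                  engine = NULL) {
  e <- .engine_for(sample, prior, NULL, engine)
  if (D > e$p) stop("D = ", D, " exceeds the number of features ", e$p)
  beta <- .engine_beta(e)
  ord <- .rank_desc(beta)
  selection_result("pofac", e$ids[ord[seq_len(D)]], scores = beta,
                   config = list(D = D, prior = e$spec$kind))
}

# MAIN on local engine indices. Returns list(selected = integer local idx in
# add order, iteration tags, pi values, trace). `s` (row log-sum-exp over
# Fr = F_t U G_accum) may be supplied by the caller to share work.
.main_idx <- function(e, Ft, Gacc, T1, T2, s = NULL) {
  sel_idx <- integer(0); sel_iter <- integer(0); sel_pi <- numeric(0)
  trace <- list()
  if (length(Ft) < 2L)
    return(list(selected = sel_idx, iteration = sel_iter, pi = sel_pi,
                trace = trace))
  H <- .engine_logH2(e)
  Fr <- sort(c(Ft, Gacc))
  # pair scores are computed once per MAIN call; row log-sum-exp over the
  # fixed pool Fr = F_t U G~ serves every inner iteration
  if (is.null(s))
    s <- if (length(Fr) == e$p) .engine_lse_state(e)$s
         else row_lse_kernel(H, Fr)
  # the largest pair score within F_t comes from the per-row top-k partner
  # lists (exact: the first list entry still inside F_t is the restricted
  # row maximum; exhausted rows are rescanned)
  tk <- .engine_topk(e)
  ptr <- rep(1L, e$p)
  in_Ft <- logical(nrow(H)); in_Ft[Ft] <- TRUE
  Gt <- Gacc
  iter <- 0L
  # T2 thresholds the bare pair score H(G) (determinant ratio without the
  # Q constants or the uniform set prior); T2 = n is the rule of thumb for
  # high-dimensional working sets, where marginal inflation rather than the
  # pair floor is the usual stopping mechanism
  logT2 <- log(T2)
  repeat {
    iter <- iter + 1L
    if (length(Ft) < 2L) break
    tm <- topk_max_kernel(H, tk$val, tk$arg, ptr, in_Ft, Ft)
    ptr <- tm$ptr
    mpair <- tm$max
    if (mpair <= logT2) {
      trace[[iter]] <- list(iteration = iter, stop = "all pair scores <= T2",
                            max_log_pair = mpair)
      break
    }
    pi_t <- 2 * exp(s[Ft] - .lse(s[Ft]))
    Gs <- Ft[pi_t > T1]
    trace[[iter]] <- list(iteration = iter, n_working = length(Ft),
                          n_added = length(Gs), max_log_pair = mpair,
                          max_marginal = max(pi_t))
    if (length(Gs) == 0L) break
    pis <- pi_t[pi_t > T1]
    ord <- order(-pis, Gs)  # within-iteration rank: descending marginal
    sel_idx <- c(sel_idx, Gs[ord])
    sel_iter <- c(sel_iter, rep(iter, length(Gs)))
    sel_pi <- c(sel_pi, pis[ord])
    Gt <- c(Gt, Gs)
    in_Ft[Gs] <- FALSE
    Ft <- setdiff(Ft, Gs)
  }
  list(selected = sel_idx, iteration = sel_iter, pi = sel_pi, trace = trace)
}

#' MAIN: one marginal-posterior-inflation pass
#'
#' The inner routine of [remain()]. Starting from a working set `F_t` (and an
#' optional set `G_accum` of features already labeled good), it repeatedly
#' (a) computes rescaled approximate marginals \eqn{\tilde\pi^*(f)} for
#' `f` in `F_t` from the pairwise H scores over `F_t` and the already-selected
#' features — selected features contribute to the sums but are excluded from
#' the rescaling \eqn{\sum_{f \in F_t} \tilde\pi^*(f) = 2} — and (b) moves
#' every feature with \eqn{\tilde\pi^*(f) > T_1} into the selected set. It
#' stops when no feature passes `T1`, or when every pair within `F_t` has
#' `H(G) <= T2` (comparison on the bare H scale), or fewer than two working
#' features remain.
#'
#' @inheritParams cmnc_obf
#' @param F_t Working feature ids/indices.
#' @param G_accum Already-selected feature ids/indices (default none).
#' @param T1 Marginal threshold in `[0, 1]`.
#' @param T2 Pair-score floor on the H scale; `"auto"` uses `n`.
#' @return A `selection_result`; `scores` holds the marginal at the moment of
#'   selection and `trace` the per-iteration records (add order in
#'   `$config$iteration`).
#' @export
main_subroutine <- function(sample, F_t, G_accum = NULL,
                            prior = niw_prior_spec("jeffreys"),
                            T1, T2 = "auto", engine = NULL) {
  if (T1 < 0 || T1 > 1) stop("`T1` must be in [0, 1]")
  if (identical(T2, "auto")) T2 <- sample$n
  if (!is.numeric(T2) || T2 <= 0) stop("`T2` must be positive or \"auto\"")
  e <- .engine_for(sample, prior, NULL, engine)
  Ft <- match(sample$feature_ids[.resolve_features(sample, F_t)], e$ids)
  Gacc <- if (is.null(G_accum)) integer(0) else
    match(sample$feature_ids[.resolve_features(sample, G_accum)], e$ids)
  if (anyNA(Ft) || anyNA(Gacc)) stop("features outside the engine working set")
  res <- .main_idx(e, Ft, Gacc, T1, T2)
  sc <- res$pi
  names(sc) <- e$ids[res$selected]
  selection_result("main", e$ids[res$selected], scores = sc,
                   trace = res$trace,
                   config = list(T1 = T1, T2 = T2, iteration = res$iteration,
                                 prior = e$spec$kind))
}

#' REMAIN: recursive marginal posterior inflation
#'
#' Repeated calls to [main_subroutine()] on a shrinking feature set: each
#' call starts from the not-yet-selected features with an empty selected set,
#' so previously found features no longer contribute to the marginals; this
#' lets weaker, independent good features surface in later calls. Stops when
#' a call selects nothing. The output size is controlled by `T1` (smaller
#' selects more) and is variable by design.
#'
#' Ranking: within a MAIN call, features are ordered by the iteration they
#' were added and then by their marginal at addition; the groups from
#' successive MAIN calls are concatenated in call order.
#'
#' @inheritParams main_subroutine
#' @return A `selection_result`; `trace` records one entry per MAIN call.
#' @export
remain <- function(sample, prior = niw_prior_spec("jeffreys"), T1,
                   T2 = "auto", engine = NULL) {
  if (T1 < 0 || T1 > 1) stop("`T1` must be in [0, 1]")
  if (identical(T2, "auto")) T2 <- sample$n
  e <- .engine_for(sample, prior, NULL, engine)
  Fr <- seq_len(e$p)
  selected <- integer(0); sel_pi <- numeric(0); sel_call <- integer(0)
  trace <- list()
  call_i <- 0L
  state <- NULL
  while (length(Fr) >= 2L) {
    call_i <- call_i + 1L
    # the pair pool shrinks between MAIN calls: downdate the row
    # log-sum-exp state instead of rescanning all pairs
    state <- if (is.null(state)) .engine_lse_state(e)
             else row_lse_downdate_kernel(.engine_logH2(e), state$mx,
                                          state$acc, Fr, removed)
    res <- .main_idx(e, Fr, integer(0), T1, T2, s = state$s)
    trace[[call_i]] <- list(call = call_i, n_working = length(Fr),
                            n_selected = length(res$selected),
                            main_trace = res$trace)
    if (length(res$selected) == 0L) break
    selected <- c(selected, res$selected)
    sel_pi <- c(sel_pi, res$pi)
    sel_call <- c(sel_call, rep(call_i, length(res$selected)))
    removed <- sort(res$selected)
    Fr <- setdiff(Fr, res$selected)
  }
  sc <- sel_pi
  names(sc) <- e$ids[selected]
  selection_result("remain", e$ids[selected], scores = sc, trace = trace,
                   config = list(T1 = T1, T2 = T2, call = sel_call,
                                 prior = e$spec$kind))
}

#' Log block-merge criterion C1
#'
#' Evidence that two disjoint feature sets belong to one dependent (good)
#' block rather than two independent ones:
#' \deqn{\log C_1 = \log\frac{\tilde\pi}{1-\tilde\pi} +
#'   \sum_y\left[\log Q^{G_{12}}_y - \log Q^{G_1}_y - \log Q^{G_2}_y\right]
#'   - \frac12 \sum_y \left[\kappa^{G_{12}*}_y \log|S^{G_{12}*}_y| -
#'     \kappa^{G_1*}_y \log|S^{G_1*}_y| -
#'     \kappa^{G_2*}_y \log|S^{G_2*}_y|\right],}
#' with \eqn{G_{12} = G_1 \cup G_2} and all quantities from the class-split
#' (good) model. The Q constants depend on the block dimension and do not
#' cancel. `prior_odds` is \eqn{\tilde\pi/(1-\tilde\pi)} for the prior
#' probability \eqn{\tilde\pi} that the sets are dependent (default 1, i.e.
#' \eqn{\tilde\pi = 0.5}).
#'
#' @inheritParams cmnc_obf
#' @param G1,G2 Disjoint non-empty feature id/index sets.
#' @param prior_odds Prior odds of dependence (default 1).
#' @return `log C1(G1, G2)` (scalar, symmetric in its arguments).
#' @export
log_C1 <- function(sample, G1, G2, prior = niw_prior_spec("jeffreys"),
                   prior_odds = 1, engine = NULL) {
  e <- .engine_for(sample, prior, NULL, engine)
  i1 <- match(sample$feature_ids[.resolve_features(sample, G1)], e$ids)
  i2 <- match(sample$feature_ids[.resolve_features(sample, G2)], e$ids)
  if (length(i1) == 0L || length(i2) == 0L) stop("G1 and G2 must be non-empty")
  if (length(intersect(i1, i2))) stop("G1 and G2 must be disjoint")
  i12 <- c(i1, i2)
  total <- log(prior_odds)
  for (y in 0:1) {
    ny <- if (y == 0) e$n0 else e$n1
    kap <- function(d) .kappa_dim(e$spec, d) + ny
    if (e$spec$kind == "jeffreys" && ny <= length(i12))
      stop("Jeffreys prior requires class sample size > |G1 u G2| ",
           "(class ", y, ": n = ", ny, ", |G12| = ", length(i12), ")")
    ld <- function(ii) .logdet_spd(.engine_block(e, y, ii), sprintf(
      "class-%d scatter for block {%s}", y, paste(e$ids[ii], collapse = ", ")))
    total <- total +
      (.log_Q(make_prior(e$spec, length(i12)), ny) -
         .log_Q(make_prior(e$spec, length(i1)), ny) -
         .log_Q(make_prior(e$spec, length(i2)), ny)) -
      0.5 * (kap(length(i12)) * ld(i12) - kap(length(i1)) * ld(i1) -
               kap(length(i2)) * ld(i2))
  }
  total
}

#' GSG: grow a good block from a seed feature
#'
#' Seed-growing block detection. Starting from `U = {seed}`, each iteration
#' evaluates the merge criterion [log_C1()] between `U` and every candidate
#' feature in `F_t \ U`, takes the best candidate `u*` (ties by ascending
#' index), and adjoins it if \eqn{C_1(U, \{u^*\}) > T_3 = t_1 n^{t_2 |U|}}
#' (with `|U|` the block size before the candidate joins); otherwise stops.
#' Under the Jeffreys prior, growth also stops (with a warning) when a larger
#' block would violate the positive-definiteness requirement
#' `|U| + 1 < min(n0, n1)`.
#'
#' @inheritParams cmnc_obf
#' @param seed_feature Seed feature id/index (must lie in `F_t`).
#' @param F_t Candidate pool ids/indices (default: all features).
#' @param t1,t2 Positive threshold family parameters.
#' @param prior_odds Prior odds of dependence used in C1 (default 1).
#' @return Character vector: the detected block, in growth order (seed
#'   first), with attribute `"trace"` (per-iteration best candidate, log C1
#'   and log threshold).
#' @export
gsg <- function(sample, seed_feature, F_t = NULL,
                prior = niw_prior_spec("jeffreys"), t1, t2, prior_odds = 1,
                engine = NULL) {
  if (!is.numeric(t2) || t2 <= 0) stop("`t2` must be positive")
  if (!is.numeric(t1) || t1 <= 0) stop("`t1` must be positive")
  e <- .engine_for(sample, prior, NULL, engine)
  seed <- match(sample$feature_ids[.resolve_features(sample, seed_feature)],
                e$ids)
  pool <- if (is.null(F_t)) seq_len(e$p) else
    match(sample$feature_ids[.resolve_features(sample, F_t)], e$ids)
  if (length(seed) != 1L || !(seed %in% pool))
    stop("`seed_feature` must be a single feature inside `F_t`")
  U <- seed
  trace <- list()
  a_good <- list(`0` = .engine_diag(e, "c0"), `1` = .engine_diag(e, "c1"))
  logn <- log(sample$n)
  repeat {
    cand <- sort(setdiff(pool, U))
    if (length(cand) == 0L) break
    d12 <- length(U) + 1L
    if (e$spec$kind == "jeffreys" && d12 >= min(e$n0, e$n1)) {
      warning("GSG: stopping block growth at |U| = ", length(U),
              "; a block of size ", d12, " is not identifiable under the ",
              "Jeffreys prior with min class sample size ", min(e$n0, e$n1))
      break
    }
    logc1 <- rep(log(prior_odds), length(cand))
    for (y in 0:1) {
      ny <- if (y == 0) e$n0 else e$n1
      kap <- function(d) .kappa_dim(e$spec, d) + ny
      AU <- .engine_block(e, y, U)
      R <- tryCatch(chol(AU), error = function(err)
        stop("rank-deficient class-", y, " scatter for block {",
             paste(e$ids[U], collapse = ", "), "}", call. = FALSE))
      ldU <- 2 * sum(log(diag(R)))
      W <- backsolve(R, .engine_block(e, y, U, cand), transpose = TRUE)
      schur <- a_good[[as.character(y)]][cand] - colSums(W^2)
      ld12 <- ifelse(schur > 0, ldU + log(schur), -Inf)
      dq <- .log_Q(make_prior(e$spec, d12), ny) -
        .log_Q(make_prior(e$spec, length(U)), ny) -
        .log_Q(make_prior(e$spec, 1L), ny)
      contrib <- dq - 0.5 * (kap(d12) * ld12 - kap(length(U)) * ldU -
                               kap(1) * log(a_good[[as.character(y)]][cand]))
      # a numerically singular merged scatter means (near-)perfect
      # dependence: treat as infinitely strong evidence for merging
      contrib[!is.finite(ld12)] <- Inf
      logc1 <- logc1 + contrib
    }
    best <- which.max(logc1)   # ties: first index; cand is sorted ascending
    logT3 <- log(t1) + t2 * length(U) * logn
    trace[[length(trace) + 1L]] <- list(
      size = length(U), candidate = e$ids[cand[best]],
      log_C1 = logc1[best], log_T3 = logT3)
    if (logc1[best] > logT3) U <- c(U, cand[best]) else break
  }
  out <- e$ids[U]
  attr(out, "trace") <- trace
  out
}

#' SPM: sequential partition mustering
#'
#' Detects good blocks one at a time. The posterior factor
#' [posterior_factor()] is computed once on the full feature set; then,
#' while the most significant remaining feature has \eqn{\tilde\beta(f) \ge
#' T_4}, SPM grows the block containing it with [gsg()], removes the block
#' from the pool, and iterates. Terminates declaring no good features remain
#' when all remaining \eqn{\tilde\beta < T_4}. The selected set is the union
#' of detected blocks (reported in detection order).
#'
#' @inheritParams gsg
#' @param T4 Posterior-factor floor (> 0).
#' @return A `selection_result` with `blocks` (detection order), `scores` =
#'   posterior factors over all features.
#' @export
spm <- function(sample, prior = niw_prior_spec("jeffreys"), t1, t2, T4,
                prior_odds = 1, engine = NULL) {
  if (!is.numeric(T4) || T4 <= 0) stop("`T4` must be positive")
  e <- .engine_for(sample, prior, NULL, engine)
  if (e$p < 2L) stop("SPM needs at least 2 features")
  beta <- .engine_beta(e)   # computed once, never refreshed after removals
  Ft <- seq_len(e$p)
  blocks <- list(); trace <- list()
  while (length(Ft) > 0L) {
    bmax <- max(beta[Ft])
    if (bmax < T4) break
    u0 <- Ft[which.max(beta[Ft])]
    U <- if (length(Ft) > 1L)
      gsg(sample, e$ids[u0], e$ids[Ft], prior = e$spec, t1 = t1, t2 = t2,
          prior_odds = prior_odds, engine = e)
    else e$ids[u0]
    blocks[[length(blocks) + 1L]] <- as.character(U)
    trace[[length(trace) + 1L]] <- list(seed = e$ids[u0],
                                        beta_seed = unname(bmax),
                                        block_size = length(U))
    Ft <- setdiff(Ft, match(U, e$ids))
  }
  selection_result("spm", as.character(unlist(blocks)), scores = beta,
                   blocks = blocks, trace = trace,
                   config = list(t1 = t1, t2 = t2, T4 = T4,
                                 prior = e$spec$kind))
}
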