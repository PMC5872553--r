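#' Construct a labeled two-class sample
#'
#' Container for an expression matrix with a binary class label per sample.
#' Rows are samples, columns are features (so `X[i, f]` is the value of
#' feature `f` in sample `i`).
#'
#' @param X Numeric matrix, `n` samples by `p` features; no missing values.
#' @param y Vector of `n` labels in `{0, 1}`; both classes must be present.
#' @param feature_ids Character vector of `p` unique feature identifiers;
#'   defaults to the column names of `X`, or `f1..fp`.
#' @return An object of class `labeled_sample` with elements `X`, `y`,
#'   `feature_ids`, `n`, `n0`, `n1`.
#' @export
labeled_sample <- function(X, y, feature_ids = NULL) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("`X` must be numeric")
  if (anyNA(X)) stop("`X` contains missing values")
  y <- as.integer(y)
  if (length(y) != nrow(X))
    stop("length(y) = ", length(y), " but nrow(X) = ", nrow(X))
  if (anyNA(y) || !all(y %in% c(0L, 1L)))
    stop("labels must be 0 or 1 with no missing values")
  n0 <- sum(y == 0L); n1 <- sum(y == 1L)
  if (n0 < 1L || n1 < 1L) stop("both classes must have at least one sample")
  if (is.null(feature_ids))
    feature_ids <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  feature_ids <- as.character(feature_ids)
  if (length(feature_ids) != ncol(X))
    stop("feature_ids length must equal ncol(X)")
  if (anyDuplicated(feature_ids))
    stop("feature_ids must be unique (duplicated: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "),
         ")")
  colnames(X) <- feature_ids
  structure(list(X = X, y = y, feature_ids = feature_ids,
                 n = nrow(X), n0 = n0, n1 = n1),
            class = "labeled_sample")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.labeled_sample <- function(x, ...) {
  cat(sprintf("labeled_sample: %d samples (n0 = %d, n1 = %d) x %d features\n",
              x$n, x$n0, x$n1, length(x$feature_ids)))
  invisible(x)
}

# resolve feature ids or indices to integer column indices
.resolve_features <- function(sample, features) {
  if (is.null(features)) return(seq_along(sample$feature_ids))
  if (is.character(features)) {
    idx <- match(features, sample$feature_ids)
    if (anyNA(idx))
      stop("unknown feature ids: ",
           paste(features[is.na(idx)], collapse = ", "))
    return(idx)
  }
  idx <- as.integer(features)
  if (anyNA(idx) || any(idx < 1L) || any(idx > length(sample$feature_ids)))
    stop("feature indices out of range")
  idx
}

#' Construct a feature partition
#'
#' A partition of the feature index set into disjoint good blocks
#' `G1, ..., Gu` (class-dependent distribution) and bad blocks `B1, ..., Bv`
#' (identical distribution in both classes). Blocks must be non-empty,
#' pairwise disjoint, and jointly cover `1..n_features`.
#'
#' @param good_blocks List of integer index vectors (possibly empty list).
#' @param bad_blocks List of integer index vectors (possibly empty list).
#' @param n_features Total number of features covered.
#' @return An object of class `feature_partition`.
#' @export
feature_partition <- function(good_blocks, bad_blocks, n_features) {
  good_blocks <- lapply(good_blocks, as.integer)
  bad_blocks <- lapply(bad_blocks, as.integer)
  all_idx <- c(unlist(good_blocks), unlist(bad_blocks))
  if (any(lengths(good_blocks) == 0L) || any(lengths(bad_blocks) == 0L))
    stop("invalid partition: empty block")
  if (anyDuplicated(all_idx))
    stop("invalid partition: blocks overlap (feature ",
         all_idx[duplicated(all_idx)][1L], ")")
  if (length(all_idx) != n_features || !setequal(all_idx, seq_len(n_features)))
    stop("invalid partition: blocks do not cover 1..", n_features)
  structure(list(good_blocks = good_blocks, bad_blocks = bad_blocks,
                 n_features = as.integer(n_features)),
            class = "feature_partition")
}

#' @export
print.feature_partition <- function(x, ...) {
  cat(sprintf("feature_partition: %d features, %d good block(s) (%d features), %d bad block(s)\n",
              x$n_features, length(x$good_blocks),
              length(unlist(x$good_blocks)), length(x$bad_blocks)))
  invisible(x)
}
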