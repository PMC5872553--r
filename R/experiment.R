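#' Score a selection against ground truth
#'
#' Computes the marker-recovery metrics used throughout the simulation
#' studies: `markers_found` (true markers selected, TP), `nonmarkers_found`
#' (non-markers selected, FP), and `correctly_labeled` = TP + TN, the number
#' of features whose good/bad label is correct (the performance measure; it
#' equals the number of features when the selection is exactly the marker
#' set).
#'
#' @param selected Character vector of selected feature ids.
#' @param truth Named logical vector over all features (`TRUE` = marker), or
#'   a `simulated_dataset`.
#' @return A one-row `data.frame` with columns `markers_found`,
#'   `nonmarkers_found`, `correctly_labeled`, `n_selected`, `n_markers`,
#'   `n_features`.
#' @export
score_selection <- function(selected, truth) {
  if (inherits(truth, "simulated_dataset")) truth <- truth$truth
  if (is.null(names(truth))) stop("`truth` must be a named logical vector")
  selected <- as.character(selected)
  unknown <- setdiff(selected, names(truth))
  if (length(unknown))
    stop("selected features not covered by truth: ",
         paste(head(unknown, 5L), collapse = ", "))
  is_sel <- names(truth) %in% selected
  tp <- sum(is_sel & truth)
  fp <- sum(is_sel & !truth)
  tn <- sum(!is_sel & !truth)
  data.frame(markers_found = tp, nonmarkers_found = fp,
             correctly_labeled = tp + tn, n_selected = length(selected),
             n_markers = sum(truth), n_features = length(truth))
}

#' Describe a selector for the evaluation harness
#'
#' @param method One of `"cmnc_obf"`, `"two_mnc_robust"`, `"remain"`,
#'   `"pofac"`, `"spm"`.
#' @param prior A [niw_prior_spec()] (or `"jeffreys"`/`"proper"`).
#' @param label Column label in the results (default `method`).
#' @param ... Method parameters (`D`, `T1`, `T2`, `t1`, `t2`, `T4`, ...).
#'   `T2 = "auto"` and `T4 = NULL` (meaning `100 n^2`) are resolved per
#'   dataset.
#' @return An object of class `selector_config`.
#' @export
selector_config <- function(method = c("cmnc_obf", "two_mnc_robust",
                                       "remain", "pofac", "spm"),
                            prior = niw_prior_spec("jeffreys"),
                            label = NULL, ...) {
  method <- match.arg(method)
  structure(list(method = method, prior = .as_prior_spec(prior),
                 label = label %||% method, args = list(...)),
            class = "selector_config")
}

.run_selector <- function(cfg, sample, engine) {
  a <- cfg$args
  switch(cfg$method,
    cmnc_obf = cmnc_obf(sample, cfg$prior, D = a$D,
                        p_good = a$p_good %||% 0.5, engine = engine),
    two_mnc_robust = two_mnc_robust(sample, cfg$prior, D = a$D,
                                    engine = engine),
    remain = remain(sample, cfg$prior, T1 = a$T1, T2 = a$T2 %||% "auto",
                    engine = engine),
    pofac = pofac(sample, cfg$prior, D = a$D, engine = engine),
    spm = spm(sample, cfg$prior, t1 = a$t1, t2 = a$t2,
              T4 = a$T4 %||% (100 * sample$n^2),
              prior_odds = a$prior_odds %||% 1, engine = engine))
}

#' Replicated selector evaluation
#'
#' Runs one or more selectors over `reps` independently generated datasets at
#' each sample size, in a paired design: within a replicate every selector
#' sees the same dataset (and shares one scoring engine per prior). The
#' replicate seed is `base_seed + replicate index`, so the whole table is a
#' pure function of the configuration. Selector failures are recorded and
#' excluded from the aggregates rather than aborting the run.
#'
#' @param generator Function `(n) -> simulated_dataset`; called after the
#'   replicate seed is set, e.g.
#'   `function(n) simulate_microarray_dataset(cfg, n)`.
#' @param selectors A [selector_config()] or list of them.
#' @param n_values Integer vector of sample sizes.
#' @param reps Replicates per sample size (`R >= 1`).
#' @param base_seed Integer base seed.
#' @param out_csv Optional path: write the per-replicate table as CSV.
#' @return List with `replicates` (one row per selector x n x replicate) and
#'   `summary` (means and standard errors of the metrics).
#' @export
run_replicates <- function(generator, selectors, n_values, reps = 30L,
                           base_seed = 1L, out_csv = NULL) {
  if (inherits(selectors, "selector_config")) selectors <- list(selectors)
  stopifnot(length(selectors) >= 1L, reps >= 1L)
  rows <- vector("list", length(n_values) * reps * length(selectors))
  ri <- 0L
  for (n in n_values) {
    for (r in seq_len(reps)) {
      seed <- base_seed + r
      set.seed(seed)
      ds <- generator(n)
      engines <- list()
      for (cfg in selectors) {
        key <- paste(unlist(cfg$prior), collapse = "/")
        if (is.null(engines[[key]]))
          engines[[key]] <- score_engine(ds$sample, cfg$prior)
        t0 <- proc.time()[["elapsed"]]
        res <- tryCatch(.run_selector(cfg, ds$sample, engines[[key]]),
                        error = function(err) err)
        elapsed <- proc.time()[["elapsed"]] - t0
        ri <- ri + 1L
        if (inherits(res, "error")) {
          message("replicate ", r, " (n = ", n, ", ", cfg$label,
                  ") failed: ", conditionMessage(res))
          rows[[ri]] <- data.frame(selector = cfg$label, n = n,
                                   replicate = r, seed = seed,
                                   markers_found = NA_real_,
                                   nonmarkers_found = NA_real_,
                                   correctly_labeled = NA_real_,
                                   n_selected = NA_integer_,
                                   elapsed = elapsed,
                                   error = conditionMessage(res))
        } else {
          sc <- score_selection(res$selected, ds$truth)
          rows[[ri]] <- data.frame(selector = cfg$label, n = n,
                                   replicate = r, seed = seed,
                                   markers_found = sc$markers_found,
                                   nonmarkers_found = sc$nonmarkers_found,
                                   correctly_labeled = sc$correctly_labeled,
                                   n_selected = sc$n_selected,
                                   elapsed = elapsed, error = NA_character_)
        }
      }
    }
  }
  reps_df <- do.call(rbind, rows)
  agg <- function(x) c(mean = mean(x, na.rm = TRUE),
                       se = sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))))
  summ <- do.call(rbind, lapply(
    split(reps_df, list(reps_df$selector, reps_df$n), drop = TRUE),
    function(d) {
      m <- agg(d$markers_found); f <- agg(d$nonmarkers_found)
      cl <- agg(d$correctly_labeled)
      data.frame(selector = d$selector[1L], n = d$n[1L],
                 reps_ok = sum(is.na(d$error)),
                 markers_found = m[["mean"]], markers_se = m[["se"]],
                 nonmarkers_found = f[["mean"]], nonmarkers_se = f[["se"]],
                 correctly_labeled = cl[["mean"]],
                 correctly_labeled_se = cl[["se"]])
    }))
  rownames(summ) <- NULL
  if (!is.null(out_csv)) data.table::fwrite(reps_df, out_csv)
  list(replicates = reps_df, summary = summ)
}

#' Read a feature matrix and labels from disk
#'
#' Expects a features-by-samples TSV/CSV matrix whose first column holds
#' feature ids and whose header row holds sample ids, plus a two-column
#' labels file mapping sample id to class 0/1. Parse problems (duplicate
#' ids, non-binary labels, missing values) raise errors naming the offending
#' entry.
#'
#' @param x_path Path to the matrix file.
#' @param labels_path Path to the labels file.
#' @return A [labeled_sample()].
#' @export
read_dataset <- function(x_path, labels_path) {
  mat <- data.table::fread(x_path, header = TRUE)
  if (ncol(mat) < 2L) stop("matrix file needs a feature id column plus samples")
  if (!is.character(mat[[1L]]))
    stop("first column of ", x_path, " must contain feature ids")
  fid <- mat[[1L]]
  if (anyDuplicated(fid))
    stop("duplicate feature id in ", x_path, ": ",
         fid[duplicated(fid)][1L], " (line ",
         which(duplicated(fid))[1L] + 1L, ")")
  vals <- as.matrix(mat[, -1L])
  if (!is.numeric(vals)) stop("non-numeric expression values in ", x_path)
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1L, any))[1L]
    stop("missing value in ", x_path, " (feature ", fid[bad], ", line ",
         bad + 1L, ")")
  }
  lab <- data.table::fread(labels_path, header = TRUE)
  if (ncol(lab) < 2L) stop("labels file needs columns: sample id, label")
  sid <- as.character(lab[[1L]])
  if (anyDuplicated(sid))
    stop("duplicate sample id in ", labels_path, ": ",
         sid[duplicated(sid)][1L])
  yv <- lab[[2L]]
  bad <- which(!(yv %in% c(0, 1)))
  if (length(bad))
    stop("non-binary label in ", labels_path, " at line ", bad[1L] + 1L,
         " (sample ", sid[bad[1L]], ", value ", yv[bad[1L]], ")")
  missing_samples <- setdiff(colnames(vals), sid)
  if (length(missing_samples))
    stop("samples without labels: ", paste(head(missing_samples, 5L),
                                           collapse = ", "))
  y <- yv[match(colnames(vals), sid)]
  labeled_sample(t(vals), y, feature_ids = fid)
}

#' Write a dataset to disk
#'
#' Inverse of [read_dataset()]: writes the features-by-samples matrix (first
#' column `feature_id`, one column per sample) and the two-column labels
#' file. Values round-trip through text at full precision.
#'
#' @param sample A [labeled_sample()].
#' @param x_path,labels_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(sample, x_path, labels_path) {
  sids <- rownames(sample$X) %||% paste0("s", seq_len(sample$n))
  mat <- data.table::data.table(feature_id = sample$feature_ids)
  vals <- t(sample$X)
  colnames(vals) <- sids
  mat <- cbind(mat, data.table::as.data.table(vals))
  data.table::fwrite(mat, x_path, sep = "\t")
  data.table::fwrite(data.table::data.table(sample_id = sids,
                                            label = sample$y),
                     labels_path, sep = "\t")
  invisible(c(x_path, labels_path))
}

#' Write a selection result to disk
#'
#' Writes the full result (ranked list, scores, blocks, configuration) as
#' JSON and the ranked list as a two-column TSV (`rank`, `feature_id`).
#'
#' @param result A `selection_result`.
#' @param json_path Path for the JSON output (optional).
#' @param tsv_path Path for the ranked-list TSV (optional).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(result, json_path = NULL, tsv_path = NULL) {
  if (!inherits(result, "selection_result"))
    stop("`result` must be a selection_result")
  paths <- character(0)
  if (!is.null(json_path)) {
    payload <- list(method = result$method, selected = result$selected,
                    scores = as.list(result$scores),
                    blocks = result$blocks, config = result$config)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    paths <- c(paths, json_path)
  }
  if (!is.null(tsv_path)) {
    data.table::fwrite(
      data.table::data.table(rank = seq_along(result$selected),
                             feature_id = result$selected),
      tsv_path, sep = "\t")
    paths <- c(paths, tsv_path)
  }
  invisible(paths)
}
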