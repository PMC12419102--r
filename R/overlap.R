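#' Select outcome-predictive features for overlap assessment
#'
#' Overlap (positivity) is judged in the covariate directions that matter
#' for the outcome, so anomaly scoring is restricted to a screened feature
#' subset. The default screen fits a pilot probability forest on the whole
#' cohort and ranks features by out-of-bag permutation importance, keeping
#' the top `top_k`. A pluggable interface: an externally supplied list is
#' returned verbatim, so any screening algorithm can be substituted.
#'
#' @param data Cohort tibble.
#' @param outcome,group_col,id_col Column names.
#' @param candidates Candidate feature columns (default: everything except
#'   id, group and outcome).
#' @param supplied Externally chosen feature list; returned unchanged when
#'   given.
#' @param top_k Number of features to keep (clamped to the number of
#'   candidates).
#' @param num_trees Pilot forest size.
#' @param seed RNG seed for the pilot forest.
#' @return Character vector of feature names, ordered by decreasing
#'   importance.
#' @export
screen_features <- function(data, outcome = "y", group_col = "hospital",
                            id_col = "id", candidates = NULL,
                            supplied = NULL, top_k = 10,
                            num_trees = 100, seed = 1) {
  if (!is.null(supplied)) return(supplied)
  check_cols(data, outcome)
  if (is.null(candidates)) {
    candidates <- setdiff(names(data), c(outcome, group_col, id_col))
  }
  check_cols(data, candidates, "feature column")
  top_k <- min(top_k, length(candidates))
  train <- data.frame(.y = factor(data[[outcome]], levels = c(0, 1)),
                      data[, candidates, drop = FALSE])
  pilot <- ranger::ranger(
    dependent.variable.name = ".y", data = train,
    num.trees = num_trees, probability = TRUE,
    importance = "permutation", seed = seed, num.threads = 1
  )
  imp <- sort(pilot$variable.importance, decreasing = TRUE)
  sel <- names(imp)[seq_len(top_k)]
  if (length(sel) == 0) {
    warn("feature screening selected nothing; falling back to all candidates")
    sel <- candidates
  }
  sel
}

#' Fit a per-hospital anomaly scorer
#'
#' Trains an isolation forest on one hospital's covariates (no outcome is
#' used) over the screened feature subset, and stores the raw score
#' distribution of that hospital's own rows as a calibration table. The
#' raw score of a row is its average isolation-tree path length: points in
#' dense, typical regions take many random splits to isolate (long paths),
#' while points outside the hospital's case mix are isolated quickly
#' (short paths).
#'
#' @param data Cohort tibble.
#' @param group Hospital label whose rows define the reference
#'   distribution.
#' @param features Feature columns to score on (typically from
#'   [screen_features()]).
#' @param group_col,id_col Column names.
#' @param num_trees Number of isolation trees (default 300).
#' @param sample_size Per-tree subsample size \eqn{\psi}
#'   (default `min(256, n(h))`).
#' @param seed RNG seed.
#' @return An object of class `vt_anomaly_scorer`.
#' @export
fit_anomaly_scorer <- function(data, group, features,
                               group_col = "hospital", id_col = "id",
                               num_trees = 300, sample_size = 256,
                               seed = 1) {
  check_cols(data, c(group_col, features))
  rows <- as.character(data[[group_col]]) == as.character(group)
  if (!any(rows)) abort(sprintf("group '%s' has no rows", group))
  x <- as.matrix(data[rows, features, drop = FALSE])
  storage.mode(x) <- "double"
  constant <- features[apply(x, 2, function(v) max(v) == min(v))]
  if (length(constant) == length(features)) {
    abort(sprintf("all scoring features are constant: %s",
                  paste(constant, collapse = ", ")))
  }
  forest <- fit_iforest(x, num_trees = num_trees,
                        sample_size = sample_size, seed = seed)
  raw_train <- iforest_raw_score(forest, x)
  structure(
    list(
      forest = forest,
      group = group,
      features = features,
      calibration = sort(raw_train),
      raw_train = raw_train,
      train_ids = if (id_col %in% names(data)) data[[id_col]][rows] else which(rows),
      n_train = sum(rows),
      seed = as.integer(seed)
    ),
    class = "vt_anomaly_scorer"
  )
}

#' @export
print.vt_anomaly_scorer <- function(x, ...) {
  cat("<vt_anomaly_scorer>\n")
  cat(sprintf("  group: %s  (n = %d)\n", x$group, x$n_train))
  cat(sprintf("  trees: %d  subsample: %d  features: %d\n",
              x$forest$num_trees, x$forest$psi, length(x$features)))
  invisible(x)
}

# Mid-rank empirical-distribution calibration of raw path lengths against
# the scorer's training table. Short path => low percentile => low score.
# Raw values below the training minimum map to 0, above the maximum to 1.
calibrate_raw <- function(calibration, raw) {
  n <- length(calibration)
  count_le <- findInterval(raw, calibration)
  count_lt <- findInterval(raw, calibration, left.open = TRUE)
  (count_lt + 0.5 * (count_le - count_lt)) / n
}

#' Calibrated anomaly scores against a hospital's case mix
#'
#' Scores arbitrary rows with a fitted [fit_anomaly_scorer()] and
#' calibrates each raw average path length to the unit interval by its
#' mid-rank position in the scorer's training distribution. A score near 0
#' means the row would be among the hospital's most anomalous patients -
#' a poor candidate for a valid virtual twin - while scores spread
#' uniformly over (0,1) for rows that look like the hospital's own
#' case mix.
#'
#' @param scorer A `vt_anomaly_scorer`.
#' @param newdata Tibble carrying the scorer's feature columns.
#' @param id_col Optional id column carried through.
#' @return A tibble with columns `id`, `raw` (average path length) and
#'   `score` (calibrated, in \[0,1\]).
#' @export
score_anomaly <- function(scorer, newdata, id_col = "id") {
  stopifnot(inherits(scorer, "vt_anomaly_scorer"))
  check_cols(newdata, scorer$features, "feature column")
  x <- as.matrix(newdata[, scorer$features, drop = FALSE])
  storage.mode(x) <- "double"
  raw <- iforest_raw_score(scorer$forest, x)
  id <- if (id_col %in% names(newdata)) newdata[[id_col]] else seq_len(nrow(newdata))
  tibble::tibble(id = id, raw = raw,
                 score = calibrate_raw(scorer$calibration, raw))
}

#' Flag rows without valid virtual twins
#'
#' Applies the anomaly-score threshold `C`: a row is kept (treated as a
#' valid virtual twin for the scorer's hospital) when its calibrated score
#' is at least `C`. With `C = 0.05` and scores calibrated on the training
#' distribution, the 5% most anomalous training rows are excluded.
#'
#' @param scores A tibble from [score_anomaly()] or a numeric score
#'   vector in \[0,1\].
#' @param threshold The cutoff `C` in (0,1).
#' @return Logical keep mask.
#' @export
flag_bad_twins <- function(scores, threshold = 0.05) {
  if (threshold <= 0 || threshold >= 1) {
    abort("threshold C must lie strictly inside (0, 1)")
  }
  s <- if (is.data.frame(scores)) scores$score else scores
  if (any(s < 0 | s > 1)) abort("scores must lie in [0, 1]")
  s >= threshold
}

#' @rdname fit_anomaly_scorer
#' @param x A `vt_anomaly_scorer`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.vt_anomaly_scorer <- function(x, ...) {
  tibble::tibble(
    id = x$train_ids,
    raw = x$raw_train,
    score = calibrate_raw(x$calibration, x$raw_train)
  )
}

#' @rdname fit_anomaly_scorer
#' @exportS3Method generics::glance
glance.vt_anomaly_scorer <- function(x, ...) {
  tibble::tibble(
    group = as.character(x$group),
    n = x$n_train,
    num_trees = x$forest$num_trees,
    subsample = x$forest$psi,
    n_features = length(x$features),
    median_raw = stats::median(x$calibration)
  )
}
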