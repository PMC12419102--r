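#' Fit a per-hospital (or pooled) risk forest for a rare binary outcome
#'
#' Trains a probability random forest on one hospital's patients (or on the
#' pooled cohort when `scope = "overall"`) and records, for every tree,
#' which training rows were in the bootstrap sample. That membership record
#' is what makes honest out-of-bag (OOB) counterfactual prediction possible
#' downstream: a training patient's own risk is estimated only from trees
#' that never saw them ([predict_risk_oob()]), while patients from other
#' hospitals are external test points scored by the full ensemble
#' ([predict_risk()]).
#'
#' Class imbalance is handled in the quantile-classification style: the
#' classification threshold `q` defaults to the training event prevalence
#' rather than 0.5 (see [rfq_classify()]); the causal pipeline itself
#' consumes the probability estimates, not the labels. Each tree is grown
#' on a bootstrap of n draws with replacement, so on average about 37% of
#' rows are out-of-bag per tree. Training rows are sorted by `id` before
#' fitting, making the fit invariant to input row order. If any training
#' row ends up in-bag for every tree (vanishingly rare for realistic
#' ensemble sizes) the forest is re-drawn with a perturbed seed.
#'
#' @param data Cohort tibble with an id column, a group column, a binary
#'   outcome column and feature columns.
#' @param scope `"overall"` for the pooled model, or a hospital label to
#'   train on that hospital's rows only.
#' @param outcome,group_col,id_col Column names.
#' @param features Character vector of feature columns; default all
#'   columns other than id, group and outcome.
#' @param num_trees Ensemble size (default 500).
#' @param mtry Candidate features per split; default `floor(sqrt(p))`.
#' @param min_node_size Minimum terminal node size for probability
#'   estimation. Default `NULL` uses `max(5, ceiling(node_fraction * n))`:
#'   terminal nodes hold a fixed *fraction* of the training data rather
#'   than a fixed count. With rare events this keeps the expected number
#'   of events per node away from zero (finer leaves mostly contain no
#'   events and estimate low risks as exactly 0), and it matches the
#'   smoothing neighbourhood of per-hospital and pooled models fit at
#'   different n, so their ratio is not biased by asymmetric smoothing.
#' @param node_fraction Fraction of the training rows per terminal node
#'   used by the default `min_node_size` rule (default 0.05).
#' @param q Classification threshold in (0,1); default the training event
#'   prevalence.
#' @param seed RNG seed for the forest.
#' @return An object of class `vt_risk_model`: the fitted ensemble plus
#'   the per-tree in-bag counts, training ids, scope, threshold `q` and
#'   probability floor `epsilon = 1/(2 * num_trees)` (risk estimates are
#'   clamped to `[epsilon, 1 - epsilon]` so that log relative risks stay
#'   finite).
#' @examples
#' sim <- simulate_cohort(sim_config(n_hospitals = 2, sizes = 300, seed = 3))
#' m <- fit_risk_model(sim$cohort, scope = "1", num_trees = 50, seed = 3)
#' predict_risk_oob(m)
#' @export
fit_risk_model <- function(data, scope = "overall",
                           outcome = "y", group_col = "hospital",
                           id_col = "id", features = NULL,
                           num_trees = 500, mtry = NULL,
                           min_node_size = NULL, node_fraction = 0.05,
                           q = NULL, seed = 1) {
  check_cols(data, c(outcome, group_col, id_col))
  check_binary_outcome(data[[outcome]], outcome)
  if (is.null(features)) {
    features <- setdiff(names(data), c(outcome, group_col, id_col))
  }
  check_cols(data, features, "feature column")

  if (!identical(scope, "overall")) {
    keep <- as.character(data[[group_col]]) == as.character(scope)
    if (!any(keep)) abort(sprintf("no rows for scope '%s'", scope))
    data <- data[keep, , drop = FALSE]
  }
  # canonical row order: fit is invariant to how the caller ordered rows
  data <- data[order(data[[id_col]]), , drop = FALSE]

  y <- data[[outcome]]
  n_events <- sum(y == 1)
  if (n_events == 0 || n_events == nrow(data)) {
    abort(sprintf(
      "degenerate outcome in scope '%s': %d events out of %d rows",
      scope, n_events, nrow(data)))
  }
  prevalence <- mean(y)
  if (is.null(q)) q <- prevalence
  if (q <= 0 || q >= 1) abort("q must lie strictly inside (0, 1)")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(features))))
  if (is.null(min_node_size)) {
    min_node_size <- max(5L, ceiling(node_fraction * nrow(data)))
  }

  train <- data.frame(.y = factor(y, levels = c(0, 1)),
                      data[, features, drop = FALSE])

  fit <- NULL
  fit_seed <- as.integer(seed)
  for (attempt in 1:5) {
    cand <- ranger::ranger(
      dependent.variable.name = ".y", data = train,
      num.trees = num_trees, mtry = mtry, min.node.size = min_node_size,
      probability = TRUE, keep.inbag = TRUE, replace = TRUE,
      sample.fraction = 1, seed = fit_seed, num.threads = 1
    )
    inbag <- do.call(cbind, cand$inbag.counts)   # n x num_trees counts
    if (all(rowSums(inbag == 0) > 0)) { fit <- cand; break }
    fit_seed <- child_seed(fit_seed, attempt)    # re-draw: a row was never OOB
  }
  if (is.null(fit)) abort("could not draw bootstraps leaving every row out-of-bag")

  structure(
    list(
      forest = fit,
      inbag = inbag,
      scope = scope,
      features = features,
      train_x = data[, features, drop = FALSE],
      train_ids = data[[id_col]],
      train_y = as.integer(y),
      q = q,
      prevalence = prevalence,
      epsilon = 1 / (2 * num_trees),
      num_trees = num_trees,
      seed = as.integer(seed)
    ),
    class = "vt_risk_model"
  )
}

#' @export
print.vt_risk_model <- function(x, ...) {
  cat("<vt_risk_model>\n")
  cat(sprintf("  scope: %s  (n = %d, events = %d)\n", x$scope,
              length(x$train_ids), sum(x$train_y)))
  cat(sprintf("  trees: %d  q: %.4f  epsilon: %.2e\n",
              x$num_trees, x$q, x$epsilon))
  invisible(x)
}

event_col <- function(model) match("1", model$forest$forest$levels)

# Per-tree event-probability matrix (rows x trees) for arbitrary rows.
tree_risk_matrix <- function(model, newdata) {
  check_cols(newdata, model$features, "feature column")
  pa <- stats::predict(model$forest,
                       data = newdata[, model$features, drop = FALSE],
                       predict.all = TRUE, num.threads = 1)
  pa$predictions[, event_col(model), , drop = TRUE]
}

new_risk_predictions <- function(id, risk, mode, model) {
  tibble::tibble(
    id = id,
    risk = unname(clamp(risk, model$epsilon, 1 - model$epsilon)),
    mode = mode
  )
}

#' Full-ensemble risk prediction
#'
#' Estimated event risk for arbitrary rows: the mean of the terminal-node
#' event frequencies across all trees, clamped to
#' `[epsilon, 1 - epsilon]`. This is the estimator used for patients
#' outside the model's training hospital, who are external test points.
#'
#' @param model A [fit_risk_model()] object.
#' @param newdata Tibble carrying the model's feature columns.
#' @param id_col Optional id column carried through to the output.
#' @return A tibble with columns `id`, `risk`, `mode = "full"`.
#' @export
predict_risk <- function(model, newdata, id_col = "id") {
  stopifnot(inherits(model, "vt_risk_model"))
  check_cols(newdata, model$features, "feature column")
  pr <- stats::predict(model$forest,
                       data = newdata[, model$features, drop = FALSE],
                       num.threads = 1)$predictions[, event_col(model)]
  id <- if (id_col %in% names(newdata)) newdata[[id_col]] else seq_len(nrow(newdata))
  new_risk_predictions(id, pr, "full", model)
}

#' Out-of-bag risk prediction for the training rows
#'
#' For each training patient, averages the event-frequency predictions of
#' only those trees whose bootstrap sample excluded that patient, using the
#' in-bag membership record stored at fit time. This is the honest
#' (leave-self-out) estimate used whenever a patient's own hospital model
#' predicts their risk.
#'
#' @param model A [fit_risk_model()] object.
#' @return A tibble with columns `id` (training ids), `risk`,
#'   `mode = "oob"`, in training-id order.
#' @export
predict_risk_oob <- function(model) {
  stopifnot(inherits(model, "vt_risk_model"))
  # per-tree predictions on the training rows, masked by the in-bag record
  tp <- tree_risk_matrix(model, model$train_x)
  oob_mask <- model$inbag == 0
  if (any(rowSums(oob_mask) == 0)) {
    abort("a training row is in-bag in every tree; refit the model")
  }
  risk <- rowSums(tp * oob_mask) / rowSums(oob_mask)
  new_risk_predictions(model$train_ids, risk, "oob", model)
}

#' Quantile-threshold classification for imbalanced outcomes
#'
#' Labels a row an event when its estimated risk reaches the threshold
#' `q`. With `q` equal to the event prevalence this is the quantile
#' classification rule for rare events; `q = 0.5` recovers the usual
#' majority-vote Bayes rule. The labels are a diagnostic output - the
#' causal estimators consume the probabilities themselves.
#'
#' @param predictions A tibble from [predict_risk()] /
#'   [predict_risk_oob()], or a numeric risk vector.
#' @param q Threshold in (0,1).
#' @return Integer 0/1 labels.
#' @export
rfq_classify <- function(predictions, q) {
  if (q <= 0 || q >= 1) abort("q must lie strictly inside (0, 1)")
  risk <- if (is.data.frame(predictions)) predictions$risk else predictions
  as.integer(risk >= q)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_risk_model
#' @param x A `vt_risk_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.vt_risk_model <- function(x, ...) {
  oob <- predict_risk_oob(x)
  tibble::tibble(id = oob$id, y = x$train_y, risk_oob = oob$risk,
                 label_rfq = rfq_classify(oob, x$q))
}

#' @rdname fit_risk_model
#' @exportS3Method generics::glance
glance.vt_risk_model <- function(x, ...) {
  oob <- predict_risk_oob(x)
  y <- x$train_y
  tibble::tibble(
    scope = as.character(x$scope),
    n = length(y),
    events = sum(y),
    prevalence = x$prevalence,
    num_trees = x$num_trees,
    q = x$q,
    oob_logloss = -mean(y * log(oob$risk) + (1 - y) * log(1 - oob$risk)),
    oob_fraction = mean(x$inbag == 0)
  )
}

#' Persist and restore a fitted risk model
#'
#' `save_risk_model()` writes the model to a binary artifact (RDS) with a
#' JSON sidecar (`<path>.json`) recording the package version, scope,
#' threshold `q`, probability floor, seed and feature names, so an
#' artifact can be identified without deserialising it.
#' `load_risk_model()` restores the model and refuses artifacts whose
#' sidecar declares a different format version.
#'
#' @param model A [fit_risk_model()] object.
#' @param path File path for the binary artifact (conventionally `.rds`).
#' @return `save_risk_model()` returns `path` invisibly;
#'   `load_risk_model()` returns the restored `vt_risk_model`.
#' @export
save_risk_model <- function(model, path) {
  stopifnot(inherits(model, "vt_risk_model"))
  saveRDS(model, path)
  sidecar <- list(
    format_version = 1L,
    package_version = as.character(utils::packageVersion("vtwins")),
    scope = as.character(model$scope),
    q = model$q,
    epsilon = model$epsilon,
    num_trees = model$num_trees,
    seed = model$seed,
    n_train = length(model$train_ids),
    features = model$features
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_risk_model
#' @export
load_risk_model <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sidecar <- jsonlite::read_json(sidecar_path)
    if (!identical(as.integer(sidecar$format_version), 1L)) {
      abort(sprintf("unsupported model artifact format version: %s",
                    sidecar$format_version))
    }
  }
  model <- readRDS(path)
  if (!inherits(model, "vt_risk_model")) {
    abort("file does not contain a vt_risk_model")
  }
  model
}
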