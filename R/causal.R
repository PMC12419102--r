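#' Stratify patients by overall-hospital risk
#'
#' Cuts the out-of-bag overall-model risks at their empirical 50th and
#' 75th percentiles: \[0, p50) is low risk, \[p50, p75) medium and
#' \[p75, Inf) high, so the strata hold about 50/25/25 percent of
#' patients. With fewer than four rows, or when every risk is identical,
#' all rows fall in a single stratum and a warning is raised.
#'
#' @param risks Numeric vector of overall-model OOB risks for all
#'   patients.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
stratify_by_overall_risk <- function(risks) {
  if (any(!is.finite(risks))) abort("risks must be finite")
  if (length(risks) < 4) {
    warn("fewer than 4 rows: assigning a single risk stratum")
    return(factor(rep("low", length(risks)),
                  levels = c("low", "medium", "high")))
  }
  p50 <- stats::quantile(risks, 0.5, names = FALSE)
  p75 <- stats::quantile(risks, 0.75, names = FALSE)
  lab <- ifelse(risks < p50, "low", ifelse(risks < p75, "medium", "high"))
  if (length(unique(lab)) == 1L) {
    warn("degenerate risk distribution: all rows in one stratum")
  }
  factor(lab, levels = c("low", "medium", "high"))
}

check_scope <- function(model, expected, what) {
  if (!identical(as.character(model$scope), as.character(expected))) {
    abort(sprintf("%s has scope '%s' but '%s' was expected",
                  what, model$scope, expected))
  }
}

# Risk of every row of `data` under `model`: the model's honest OOB
# estimate where the row is labelled as (and present in) the model's own
# training data, the full-ensemble estimate for external test points.
# `use_oob` restricts which rows are eligible for the OOB path; rows
# eligible but absent from the training ids (external probes carrying the
# model's label) fall back to the full ensemble.
counterfactual_risk <- function(model, data, id_col = "id",
                                use_oob = rep(TRUE, nrow(data)),
                                oob = NULL) {
  full <- predict_risk(model, data, id_col = id_col)
  risk <- full$risk
  if (is.null(oob)) oob <- predict_risk_oob(model)
  hit <- match(data[[id_col]], oob$id)
  own <- use_oob & !is.na(hit)
  risk[own] <- oob$risk[hit[own]]
  list(risk = risk, own = own)
}

#' Per-patient causal relative risk against the overall hospital
#'
#' For every patient in the cohort, estimates the causal relative risk
#' \eqn{\hat\tau_h(x) = \hat\theta_h(x) / \hat\theta_O(x)} of being
#' treated at hospital `h` versus at the pooled overall hospital. The
#' numerator uses hospital `h`'s model: out-of-bag for `h`'s own patients
#' (they are in that model's training data), full-ensemble for patients
#' of other hospitals, who are external test points. The denominator is
#' always the overall model's out-of-bag estimate, since every patient is
#' in the pooled training data. Values below 1 mean the patient is
#' expected to fare better at hospital `h` than at the average system
#' hospital.
#'
#' Rows are screened with hospital `h`'s anomaly scorer: a patient whose
#' calibrated score falls below `threshold` has no valid virtual twin in
#' `h`'s case mix ("bad virtual twin") and is marked `keep = FALSE`.
#' Filtering never alters the kept rows' estimates - it only removes
#' rows. Each patient is also assigned a risk stratum from the overall
#' OOB risks (see [stratify_by_overall_risk()]).
#'
#' @param data The full cohort tibble (all hospitals).
#' @param hospital Focal hospital label `h`.
#' @param model_h Risk model fitted on hospital `h`'s rows only.
#' @param model_o Risk model fitted on the pooled cohort
#'   (`scope = "overall"`).
#' @param scorer Anomaly scorer fitted on hospital `h`'s rows
#'   ([fit_anomaly_scorer()]).
#' @param threshold Anomaly-score cutoff `C` (default 0.05).
#' @param group_col,id_col Column names.
#' @param oob_overall Optional precomputed [predict_risk_oob()] tibble for
#'   `model_o`; supply it when estimating effects for many focal
#'   hospitals against the same pooled model to avoid recomputing it.
#' @return A tibble of class `vt_estimates` with one row per patient:
#'   `id`, `hospital` (actual), `focal`, `origin` (`in_h`/`out_h`),
#'   `theta_h`, `theta_o`, `tau`, `log_tau`, `anomaly_score`, `keep`,
#'   `stratum`.
#' @export
estimate_effects <- function(data, hospital, model_h, model_o, scorer,
                             threshold = 0.05, group_col = "hospital",
                             id_col = "id", oob_overall = NULL) {
  stopifnot(inherits(model_h, "vt_risk_model"),
            inherits(model_o, "vt_risk_model"))
  check_scope(model_h, hospital, "model_h")
  check_scope(model_o, "overall", "model_o")
  if (!identical(as.character(scorer$group), as.character(hospital))) {
    abort(sprintf("scorer was fitted on group '%s', not focal hospital '%s'",
                  scorer$group, hospital))
  }
  check_cols(data, c(group_col, id_col))

  in_h <- as.character(data[[group_col]]) == as.character(hospital)
  num <- counterfactual_risk(model_h, data, id_col, use_oob = in_h)
  den <- counterfactual_risk(model_o, data, id_col, oob = oob_overall)

  scores <- score_anomaly(scorer, data, id_col = id_col)
  keep <- flag_bad_twins(scores, threshold)

  focal_label <- as.character(hospital)
  out <- tibble::tibble(
    id = data[[id_col]],
    hospital = data[[group_col]],
    focal = focal_label,
    origin = ifelse(in_h, "in_h", "out_h"),
    theta_h = num$risk,
    theta_o = den$risk,
    tau = num$risk / den$risk,
    log_tau = log(num$risk) - log(den$risk),
    anomaly_score = scores$score,
    keep = keep,
    stratum = stratify_by_overall_risk(den$risk)
  )
  structure(out,
            class = c("vt_estimates", class(out)),
            threshold = threshold,
            n_kept = sum(keep))
}

#' Pairwise causal comparison of two hospitals
#'
#' Head-to-head counterpart of [estimate_effects()]: for each patient
#' computes \eqn{\log\tau_{a\sim b}(x) = \log\hat\theta_b(x) -
#' \log\hat\theta_a(x)}, the log relative risk of hospital `b` versus
#' hospital `a`. Positive values indicate better outcomes at the
#' first-listed hospital `a`. Each side uses its model's OOB estimate for
#' that hospital's own patients and the full ensemble otherwise. A row is
#' kept only when it has a valid virtual twin under *both* hospitals'
#' anomaly scorers. An optional subgroup filter (a data-masked predicate,
#' e.g. `x3 > 0`) restricts the comparison to a patient subgroup.
#'
#' @param data Cohort tibble (any hospitals; typically the full cohort).
#' @param a,b Hospital labels being compared.
#' @param model_a,model_b Risk models fitted on hospitals `a`, `b`.
#' @param scorer_a,scorer_b Anomaly scorers fitted on hospitals `a`, `b`.
#' @param threshold Anomaly-score cutoff `C`.
#' @param subgroup Optional unquoted predicate evaluated in `data`.
#' @param group_col,id_col Column names.
#' @return A tibble of class `vt_pairwise`: `id`, `hospital`, `theta_a`,
#'   `theta_b`, `tau` (\eqn{\theta_b/\theta_a}), `log_tau`, `score_a`,
#'   `score_b`, `keep`.
#' @export
pairwise_effects <- function(data, a, b, model_a, model_b,
                             scorer_a, scorer_b, threshold = 0.05,
                             subgroup = NULL, group_col = "hospital",
                             id_col = "id") {
  check_scope(model_a, a, "model_a")
  check_scope(model_b, b, "model_b")
  sub <- rlang::enquo(subgroup)
  if (!rlang::quo_is_null(sub)) {
    data <- dplyr::filter(data, !!sub)
  }
  if (nrow(data) == 0) {
    warn("subgroup filter left 0 rows; returning an empty result")
    out <- tibble::tibble(
      id = integer(0), hospital = factor(), theta_a = numeric(0),
      theta_b = numeric(0), tau = numeric(0), log_tau = numeric(0),
      score_a = numeric(0), score_b = numeric(0), keep = logical(0)
    )
    return(structure(out, class = c("vt_pairwise", class(out)),
                     threshold = threshold, n_kept = 0L))
  }
  lbl <- as.character(data[[group_col]])
  ra <- counterfactual_risk(model_a, data, id_col,
                            use_oob = lbl == as.character(a))
  rb <- counterfactual_risk(model_b, data, id_col,
                            use_oob = lbl == as.character(b))
  sa <- score_anomaly(scorer_a, data, id_col = id_col)
  sb <- score_anomaly(scorer_b, data, id_col = id_col)
  keep <- flag_bad_twins(sa, threshold) & flag_bad_twins(sb, threshold)
  out <- tibble::tibble(
    id = data[[id_col]],
    hospital = data[[group_col]],
    theta_a = ra$risk,
    theta_b = rb$risk,
    tau = rb$risk / ra$risk,
    log_tau = log(rb$risk) - log(ra$risk),
    score_a = sa$score,
    score_b = sb$score,
    keep = keep
  )
  structure(out, class = c("vt_pairwise", class(out)),
            threshold = threshold, n_kept = sum(keep))
}

#' @rdname estimate_effects
#' @param x A `vt_estimates` tibble.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.vt_estimates <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$focal) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_kept = sum(.data$keep),
      n_in_h = sum(.data$origin == "in_h"),
      median_tau = stats::median(.data$tau[.data$keep]),
      q1_tau = stats::quantile(.data$tau[.data$keep], 0.25, names = FALSE),
      q3_tau = stats::quantile(.data$tau[.data$keep], 0.75, names = FALSE),
      .groups = "drop"
    )
}
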