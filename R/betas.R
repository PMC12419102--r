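#' Standardize log relative risks by the pooled sample SD
#'
#' Divides every log relative risk by the single sample standard
#' deviation of all supplied values (all hospitals pooled, before any
#' stratification), so that downstream hospital effects are on a common
#' unit-variance scale and panels stay comparable.
#'
#' @param log_rr Numeric vector of (kept) log relative risks.
#' @return The standardized vector; its pooled SD is exactly 1.
#' @export
standardize_log_rr <- function(log_rr) {
  if (sum(is.finite(log_rr)) < 2) {
    abort("need at least 2 finite log relative risks to standardize")
  }
  s <- stats::sd(log_rr)
  if (!is.finite(s) || s == 0) {
    abort("log relative risks have zero standard deviation; cannot standardize")
  }
  log_rr / s
}

#' Hospital-specific standardized effects from an ANOVA fit
#'
#' Fits a least-squares model of the standardized log relative risk on
#' hospital-specific intercepts (cell-means coding, no global intercept),
#' optionally with one independent variable as an additional term. The
#' reported effect is the *negated* intercept for each hospital, so that
#' a positive beta indicates superior performance (hospitals whose
#' patients have log relative risk below zero fare better there than at
#' the average hospital). With no covariate this reduces exactly to the
#' negated per-hospital mean.
#'
#' @param data Tibble holding the standardized values and hospital
#'   labels (and the covariate, if used).
#' @param value_col Column of standardized log relative risks.
#' @param hospital_col Column of hospital labels.
#' @param covariate_col Optional covariate column (continuous enters
#'   linearly; factors as cell means). Dropped with a warning if it is
#'   collinear with the hospital intercepts (e.g. constant within every
#'   hospital).
#' @return Tibble with columns `hospital`, `beta`, `n`.
#' @export
fit_beta <- function(data, value_col = "std_log_rr",
                     hospital_col = "focal", covariate_col = NULL) {
  check_cols(data, c(value_col, hospital_col, covariate_col))
  df <- data.frame(
    .value = data[[value_col]],
    .hospital = factor(as.character(data[[hospital_col]]))
  )
  have_cov <- !is.null(covariate_col)
  if (have_cov) df$.cov <- data[[covariate_col]]
  fml <- if (have_cov) .value ~ 0 + .hospital + .cov else .value ~ 0 + .hospital
  fit <- stats::lm(fml, data = df)
  coefs <- stats::coef(fit)
  if (have_cov && any(is.na(coefs[grep("^\\.cov", names(coefs))]))) {
    warn(sprintf(
      "covariate '%s' is collinear with hospital intercepts; dropping it",
      covariate_col))
    fit <- stats::lm(.value ~ 0 + .hospital, data = df)
    coefs <- stats::coef(fit)
  }
  hosp_terms <- grep("^\\.hospital", names(coefs))
  tibble::tibble(
    hospital = sub("^\\.hospital", "", names(coefs)[hosp_terms]),
    beta = -unname(coefs[hosp_terms]),
    n = as.integer(table(df$.hospital)[sub("^\\.hospital", "",
                                           names(coefs)[hosp_terms])])
  )
}

grade_levels <- c("A+", "A", "A-", "B+", "B", "B-", "C+", "C")

#' Letter grades from within-panel percentile ranks
#'
#' Ranks hospitals by their beta within one panel (one stratum x variable
#' combination) and maps the percentile rank into eight equal-width bins,
#' A+ (top) through C (bottom). Grades reflect relative standing only: a
#' hospital with a slightly negative beta can still earn an A-range grade
#' if it ranks high. Ties share the better grade; if every beta is equal,
#' every hospital receives A+.
#'
#' @param beta Numeric vector of hospital effects (one per hospital).
#' @return Factor of grades with levels `A+` .. `C`.
#' @export
assign_grades <- function(beta) {
  m <- length(beta)
  if (m == 0) return(factor(character(0), levels = grade_levels))
  r <- rank(-beta, ties.method = "min")
  pct <- (r - 1) / m
  bin <- pmin(floor(pct * 8) + 1L, 8L)
  factor(grade_levels[bin], levels = grade_levels)
}

#' Standardized-beta table across strata and variables
#'
#' The full grading summary: joins the causal estimates with the cohort's
#' covariates, standardizes the kept log relative risks once by their
#' pooled SD, then for every risk stratum (`low`, `medium`, `high`, plus
#' the unstratified `overall`) and every requested variable (plus the
#' intercept-only `"Overall"` panel) fits [fit_beta()] and assigns letter
#' grades within the panel.
#'
#' @param estimates A `vt_estimates` tibble, typically row-bound across
#'   all focal hospitals (see [estimate_effects()]).
#' @param cohort The cohort tibble (source of the covariate values);
#'   only needed when `variables` is non-empty.
#' @param variables Character vector of covariate columns to use as
#'   independent variables; default none (intercept-only panels).
#' @param id_col Id column used to join estimates to the cohort.
#' @return A tibble of class `vt_beta_table` with columns `hospital`,
#'   `stratum`, `variable`, `beta`, `grade`, `n`; the pooled SD used for
#'   standardization is attached as attribute `pooled_sd`.
#' @export
beta_table <- function(estimates, cohort = NULL, variables = character(0),
                       id_col = "id") {
  kept <- estimates[estimates$keep, , drop = FALSE]
  if (nrow(kept) < 2) abort("fewer than 2 kept estimates; nothing to grade")
  pooled_sd <- stats::sd(kept$log_tau)
  kept$std_log_rr <- standardize_log_rr(kept$log_tau)
  if (length(variables) > 0) {
    if (is.null(cohort)) abort("cohort is required when variables are given")
    check_cols(cohort, c(id_col, variables))
    kept <- dplyr::left_join(kept,
                             cohort[, c(id_col, variables), drop = FALSE],
                             by = id_col)
  }
  panels <- tidyr::expand_grid(
    stratum = c("low", "medium", "high", "overall"),
    variable = c("Overall", variables)
  )
  out <- purrr::pmap_dfr(panels, function(stratum, variable) {
    rows <- if (stratum == "overall") kept else
      kept[as.character(kept$stratum) == stratum, , drop = FALSE]
    if (nrow(rows) == 0) return(NULL)
    cov <- if (variable == "Overall") NULL else variable
    betas <- fit_beta(rows, value_col = "std_log_rr",
                      hospital_col = "focal", covariate_col = cov)
    betas$stratum <- stratum
    betas$variable <- variable
    betas$grade <- assign_grades(betas$beta)
    betas
  })
  out <- out[, c("hospital", "stratum", "variable", "beta", "grade", "n")]
  structure(out, class = c("vt_beta_table", class(out)),
            pooled_sd = pooled_sd)
}

#' Sorted per-variable effects for one hospital
#'
#' Extracts one hospital's standardized betas across all variables from a
#' [beta_table()] and sorts them from the largest positive to the largest
#' negative, the layout used to read off which patient characteristics a
#' hospital handles comparatively well.
#'
#' @param betas A `vt_beta_table`.
#' @param hospital Hospital label.
#' @param stratum Stratum to display (default `"overall"`).
#' @return Tibble sorted by decreasing `beta`.
#' @export
sorted_betas <- function(betas, hospital, stratum = "overall") {
  out <- betas[betas$hospital == as.character(hospital) &
                 betas$stratum == stratum &
                 betas$variable != "Overall", , drop = FALSE]
  dplyr::arrange(out, dplyr::desc(.data$beta))
}

#' Per-variable standardized slopes for a pairwise contrast
#'
#' For a head-to-head comparison from [pairwise_effects()], standardizes
#' the kept log relative risks by their pooled SD and regresses them on
#' each variable in turn (`std_log_rr ~ variable`). The reported beta is
#' the variable's slope: since positive standardized log relative risk
#' already means the first-listed hospital is better, a positive slope
#' identifies patient characteristics for which that hospital's advantage
#' grows. Output is sorted from the largest positive to the largest
#' negative slope.
#'
#' @param pairwise A `vt_pairwise` tibble.
#' @param cohort Cohort tibble carrying the variables.
#' @param variables Character vector of covariate columns.
#' @param id_col Id column for the join.
#' @return Tibble of class `vt_beta_sorted` with columns `variable`,
#'   `beta`, `n`, sorted by decreasing `beta`.
#' @export
pairwise_variable_betas <- function(pairwise, cohort, variables,
                                    id_col = "id") {
  kept <- pairwise[pairwise$keep, , drop = FALSE]
  if (nrow(kept) < 3) abort("fewer than 3 kept pairwise estimates")
  check_cols(cohort, c(id_col, variables))
  kept$std_log_rr <- standardize_log_rr(kept$log_tau)
  kept <- dplyr::left_join(kept, cohort[, c(id_col, variables), drop = FALSE],
                           by = id_col)
  out <- purrr::map_dfr(variables, function(v) {
    fit <- stats::lm(stats::reformulate(v, response = "std_log_rr"),
                     data = kept)
    tibble::tibble(variable = v,
                   beta = unname(stats::coef(fit)[2]),
                   n = nrow(kept))
  })
  out <- dplyr::arrange(out, dplyr::desc(.data$beta))
  structure(out, class = c("vt_beta_sorted", class(out)))
}
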