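#' Configuration for a synthetic multi-hospital cohort
#'
#' Builds and validates the parameter set for [simulate_cohort()]. The
#' simulator emulates the structure of a multi-centre surgical registry:
#' many hospitals of unequal size, a rare binary adverse outcome, hospital
#' effects on the logit scale, and hospital-specific covariate shift
#' (case-mix differences). Covariates are standard normal, optionally
#' equicorrelated; the true risk at hospital \eqn{h} is
#' \deqn{\theta_h(x) = \mathrm{logit}^{-1}(b_0 + x^\top w + \delta_h),}
#' and the risk at the pooled "overall hospital" is the size-weighted
#' mixture \eqn{\theta_O(x) = \sum_h \pi_h \theta_h(x)} with
#' \eqn{\pi_h = n(h)/n}: the risk a patient faces at a randomly drawn
#' system hospital. The true causal relative risk is
#' \eqn{\tau_h(x) = \theta_h(x)/\theta_O(x)}.
#'
#' @param n_hospitals Number of hospitals \eqn{H}.
#' @param sizes Integer vector of per-hospital patient counts \eqn{n(h)};
#'   recycled to length `n_hospitals`.
#' @param n_covariates Number of covariates \eqn{p}.
#' @param target_prevalence Desired mean outcome prevalence in (0,1).
#'   Rare adverse surgical events sit around 1-5%; the default 3% is a
#'   plausible operative-mortality regime.
#' @param effect_weights Length-`p` vector of covariate effects \eqn{w} on
#'   the logit scale. Default: `c(1, 0.8, 0.6, 0.5, 0.4)` padded with zeros,
#'   i.e. five informative covariates and the rest pure noise.
#' @param hospital_logit_shifts Length-`H` vector \eqn{\delta_h} of hospital
#'   effects on the logit scale (0 = average performance).
#' @param casemix_shifts Length-`H` vector of mean shifts applied to the
#'   covariates in `shift_features` for each hospital, producing case-mix
#'   differences and, when large, overlap violations.
#' @param shift_features Indices of the covariates that receive the
#'   case-mix shift (and anomaly displacement).
#' @param equicorrelation Common pairwise correlation of the covariates.
#' @param baseline_intercept Logit-scale intercept \eqn{b_0}; if `NULL`
#'   (default) it is auto-tuned by bisection so the mean true risk matches
#'   `target_prevalence`.
#' @param anomaly_fraction Fraction in \[0,1) of each hospital's rows that
#'   are deliberately displaced off-distribution (see
#'   [inject_anomalies()]); used to exercise the bad-twin filter.
#' @param anomaly_shift Displacement size in covariate standard deviations
#'   for the off-distribution rows.
#' @param seed Master seed; all stage-specific randomness is derived from
#'   it deterministically.
#'
#' @return An object of class `vt_sim_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_hospitals = 5,
                       sizes = 2000,
                       n_covariates = 10,
                       target_prevalence = 0.03,
                       effect_weights = NULL,
                       hospital_logit_shifts = 0,
                       casemix_shifts = 0,
                       shift_features = seq_len(min(3, n_covariates)),
                       equicorrelation = 0,
                       baseline_intercept = NULL,
                       anomaly_fraction = 0,
                       anomaly_shift = 6,
                       seed = 1) {
  H <- as.integer(n_hospitals)
  p <- as.integer(n_covariates)
  if (H < 1) abort("n_hospitals must be >= 1")
  if (p < 1) abort("n_covariates must be >= 1")
  sizes <- as.integer(rep_len(sizes, H))
  if (any(sizes < 1)) abort("all hospital sizes must be >= 1")
  if (!is.numeric(target_prevalence) || target_prevalence <= 0 ||
      target_prevalence >= 1) {
    abort("target_prevalence must lie strictly inside (0, 1)")
  }
  if (is.null(effect_weights)) {
    effect_weights <- c(1, 0.8, 0.6, 0.5, 0.4)[seq_len(min(5, p))]
  }
  effect_weights <- c(effect_weights, numeric(p))[seq_len(p)]
  hospital_logit_shifts <- rep_len(hospital_logit_shifts, H)
  if (any(!is.finite(hospital_logit_shifts))) {
    abort("hospital_logit_shifts must all be finite")
  }
  casemix_shifts <- rep_len(casemix_shifts, H)
  shift_features <- as.integer(shift_features)
  if (length(shift_features) == 0 || any(shift_features < 1) ||
      any(shift_features > p)) {
    abort("shift_features must index covariates 1..n_covariates")
  }
  if (equicorrelation < 0 || equicorrelation >= 1) {
    abort("equicorrelation must lie in [0, 1)")
  }
  if (anomaly_fraction < 0 || anomaly_fraction >= 1) {
    abort("anomaly_fraction must lie in [0, 1)")
  }
  structure(
    list(
      n_hospitals = H, sizes = sizes, n_covariates = p,
      target_prevalence = target_prevalence,
      effect_weights = as.numeric(effect_weights),
      hospital_logit_shifts = as.numeric(hospital_logit_shifts),
      casemix_shifts = as.numeric(casemix_shifts),
      shift_features = shift_features,
      equicorrelation = equicorrelation,
      baseline_intercept = baseline_intercept,
      anomaly_fraction = anomaly_fraction,
      anomaly_shift = anomaly_shift,
      seed = as.integer(seed)
    ),
    class = "vt_sim_config"
  )
}

#' @export
print.vt_sim_config <- function(x, ...) {
  cat("<vt_sim_config>\n")
  cat(sprintf("  hospitals: %d  (n = %d)\n", x$n_hospitals, sum(x$sizes)))
  cat(sprintf("  covariates: %d  target prevalence: %.3f\n",
              x$n_covariates, x$target_prevalence))
  cat(sprintf("  hospital logit shifts: %s\n",
              paste(format(x$hospital_logit_shifts), collapse = ", ")))
  cat(sprintf("  casemix shifts: %s\n",
              paste(format(x$casemix_shifts), collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Simulate a multi-hospital cohort with known ground truth
#'
#' Draws a patient-level cohort under the risk model described in
#' [sim_config()], returning both the observed table (covariates, hospital
#' label, one realised binary outcome per patient) and the full latent
#' truth: every patient's risk at every hospital, their risk at the pooled
#' overall hospital, the true causal relative risk, and coupled potential
#' outcomes (one uniform draw per patient thresholded against each
#' hospital's risk, so the observed outcome equals the potential outcome
#' at the assigned hospital).
#'
#' When `baseline_intercept` is `NULL` the intercept is tuned by bisection
#' on the realised covariates so that the mean assigned-hospital risk
#' equals `target_prevalence`; the realised event rate then fluctuates
#' binomially around the target.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `vt_cohort_sim` with elements:
#'   \describe{
#'     \item{cohort}{tibble with columns `id`, `hospital` (factor),
#'       `y` (0/1) and covariates `x1..xp`.}
#'     \item{truth}{long tibble with one row per patient x hospital:
#'       `id`, `hospital`, `theta` (\eqn{\theta_h(x)}), `theta_o`
#'       (\eqn{\theta_O(x)}), `tau` (\eqn{\theta_h/\theta_O}), `y_pot`
#'       (potential outcome at that hospital).}
#'     \item{config}{the input configuration, with the tuned intercept
#'       filled in.}
#'     \item{anomaly_ids}{ids of rows displaced off-distribution (empty
#'       unless `anomaly_fraction > 0`).}
#'   }
#' @examples
#' sim <- simulate_cohort(sim_config(n_hospitals = 3, sizes = 200, seed = 7))
#' dplyr::count(sim$cohort, hospital, y)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "vt_sim_config")) {
    abort("config must be built with sim_config()")
  }
  H <- config$n_hospitals
  p <- config$n_covariates
  sizes <- config$sizes
  n <- sum(sizes)
  hosp <- rep(seq_len(H), times = sizes)

  # covariates: equicorrelated normals plus per-hospital case-mix shift
  set.seed(child_seed(config$seed, 1))
  rho <- config$equicorrelation
  x <- matrix(stats::rnorm(n * p), n, p)
  if (rho > 0) {
    z0 <- stats::rnorm(n)
    x <- sqrt(rho) * z0 + sqrt(1 - rho) * x
  }
  shift_vec <- config$casemix_shifts[hosp]
  x[, config$shift_features] <- x[, config$shift_features] + shift_vec
  colnames(x) <- paste0("x", seq_len(p))

  anomaly_ids <- integer(0)
  if (config$anomaly_fraction > 0) {
    set.seed(child_seed(config$seed, 2))
    for (h in seq_len(H)) {
      rows_h <- which(hosp == h)
      k <- round(config$anomaly_fraction * length(rows_h))
      if (k > 0) {
        pick <- sample(rows_h, k)
        x[pick, config$shift_features] <-
          x[pick, config$shift_features] + config$anomaly_shift
        anomaly_ids <- c(anomaly_ids, pick)
      }
    }
    anomaly_ids <- sort(anomaly_ids)
  }

  eta <- drop(x %*% config$effect_weights)
  delta <- config$hospital_logit_shifts

  b0 <- config$baseline_intercept
  if (is.null(b0)) {
    own_shift <- delta[hosp]
    target <- config$target_prevalence
    f <- function(b) mean(stats::plogis(b + eta + own_shift)) - target
    lo <- -40; hi <- 10
    if (f(lo) > 0 || f(hi) < 0) abort("cannot tune intercept to target prevalence")
    for (i in 1:80) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    b0 <- (lo + hi) / 2
  }

  # theta[, h]: risk of each patient at hospital h; theta_o is the
  # size-weighted mixture (risk at a randomly drawn system hospital)
  theta <- stats::plogis(outer(b0 + eta, delta, `+`))
  pi_h <- sizes / n
  theta_o <- drop(theta %*% pi_h)

  set.seed(child_seed(config$seed, 3))
  u <- stats::runif(n)
  y_pot <- theta > u          # n x H matrix of coupled potential outcomes
  y <- as.integer(y_pot[cbind(seq_len(n), hosp)])

  cohort <- tibble::tibble(
    id = seq_len(n),
    hospital = factor(hosp, levels = seq_len(H)),
    y = y
  )
  cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(x))

  theta_vec <- as.vector(theta)
  theta_o_vec <- rep(theta_o, times = H)
  truth <- tibble::tibble(
    id = rep(seq_len(n), times = H),
    hospital = factor(rep(seq_len(H), each = n), levels = seq_len(H)),
    theta = theta_vec,
    theta_o = theta_o_vec,
    tau = theta_vec / theta_o_vec,
    y_pot = as.integer(y_pot)
  )

  config$baseline_intercept <- b0
  structure(
    list(cohort = cohort, truth = truth, config = config,
         anomaly_ids = anomaly_ids),
    class = "vt_cohort_sim"
  )
}

#' @export
print.vt_cohort_sim <- function(x, ...) {
  cat("<vt_cohort_sim>\n")
  cat(sprintf("  n = %d patients, %d hospitals, %d covariates\n",
              nrow(x$cohort), nlevels(x$cohort$hospital),
              x$config$n_covariates))
  cat(sprintf("  observed prevalence: %.4f (target %.4f)\n",
              mean(x$cohort$y), x$config$target_prevalence))
  if (length(x$anomaly_ids) > 0) {
    cat(sprintf("  off-distribution rows: %d\n", length(x$anomaly_ids)))
  }
  invisible(x)
}

#' Displace a fraction of one hospital's rows off-distribution
#'
#' Moves a random subset of one hospital's patients away from the bulk of
#' the covariate distribution by `shift` standard deviations on a covariate
#' subset, emulating patients without valid counterfactual support. The
#' outcome column is left untouched. Used to exercise the bad-virtual-twin
#' filter ([flag_bad_twins()]).
#'
#' @param cohort A cohort tibble (as produced by [simulate_cohort()]).
#' @param group Hospital label whose rows are displaced.
#' @param fraction Fraction in \[0,1) of the group's rows to displace.
#' @param shift Displacement in units of each feature's sample standard
#'   deviation (computed over the whole table).
#' @param features Character vector of covariate columns to displace;
#'   default the first three `x*` columns.
#' @param group_col,seed Group column name and RNG seed.
#' @return The cohort tibble with displaced covariates; the displaced row
#'   ids are attached as attribute `"displaced_ids"`.
#' @export
inject_anomalies <- function(cohort, group, fraction, shift = 6,
                             features = NULL, group_col = "hospital",
                             seed = 1) {
  check_cols(cohort, group_col)
  if (fraction < 0 || fraction >= 1) abort("fraction must lie in [0, 1)")
  g <- cohort[[group_col]]
  rows_g <- which(as.character(g) == as.character(group))
  if (length(rows_g) == 0) {
    abort(sprintf("group '%s' not present in column '%s'", group, group_col))
  }
  if (is.null(features)) {
    xcols <- grep("^x[0-9]+$", names(cohort), value = TRUE)
    features <- utils::head(xcols, 3)
  }
  check_cols(cohort, features, "feature column")
  k <- round(fraction * length(rows_g))
  if (k == 0) {
    attr(cohort, "displaced_ids") <- integer(0)
    return(cohort)
  }
  set.seed(seed)
  pick <- sort(sample(rows_g, k))
  for (f in features) {
    cohort[[f]][pick] <- cohort[[f]][pick] + shift * stats::sd(cohort[[f]])
  }
  ids <- if ("id" %in% names(cohort)) cohort$id[pick] else pick
  attr(cohort, "displaced_ids") <- ids
  cohort
}

#' Write a simulated cohort to disk
#'
#' Writes `cohort.csv` (columns id, hospital, y, x1..xp), `truth.csv`
#' (the long ground-truth table) and `config.yaml` into `dir`.
#'
#' @param sim A `vt_cohort_sim` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "vt_cohort_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(sim$cohort, file.path(dir, "cohort.csv"))
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"))
  cfg <- sim$config
  cfg$sizes <- as.integer(cfg$sizes)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a patient-level cohort table from CSV
#'
#' Expects a header row with a group column, a binary outcome column and
#' covariate columns; the group column is converted to a factor.
#'
#' @param path CSV file path.
#' @param group_col,outcome_col Column names for the hospital label and
#'   binary outcome.
#' @return A tibble.
#' @export
read_cohort <- function(path, group_col = "hospital", outcome_col = "y") {
  cohort <- readr::read_csv(path, show_col_types = FALSE)
  check_cols(cohort, c(group_col, outcome_col))
  check_binary_outcome(cohort[[outcome_col]], outcome_col)
  cohort[[group_col]] <- factor(cohort[[group_col]])
  cohort
}
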