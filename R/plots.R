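#' Hospital effect plot: stratified relative-risk boxplots
#'
#' Boxplots of the kept causal relative risks \eqn{\hat\tau_h(x)} per
#' hospital, faceted by risk stratum (low / medium / high / overall),
#' drawn on a logarithmic relative-risk axis so that reciprocal pairs sit
#' symmetrically about the reference line at 1 (the distance 1 to 2
#' equals the distance 1 to 0.5). Box widths are scaled to the kept
#' sample size of each hospital - wider boxes are larger hospitals.
#' Whiskers extend to the most extreme value within 1.5 IQR of the box.
#'
#' @param estimates A `vt_estimates` tibble (row-bound across focal
#'   hospitals).
#' @param width_scale `"linear"` (width proportional to kept n, default)
#'   or `"sqrt"`.
#' @param whisker_mult Whisker reach in IQR multiples (default 1.5).
#' @return A ggplot object. The numeric box statistics are attached as
#'   attribute `"plot_data"` so the graphic can be regenerated.
#' @export
plot_hospital_effects <- function(estimates, width_scale = c("linear", "sqrt"),
                                  whisker_mult = 1.5) {
  width_scale <- match.arg(width_scale)
  kept <- estimates[estimates$keep, , drop = FALSE]
  if (nrow(kept) == 0) abort("no kept estimates to plot")
  kept$stratum <- as.character(kept$stratum)
  both <- dplyr::bind_rows(kept, dplyr::mutate(kept, stratum = "overall"))
  both$stratum <- factor(both$stratum,
                         levels = c("low", "medium", "high", "overall"))
  stats_tbl <- both |>
    dplyr::group_by(.data$focal, .data$stratum) |>
    dplyr::summarise(
      n = dplyr::n(),
      q1 = stats::quantile(.data$tau, 0.25, names = FALSE),
      med = stats::median(.data$tau),
      q3 = stats::quantile(.data$tau, 0.75, names = FALSE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      iqr = .data$q3 - .data$q1,
      lo = .data$q1 - whisker_mult * .data$iqr,
      hi = .data$q3 + whisker_mult * .data$iqr
    )
  whisk <- both |>
    dplyr::left_join(stats_tbl, by = c("focal", "stratum")) |>
    dplyr::group_by(.data$focal, .data$stratum) |>
    dplyr::summarise(
      wlo = min(.data$tau[.data$tau >= .data$lo]),
      whi = max(.data$tau[.data$tau <= .data$hi]),
      .groups = "drop"
    )
  stats_tbl <- dplyr::left_join(stats_tbl, whisk, by = c("focal", "stratum"))
  wmax <- max(stats_tbl$n)
  stats_tbl$w <- if (width_scale == "linear") {
    0.8 * stats_tbl$n / wmax
  } else {
    0.8 * sqrt(stats_tbl$n / wmax)
  }
  stats_tbl$xpos <- as.numeric(factor(stats_tbl$focal))

  p <- ggplot2::ggplot(stats_tbl) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$xpos, xend = .data$xpos,
                                       y = .data$wlo, yend = .data$q1)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$xpos, xend = .data$xpos,
                                       y = .data$q3, yend = .data$whi)) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$xpos - .data$w / 2,
                                    xmax = .data$xpos + .data$w / 2,
                                    ymin = .data$q1, ymax = .data$q3),
                       fill = "grey85", colour = "grey25") +
    ggplot2::geom_segment(ggplot2::aes(x = .data$xpos - .data$w / 2,
                                       xend = .data$xpos + .data$w / 2,
                                       y = .data$med, yend = .data$med),
                          linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::scale_x_continuous(
      breaks = sort(unique(stats_tbl$xpos)),
      labels = levels(factor(stats_tbl$focal))
    ) +
    ggplot2::facet_wrap(~stratum, nrow = 1) +
    ggplot2::labs(x = "hospital", y = "causal relative risk (log scale)",
                  title = "Hospital effects vs the overall hospital",
                  subtitle = "box width proportional to kept sample size; below 1 = better than average")
  attr(p, "plot_data") <- stats_tbl
  p
}

#' Anomaly-score density plot with the bad-twin cutoff
#'
#' Kernel density of the calibrated anomaly scores per hospital with a
#' thin vertical line at the cutoff `C`. Mass piling up near zero signals
#' hospitals whose case mix leaves many patients without valid virtual
#' twins. Groups with fewer than 10 scores fall back to a histogram.
#'
#' @param scores Tibble with columns `hospital` and `score` (e.g. the
#'   estimates table, using `focal`-scorer scores, or [score_anomaly()]
#'   output augmented with a hospital column).
#' @param threshold The cutoff `C` to mark.
#' @param score_col,group_col Column names.
#' @return A ggplot object.
#' @export
plot_anomaly_density <- function(scores, threshold = 0.05,
                                 score_col = "anomaly_score",
                                 group_col = "focal") {
  check_cols(scores, c(score_col, group_col))
  s <- scores[[score_col]]
  if (any(s < 0 | s > 1)) abort("scores must lie in [0, 1]")
  df <- tibble::tibble(score = s,
                       hospital = factor(scores[[group_col]]))
  small <- min(table(df$hospital)) < 10
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$score))
  p <- if (small) {
    p + ggplot2::geom_histogram(bins = 20, fill = "grey80", colour = "grey30")
  } else {
    p + ggplot2::geom_density(fill = "grey80", colour = "grey30")
  }
  p +
    ggplot2::geom_vline(xintercept = threshold, linewidth = 0.3,
                        colour = "red") +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::facet_wrap(~hospital, scales = "free_y") +
    ggplot2::labs(x = "calibrated anomaly score",
                  y = "density",
                  title = "Isolation-forest anomaly scores by hospital",
                  subtitle = sprintf("scores below C = %.2f flag bad virtual twins", threshold))
}

#' Standardized-beta grade panels
#'
#' Dot plot of each hospital's standardized beta per (stratum x variable)
#' panel, labelled with its letter grade. Positive betas (better than the
#' average hospital) plot blue, negative red.
#'
#' @param betas A [beta_table()] result.
#' @return A ggplot object.
#' @export
plot_beta_grades <- function(betas) {
  df <- tibble::as_tibble(betas)
  df$stratum <- factor(df$stratum, levels = c("low", "medium", "high", "overall"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = .data$hospital)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$beta > 0), size = 2,
                        show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$grade), hjust = -0.5,
                       size = 3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "steelblue",
                                            `FALSE` = "firebrick")) +
    ggplot2::facet_grid(variable ~ stratum) +
    ggplot2::labs(x = "standardized beta (positive = better)",
                  y = "hospital",
                  title = "Hospital grades by risk stratum")
}

#' Sorted standardized-beta bars
#'
#' Horizontal bars of per-variable standardized betas sorted from the
#' largest positive to the largest negative, for a single hospital
#' ([sorted_betas()]) or a pairwise contrast
#' ([pairwise_variable_betas()]). Blue bars favour the (first) hospital,
#' red bars the comparator.
#'
#' @param betas Tibble with columns `variable` and `beta`, already
#'   sorted.
#' @return A ggplot object.
#' @export
plot_beta_sorted <- function(betas) {
  df <- tibble::as_tibble(betas)
  df$variable <- factor(df$variable, levels = rev(df$variable))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = .data$variable,
                                   fill = .data$beta > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "firebrick")) +
    ggplot2::labs(x = "standardized beta", y = NULL,
                  title = "Per-variable standardized effects")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plot_hospital_effects
#' @param object,... `autoplot` method arguments.
#' @exportS3Method ggplot2::autoplot
autoplot.vt_estimates <- function(object, ...) {
  plot_hospital_effects(object, ...)
}

#' @rdname plot_beta_grades
#' @param object,... `autoplot` method arguments.
#' @exportS3Method ggplot2::autoplot
autoplot.vt_beta_table <- function(object, ...) plot_beta_grades(object)

#' @rdname plot_beta_sorted
#' @param object,... `autoplot` method arguments.
#' @exportS3Method ggplot2::autoplot
autoplot.vt_beta_sorted <- function(object, ...) plot_beta_sorted(object)
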