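#' Plot a threshold scan
#'
#' Unadjusted, Bonferroni- and permutation-FWER-adjusted p-values across
#' the scanned cutoffs, with the conventional 0.05 reference line.
#'
#' @param object a `margin_scan` from [margin_scan()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.margin_scan <- function(object, ...) {
  long <- as_tibble(object) %>%
    select("cutoff", "p_unadj", "p_bonf", "p_fwer") %>%
    tidyr::pivot_longer(-"cutoff", names_to = "adjustment",
                        values_to = "p") %>%
    mutate(adjustment = factor(.data$adjustment,
                               levels = c("p_unadj", "p_bonf", "p_fwer"),
                               labels = c("unadjusted", "Bonferroni",
                                          "permutation FWER")))
  ggplot2::ggplot(long, ggplot2::aes(.data$cutoff, .data$p,
                                     colour = .data$adjustment)) +
    ggplot2::geom_hline(yintercept = 0.05, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "margin cutoff (mm)", y = "two-sided p-value",
                  colour = NULL,
                  title = "Margin-threshold scan with multiplicity control") +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object a `roc_curve` from [roc_from_scores()] or [logit_roc()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.roc_curve <- function(object, ...) {
  dat <- as_tibble(object) %>% arrange(1 - .data$specificity, .data$sensitivity)
  ggplot2::ggplot(dat, ggplot2::aes(1 - .data$specificity,
                                    .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC curve (AUC = %.2f)",
                                  attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' Bar chart of recurrence rates by margin category
#'
#' @param cohort a cohort tibble.
#' @return a ggplot.
#' @export
plot_category_rates <- function(cohort) {
  rates <- category_rates(cohort) %>%
    mutate(margin_category = factor(.data$margin_category,
                                    levels = margin_levels,
                                    labels = c("< 1 mm", "1–5 mm",
                                               "> 5 mm", "missing")))
  ggplot2::ggplot(rates, ggplot2::aes(.data$margin_category,
                                      .data$rate_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d/%d", .data$events, .data$n)), vjust = -0.4) +
    ggplot2::labs(x = "resection margin category",
                  y = "local recurrence rate (%)") +
    ggplot2::theme_minimal()
}

#' Predicted recurrence-probability curves by radiotherapy status
#'
#' Evaluates [recurrence_curve()] with and without radiotherapy and draws
#' both curves; exploratory — thresholds should not be read off the curves.
#'
#' @param fit a [fit_recurrence_logit()] with a continuous margin term.
#' @param margin_grid numeric grid of margins in mm.
#' @return a ggplot.
#' @export
plot_recurrence_curves <- function(fit, margin_grid = seq(0.1, 8, by = 0.1)) {
  has_rt <- "rtTRUE" %in% names(fit$coefficients)
  dat <- if (has_rt) {
    bind_rows(recurrence_curve(fit, margin_grid, rt = TRUE),
              recurrence_curve(fit, margin_grid, rt = FALSE))
  } else {
    recurrence_curve(fit, margin_grid, rt = FALSE)
  }
  dat$arm <- ifelse(dat$rt, "radiotherapy", "no radiotherapy")
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$margin_mm,
                                         .data$probability))
  p <- if (has_rt) {
    p + ggplot2::geom_line(ggplot2::aes(colour = .data$arm))
  } else {
    p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "resection margin (mm)",
                    y = "predicted recurrence probability", colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
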