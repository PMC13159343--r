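#' ROC curve from scores and binary labels
#'
#' Builds the receiver operating characteristic curve over all distinct
#' score thresholds (a case is called positive when its score is at or
#' above the threshold), computes the area under the curve by the
#' trapezoidal rule — which equals the Mann-Whitney concordance estimator
#' with half credit for ties — and the Youden-optimal threshold maximising
#' `J = sensitivity + specificity - 1`, breaking ties towards the
#' higher-specificity (higher) threshold.
#'
#' @param scores numeric risk scores; higher means more likely positive.
#' @param labels logical (or 0/1) outcome labels.
#' @return a tibble of class `roc_curve` with columns `threshold`,
#'   `sensitivity`, `specificity`, `youden_j` and attributes `auc`,
#'   `youden_threshold`, `youden_sensitivity`, `youden_specificity`,
#'   `n_pos`, `n_neg`.
#' @export
roc_from_scores <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort("both classes must be present to build a ROC curve")
  }
  thr <- c(sort(unique(scores)), Inf)   # Inf: the all-negative corner
  sens <- vapply(thr, function(t) sum(scores[labels] >= t) / n_pos,
                 numeric(1))
  spec <- vapply(thr, function(t) sum(scores[!labels] < t) / n_neg,
                 numeric(1))
  curve <- tibble(threshold = thr, sensitivity = sens, specificity = spec,
                  youden_j = sens + spec - 1)
  # trapezoid over (1 - specificity, sensitivity), sorted by FPR
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  xs <- c(0, fpr[ord], 1); ys <- c(0, sens[ord], 1)
  auc <- sum(diff(xs) * (head(ys, -1) + ys[-1]) / 2)
  best_j <- max(curve$youden_j)
  best <- curve %>%
    filter(abs(.data$youden_j - best_j) < 1e-12) %>%
    arrange(dplyr::desc(.data$specificity), dplyr::desc(.data$threshold)) %>%
    head(1)
  structure(curve, class = c("roc_curve", class(curve)),
            auc = auc,
            youden_threshold = best$threshold,
            youden_sensitivity = best$sensitivity,
            youden_specificity = best$specificity,
            n_pos = n_pos, n_neg = n_neg)
}

#' @exportS3Method generics::glance
glance.roc_curve <- function(x, ...) {
  tibble(auc = attr(x, "auc"),
         youden_threshold = attr(x, "youden_threshold"),
         youden_sensitivity = attr(x, "youden_sensitivity"),
         youden_specificity = attr(x, "youden_specificity"),
         n_pos = attr(x, "n_pos"), n_neg = attr(x, "n_neg"))
}

#' ROC analysis of a fitted recurrence model
#'
#' Scores every record used in the fit with its predicted recurrence
#' probability and builds the ROC curve.  For a margin-only model the
#' Youden-optimal probability threshold is also mapped back to the margin
#' scale by inverting the (monotone) linear predictor; for multi-predictor
#' models the threshold is reported on the score scale only, since a
#' probability cutoff then has no unique margin equivalent.
#'
#' @param fit a [fit_recurrence_logit()] object.
#' @return a `roc_curve`; for margin-only models with attribute
#'   `youden_margin_mm`.
#' @export
logit_roc <- function(fit) {
  stopifnot(inherits(fit, "recurrence_logit"))
  roc <- roc_from_scores(predict(fit), fit$y == 1)
  cf <- fit$coefficients
  if (identical(sort(names(cf)), sort(c("(Intercept)", "margin_mm"))) &&
      cf[["margin_mm"]] != 0) {
    thr <- attr(roc, "youden_threshold")
    if (is.finite(thr) && thr > 0 && thr < 1) {
      attr(roc, "youden_margin_mm") <-
        (qlogis(thr) - cf[["(Intercept)"]]) / cf[["margin_mm"]]
    }
  }
  roc
}

#' Bootstrap stability of the dichotomized-margin odds ratio
#'
#' Resamples records with replacement at the original size, refits the
#' logistic recurrence model, and records the odds ratio of the margin term
#' in every resample.  Resamples that fail to converge, are quasi-separated
#' or degenerate (single outcome class) are counted and excluded from the
#' percentile summaries.  With small cohorts and sparse events the
#' dispersion is typically wide — the instability this analysis is meant
#' to expose.
#'
#' @param cohort a cohort tibble.
#' @param predictors as in [fit_recurrence_logit()].
#' @param dichotomize_at margin cutoff in mm for the margin term
#'   (default 0.3).
#' @param n_resamples number of bootstrap resamples (default 2000).
#' @param seed RNG seed.
#' @return an object of class `or_bootstrap`: the per-resample odds ratios
#'   (`NA` where excluded), percentile summaries (2.5th, 50th, 97.5th), the
#'   failure count, and an `unreliable` flag when more than half the
#'   resamples failed.  Supports [tidy()] and [glance()].
#' @export
bootstrap_or <- function(cohort, predictors = c("margin", "rt"),
                         dichotomize_at = 0.3, n_resamples = 2000,
                         seed = NULL) {
  cohort <- as_cohort(cohort)
  dat <- complete_cases(cohort)
  if ("margin" %in% predictors) dat <- filter(dat, !is.na(.data$margin_mm))
  stopifnot(n_resamples >= 1)
  term <- if (is.null(dichotomize_at)) "margin_mm" else
    sprintf("margin_ge_%g", dichotomize_at)
  ors <- with_seed_if(seed, {
    vapply(seq_len(n_resamples), function(b) {
      idx <- sample.int(nrow(dat), replace = TRUE)
      boot <- dat[idx, ]
      if (length(unique(boot$lr)) < 2) return(NA_real_)
      fit <- tryCatch(
        fit_recurrence_logit(boot, predictors = predictors,
                             dichotomize_at = dichotomize_at),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged || fit$separation_warning) {
        return(NA_real_)
      }
      if (!term %in% names(fit$coefficients)) return(NA_real_)
      exp(fit$coefficients[[term]])
    }, numeric(1))
  })
  n_failed <- sum(is.na(ors))
  qs <- quantile(ors, c(0.025, 0.5, 0.975), na.rm = TRUE, type = 7)
  structure(list(
    or = ors,
    percentiles = tibble(quantile = c(0.025, 0.5, 0.975),
                         odds_ratio = unname(qs)),
    n_resamples = n_resamples, n_failed = n_failed,
    unreliable = n_failed > n_resamples / 2,
    term = term, seed = seed
  ), class = "or_bootstrap")
}

#' @exportS3Method generics::tidy
tidy.or_bootstrap <- function(x, ...) x$percentiles

#' @exportS3Method generics::glance
glance.or_bootstrap <- function(x, ...) {
  tibble(term = x$term, n_resamples = x$n_resamples, n_failed = x$n_failed,
         unreliable = x$unreliable,
         or_p2.5 = x$percentiles$odds_ratio[1],
         or_median = x$percentiles$odds_ratio[2],
         or_p97.5 = x$percentiles$odds_ratio[3])
}

#' @export
print.or_bootstrap <- function(x, ...) {
  cat(sprintf(
    "Bootstrap odds-ratio stability for %s: %d resamples (%d excluded)%s\n",
    x$term, x$n_resamples, x$n_failed,
    if (x$unreliable) " ** unreliable **" else ""))
  print(x$percentiles, ...)
  invisible(x)
}
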