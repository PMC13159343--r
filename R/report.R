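#' Configuration of a full analysis run
#'
#' @param input `"reconstructed"` (the canonical cohort), `"simulated"`, or
#'   a path to a cohort CSV.
#' @param sim_params a [sim_params()], used when `input = "simulated"`.
#' @param scan a [scan_config()].
#' @param predictors,dichotomize_at model specification for the logistic
#'   stage (see [fit_recurrence_logit()]).
#' @param n_bootstrap bootstrap resamples for the odds-ratio stability
#'   stage (default 2000; 0 skips the stage).
#' @param out_dir output directory for the report files (`NULL` = do not
#'   write files).
#' @param seed global seed, propagated to every stochastic stage that has
#'   no seed of its own.
#' @return a `run_config` list.
#' @export
run_config <- function(input = "reconstructed",
                       sim_params = marginscan::sim_params(),
                       scan = scan_config(),
                       predictors = c("margin", "rt"),
                       dichotomize_at = 0.3,
                       n_bootstrap = 2000,
                       out_dir = NULL,
                       seed = 1) {
  stopifnot(is.character(input), length(input) == 1)
  if (is.null(scan$seed)) scan$seed <- seed
  if (input == "simulated" && is.null(sim_params$seed)) {
    sim_params$seed <- seed
  }
  structure(list(input = input, sim_params = sim_params, scan = scan,
                 predictors = predictors, dichotomize_at = dichotomize_at,
                 n_bootstrap = n_bootstrap, out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Run the full margin-recurrence analysis
#'
#' Orchestrates every stage on one cohort, in the order of the original
#' analysis: margin distribution summary, recurrence rates by margin
#' category, the margin-by-radiotherapy cross-tabulation, the crude
#' radiotherapy comparison, the threshold scan with Bonferroni and
#' permutation FWER adjustment, and the exploratory logistic / ROC /
#' bootstrap stage.  The run is deterministic given the configuration; a
#' stage that fails is recorded in `$errors` and the run continues.  When
#' `out_dir` is set, the bundle is written as `report.json` (p-values
#' unrounded, with 3-decimal renderings alongside), `cohort.csv`, and
#' threshold-table and crosstab-shaped CSVs.
#'
#' @param config a [run_config()].
#' @return a list of class `margin_report` with elements `cohort`,
#'   `margin_summary`, `category_rates`, `crosstab`, `rt_comparison`,
#'   `scan`, `logistic`, `roc`, `bootstrap`, `config`, `errors`.
#' @export
run_full_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- switch(config$input,
    reconstructed = reconstruct_full_cohort(),
    simulated = simulate_cohort(config$sim_params),
    read_cohort_csv(config$input)
  )
  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  m <- scan_cases(cohort)$margin_mm
  margin_summary <- tibble(
    n_documented = length(m),
    n_at_floor = sum(m == 0.1),
    median = median(m),
    q1 = unname(quantile(m, 0.25, type = 7)),
    q3 = unname(quantile(m, 0.75, type = 7)),
    min = min(m), max = max(m)
  )
  rates <- stage("category_rates", category_rates(cohort))
  xtab <- stage("crosstab", margin_rt_crosstab(cohort))
  rtcmp <- stage("rt_comparison", rt_crude_comparison(cohort))
  scan <- stage("scan", margin_scan(cohort, config$scan))
  fit <- stage("logistic", fit_recurrence_logit(
    cohort, predictors = config$predictors,
    dichotomize_at = config$dichotomize_at))
  roc <- if (!is.null(fit)) stage("roc", logit_roc(fit)) else NULL
  boot <- if (config$n_bootstrap > 0) {
    stage("bootstrap", bootstrap_or(
      cohort, predictors = config$predictors,
      dichotomize_at = config$dichotomize_at,
      n_resamples = config$n_bootstrap, seed = config$seed))
  } else NULL
  report <- structure(list(
    cohort = cohort, margin_summary = margin_summary,
    category_rates = rates, crosstab = xtab, rt_comparison = rtcmp,
    scan = scan, logistic = fit, roc = roc, bootstrap = boot,
    config = config, errors = errors
  ), class = "margin_report")
  if (!is.null(config$out_dir)) write_report_bundle(report, config$out_dir)
  report
}

write_report_bundle <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_csv(report$cohort, file.path(out_dir, "cohort.csv"))
  if (!is.null(report$scan)) {
    readr::write_csv(render_scan_table(report$scan),
                     file.path(out_dir, "threshold_table.csv"))
  }
  if (!is.null(report$crosstab)) {
    readr::write_csv(report$crosstab, file.path(out_dir, "crosstab.csv"))
  }
  json <- list(
    config = list(
      input = report$config$input, seed = report$config$seed,
      min_group_size = report$config$scan$min_group_size,
      n_permutations = report$config$scan$n_permutations,
      estimator = report$config$scan$estimator,
      predictors = report$config$predictors,
      dichotomize_at = report$config$dichotomize_at,
      n_bootstrap = report$config$n_bootstrap
    ),
    margin_summary = report$margin_summary,
    category_rates = report$category_rates,
    crosstab = report$crosstab,
    rt_comparison = report$rt_comparison,
    scan = if (!is.null(report$scan)) {
      c(as.list(as_tibble(report$scan)),
        list(p_unadj_3dp = round(report$scan$p_unadj, 3),
             p_bonf_3dp = round(report$scan$p_bonf, 3),
             p_fwer_3dp = round(report$scan$p_fwer, 3),
             m = attr(report$scan, "m"),
             B_used = attr(report$scan, "B_used")))
    },
    logistic = if (!is.null(report$logistic)) {
      c(as.list(tidy(report$logistic)), as.list(glance(report$logistic)))
    },
    roc = if (!is.null(report$roc)) as.list(glance(report$roc)),
    bootstrap = if (!is.null(report$bootstrap)) {
      as.list(glance(report$bootstrap))
    },
    errors = report$errors
  )
  jsonlite::write_json(json[!vapply(json, is.null, logical(1))],
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# Threshold-table-shaped rendering: counts plus 3-decimal p-values.
render_scan_table <- function(scan) {
  tibble(cutoff = scan$cutoff,
         n_below = scan$n_below, n_at_or_above = scan$n_at_or_above,
         lr_below = scan$lr_below, lr_at_or_above = scan$lr_at_or_above,
         p_unadj = sprintf("%.3f", scan$p_unadj),
         p_bonf = sprintf("%.3f", scan$p_bonf),
         p_fwer = sprintf("%.3f", scan$p_fwer))
}

#' @export
print.margin_report <- function(x, ...) {
  cat("Margin-recurrence analysis report\n")
  cat(sprintf("  input: %s; n = %d (%d margin-documented, %d complete-case)\n",
              x$config$input, nrow(x$cohort),
              sum(!is.na(x$cohort$margin_mm)), sum(!is.na(x$cohort$lr))))
  if (!is.null(x$scan) && nrow(x$scan) > 0) {
    best <- x$scan[which.min(x$scan$p_unadj), ]
    cat(sprintf(
      "  scan: %d cutoffs; smallest p_unadj %.3f at %.1f mm (Bonferroni %.3f, permutation FWER %.3f)\n",
      attr(x$scan, "m"), best$p_unadj, best$cutoff, best$p_bonf, best$p_fwer))
  }
  if (length(x$errors) > 0) {
    cat("  failed stages:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}
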