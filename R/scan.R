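#' Configuration of a margin-threshold scan
#'
#' @param min_group_size minimum size of both the below-cutoff and
#'   at-or-above-cutoff groups for a cutoff to enter the scan (default 6,
#'   the smallest value under which the canonical cohort yields exactly the
#'   eight published candidate cutoffs).
#' @param candidate_rule `"distinct_observed"` (candidates are the distinct
#'   observed margins; default) or `"fixed_grid"`.
#' @param grid_start,grid_stop,grid_step grid in mm, used only by
#'   `"fixed_grid"` and by [scan_profile()] (defaults 0.1, 6.0, 0.1).
#' @param n_permutations number of label permutations for the min-p
#'   family-wise error adjustment (default 5000).
#' @param seed RNG seed for the permutations (`NULL` = use current state).
#' @param estimator `"add_one"` (default; permutation p is
#'   `(1 + count) / (B + 1)`, strictly positive and valid) or `"plug_in"`
#'   (`count / B`).
#' @return a `scan_config` list.
#' @export
scan_config <- function(min_group_size = 6,
                        candidate_rule = c("distinct_observed", "fixed_grid"),
                        grid_start = 0.1, grid_stop = 6.0, grid_step = 0.1,
                        n_permutations = 5000, seed = NULL,
                        estimator = c("add_one", "plug_in")) {
  candidate_rule <- arg_match(candidate_rule)
  estimator <- arg_match(estimator)
  stopifnot(min_group_size >= 1, n_permutations >= 1,
            grid_start < grid_stop, grid_step > 0)
  structure(list(min_group_size = as.integer(min_group_size),
                 candidate_rule = candidate_rule,
                 grid_start = grid_start, grid_stop = grid_stop,
                 grid_step = grid_step,
                 n_permutations = as.integer(n_permutations),
                 seed = seed, estimator = estimator),
            class = "scan_config")
}

#' Enumerate admissible dichotomization cutoffs
#'
#' A candidate cutoff `c` splits the cohort into margins `< c` and `>= c`.
#' Under the `"distinct_observed"` rule candidates are the distinct observed
#' margin values; a candidate is admissible when both groups reach
#' `min_group_size`.  Under `"fixed_grid"` candidates come from the
#' configured grid instead.
#'
#' @param margins numeric vector of documented margins (mm).
#' @param config a [scan_config()].
#' @return sorted numeric vector of admissible cutoffs (warns when empty).
#' @export
enumerate_cutoffs <- function(margins, config = scan_config()) {
  stopifnot(length(margins) > 0, !anyNA(margins))
  cand <- if (config$candidate_rule == "distinct_observed") {
    sort(unique(margins))
  } else {
    # round away the accumulation error of seq() so grid points compare
    # cleanly against one-decimal margins
    round(seq(config$grid_start, config$grid_stop, by = config$grid_step), 10)
  }
  ok <- vapply(cand, function(c0) {
    nb <- sum(margins < c0)
    nb >= config$min_group_size &&
      (length(margins) - nb) >= config$min_group_size
  }, logical(1))
  out <- cand[ok]
  if (length(out) == 0) warn("no admissible cutoff under min_group_size")
  out
}

# Fisher p as a function of the number of events below the cutoff, for a
# fixed split (n_below of n, k_total events).  Returned over k = 0..k_total
# with NA at infeasible counts; used to make the permutation loop cheap.
fisher_p_by_events_below <- function(n_below, n, k_total) {
  vapply(0:k_total, function(k) {
    d <- n - n_below - (k_total - k)
    if (k > n_below || d < 0) return(NA_real_)
    fisher_exact_2x2(c(k, n_below - k, k_total - k, d))
  }, numeric(1))
}

#' Margin-threshold scan with multiplicity control
#'
#' For every admissible cutoff, builds the 2x2 table (below / at-or-above
#' cutoff versus recurrence yes / no), computes the two-sided Fisher exact
#' p-value, the Bonferroni-adjusted p `min(1, m p)` with `m` the number of
#' admissible cutoffs, and the min-p permutation family-wise-error-adjusted
#' p (see [minp_permutation_fwer()]).  Only records with documented margin
#' and recurrence status enter the scan.
#'
#' @param cohort a cohort tibble (see [as_cohort()]).
#' @param config a [scan_config()].
#' @return a tibble of class `margin_scan` with columns `cutoff`, `n_below`,
#'   `n_at_or_above`, `lr_below`, `lr_at_or_above`, `p_unadj`, `p_bonf`,
#'   `p_fwer`, and attributes `m`, `B_used`, `seed_used` and `estimator`.
#' @export
margin_scan <- function(cohort, config = scan_config()) {
  sc <- scan_cases(as_cohort(cohort))
  if (nrow(sc) < 2) abort("the scan needs at least 2 records with documented margin and recurrence status")
  if (length(unique(sc$lr)) < 2) {
    warn("degenerate outcome (all events or all non-events); all p-values are 1")
  }
  cutoffs <- enumerate_cutoffs(sc$margin_mm, config)
  m <- length(cutoffs)
  rows <- purrr::map_dfr(cutoffs, function(c0) {
    below <- sc$margin_mm < c0
    tibble(cutoff = c0,
           n_below = sum(below), n_at_or_above = sum(!below),
           lr_below = sum(sc$lr[below]), lr_at_or_above = sum(sc$lr[!below]))
  })
  if (m == 0) {
    rows <- tibble(cutoff = numeric(), n_below = integer(),
                   n_at_or_above = integer(), lr_below = integer(),
                   lr_at_or_above = integer(), p_unadj = numeric(),
                   p_bonf = numeric(), p_fwer = numeric())
  } else {
    rows$p_unadj <- vapply(seq_len(m), function(j) {
      fisher_exact_2x2(c(rows$lr_below[j],
                         rows$n_below[j] - rows$lr_below[j],
                         rows$lr_at_or_above[j],
                         rows$n_at_or_above[j] - rows$lr_at_or_above[j]))
    }, numeric(1))
    rows$p_bonf <- pmin(1, m * rows$p_unadj)
    rows$p_fwer <- minp_permutation_fwer(
      sc$margin_mm, sc$lr, cutoffs,
      B = config$n_permutations, seed = config$seed,
      estimator = config$estimator)
  }
  structure(rows, class = c("margin_scan", class(rows)),
            m = m, B_used = config$n_permutations,
            seed_used = config$seed, estimator = config$estimator)
}

#' Min-p permutation family-wise error adjustment
#'
#' Joint multiplicity adjustment over all scanned cutoffs: outcome labels
#' are permuted against the fixed margin vector `B` times; for each
#' permutation the full vector of Fisher p-values across all cutoffs is
#' recomputed and its minimum recorded.  The adjusted p-value of cutoff `j`
#' is the fraction of permutation minima at or below its observed
#' unadjusted p — `(1 + count) / (B + 1)` under the add-one estimator, or
#' `count / B` under plug-in.  Ties between a permuted minimum and the
#' observed p count toward the "at or below" side (conservative).  Records
#' are canonically sorted by margin and outcome before permuting, so the
#' result does not depend on input row order.
#'
#' @param margins,lr documented margins (mm) and recurrence flags.
#' @param cutoffs admissible cutoffs from [enumerate_cutoffs()].
#' @param B number of permutations.
#' @param seed RNG seed (`NULL` = use current state).
#' @param estimator `"add_one"` or `"plug_in"`.
#' @return numeric vector of adjusted p-values, one per cutoff.
#' @export
minp_permutation_fwer <- function(margins, lr, cutoffs, B = 5000,
                                  seed = NULL,
                                  estimator = c("add_one", "plug_in")) {
  estimator <- arg_match(estimator)
  stopifnot(length(margins) == length(lr), B >= 1)
  if (length(cutoffs) == 0) return(numeric(0))
  ord <- order(margins, lr)             # canonical order: permutation
  margins <- margins[ord]; lr <- lr[ord]  # results invariant to row order
  n <- length(margins); k_total <- sum(lr)
  n_below <- vapply(cutoffs, function(c0) sum(margins < c0), integer(1))
  lookup <- lapply(n_below, fisher_p_by_events_below, n = n, k = k_total)
  p_obs <- vapply(seq_along(cutoffs), function(j) {
    lookup[[j]][sum(lr[seq_len(n_below[j])]) + 1L]
  }, numeric(1))
  lab <- as.integer(lr)
  mins <- with_seed_if(seed, {
    vapply(seq_len(B), function(b) {
      perm <- lab[sample.int(n)]
      ev_below <- cumsum(perm)[n_below]
      min(vapply(seq_along(cutoffs),
                 function(j) lookup[[j]][ev_below[j] + 1L], numeric(1)))
    }, numeric(1))
  })
  # a permuted minimum within round-off of the observed p counts as <=
  counts <- vapply(p_obs, function(p) sum(mins <= p * (1 + 1e-12)), numeric(1))
  if (estimator == "add_one") (1 + counts) / (B + 1) else counts / B
}

#' Unadjusted p-value profile over a continuous cutoff grid
#'
#' Computes the unadjusted Fisher p-value at every grid cutoff for which
#' both groups are nonempty, with no minimum-group-size filter and no
#' multiplicity adjustment.  For plotting and inspection only; the result
#' carries the flag `"exploratory, multiplicity-unadjusted"`.
#'
#' @param cohort a cohort tibble.
#' @param config a [scan_config()]; only the grid fields are used.
#' @return a tibble with columns `cutoff`, `n_below`, `n_at_or_above`,
#'   `p_unadj` and attribute `flag`.
#' @export
scan_profile <- function(cohort, config = scan_config()) {
  sc <- scan_cases(as_cohort(cohort))
  grid <- round(seq(config$grid_start, config$grid_stop,
                    by = config$grid_step), 10)
  rows <- purrr::map_dfr(grid, function(c0) {
    nb <- sum(sc$margin_mm < c0)
    if (nb == 0 || nb == nrow(sc)) return(NULL)
    lb <- sum(sc$lr[sc$margin_mm < c0])
    tibble(cutoff = c0, n_below = nb, n_at_or_above = nrow(sc) - nb,
           p_unadj = fisher_exact_2x2(c(lb, nb - lb, sum(sc$lr) - lb,
                                        nrow(sc) - nb - (sum(sc$lr) - lb))))
  })
  if (nrow(rows) == 0) {
    rows <- tibble(cutoff = numeric(), n_below = integer(),
                   n_at_or_above = integer(), p_unadj = numeric())
  }
  structure(rows, flag = "exploratory, multiplicity-unadjusted")
}
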