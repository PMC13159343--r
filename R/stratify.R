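#' Recurrence rates by margin category
#'
#' One stratum per margin category (`lt1`, `1to5`, `gt5`, `missing`) among
#' complete-case records (documented recurrence status).  Rates are
#' percentages; an empty category is kept with `n = 0` and an undefined,
#' flagged rate.
#'
#' @param cohort a cohort tibble.
#' @return a tibble with columns `margin_category`, `n`, `events`,
#'   `rate_pct` and `empty`.
#' @export
category_rates <- function(cohort) {
  cc <- complete_cases(as_cohort(cohort))
  purrr::map_dfr(margin_levels, function(lev) {
    sel <- cc$margin_category == lev
    n <- sum(sel)
    events <- sum(cc$lr[sel])
    tibble(margin_category = lev, n = n, events = events,
           rate_pct = if (n > 0) 100 * events / n else NA_real_,
           empty = n == 0)
  })
}

#' Margin-category by radiotherapy cross-tabulation
#'
#' Reproduces the stratified recurrence table of the complete-case cohort:
#' one row per populated margin-category x radiotherapy stratum plus a
#' `Total` row, with counts, events and percentage rates.  Within each
#' margin category in which both radiotherapy arms are populated, the
#' two-sided Fisher exact p comparing recurrence between arms is attached
#' (repeated on both rows of the category; `NA` otherwise).
#'
#' @param cohort a cohort tibble.
#' @return a tibble with columns `margin_category`, `rt`, `n`, `events`,
#'   `rate_pct`, `p_rt`.
#' @export
margin_rt_crosstab <- function(cohort) {
  cc <- complete_cases(as_cohort(cohort))
  body <- cc %>%
    mutate(margin_category = factor(.data$margin_category,
                                    levels = margin_levels)) %>%
    group_by(.data$margin_category, .data$rt) %>%
    summarise(n = n(), events = sum(.data$lr), .groups = "drop") %>%
    arrange(.data$margin_category, dplyr::desc(.data$rt)) %>%
    mutate(margin_category = as.character(.data$margin_category),
           rate_pct = 100 * .data$events / .data$n)
  body <- body %>%
    group_by(.data$margin_category) %>%
    mutate(p_rt = if (dplyr::n_distinct(.data$rt) == 2) {
      fisher_exact_2x2(c(.data$events[1], .data$n[1] - .data$events[1],
                         .data$events[2], .data$n[2] - .data$events[2]))
    } else NA_real_) %>%
    ungroup()
  total <- tibble(margin_category = "Total", rt = NA,
                  n = nrow(cc), events = sum(cc$lr),
                  rate_pct = 100 * sum(cc$lr) / nrow(cc), p_rt = NA_real_)
  bind_rows(body, total)
}

#' Crude recurrence comparison by radiotherapy exposure
#'
#' Complete-case recurrence rates in the irradiated and unirradiated arms
#' with a two-sided Fisher exact p-value.  Treatment here was risk-adapted,
#' not randomised, so the crude contrast is vulnerable to confounding by
#' indication; the output carries that caveat.
#'
#' @param cohort a cohort tibble.
#' @return a one-row tibble: `n_rt`, `events_rt`, `rate_rt_pct`, `n_no_rt`,
#'   `events_no_rt`, `rate_no_rt_pct`, `p_value`, `caveat`.
#' @export
rt_crude_comparison <- function(cohort) {
  cc <- complete_cases(as_cohort(cohort))
  a <- sum(cc$lr[cc$rt]);  n1 <- sum(cc$rt)
  b <- sum(cc$lr[!cc$rt]); n0 <- sum(!cc$rt)
  tibble(
    n_rt = n1, events_rt = a, rate_rt_pct = 100 * a / n1,
    n_no_rt = n0, events_no_rt = b, rate_no_rt_pct = 100 * b / n0,
    p_value = fisher_exact_2x2(c(a, n1 - a, b, n0 - b)),
    caveat = paste("crude, unadjusted comparison; radiotherapy was",
                   "risk-adapted, so confounding by indication is likely")
  )
}
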