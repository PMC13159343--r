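# 2x2 tables are passed as a matrix, a length-4 vector (row-wise: a, b, c, d)
# or four scalars.  Orientation: rows are the two exposure groups (for the
# threshold scan: below / at-or-above the cutoff), columns are event /
# non-event (recurrence yes / no).
as_table_2x2 <- function(x) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(2L, 2L))) abort("table must be 2x2")
    x <- as.vector(t(x))
  }
  if (length(x) != 4) abort("a 2x2 table needs exactly 4 cells")
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    abort("cells must be nonnegative integers")
  }
  if (all(x == 0)) abort("at least one cell must be positive")
  as.integer(round(x))
}

#' Exact hypergeometric point probability of a 2x2 table
#'
#' Probability of the observed table under the hypergeometric distribution
#' induced by conditioning on both margins, evaluated in log-space.
#'
#' @param x a 2x2 matrix or length-4 vector `c(a, b, c, d)` read row-wise;
#'   rows are groups, columns are event / non-event.
#' @return the point probability.
#' @export
hypergeom_point_prob <- function(x) {
  t <- as_table_2x2(x)
  a <- t[1]; b <- t[2]; c <- t[3]; d <- t[4]
  # margins: row 1 total drawn, column totals = event/non-event urn
  exp(dhyper(a, m = a + c, n = b + d, k = a + b, log = TRUE))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' The default two-sided rule is the point-probability method: the p-value
#' sums the conditional hypergeometric probabilities of every table with the
#' same margins whose point probability does not exceed that of the observed
#' table.  Point probabilities are compared in log-space with a relative
#' tolerance of `1e-7` to absorb floating round-off; this is the convention
#' of `stats::fisher.test()` and the one under which the published
#' threshold-table p-values reproduce.  `"mid_p"` gives half credit to
#' tables exactly as likely as the observed one; `"twice_one_sided"` doubles
#' the smaller tail (capped at 1).
#'
#' @param x a 2x2 matrix or length-4 vector `c(a, b, c, d)` read row-wise.
#' @param method two-sided rule; default `"point_prob"`.
#' @param rel_tol relative tolerance when comparing point probabilities.
#' @return the two-sided p-value.  A degenerate table (an all-zero row or
#'   column) returns 1 with a warning.
#' @export
fisher_exact_2x2 <- function(x,
                             method = c("point_prob", "mid_p",
                                        "twice_one_sided"),
                             rel_tol = 1e-7) {
  method <- arg_match(method)
  t <- as_table_2x2(x)
  a <- t[1]; b <- t[2]; c <- t[3]; d <- t[4]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    warn("degenerate 2x2 table (an empty row or column); returning p = 1")
    return(1)
  }
  supp <- max(0L, r1 - c2):min(r1, c1)
  lp <- dhyper(supp, m = c1, n = c2, k = r1, log = TRUE)
  lp_obs <- lp[match(a, supp)]
  p <- switch(method,
    point_prob = sum(exp(lp[lp <= lp_obs + log1p(rel_tol)])),
    mid_p = {
      eq <- abs(lp - lp_obs) <= log1p(rel_tol)
      sum(exp(lp[lp < lp_obs - log1p(rel_tol)])) + 0.5 * sum(exp(lp[eq]))
    },
    twice_one_sided = {
      lower <- sum(exp(lp[supp <= a]))
      upper <- sum(exp(lp[supp >= a]))
      2 * min(lower, upper)
    }
  )
  min(1, p)
}

#' Pearson chi-squared test for a 2x2 table
#'
#' Closed-form Pearson statistic with 1 degree of freedom,
#' `n (ad - bc)^2 / (r1 r2 c1 c2)`, optionally with the Yates continuity
#' correction, and its p-value from the chi-squared survival function.
#'
#' @param x a 2x2 matrix or length-4 vector `c(a, b, c, d)` read row-wise.
#' @param correct apply the Yates continuity correction?
#' @return a list with `statistic` and `p_value`.
#' @export
chi2_2x2 <- function(x, correct = FALSE) {
  t <- as_table_2x2(x)
  a <- t[1]; b <- t[2]; c <- t[3]; d <- t[4]
  n <- sum(t)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  expected <- outer(c(r1, r2), c(c1, c2)) / n
  if (any(expected == 0)) {
    zero <- which(expected == 0, arr.ind = TRUE)[1, ]
    abort(sprintf("zero expected count in cell (%d, %d)", zero[1], zero[2]))
  }
  num <- abs(a * d - b * c)
  if (correct) num <- max(0, num - n / 2)
  stat <- n * num^2 / (r1 * r2 * c1 * c2)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}
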