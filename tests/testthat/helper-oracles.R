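# Independent oracles used across the suite.  They deliberately avoid the
# package's own code paths: point probabilities come from choose(), not
# dhyper(), and enumeration is explicit.

# Exhaustive two-sided Fisher p by enumerating every table with the observed
# margins and summing the point probabilities of tables no more likely than
# the observed one (point-probability rule).
fisher_oracle <- function(a, b, c, d, rel_tol = 1e-7) {
  r1 <- a + b; c1 <- a + c; c2 <- b + d; n <- a + b + c + d
  supp <- max(0, r1 - c2):min(r1, c1)
  pt <- function(x) {
    choose(c1, x) * choose(c2, r1 - x) / choose(n, r1)
  }
  probs <- vapply(supp, pt, numeric(1))
  p_obs <- pt(a)
  sum(probs[probs <= p_obs * (1 + rel_tol)])
}

# Closed-form Pearson chi-squared statistic for a 2x2 table.
chi2_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# Random non-degenerate 2x2 tables with all margins at most max_margin.
random_tables <- function(n_tables, max_margin = 40, seed = 42) {
  withr::with_seed(seed, {
    lapply(seq_len(n_tables), function(i) {
      repeat {
        t <- as.integer(sample(0:(max_margin %/% 2), 4, replace = TRUE))
        if (sum(t) == 0) next
        if (all(c(t[1] + t[2], t[3] + t[4], t[1] + t[3], t[2] + t[4]) > 0) &&
            sum(t) <= max_margin) {
          return(t)
        }
      }
    })
  })
}

# Mann-Whitney concordance with half credit for ties; equals the ROC AUC.
concordance_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Tiny hand-built cohort for I/O and stratification edge cases.
toy_cohort <- function() {
  tibble::tibble(
    id = sprintf("T%02d", 1:8),
    margin_mm = c(0.1, 0.1, 0.5, 2, NA, NA, 7, 0.3),
    rt = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE),
    lr = c(TRUE, TRUE, FALSE, FALSE, TRUE, NA, FALSE, FALSE),
    grade = c("G1", "G2", "G3", NA, "G1", "G2", "G3", "G1"),
    prior_external_surgery = c(NA, TRUE, FALSE, NA, TRUE, TRUE, FALSE, NA)
  )
}
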