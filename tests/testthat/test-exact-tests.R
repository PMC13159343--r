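test_that("hypergeometric point probability matches closed forms and normalises", {
  expect_equal(hypergeom_point_prob(c(1, 0, 0, 1)), 0.5)
  expect_equal(hypergeom_point_prob(c(2, 0, 0, 2)), 1 / 6)
  # summing over all tables with fixed margins gives 1
  for (t in random_tables(20)) {
    r1 <- t[1] + t[2]; c1 <- t[1] + t[3]; c2 <- t[2] + t[4]
    supp <- max(0, r1 - c2):min(r1, c1)
    total <- sum(vapply(supp, function(a) {
      hypergeom_point_prob(c(a, r1 - a, c1 - a, c2 - (r1 - a)))
    }, numeric(1)))
    expect_equal(total, 1, tolerance = 1e-12)
  }
})

test_that("two-sided Fisher p reproduces the published margin tables", {
  # 0.3 mm cutoff table and the <1 mm radiotherapy comparison
  expect_equal(round(fisher_exact_2x2(c(12, 12, 1, 13)), 3), 0.012)
  expect_equal(round(fisher_exact_2x2(c(6, 14, 6, 6)), 3), 0.288)
})

test_that("Fisher p agrees with exhaustive enumeration and fisher.test", {
  for (t in random_tables(60)) {
    p <- fisher_exact_2x2(t)
    expect_equal(p, fisher_oracle(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-10)
    expect_equal(p,
                 stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-7)
  }
})

test_that("Fisher p is symmetric, bounded below by the point probability", {
  for (t in random_tables(30, seed = 7)) {
    p <- fisher_exact_2x2(t)
    transpose <- c(t[1], t[3], t[2], t[4])
    swapped <- c(t[4], t[3], t[2], t[1])   # both rows and columns swapped
    expect_equal(fisher_exact_2x2(transpose), p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(swapped), p, tolerance = 1e-12)
    expect_gte(p + 1e-12, hypergeom_point_prob(t))
  }
  # diagonal tables equal their transpose exactly
  expect_equal(fisher_exact_2x2(c(3, 0, 0, 5)),
               fisher_exact_2x2(c(5, 0, 0, 3)))
})

test_that("degenerate tables return p = 1 with a warning", {
  expect_warning(p <- fisher_exact_2x2(c(0, 0, 3, 4)), "degenerate")
  expect_equal(p, 1)
  expect_warning(p <- fisher_exact_2x2(c(5, 0, 3, 0)), "degenerate")
  expect_equal(p, 1)
})

test_that("mid-p and twice-one-sided variants are ordered sensibly", {
  for (t in random_tables(20, seed = 11)) {
    p_point <- fisher_exact_2x2(t)
    p_mid <- fisher_exact_2x2(t, method = "mid_p")
    expect_lte(p_mid, p_point + 1e-12)
    expect_lte(fisher_exact_2x2(t, method = "twice_one_sided"), 1)
  }
})

test_that("exact test is conservative under the permutation null", {
  # fixed margins, labels permuted: rejection rate at 0.05 stays below
  # 0.05 plus Monte-Carlo error
  n <- 30; k <- 9; n1 <- 14
  lab <- c(rep(TRUE, k), rep(FALSE, n - k))
  rejections <- withr::with_seed(99, {
    vapply(seq_len(2000), function(i) {
      l <- sample(lab)
      a <- sum(l[seq_len(n1)])
      fisher_exact_2x2(c(a, n1 - a, k - a, n - n1 - (k - a))) <= 0.05
    }, logical(1))
  })
  rate <- mean(rejections)
  mc_se <- sqrt(0.05 * 0.95 / 2000)
  expect_lte(rate, 0.05 + 3 * mc_se)
})

test_that("chi-squared statistic matches its closed form", {
  expect_equal(chi2_2x2(c(10, 10, 10, 10))$statistic, 0)
  expect_equal(chi2_2x2(c(10, 10, 10, 10))$p_value, 1)
  expect_equal(chi2_2x2(c(20, 0, 0, 20))$statistic, 40)
  for (t in random_tables(30, seed = 3)) {
    res <- chi2_2x2(t)
    expect_equal(res$statistic, chi2_oracle(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-10)
    # and the Yates-corrected version matches chisq.test
    res_y <- chi2_2x2(t, correct = TRUE)
    ref <- suppressWarnings(
      stats::chisq.test(matrix(t, 2, byrow = TRUE), correct = TRUE))
    expect_equal(res_y$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res_y$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("chi-squared errors on a zero expected cell, naming it", {
  expect_error(chi2_2x2(c(0, 0, 3, 4)), "cell \\(1")
})
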