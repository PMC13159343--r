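test_that("cutoff enumeration yields the eight admissible canonical cutoffs", {
  m <- reconstruct_margin_vector()
  expect_equal(enumerate_cutoffs(m, scan_config(min_group_size = 6)),
               c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 1.0))
  # with no size requirement every distinct value but the minimum splits
  expect_equal(enumerate_cutoffs(m, scan_config(min_group_size = 1)),
               setdiff(sort(unique(m)), min(m)))
  expect_warning(out <- enumerate_cutoffs(rep(2.5, 10), scan_config()),
                 "no admissible cutoff")
  expect_length(out, 0)
})

test_that("a degenerate outcome gives p = 1 at every cutoff", {
  co <- tibble::tibble(margin_mm = c(rep(0.1, 8), rep(2, 8)),
                       rt = FALSE, lr = FALSE)
  s <- suppressWarnings(margin_scan(co, scan_config(n_permutations = 10,
                                                    seed = 1)))
  expect_true(all(s$p_unadj == 1))
})

test_that("events are conserved and Bonferroni is m times the raw p", {
  s <- margin_scan(reconstruct_subcohort(),
                   scan_config(n_permutations = 200, seed = 4))
  m <- attr(s, "m")
  expect_true(all(s$n_below + s$n_at_or_above == 38))
  expect_true(all(s$lr_below + s$lr_at_or_above == 13))
  expect_equal(s$p_bonf, pmin(1, m * s$p_unadj))
})

test_that("a single-cutoff scan recovers the unadjusted p", {
  # restrict candidates to one admissible cutoff via a coarse grid
  sc <- reconstruct_subcohort()
  cfg <- scan_config(candidate_rule = "fixed_grid", grid_start = 0.3,
                     grid_stop = 0.35, grid_step = 0.1,
                     n_permutations = 4000, seed = 8)
  s <- margin_scan(sc, cfg)
  expect_equal(nrow(s), 1)
  expect_equal(s$cutoff, 0.3)
  mc_se <- sqrt(s$p_unadj * (1 - s$p_unadj) / 4000)
  expect_lt(abs(s$p_fwer - s$p_unadj), 3 * mc_se + 1 / 4001)
})

test_that("permutation adjustment is invariant to input row order", {
  sc <- reconstruct_subcohort()
  shuffled <- withr::with_seed(1, sc[sample.int(nrow(sc)), ])
  cfg <- scan_config(n_permutations = 500, seed = 12)
  expect_equal(margin_scan(sc, cfg)$p_fwer,
               margin_scan(shuffled, cfg)$p_fwer)
})

test_that("adjusted p-values are monotone in the unadjusted p-values", {
  s <- margin_scan(reconstruct_subcohort(),
                   scan_config(n_permutations = 1000, seed = 13))
  ord <- order(s$p_unadj)
  expect_true(all(diff(s$p_fwer[ord]) >= 0))
})

test_that("the sandwich ordering raw <= FWER <= Bonferroni holds", {
  for (seed in c(2, 3)) {
    s <- margin_scan(reconstruct_subcohort(),
                     scan_config(n_permutations = 2000, seed = seed))
    B <- attr(s, "B_used")
    expect_true(all(s$p_unadj <= s$p_fwer + 1 / (B + 1)))
    mc_se <- sqrt(pmax(s$p_fwer * (1 - s$p_fwer), 0.25 / B) / B)
    expect_true(all(s$p_fwer <= pmin(1, s$p_bonf + 3 * mc_se + 1 / (B + 1))))
  }
})

test_that("plug-in and add-one estimators agree up to the add-one shift", {
  sc <- reconstruct_subcohort()
  cfg1 <- scan_config(n_permutations = 500, seed = 6, estimator = "add_one")
  cfg2 <- scan_config(n_permutations = 500, seed = 6, estimator = "plug_in")
  p1 <- margin_scan(sc, cfg1)$p_fwer
  p2 <- margin_scan(sc, cfg2)$p_fwer
  expect_equal(p1, (p2 * 500 + 1) / 501, tolerance = 1e-12)
  expect_true(all(p1 > 0))
})

test_that("the continuous profile dips where the published scan dips", {
  sc <- reconstruct_subcohort()
  prof <- scan_profile(sc, scan_config())
  best <- prof$cutoff[which.min(prof$p_unadj)]
  expect_gt(best, 0.2)
  expect_lte(best, 0.4)
  # profile values coincide with the admissible scan where cutoffs match
  s <- margin_scan(sc, scan_config(n_permutations = 10, seed = 1))
  shared <- intersect(round(prof$cutoff, 10), round(s$cutoff, 10))
  expect_length(shared, 8)
  for (c0 in shared) {
    expect_equal(prof$p_unadj[abs(prof$cutoff - c0) < 1e-9],
                 s$p_unadj[abs(s$cutoff - c0) < 1e-9], tolerance = 1e-12)
  }
})

test_that("a grid entirely above the margins yields an empty profile", {
  co <- tibble::tibble(margin_mm = runif(10, 0.1, 0.5), rt = FALSE,
                       lr = rep(c(TRUE, FALSE), 5))
  prof <- scan_profile(co, scan_config(grid_start = 5, grid_stop = 6))
  expect_equal(nrow(prof), 0)
})
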