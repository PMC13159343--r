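test_that("the IRLS fit matches glm on simulated cohorts", {
  for (seed in c(1, 2)) {
    co <- simulate_cohort(sim_params(n = 500, gamma_confound = 0,
                                     p_margin_missing = 0,
                                     p_lr_missing = 0, seed = seed))
    fit <- fit_recurrence_logit(co, predictors = c("margin", "rt"))
    ref <- stats::glm(lr ~ margin_mm + rt, binomial(), data = co)
    expect_equal(unname(fit$coefficients), unname(coef(ref)),
                 tolerance = 1e-6)
    expect_equal(unname(tidy(fit)$std.error),
                 unname(summary(ref)$coefficients[, 2]), tolerance = 1e-4)
    expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
    expect_true(fit$converged)
  }
})

test_that("the IRLS log-likelihood trace is non-decreasing", {
  co <- simulate_cohort(sim_params(n = 300, seed = 3, p_lr_missing = 0,
                                   p_margin_missing = 0))
  fit <- fit_recurrence_logit(co, predictors = c("margin", "rt"))
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
})

test_that("the Wald interval excludes 1 exactly when p is below 0.05", {
  for (seed in 1:5) {
    co <- simulate_cohort(sim_params(n = 150, seed = 40 + seed,
                                     p_margin_missing = 0,
                                     p_lr_missing = 0))
    est <- tidy(fit_recurrence_logit(co, predictors = c("margin", "rt")))
    excl <- exp(est$conf.low) > 1 | exp(est$conf.high) < 1
    expect_equal(excl, est$p.value < 0.05)
  }
})

test_that("null predictors rarely reach |z| = 3", {
  zs <- unlist(lapply(1:10, function(s) {
    co <- simulate_cohort(sim_params(n = 2000, beta_margin = 0, beta_rt = 0,
                                     gamma_confound = 0, frailty_sd = 0,
                                     p_margin_missing = 0, p_lr_missing = 0,
                                     seed = 50 + s))
    est <- tidy(fit_recurrence_logit(co, predictors = c("margin", "rt")))
    est$statistic[est$term != "(Intercept)"]
  }))
  expect_gte(mean(abs(zs) < 3), 0.99)
})

test_that("separated data raise the separation flag, not an error", {
  co <- tibble::tibble(margin_mm = c(rep(0.1, 10), rep(4, 10)), rt = FALSE,
                       lr = c(rep(TRUE, 10), rep(FALSE, 10)))
  fit <- fit_recurrence_logit(co, predictors = "margin")
  expect_true(fit$separation_warning)
})

test_that("the canonical subcohort margin term is protective", {
  fit <- fit_recurrence_logit(reconstruct_subcohort(),
                              predictors = c("margin", "rt"),
                              dichotomize_at = 0.3)
  or <- exp(fit$coefficients[["margin_ge_0.3"]])
  expect_lt(or, 1)
})

test_that("predicted probability curves follow the link closed form", {
  co <- simulate_cohort(sim_params(n = 400, seed = 6, p_margin_missing = 0,
                                   p_lr_missing = 0))
  fit <- fit_recurrence_logit(co, predictors = c("margin", "rt"))
  grid <- seq(0.1, 5, by = 0.5)
  curve <- recurrence_curve(fit, grid, rt = TRUE)
  manual <- plogis(fit$coefficients[["(Intercept)"]] +
                     fit$coefficients[["margin_mm"]] * grid +
                     fit$coefficients[["rtTRUE"]])
  expect_equal(curve$probability, manual, tolerance = 1e-12)
  if (fit$coefficients[["margin_mm"]] < 0) {
    expect_true(all(diff(curve$probability) < 0))
  }
})

test_that("a zero-coefficient model gives a flat curve at one half", {
  fit <- fit_recurrence_logit(
    tibble::tibble(margin_mm = rep(c(0.2, 3), 10), rt = FALSE,
                   lr = rep(c(TRUE, FALSE), each = 10)),
    predictors = "margin")
  fit$coefficients[] <- 0
  curve <- recurrence_curve(fit, seq(0.1, 2, 0.1))
  expect_true(all(curve$probability == 0.5))
})

test_that("ROC handles the textbook cases", {
  expect_equal(attr(roc_from_scores(c(1, 2, 3, 10, 11, 12),
                                    c(0, 0, 0, 1, 1, 1)), "auc"), 1)
  expect_error(roc_from_scores(1:5, rep(TRUE, 5)), "both classes")
  # labels independent of scores: AUC near one half
  withr::with_seed(60, {
    sc <- rnorm(4000); lab <- runif(4000) < 0.5
  })
  auc <- attr(roc_from_scores(sc, lab), "auc")
  expect_lt(abs(auc - 0.5), 3 * sqrt(1 / (12 * 1000)))
})

test_that("trapezoidal AUC equals Mann-Whitney concordance with tied scores", {
  withr::with_seed(61, {
    for (i in 1:20) {
      n <- sample(20:80, 1)
      scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
      labels <- runif(n) < 0.4
      if (sum(labels) == 0 || sum(!labels) == 0) next
      roc <- roc_from_scores(scores, labels)
      expect_equal(attr(roc, "auc"), concordance_oracle(scores, labels),
                   tolerance = 1e-10)
    }
  })
})

test_that("AUC is invariant under strictly increasing score transforms", {
  withr::with_seed(62, {
    scores <- rnorm(200); labels <- runif(200) < 0.3
  })
  a1 <- attr(roc_from_scores(scores, labels), "auc")
  a2 <- attr(roc_from_scores(exp(scores), labels), "auc")
  a3 <- attr(roc_from_scores(5 * scores - 2, labels), "auc")
  expect_equal(a1, a2, tolerance = 1e-12)
  expect_equal(a1, a3, tolerance = 1e-12)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(63, {
    scores <- rnorm(150); labels <- runif(150) < plogis(scores)
  })
  auc <- attr(roc_from_scores(scores, labels), "auc")
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc, ref, tolerance = 1e-10)
})

test_that("a margin-only model maps the Youden cutoff back to millimetres", {
  fit <- fit_recurrence_logit(reconstruct_subcohort(), predictors = "margin")
  roc <- logit_roc(fit)
  mm <- attr(roc, "youden_margin_mm")
  expect_false(is.null(mm))
  expect_gt(mm, 0.1)
  expect_lt(mm, 8)
  # multi-predictor models stay on the score scale
  fit2 <- fit_recurrence_logit(reconstruct_subcohort(),
                               predictors = c("margin", "rt"))
  expect_null(attr(logit_roc(fit2), "youden_margin_mm"))
})

test_that("bootstrap degenerate and determinism cases behave", {
  sc <- reconstruct_subcohort()
  one <- bootstrap_or(sc, n_resamples = 1, seed = 5)
  if (!is.na(one$or[1])) {
    expect_true(all(one$percentiles$odds_ratio == one$or[1]))
  }
  b1 <- bootstrap_or(sc, n_resamples = 50, seed = 9)
  b2 <- bootstrap_or(sc, n_resamples = 50, seed = 9)
  expect_identical(b1$or, b2$or)
})

test_that("the canonical bootstrap exposes the instability of the dichotomized OR", {
  boot <- bootstrap_or(reconstruct_subcohort(),
                       predictors = c("margin", "rt"),
                       dichotomize_at = 0.3, n_resamples = 400, seed = 10)
  g <- glance(boot)
  expect_false(boot$unreliable)
  # the single event above the cutoff makes the estimate fragile: a large
  # share of resamples are quasi-separated, and the converged odds ratios
  # span more than an order of magnitude
  expect_gt(g$n_failed / g$n_resamples, 0.2)
  expect_gt(g$or_p97.5 / g$or_p2.5, 10)
  expect_lt(g$or_median, 1)
})
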