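#' Logistic recurrence model fitted by IRLS
#'
#' Maximum-likelihood logistic regression of local recurrence on margin
#' width and/or radiotherapy, fitted by iteratively reweighted least
#' squares with Wald standard errors from the observed information.  The
#' margin enters either continuously (`"margin"`, per mm) or dichotomized
#' at a cutoff (`dichotomize_at`, giving the indicator `margin >= cutoff`).
#' Convergence is declared when the relative log-likelihood change falls
#' below `1e-10` (at most 100 iterations); quasi-separation is flagged when
#' any coefficient exceeds 15 on the log-odds scale.  Only complete-case
#' records enter, and records with undocumented margins are dropped when a
#' margin predictor is requested.
#'
#' @param cohort a cohort tibble.
#' @param predictors subset of `c("margin", "rt")`; extra numeric or
#'   logical columns of `cohort` may be named as additional covariates.
#' @param dichotomize_at optional margin cutoff in mm; replaces the
#'   continuous margin term by `margin >= cutoff`.
#' @return an object of class `recurrence_logit`: coefficients, standard
#'   errors, odds ratios with 95% Wald intervals, the per-iteration
#'   log-likelihood trace, and convergence/separation flags.  Supports
#'   [tidy()], [glance()] and [predict()].
#' @export
fit_recurrence_logit <- function(cohort, predictors = c("margin", "rt"),
                                 dichotomize_at = NULL) {
  cohort <- as_cohort(cohort)
  dat <- complete_cases(cohort)
  uses_margin <- "margin" %in% predictors
  if (uses_margin) dat <- filter(dat, !is.na(.data$margin_mm))
  if (nrow(dat) < 2 || length(unique(dat$lr)) < 2) {
    abort("the fit needs at least one event and one non-event")
  }
  X <- matrix(1, nrow(dat), 1, dimnames = list(NULL, "(Intercept)"))
  for (p in predictors) {
    if (p == "margin") {
      col <- if (is.null(dichotomize_at)) {
        setNames(list(dat$margin_mm), "margin_mm")
      } else {
        setNames(list(as.numeric(dat$margin_mm >= dichotomize_at)),
                 sprintf("margin_ge_%g", dichotomize_at))
      }
    } else if (p == "rt") {
      col <- list(rtTRUE = as.numeric(dat$rt))
    } else {
      if (!p %in% names(dat)) abort(sprintf("unknown predictor '%s'", p))
      v <- dat[[p]]
      if (anyNA(v)) abort(sprintf("predictor '%s' has missing values", p))
      col <- setNames(list(as.numeric(v)), p)
    }
    X <- cbind(X, matrix(col[[1]], ncol = 1,
                         dimnames = list(NULL, names(col))))
  }
  y <- as.numeric(dat$lr)
  fit <- irls_logit(X, y)
  se <- sqrt(diag(fit$vcov))
  z <- fit$coefficients / se
  est <- tibble(
    term = colnames(X),
    estimate = fit$coefficients,
    std.error = se,
    statistic = z,
    p.value = 2 * stats::pnorm(-abs(z)),
    odds.ratio = exp(fit$coefficients),
    conf.low = fit$coefficients - qnorm(0.975) * se,
    conf.high = fit$coefficients + qnorm(0.975) * se
  )
  structure(list(
    coefficients = setNames(fit$coefficients, colnames(X)),
    vcov = fit$vcov,
    estimates = est,
    loglik = fit$loglik,
    loglik_trace = fit$trace,
    iterations = fit$iterations,
    converged = fit$converged,
    separation_warning = any(abs(fit$coefficients) > 15),
    n = nrow(dat), n_events = sum(y),
    predictors = predictors, dichotomize_at = dichotomize_at,
    X = X, y = y
  ), class = "recurrence_logit")
}

# IRLS core.  Weights are clamped away from zero so a step towards
# separation does not produce a singular system before the flag is raised.
irls_logit <- function(X, y, tol = 1e-10, max_iter = 100) {
  beta <- rep(0, ncol(X))
  ll <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  trace <- ll(beta)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    zz <- eta + (y - mu) / w
    WX <- X * w
    beta <- drop(solve(crossprod(X, WX), crossprod(WX, zz)))
    trace <- c(trace, ll(beta))
    k <- length(trace)
    if (abs(trace[k] - trace[k - 1]) <
        tol * (abs(trace[k - 1]) + tol)) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  info <- crossprod(X, X * pmax(mu * (1 - mu), 1e-10))
  list(coefficients = beta, vcov = solve(info), loglik = trace[length(trace)],
       trace = trace, iterations = iter, converged = converged)
}

#' @exportS3Method generics::tidy
tidy.recurrence_logit <- function(x, exponentiate = FALSE, ...) {
  est <- x$estimates
  if (exponentiate) {
    est <- mutate(est, estimate = exp(.data$estimate),
                  conf.low = exp(.data$conf.low),
                  conf.high = exp(.data$conf.high))
  }
  est
}

#' @exportS3Method generics::glance
glance.recurrence_logit <- function(x, ...) {
  tibble(logLik = x$loglik, AIC = -2 * x$loglik + 2 * length(x$coefficients),
         nobs = x$n, n_events = x$n_events, iterations = x$iterations,
         converged = x$converged, separation_warning = x$separation_warning)
}

#' @export
print.recurrence_logit <- function(x, ...) {
  cat(sprintf("Logistic recurrence model (IRLS): n = %d, events = %d\n",
              x$n, x$n_events))
  if (!x$converged) cat("  ** did not converge **\n")
  if (x$separation_warning) cat("  ** quasi-separation suspected **\n")
  print(x$estimates, ...)
  invisible(x)
}

#' @export
predict.recurrence_logit <- function(object, newdata = NULL,
                                     type = c("response", "link"), ...) {
  type <- arg_match(type)
  X <- if (is.null(newdata)) object$X else newdata
  eta <- drop(X %*% object$coefficients)
  if (type == "response") plogis(eta) else eta
}

#' Predicted recurrence-probability curve over a margin grid
#'
#' Evaluates the fitted model along a grid of margin widths at fixed
#' radiotherapy status, on the probability scale.  Only meaningful for
#' models with a continuous margin term; the curve is monotone when the
#' margin coefficient has a single sign.
#'
#' @param fit a converged [fit_recurrence_logit()] with a `margin_mm` term.
#' @param margin_grid numeric grid of margins in mm.
#' @param rt radiotherapy status at which to evaluate (ignored when the
#'   model has no radiotherapy term).
#' @return a tibble with columns `margin_mm`, `rt`, `probability`.
#' @export
recurrence_curve <- function(fit, margin_grid = seq(0.1, 8, by = 0.1),
                             rt = FALSE) {
  stopifnot(inherits(fit, "recurrence_logit"))
  if (!"margin_mm" %in% names(fit$coefficients)) {
    abort("the fitted model has no continuous margin term")
  }
  X <- matrix(0, length(margin_grid), length(fit$coefficients),
              dimnames = list(NULL, names(fit$coefficients)))
  X[, "(Intercept)"] <- 1
  X[, "margin_mm"] <- margin_grid
  if ("rtTRUE" %in% colnames(X)) X[, "rtTRUE"] <- as.numeric(rt)
  tibble(margin_mm = margin_grid, rt = rt,
         probability = predict(fit, newdata = X))
}
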