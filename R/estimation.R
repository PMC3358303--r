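# Logistic estimation of the treatment effect on one simulated trial.
#
# The unadjusted model (intercept + treatment) on a collapsed 2x2 table has a
# closed-form MLE: log odds ratio and its standard error from the reciprocal
# cell counts. The adjusted model (intercept + treatment + prognostic factor)
# is fit by IRLS on the four aggregated binomial cells. Separation (a zero
# margin making the MLE non-finite) triggers a documented fallback: add 0.5
# events and 0.5 non-events to every design cell, refit, and flag the fit as
# corrected.

#' Wald confidence interval
#'
#' `beta +/- z * se` on the estimation scale, with
#' `z = qnorm(1 - (1 - level)/2)` (1.959964 at the default 95% level).
#'
#' @param beta point estimate.
#' @param se standard error (> 0).
#' @param level confidence level.
#' @return Numeric vector `c(low, high)`.
#' @export
wald_ci <- function(beta, se, level = 0.95) {
  stopifnot(se > 0, level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(beta - z * se, beta + z * se)
}

new_fit_result <- function(model, beta1_hat, se1, level, converged, corrected,
                           coefficients = NULL) {
  ci <- if (converged) wald_ci(beta1_hat, se1, level) else c(NA_real_, NA_real_)
  structure(
    list(model = model, beta1_hat = beta1_hat, se1 = se1,
         ci_low = ci[1L], ci_high = ci[2L],
         converged = converged, corrected = corrected,
         orr_hat = 1 - exp(beta1_hat),
         coefficients = coefficients),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s logistic fit: beta1 = %.4f (SE %.4f), 95%% CI [%.4f, %.4f]\n",
              x$model, x$beta1_hat, x$se1, x$ci_low, x$ci_high))
  cat(sprintf("  OR = %.4f, ORR = %.4f; converged: %s, corrected: %s\n",
              exp(x$beta1_hat), x$orr_hat, x$converged, x$corrected))
  invisible(x)
}

#' Unadjusted treatment-effect fit (intercept + treatment)
#'
#' Collapses the trial over the prognostic factor to a 2x2 treatment-by-
#' outcome table; the logistic MLE for the treatment coefficient is then the
#' sample log odds ratio `log[(a/(n1-a)) / (b/(n0-b))]` with standard error
#' `sqrt(1/a + 1/(n1-a) + 1/b + 1/(n0-b))`. If any of the four collapsed
#' cells is zero the MLE is infinite; 0.5 is added to all four cells and the
#' fit is flagged `corrected`.
#'
#' @param counts a [trial_counts()] object.
#' @param level confidence level for the Wald interval.
#' @return A `fit_result`.
#' @export
fit_unadjusted <- function(counts, level = 0.95) {
  stopifnot(inherits(counts, "trial_counts"))
  if (counts$n0 < 1 || counts$n1 < 1) {
    stop("both arms must contain at least one patient", call. = FALSE)
  }
  a <- sum(counts$n_events["1", ]) # events, treatment arm
  b <- sum(counts$n_events["0", ]) # events, control arm
  cells <- c(a, counts$n1 - a, b, counts$n0 - b)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  beta1 <- log(cells[1L] / cells[2L]) - log(cells[3L] / cells[4L])
  se1 <- sqrt(sum(1 / cells))
  beta0 <- log(cells[3L] / cells[4L])
  new_fit_result("unadjusted", beta1, se1, level, converged = TRUE,
                 corrected = corrected, coefficients = c(b0 = beta0, b1 = beta1))
}

# IRLS logistic fit on aggregated binomial rows. Returns coefficients and
# their covariance; rank-deficient columns (a constant covariate) are dropped
# by glm.fit's pivoting and reported as NA.
logistic_ml <- function(X, events, sizes, epsilon = 1e-10, maxit = 100L) {
  keep <- sizes > 0
  X <- X[keep, , drop = FALSE]
  events <- events[keep]
  sizes <- sizes[keep]
  fit <- suppressWarnings(stats::glm.fit(
    x = X, y = events / sizes, weights = sizes,
    family = stats::binomial(),
    control = stats::glm.control(epsilon = epsilon, maxit = maxit)
  ))
  coefs <- fit$coefficients
  est <- !is.na(coefs)
  Xe <- X[, est, drop = FALSE]
  w <- fit$weights # n_i mu_i (1 - mu_i) at convergence
  info <- crossprod(Xe * sqrt(w))
  # glm.fit's relative-deviance criterion can stall at floating-point
  # resolution on large aggregated counts; the fit is accepted whenever the
  # score equations hold to relative precision
  score <- crossprod(Xe, events - sizes * fit$fitted.values)
  converged <- fit$converged || max(abs(score)) <= 1e-8 * (sum(sizes) + 1)
  vcov <- matrix(NA_real_, ncol(X), ncol(X),
                 dimnames = list(colnames(X), colnames(X)))
  ok <- TRUE
  vc <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
  if (is.null(vc)) ok <- FALSE else vcov[est, est] <- vc
  list(coefficients = coefs, vcov = vcov,
       converged = converged && ok,
       loglik = suppressWarnings(
         sum(stats::dbinom(events, sizes, fit$fitted.values, log = TRUE))))
}

#' Adjusted treatment-effect fit (intercept + treatment + prognostic factor)
#'
#' Maximum-likelihood logistic fit of the three-parameter data-generating
#' model to the four aggregated binomial cells, with the Wald standard error
#' taken from the inverse observed information (observed = expected under the
#' canonical logit link). When every patient shares the same factor level the
#' factor column is dropped and the fit reduces to the unadjusted estimate.
#' A non-finite MLE (|coefficient| beyond 15 on the log-odds scale, or IRLS
#' failure) triggers the 0.5-per-cell fallback with `corrected = TRUE`; if
#' the refit still fails, `converged = FALSE`.
#'
#' @inheritParams fit_unadjusted
#' @return A `fit_result`.
#' @export
fit_adjusted <- function(counts, level = 0.95) {
  stopifnot(inherits(counts, "trial_counts"))
  if (counts$n0 < 1 || counts$n1 < 1) {
    stop("both arms must contain at least one patient", call. = FALSE)
  }
  df <- as.data.frame(counts)
  X <- cbind(intercept = 1, t = df$t, c = df$c)
  fit <- logistic_ml(X, df$n_events, df$n_patients)
  finite <- function(f) {
    est <- f$coefficients[!is.na(f$coefficients)]
    f$converged && all(abs(est) < 15) && is.finite(f$vcov["t", "t"]) &&
      f$vcov["t", "t"] > 0
  }
  corrected <- FALSE
  if (!finite(fit)) {
    corrected <- TRUE
    fit <- logistic_ml(X, df$n_events + 0.5, df$n_patients + 1)
  }
  if (!finite(fit)) {
    return(new_fit_result("adjusted", NA_real_, NA_real_, level,
                          converged = FALSE, corrected = corrected,
                          coefficients = fit$coefficients))
  }
  new_fit_result("adjusted", fit$coefficients[["t"]], sqrt(fit$vcov["t", "t"]),
                 level, converged = TRUE, corrected = corrected,
                 coefficients = stats::setNames(fit$coefficients, c("b0", "b1", "b2")))
}

#' Fit one model to one trial
#'
#' @param counts a [trial_counts()] object.
#' @param model `"adjusted"` or `"unadjusted"`.
#' @param level confidence level.
#' @return A `fit_result`.
#' @export
fit_trial <- function(counts, model = c("adjusted", "unadjusted"), level = 0.95) {
  model <- match.arg(model)
  if (model == "adjusted") fit_adjusted(counts, level) else fit_unadjusted(counts, level)
}

# one-row data.frame view used by the aggregation layer
fit_row <- function(fit) {
  data.frame(model = fit$model, beta1_hat = fit$beta1_hat, se1 = fit$se1,
             ci_low = fit$ci_low, ci_high = fit$ci_high,
             converged = fit$converged, corrected = fit$corrected,
             orr_hat = fit$orr_hat)
}
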