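# Replicate-level fits -> the study's performance surfaces: bias, empirical
# SD, MSE, coverage of the 95% CI against the true conditional log OR, power
# (CI excluding zero), power loss between models, odds-ratio-reduction
# deviation tables, and the two-proportion sample-size calculation.

#' Summarize replicate fits into performance metrics
#'
#' Given per-replicate treatment-coefficient fits and the true conditional
#' log odds ratio, computes bias `mean(beta1_hat) - beta1`, the empirical SD
#' across replicates, MSE (mean squared deviation from `beta1`), coverage
#' (proportion of CIs containing `beta1` — for the unadjusted model too, by
#' design: the conditional effect is the estimand, which is what exposes the
#' non-collapsibility under-coverage), and power (proportion of CIs excluding
#' zero). Non-converged replicates are excluded from all metrics and counted;
#' corrected (continuity-fallback) replicates are included and counted. Set
#' `include_corrected = FALSE` for the sensitivity variant that drops them.
#'
#' @param fits data.frame with columns `beta1_hat`, `ci_low`, `ci_high`,
#'   `converged`, `corrected` (one row per replicate), e.g. from [run_cell()].
#' @param true_beta1 true conditional treatment log odds ratio.
#' @param include_corrected include separation-corrected replicates (default).
#' @return One-row data.frame: `bias`, `empirical_sd`, `mse`, `coverage`,
#'   `power`, `n_effective`, `n_corrected`, `n_nonconverged`.
#' @export
summarize_fits <- function(fits, true_beta1, include_corrected = TRUE) {
  stopifnot(is.data.frame(fits), nrow(fits) >= 1)
  keep <- fits$converged
  if (!include_corrected) keep <- keep & !fits$corrected
  use <- fits[keep, , drop = FALSE]
  if (nrow(use) < 2) stop("need at least 2 contributing replicates", call. = FALSE)
  est <- use$beta1_hat
  data.frame(
    bias = mean(est) - true_beta1,
    empirical_sd = stats::sd(est),
    mse = mean((est - true_beta1)^2),
    coverage = mean(use$ci_low <= true_beta1 & true_beta1 <= use$ci_high),
    power = mean(use$ci_low > 0 | use$ci_high < 0),
    n_effective = nrow(use),
    n_corrected = sum(use$corrected),
    n_nonconverged = sum(!fits$converged)
  )
}

#' Power loss of the unadjusted relative to the adjusted model
#'
#' With `relative = FALSE` (default) returns the absolute difference
#' `(power_adjusted - power_unadjusted) * 100` in percentage points. With
#' `relative = TRUE` returns the loss as a percentage of the adjusted
#' model's power, `(power_adj - power_unadj) / power_adj * 100` — the scale
#' on which such losses are usually quoted, and the one that stays
#' informative when both powers approach 0 or 1 (where absolute differences
#' are floor/ceiling-compressed).
#'
#' @param summary_unadj,summary_adj one-row summaries from [summarize_fits()]
#'   for the same simulation cell.
#' @param relative express the loss relative to the adjusted model's power.
#' @return Power loss in percentage points (or percent if `relative`).
#' @export
power_loss <- function(summary_unadj, summary_adj, relative = FALSE) {
  diff <- summary_adj$power - summary_unadj$power
  if (relative) {
    if (summary_adj$power <= 0) stop("adjusted power is zero", call. = FALSE)
    100 * diff / summary_adj$power
  } else {
    100 * diff
  }
}

default_d2_thresholds <- function() c(0, 0.05, 0.10, 0.15, 0.20, 0.25)

#' Deviation table for the odds-ratio reduction
#'
#' The odds-ratio reduction is `ORR = 1 - OR`; each replicate's deviation is
#' `D_ORR = orr_hat - true ORR` with `orr_hat = 1 - exp(beta1_hat)`. Positive
#' deviations overstate the treatment benefit. For each threshold `d` the
#' table reports `Pr(D_ORR >= d)` (overestimation), `Pr(D_ORR <= -d)`
#' (underestimation) and `Pr(|D_ORR| >= d)`. At `d = 0` the overall
#' probability is 1 by convention and the over/under split is
#' `Pr(D_ORR >= 0)` / `Pr(D_ORR < 0)`.
#'
#' @param fits data.frame of replicate fits (as for [summarize_fits()]);
#'   non-converged replicates are excluded.
#' @param true_or true conditional odds ratio, `exp(beta1)`.
#' @param thresholds deviation thresholds `d`.
#' @return data.frame with columns `d`, `prob_over`, `prob_under`,
#'   `prob_overall`.
#' @export
deviation_table <- function(fits, true_or, thresholds = default_d2_thresholds()) {
  stopifnot(true_or > 0)
  use <- fits[fits$converged, , drop = FALSE]
  dev <- (1 - exp(use$beta1_hat)) - (1 - true_or)
  rows <- lapply(thresholds, function(d) {
    if (d == 0) {
      data.frame(d = d, prob_over = mean(dev >= 0),
                 prob_under = mean(dev < 0), prob_overall = 1)
    } else {
      over <- mean(dev >= d)
      under <- mean(dev <= -d)
      data.frame(d = d, prob_over = over, prob_under = under,
                 prob_overall = over + under)
    }
  })
  do.call(rbind, rows)
}

#' Per-arm sample size for comparing two proportions
#'
#' Normal-approximation sample size for a two-sided test of `p1 = rr * p0`
#' against `p0` at significance `alpha` and the given power. The default
#' (unpooled) form is
#' \deqn{n \ge (z_{1-\alpha/2} + z_{1-\beta})^2
#'       \frac{p_0(1-p_0) + p_1(1-p_1)}{(p_1 - p_0)^2},}
#' rounded up. `variance = "pooled"` uses the pooled null variance for the
#' alpha term: `(z_a sqrt(2 pbar qbar) + z_b sqrt(p0 q0 + p1 q1))^2 / (p1-p0)^2`.
#'
#' @param p0 control-arm risk.
#' @param rr treatment relative risk.
#' @param alpha two-sided type-I error rate.
#' @param power target power.
#' @param variance `"unpooled"` (default) or `"pooled"`.
#' @return Smallest integer per-arm sample size meeting the target.
#' @examples
#' required_sample_size(0.10, 0.75) # 2002, i.e. ~2000 per arm
#' @export
required_sample_size <- function(p0, rr, alpha = 0.05, power = 0.80,
                                 variance = c("unpooled", "pooled")) {
  variance <- match.arg(variance)
  stopifnot(p0 > 0, p0 < 1, rr > 0, alpha > 0, alpha < 1,
            power > 0, power < 1)
  p1 <- rr * p0
  if (p1 >= 1) stop("rr * p0 must be < 1", call. = FALSE)
  if (p1 == p0) stop("zero effect (rr = 1): sample size diverges", call. = FALSE)
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  v_alt <- p0 * (1 - p0) + p1 * (1 - p1)
  n <- if (variance == "unpooled") {
    (za + zb)^2 * v_alt / (p1 - p0)^2
  } else {
    pbar <- (p0 + p1) / 2
    (za * sqrt(2 * pbar * (1 - pbar)) + zb * sqrt(v_alt))^2 / (p1 - p0)^2
  }
  as.integer(ceiling(n))
}
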