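#' Convert a relative risk to a log odds ratio at a given baseline risk
#'
#' The simulation scenarios are framed clinically as relative risks (RR): the
#' treatment effect is the RR of the outcome under treatment vs control among
#' patients without the prognostic factor, and the prognostic-factor effect is
#' the RR for patients with vs without the factor in the control arm. The
#' logistic outcome model needs these on the log-odds-ratio scale. With
#' baseline risk \eqn{p} and risk \eqn{rr \cdot p} in the index group, the log
#' odds ratio is
#' \deqn{\log\frac{rr\,p/(1 - rr\,p)}{p/(1-p)}.}
#'
#' @param rr relative risk (> 0).
#' @param baseline_risk risk in the reference group, in (0, 1).
#' @return The log odds ratio whose risk ratio at `baseline_risk` equals `rr`.
#' @examples
#' rr_to_log_or(5, 0.10)    # 2.197
#' rr_to_log_or(0.75, 0.10) # -0.315
#' @export
rr_to_log_or <- function(rr, baseline_risk) {
  stopifnot(rr > 0, baseline_risk > 0, baseline_risk < 1)
  p1 <- rr * baseline_risk
  if (p1 >= 1) {
    stop("invalid effect: rr * baseline_risk = ", p1,
         " >= 1, risk would exceed 1", call. = FALSE)
  }
  log(p1 / (1 - p1)) - log(baseline_risk / (1 - baseline_risk))
}

#' Construct an effect specification from clinical inputs
#'
#' Bundles the baseline risk and the two relative risks with the implied
#' logistic coefficients: `b0 = logit(baseline_risk)` (log odds of the outcome
#' for untreated patients without the prognostic factor), `b1` the conditional
#' treatment log OR, `b2` the prognostic-factor log OR. Coefficients are kept
#' at full double precision.
#'
#' @param baseline_risk risk of the outcome in the control arm without the
#'   prognostic factor.
#' @param treatment_rr relative risk of the outcome under treatment (vs
#'   control) among patients without the factor.
#' @param pf_rr relative risk of the outcome for patients with (vs without)
#'   the factor in the control arm.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(baseline_risk, treatment_rr, pf_rr) {
  stopifnot(baseline_risk > 0, baseline_risk < 1,
            treatment_rr > 0, pf_rr > 0)
  structure(
    list(
      baseline_risk = baseline_risk,
      treatment_rr  = treatment_rr,
      pf_rr         = pf_rr,
      b0 = stats::qlogis(baseline_risk),
      b1 = rr_to_log_or(treatment_rr, baseline_risk),
      b2 = rr_to_log_or(pf_rr, baseline_risk)
    ),
    class = "effect_spec"
  )
}

#' @export
print.effect_spec <- function(x, ...) {
  cat("Effect specification\n")
  cat(sprintf("  baseline risk      : %.4g  (b0 = %.4f)\n", x$baseline_risk, x$b0))
  cat(sprintf("  treatment RR       : %.4g  (b1 = %.4f)\n", x$treatment_rr, x$b1))
  cat(sprintf("  prognostic-factor RR: %.4g (b2 = %.4f)\n", x$pf_rr, x$b2))
  invisible(x)
}

# The eight study scenarios: a 2x2x2 factorial in control-arm risk
# (0.10 / 0.05), treatment RR (0.75 / 1) and prognostic-factor RR (5 / 2).
scenario_table <- function() {
  data.frame(
    scenario_id   = 1:8,
    baseline_risk = c(0.10, 0.10, 0.10, 0.10, 0.05, 0.05, 0.05, 0.05),
    treatment_rr  = c(0.75, 0.75, 1, 1, 0.75, 0.75, 1, 1),
    pf_rr         = c(5, 2, 5, 2, 5, 2, 5, 2)
  )
}

#' Default prevalence grid for a setting
#'
#' The unconditional setting spans 14 prevalences from 0.005 to 0.995; the
#' conditional setting (a fixed 5-point between-arm difference) uses 11 values
#' from 0.05 to 0.95, since imposing a 5-point difference is infeasible or
#' vacuous at the extremes.
#'
#' @param setting `"unconditional"` or `"conditional"`.
#' @return Numeric vector of prevalences, ascending.
#' @export
default_lambda_grid <- function(setting = c("unconditional", "conditional")) {
  setting <- match.arg(setting)
  if (setting == "unconditional") {
    c(0.005, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 0.995)
  } else {
    c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95)
  }
}

#' Default per-arm sample-size grid
#'
#' 2000 per arm is the two-proportion sample-size solution for the moderate
#' effect scenario (control risk 0.10, RR 0.75, alpha 0.05, power 0.80);
#' 1000, 500 and 125 are 1/2, 1/4 and 1/16 of it, and 25 and 50 represent
#' small trials.
#'
#' @return Integer vector of per-arm sizes.
#' @export
default_n_grid <- function() c(25L, 50L, 125L, 500L, 1000L, 2000L)

#' Build a full scenario specification
#'
#' Looks up one of the eight study scenarios and assembles the simulation
#' specification: logistic coefficients (recomputed from the relative risks,
#' never hard-coded), prevalence grid matching the setting, per-arm size grid,
#' replicate count and seed.
#'
#' @param scenario_id integer in 1..8.
#' @param setting `"unconditional"` (prognostic-factor counts drawn
#'   Binomial(n, lambda) independently per arm) or `"conditional"` (a fixed
#'   5-percentage-point excess of the factor in the control arm).
#' @param n_replicates Monte-Carlo replicates per (lambda, n) cell.
#' @param seed base seed for reproducible streams.
#' @param lambda_grid,n_grid optional grid overrides.
#' @return An object of class `scenario_spec`.
#' @examples
#' build_scenario(1, "unconditional")
#' @export
build_scenario <- function(scenario_id,
                           setting = c("unconditional", "conditional"),
                           n_replicates = 10000L, seed = 1L,
                           lambda_grid = NULL, n_grid = NULL) {
  setting <- match.arg(setting)
  tab <- scenario_table()
  if (!(length(scenario_id) == 1 && scenario_id %in% tab$scenario_id)) {
    stop("unknown scenario_id: ", scenario_id, call. = FALSE)
  }
  row <- tab[tab$scenario_id == scenario_id, ]
  if (is.null(lambda_grid)) lambda_grid <- default_lambda_grid(setting)
  stopifnot(all(lambda_grid > 0), all(lambda_grid < 1),
            !is.unsorted(lambda_grid, strictly = TRUE))
  if (is.null(n_grid)) n_grid <- default_n_grid()
  structure(
    list(
      scenario_id = as.integer(scenario_id),
      effects = effect_spec(row$baseline_risk, row$treatment_rr, row$pf_rr),
      lambda_grid = lambda_grid,
      n_grid = as.integer(n_grid),
      setting = setting,
      imbalance_delta = if (setting == "conditional") 0.05 else 0,
      n_replicates = as.integer(n_replicates),
      seed = as.integer(seed)
    ),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario %d (%s setting)\n", x$scenario_id, x$setting))
  print(x$effects)
  cat(sprintf("  lambda grid : %s\n", paste(x$lambda_grid, collapse = ", ")))
  cat(sprintf("  n grid      : %s\n", paste(x$n_grid, collapse = ", ")))
  cat(sprintf("  replicates  : %d, seed %d\n", x$n_replicates, x$seed))
  invisible(x)
}

#' True outcome probability for one treatment-by-factor cell
#'
#' Inverse logit of `b0 + b1 * t + b2 * c` — the data-generating model for a
#' patient with treatment indicator `t` and prognostic-factor indicator `c`.
#'
#' @param effects an [effect_spec()].
#' @param t treatment indicator, 0 or 1 (vectorized).
#' @param c prognostic-factor indicator, 0 or 1 (vectorized).
#' @return Outcome probability in (0, 1).
#' @export
cell_probability <- function(effects, t, c) {
  stopifnot(inherits(effects, "effect_spec"), all(t %in% c(0, 1)), all(c %in% c(0, 1)))
  stats::plogis(effects$b0 + effects$b1 * t + effects$b2 * c)
}

#' Analytic marginal (collapsed) treatment log odds ratio
#'
#' The conditional treatment effect `b1` is a within-stratum odds ratio. The
#' marginal effect collapses the true cell probabilities over the
#' prognostic-factor distribution at prevalence `lam` (identical in both arms,
#' i.e. perfect balance) and takes the odds ratio of the two marginal risks.
#' Because the odds ratio is non-collapsible, the marginal log OR is
#' attenuated toward zero relative to `b1` whenever both `b1` and `b2` are
#' nonzero and `lam` is interior — even though there is no confounding. This
#' is the large-sample limit of the unadjusted logistic estimator under
#' perfectly balanced arms.
#'
#' @param effects an [effect_spec()].
#' @param lam prevalence of the prognostic factor, in [0, 1].
#' @return Marginal log odds ratio (treatment vs control).
#' @export
marginal_log_or <- function(effects, lam) {
  stopifnot(inherits(effects, "effect_spec"), lam >= 0, lam <= 1)
  risk <- function(t) {
    (1 - lam) * cell_probability(effects, t, 0) + lam * cell_probability(effects, t, 1)
  }
  p1 <- risk(1)
  p0 <- risk(0)
  log(p1 / (1 - p1)) - log(p0 / (1 - p0))
}
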