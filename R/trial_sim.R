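# Trial generator: one simulated RCT is reduced to its four treatment-by-
# prognostic-factor cells, each carrying a patient count and an event count.
# Outcomes are drawn per cell as Binomial(cell size, cell probability), which
# is distributionally identical to drawing one Bernoulli outcome per patient.

#' Construct a trial-counts object
#'
#' @param n_patients 2x2 matrix of patient counts, rows = treatment (0, 1),
#'   columns = prognostic factor (0, 1).
#' @param n_events 2x2 matrix of event counts, same layout.
#' @return An object of class `trial_counts` with per-arm totals `n0`, `n1`.
#' @export
trial_counts <- function(n_patients, n_events) {
  n_patients <- matrix(as.integer(n_patients), 2, 2,
                       dimnames = list(t = c("0", "1"), c = c("0", "1")))
  n_events <- matrix(as.integer(n_events), 2, 2,
                     dimnames = list(t = c("0", "1"), c = c("0", "1")))
  stopifnot(all(n_patients >= 0), all(n_events >= 0),
            all(n_events <= n_patients))
  structure(
    list(n_patients = n_patients, n_events = n_events,
         n0 = sum(n_patients["0", ]), n1 = sum(n_patients["1", ])),
    class = "trial_counts"
  )
}

#' @export
print.trial_counts <- function(x, ...) {
  cat("Trial counts (events / patients)\n")
  for (t in c("0", "1")) {
    cat(sprintf("  arm t=%s: c=0 %d/%d, c=1 %d/%d\n", t,
                x$n_events[t, "0"], x$n_patients[t, "0"],
                x$n_events[t, "1"], x$n_patients[t, "1"]))
  }
  invisible(x)
}

# Outcomes for fixed cell sizes: Binomial draws at the true cell probabilities.
draw_events <- function(effects, n_patients) {
  p <- matrix(cell_probability(effects,
                               t = c(0, 0, 1, 1), c = c(0, 1, 0, 1)), 2, 2,
              byrow = TRUE)
  matrix(stats::rbinom(4L, size = as.vector(n_patients), prob = as.vector(p)), 2, 2)
}

#' Simulate one trial, unconditional setting
#'
#' Prognostic-factor counts are drawn independently per arm from
#' Binomial(n, lambda) — between-arm imbalance arises purely from sampling
#' variability, as under simple randomization. Outcomes are then drawn per
#' cell from the logistic model. Uses the current R random stream; seed with
#' `set.seed()` (the runner derives one stream per grid cell via [seed_for()]).
#'
#' @param spec a [build_scenario()] specification.
#' @param lam prevalence of the prognostic factor, in (0, 1).
#' @param n patients per arm.
#' @return A [trial_counts()] object.
#' @export
simulate_unconditional <- function(spec, lam, n) {
  stopifnot(inherits(spec, "scenario_spec"), lam > 0, lam < 1, n >= 1)
  m <- stats::rbinom(2L, size = n, prob = lam) # PF-positive per arm: control, treatment
  n_pat <- rbind("0" = c(n - m[1L], m[1L]),
                 "1" = c(n - m[2L], m[2L]))
  trial_counts(n_pat, draw_events(spec$effects, n_pat))
}

# round half away from zero (base round() is half-to-even)
round_half_up <- function(x) floor(x + 0.5)

#' Fixed prognostic-factor counts for the conditional setting
#'
#' The conditional design imposes a fixed imbalance: `delta` (default 0.05)
#' more of the control arm carries the factor, at overall prevalence `lam`.
#' Counts are `round(n (lam + delta/2))` in control and
#' `round(n (lam - delta/2))` in treatment, rounding half away from zero;
#' if rounding perturbs the arm difference away from `round(n delta)` the
#' treatment count is adjusted so the between-arm difference in counts equals
#' `round(n delta)` exactly — the imposed difference is the design constraint,
#' the overall prevalence is secondary.
#'
#' @param lam overall prevalence.
#' @param n patients per arm.
#' @param delta imposed prevalence difference (control minus treatment).
#' @return Named integer vector `c(control = m0, treatment = m1)`.
#' @export
conditional_pf_counts <- function(lam, n, delta = 0.05) {
  m0 <- round_half_up(n * (lam + delta / 2))
  target_diff <- round_half_up(n * delta)
  m1 <- m0 - target_diff
  if (m1 < 0 || m0 > n) {
    stop(sprintf("infeasible conditional design: lam=%g, n=%d, delta=%g gives counts %d/%d",
                 lam, as.integer(n), delta, m0, m1), call. = FALSE)
  }
  c(control = as.integer(m0), treatment = as.integer(m1))
}

#' Simulate one trial, conditional setting
#'
#' Prognostic-factor counts are deterministic, fixed by
#' [conditional_pf_counts()] to impose a 5-percentage-point excess of the
#' factor in the control arm (the imbalance is a design constant, not
#' sampled). Outcomes are drawn exactly as in the unconditional setting given
#' those cell sizes.
#'
#' @inheritParams simulate_unconditional
#' @return A [trial_counts()] object.
#' @export
simulate_conditional <- function(spec, lam, n) {
  stopifnot(inherits(spec, "scenario_spec"), lam > 0, lam < 1, n >= 1)
  m <- conditional_pf_counts(lam, n, spec$imbalance_delta)
  n_pat <- rbind("0" = c(n - m[["control"]], m[["control"]]),
                 "1" = c(n - m[["treatment"]], m[["treatment"]]))
  trial_counts(n_pat, draw_events(spec$effects, n_pat))
}

#' Simulate one trial under the spec's setting
#'
#' Dispatches to [simulate_unconditional()] or [simulate_conditional()]
#' according to `spec$setting`.
#'
#' @inheritParams simulate_unconditional
#' @return A [trial_counts()] object.
#' @export
simulate_trial <- function(spec, lam, n) {
  if (spec$setting == "conditional") {
    simulate_conditional(spec, lam, n)
  } else {
    simulate_unconditional(spec, lam, n)
  }
}

#' Flatten a trial to one row per cell
#'
#' Long-format audit view: one row per treatment-by-factor cell with patient
#' and event counts, suitable for a replicate dump.
#'
#' @param x a [trial_counts()] object.
#' @param row.names,optional,... unused, for generic consistency.
#' @return A data.frame with columns `t`, `c`, `n_patients`, `n_events`.
#' @export
as.data.frame.trial_counts <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    t = c(0L, 0L, 1L, 1L),
    c = c(0L, 1L, 0L, 1L),
    n_patients = c(x$n_patients["0", ], x$n_patients["1", ]),
    n_events = c(x$n_events["0", ], x$n_events["1", ])
  )
}
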