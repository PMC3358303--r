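---
title: "Chance prognostic imbalance in two-arm trials: models, measures and Monte-Carlo design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chance prognostic imbalance in two-arm trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prognosim)
```

## The problem

Simple 1:1 randomization guarantees balance of prognostic factors only *in
expectation*. In any single trial, a binary prognostic factor (PF) with
prevalence $\lambda$ ends up in the two arms as two independent
$\mathrm{Bin}(n, \lambda)$ draws, and the realized between-arm difference can
be material, especially in small trials. `prognosim` quantifies two
consequences for trials with a binary outcome analyzed by logistic
regression: (i) how *likely* a given level of imbalance is, as a function of
$\lambda$ and the per-arm size $n$; and (ii) what omitting the PF from the
analysis does to the treatment-effect estimate — through chance imbalance
and, more subtly, through the non-collapsibility of the odds ratio, which
biases the unadjusted estimate even under perfect balance.

## Data-generating model

Each patient has a treatment indicator $T \in \{0, 1\}$ (equal allocation,
$n$ per arm) and a PF indicator $C \in \{0, 1\}$. Outcomes follow

$$\operatorname{logit} \Pr(Y = 1 \mid T, C) = \beta_0 + \beta_1 T + \beta_2 C,$$

so $\beta_0$ is the log odds of the outcome for untreated, PF-negative
patients, $\beta_1$ the conditional (within-stratum) treatment log OR, and
$\beta_2$ the PF log OR. A trial is fully described by the four $T \times C$
cells (patient and event counts); per-cell binomial sampling is
distributionally identical to per-patient Bernoulli sampling, and the suite
verifies this equivalence against a patient-level simulation.

Scenarios are specified clinically and converted internally: a baseline risk
$p$ and a relative risk $rr$ give
$\beta = \log\frac{rr\,p/(1-rr\,p)}{p/(1-p)}$ (`rr_to_log_or()`).
The packaged default grid (`prognosim_default_config()`) crosses control-arm
risk $\{0.10, 0.05\}$, treatment RR $\{0.75, 1\}$ and PF RR $\{5, 2\}$ into
eight scenarios; coefficients are carried at full double precision, with the
familiar 3-decimal values (e.g. $\beta_2 = 2.197$ for RR 5 at risk 0.10)
reproduced only as test expectations.

Two settings generate the PF:

* **unconditional** — $C$-counts drawn $\mathrm{Bin}(n, \lambda)$
  independently per arm; imbalance is whatever randomization produces.
  Default $\lambda$ grid: 14 values from 0.005 to 0.995.
* **conditional** — the imbalance is the *design*: the control arm carries a
  fixed 5-percentage-point PF excess at overall prevalence $\lambda$
  (11 values, 0.05–0.95; outside that range a 5-point difference is
  essentially infeasible).

### Rounding in the conditional design

With non-integer $n(\lambda \pm 0.025)$ some convention is unavoidable. We
round half away from zero and then constrain the arm difference to
$\mathrm{round}(0.05\,n)$ (adjusting the treatment-arm count), so the imposed
difference — the quantity the setting exists to study — is exact in counts;
the overall prevalence absorbs the remainder. At $n = 125$ the realized
difference is $6/125 = 0.048$, which slightly dilutes conditional-setting
biases relative to an ideal 0.05; this is visible (third decimal) in the
scenario-2 averaged bias.

## Imbalance measures

Both measures use continuity-corrected prevalences $(m + 0.5)/(n + 1)$,
keeping proportions strictly inside $(0,1)$ even when an arm has zero (or
only) PF-positive patients:

* $D_1 = |p^c_1 - p^c_0|$, the absolute difference — the primary,
  clinician-facing measure;
* $D_2 = D_1 \big/ \sqrt{(p^c_1(1-p^c_1) + p^c_0(1-p^c_0))/2}$, the
  standardized difference, approximately $\lambda$-invariant. The pooled-SD
  denominator is the standard two-group form from the imbalance literature;
  we adopt it as the package's definition.

Exceedance curves $\Pr(D \ge d)$ (closed thresholds, default grid
$d = 0.005,\dots,0.20$) come in two routes: Monte Carlo
(`imbalance_curve_mc()`) and exact double-binomial enumeration
(`imbalance_curve_exact()`), which sums
$\mathrm{Bin}(k_1; n, \lambda)\mathrm{Bin}(k_0; n, \lambda)$ over all
$(n+1)^2$ count pairs. Enumeration is $O(n^2)$ and capped at $n \le 4000$
(about $16 \times 10^6$ terms, seconds of work); it is the oracle against
which the MC route is tested. Enumeration shows, for instance, that at
$\lambda = 0.5$ the probability of a $\ge 5$-point imbalance is 0.411 at
125/arm and 0.024 at 1000/arm.

## Estimation

Each simulated trial is fit two ways:

* **adjusted** — the three-parameter generating model, by IRLS
  (`stats::glm.fit` on the four aggregated binomial cells; relative-deviance
  tolerance $10^{-10}$, 100 iterations). The Wald SE comes from the inverse
  information at the MLE (observed = expected under the canonical logit
  link). Because the relative-deviance rule can stall at floating-point
  resolution on near-saturated aggregated counts, a fit is also accepted
  when the score equations hold to $10^{-8}$ relative to the total patient
  count. When $C$ is constant the PF column is dropped and the fit
  coincides with the unadjusted one.
* **unadjusted** — intercept + treatment only; on the collapsed $2\times2$
  table the MLE is the sample log OR with SE
  $\sqrt{1/a + 1/(n_1-a) + 1/b + 1/(n_0-b)}$, so it is computed in closed
  form.

**Separation.** A zero margin makes the logistic MLE infinite. The fallback
adds 0.5 events and 0.5 non-events to every cell of the model's design,
refits, and flags the replicate `corrected`. The choice mirrors the
continuity correction used for the imbalance measures; alternatives (Firth
penalization, profile CIs) are deliberately out of scope. Summaries count
corrected and non-converged replicates, and a strict variant excluding
corrected fits is always available (`include_corrected = FALSE`,
`performance_strict` in run bundles), since it is not knowable whether such
replicates should be kept when comparing against published figures.

Confidence intervals are Wald, $\hat\beta_1 \pm 1.959964\,\mathrm{SE}$ at
95%.

## Performance metrics and their estimand

For both models the estimand is the **conditional** $\beta_1$: bias
$= \overline{\hat\beta_1} - \beta_1$, empirical SD, MSE, coverage
(CIs containing $\beta_1$) and power (CIs excluding 0). Holding the
unadjusted model to the conditional estimand is a deliberate choice — it is
exactly what makes non-collapsibility visible as under-coverage at large
$n$. Power loss from not adjusting is reported both as an absolute
difference in points and relative to the adjusted model's power
(`power_loss(..., relative = TRUE)`); the relative scale is the one such
losses are usually quoted on and stays informative near the power floor and
ceiling, where absolute differences are compressed. The analytic anchor is
`marginal_log_or()`, which collapses the true
cell probabilities over $C$ at prevalence $\lambda$ in both arms: for the
strong-PF scenario at $\lambda = 0.5$ it gives $-0.2597$ against the
conditional $-0.3151$, and the mean unadjusted estimate converges to the
former. Attenuation is unimodal in $\lambda$ (maximal near
$\lambda \approx 0.36$ in that scenario, vanishing at $\lambda \in \{0,1\}$) —
a property the test suite checks, rather than monotonicity up to 0.5.

On the clinical scale, replicate deviations of the odds-ratio reduction
($\mathrm{ORR} = 1 - e^{\beta_1}$) are tabulated as
$\Pr(D_\mathrm{ORR} \ge d)$ / $\Pr(D_\mathrm{ORR} \le -d)$ /
$\Pr(|D_\mathrm{ORR}| \ge d)$ for $d = 0, 0.05, \dots, 0.25$, with positive
deviations meaning the treatment looks better than it is. At $d = 0$ the
two-sided probability is 1 by convention and the split reports
$\Pr(D_\mathrm{ORR} \ge 0)$ vs $\Pr(< 0)$.

The design anchor `required_sample_size()` uses the unpooled two-proportion
normal approximation
$n = (z_{1-\alpha/2} + z_{1-\beta})^2 [p_0 q_0 + p_1 q_1] / (p_1 - p_0)^2$
(2002/arm for risk 0.10 vs RR 0.75 at $\alpha = 0.05$, power 0.80 — the
"2000 per arm" anchor; the pooled-variance variant, 2005/arm here, is
available via `variance = "pooled"`).

## Reproducibility

Every grid cell gets its own Mersenne–Twister stream via
`seed_for(base_seed, scenario, setting, lambda, n)`, an injective encoding
of the cell tuple (3-decimal $\lambda$ resolution, $n < 10^5$), so any
single table cell can be regenerated in isolation and a full rerun is
bit-identical. `run_experiment()` consumes a YAML configuration, skips
infeasible conditional cells with a warning, and writes upsert-style CSV
tables plus a JSON manifest recording the seed rule and cell counts.

## Problem sizes and Monte-Carlo error

The default replicate count is 10,000 per cell, at which a coverage
proportion near 0.9 carries a standard error of about 0.3 percentage points
and a power difference about 0.4–0.6 points. The test suite runs its heavy
checks at 10,000 replicates on a handful of focal cells (a few minutes
total) and smaller counts (400–5,000) for distributional properties; the
`analysis/` drivers default to focal sub-grids of the full factorial for the
same reason, with `--full` escaping to the complete grid where offered.
When comparing against *published* Monte-Carlo figures, both sides of the
comparison are 10,000-replicate estimates, so agreement bands use the SE of
a difference of two such draws.

## What the generator does and does not emulate

The simulated world is exactly the assumed model: a single binary PF, equal
allocation, binomial outcomes, no dropout, no measurement error, no other
covariates, logistic link true by construction. Passing tests therefore
validate the machinery and the published quantities under these conditions;
they say nothing about model misspecification, continuous or multiple
correlated prognostic factors, stratified or blocked randomization (all
deliberately out of scope), or risk-scale estimands (risk ratio, risk
difference), for which collapsibility behaves differently.

## Known limitations

* Exact enumeration is dense $O(n^2)$; beyond $n = 4000$ use Monte Carlo.
* The separation fallback is one convention among several; conclusions at
  $n = 25$ with rare events are sensitive to it, which is why corrected
  counts are always reported.
* The standardized-difference denominator is fixed to the two-group pooled
  form; no alternative definitions are implemented.
* Wald inference only; profile-likelihood or score intervals are not
  provided.
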