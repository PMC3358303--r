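#!/usr/bin/env Rscript
# Unconditional setting: what does omitting a strong prognostic factor from
# the logistic analysis cost? Bias, empirical SD, MSE, 95%-CI coverage and
# power for the adjusted (treatment + factor) vs unadjusted (treatment only)
# models, scenario 1 (control risk 0.10, treatment RR 0.75, factor RR 5).
#
# The replicate count and grid are configurable; the default below keeps a
# laptop run to a few minutes while giving ~0.5%-precision on coverage.
# Pass "--full" to use the full 14-lambda grid.
#
# Findings this script prints: the unadjusted log OR is attenuated toward
# zero (bias ~ +0.055 at lambda 0.5: the marginal, non-collapsible effect),
# its CI coverage decays with n (to ~88% at 2000/arm) while the adjusted
# model holds ~95%, and adjustment buys up to ~8-15 points of power at
# intermediate n.

suppressPackageStartupMessages(library(prognosim))

full <- any(commandArgs(trailingOnly = TRUE) == "--full")
reps <- 10000L
lambda_grid <- if (full) NULL else c(0.05, 0.2, 0.5, 0.8)
n_grid <- c(125L, 500L, 1000L, 2000L)

cfg <- list(
  scenarios = list(list(id = 1, baseline_risk = 0.10, treatment_rr = 0.75, pf_rr = 5)),
  settings = "unconditional",
  lambda_grid = lambda_grid, n_grid = n_grid,
  n_replicates = reps, base_seed = 20120401
)
res <- run_experiment(cfg)
write_results(res, "results/unconditional_s1")

perf <- res$performance
focal <- subset(perf, lam == 0.5,
                select = c(model, n, bias, empirical_sd, coverage, power))
cat("Scenario 1, prevalence 0.5 (", reps, "replicates/cell ):\n")
print(focal[order(focal$n, focal$model), ], row.names = FALSE, digits = 3)

cat("\nPower loss of the unadjusted model by n at lambda 0.5:\n")
for (nn in n_grid) {
  pu <- subset(perf, lam == 0.5 & n == nn & model == "unadjusted")
  pa <- subset(perf, lam == 0.5 & n == nn & model == "adjusted")
  cat(sprintf("  n=%4d: %5.2f points absolute, %5.2f%% of adjusted power\n",
              nn, power_loss(pu, pa), power_loss(pu, pa, relative = TRUE)))
}

cat("\nAnalytic marginal log OR at lambda 0.5:",
    round(marginal_log_or(build_scenario(1, "unconditional")$effects, 0.5), 4),
    "(conditional effect -0.3151)\n")
cat("Wrote results/unconditional_s1/\n")
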