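#!/usr/bin/env Rscript
# Conditional setting: the trial you actually got has 5% more factor-positive
# patients in the control arm. How biased is the unadjusted treatment effect,
# and does adjustment repair it? Scenarios 1 (factor RR 5) and 2 (factor
# RR 2) across the 11-value prevalence grid.
#
# Findings this script prints: ignoring the imbalanced factor overestimates
# the treatment benefit (negative bias of the log OR when b1 < 0); with a
# strong factor and 125/arm the bias reaches -0.18..-0.09 for rare factors,
# while the adjusted model is roughly unbiased throughout. With the moderate
# factor the averaged unadjusted bias at 125/arm is about -0.05.

suppressPackageStartupMessages(library(prognosim))

reps <- 10000L
dir.create("results", showWarnings = FALSE)

for (id in c(1L, 2L)) {
  spec <- build_scenario(id, "conditional", n_replicates = reps, seed = 20120401)
  rows <- list()
  for (lam in spec$lambda_grid) {
    fits <- run_cell(spec, lam, 125)
    for (m in c("unadjusted", "adjusted")) {
      s <- summarize_fits(fits[fits$model == m, ], spec$effects$b1)
      rows[[length(rows) + 1L]] <- cbind(data.frame(lam = lam, model = m), s)
    }
  }
  tab <- do.call(rbind, rows)
  write.csv(tab, sprintf("results/conditional_bias_s%d.csv", id), row.names = FALSE)

  cat(sprintf("\nScenario %d, conditional, n = 125/arm (%d reps/cell):\n", id, reps))
  un <- subset(tab, model == "unadjusted")
  cat("  unadjusted bias by lambda:\n")
  print(un[, c("lam", "bias", "coverage")], row.names = FALSE, digits = 2)
  cat(sprintf("  averaged unadjusted bias over the 11 prevalences: %.4f\n",
              mean(un$bias)))
  cat(sprintf("  averaged adjusted bias: %.4f\n",
              mean(subset(tab, model == "adjusted")$bias)))
}
cat("Wrote results/conditional_bias_s{1,2}.csv\n")
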