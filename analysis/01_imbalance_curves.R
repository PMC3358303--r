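#!/usr/bin/env Rscript
# How likely is a chance imbalance in a binary prognostic factor between the
# arms of a simply-randomized trial? Exceedance curves Pr(D >= d) for the
# absolute (D1) and standardized (D2) measures over the full prevalence and
# sample-size grids, by exact double-binomial enumeration, cross-checked by
# Monte Carlo at two focal cells.
#
# Key finding at prevalence 0.5: Pr(D1 >= 0.05) is ~0.67 / 0.62 / 0.41 with
# 25 / 50 / 125 patients per arm, and falls to ~0.02 at 1000 per arm —
# only four-digit trials give real protection against a 5-point imbalance.

suppressPackageStartupMessages(library(prognosim))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

curves <- list()
for (measure in c("absolute", "standardized")) {
  for (lam in default_lambda_grid("unconditional")) {
    for (n in default_n_grid()) {
      curves[[length(curves) + 1L]] <-
        as.data.frame(imbalance_curve_exact(lam, n, measure = measure))
    }
  }
}
curves <- do.call(rbind, curves)
write.csv(curves, file.path(out_dir, "imbalance_curves.csv"), row.names = FALSE)

focal <- subset(curves, measure == "absolute" & lam == 0.5 & d == 0.05)
cat("Pr(D1 >= 0.05) at prevalence 0.5, by patients per arm:\n")
print(focal[order(focal$n), c("n", "prob")], row.names = FALSE)

# Monte-Carlo cross-check at two cells
for (cell in list(c(0.5, 125), c(0.05, 125))) {
  set.seed(seed_for(20120401, 1, "unconditional", cell[1], cell[2]))
  mc <- imbalance_curve_mc(cell[1], cell[2], thresholds = 0.05,
                           n_replicates = 10000)$probabilities
  ex <- imbalance_curve_exact(cell[1], cell[2], thresholds = 0.05)$probabilities
  cat(sprintf("lambda=%.2f n=%d: exact %.4f, MC %.4f (10,000 reps)\n",
              cell[1], cell[2], ex, mc))
}
cat("Wrote", file.path(out_dir, "imbalance_curves.csv"), "\n")
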