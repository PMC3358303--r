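Package: prognosim
Title: Simulation of Chance Prognostic Imbalance in Two-Arm Randomized Trials
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo machinery for studying chance imbalance in a binary
    prognostic factor between the arms of a parallel-group randomized
    controlled trial with a binary outcome. Simulates trials under a logistic
    outcome model, quantifies between-arm imbalance with absolute and
    standardized difference measures (with continuity correction), computes
    exceedance-probability curves both by simulation and by exact
    double-binomial enumeration, contrasts covariate-adjusted and unadjusted
    logistic estimation of the treatment effect (bias, empirical SD, MSE,
    confidence-interval coverage, power, odds-ratio-reduction deviation
    tables), and provides the two-proportion normal-approximation sample-size
    calculation. Includes a scenario runner driven by plain-text
    configuration with reproducible per-cell seeding.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
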