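# Between-arm imbalance in the prevalence of a binary prognostic factor.
# Both measures work on continuity-corrected prevalences so that arms with
# zero (or all) factor-positive patients still give proportions strictly
# inside (0, 1).

#' Continuity-corrected prevalence
#'
#' Adds 0.5 to both cells of an arm's factor-positive / factor-negative split
#' before forming the proportion: `(m + 0.5) / (n + 1)`. Always strictly
#' inside (0, 1), even at `m = 0` or `m = n`.
#'
#' @param m factor-positive count in the arm (vectorized).
#' @param n arm size.
#' @return Corrected proportion in (0, 1).
#' @export
corrected_prevalence <- function(m, n) {
  stopifnot(all(m >= 0), all(m <= n), all(n >= 1))
  (m + 0.5) / (n + 1)
}

corrected_prevalences <- function(counts) {
  c(p0 = corrected_prevalence(counts$n_patients["0", "1"], counts$n0),
    p1 = corrected_prevalence(counts$n_patients["1", "1"], counts$n1))
}

#' Absolute between-arm difference in prognostic-factor prevalence
#'
#' `D1 = |p1 - p0|` on continuity-corrected prevalences: the primary,
#' clinically intuitive imbalance measure.
#'
#' @param counts a [trial_counts()] object.
#' @return Value in \[0, 1); symmetric under arm exchange.
#' @export
d1 <- function(counts) {
  p <- corrected_prevalences(counts)
  abs(p[["p1"]] - p[["p0"]])
}

#' Standardized between-arm difference in prognostic-factor prevalence
#'
#' `D2 = D1 / sqrt((p1 (1 - p1) + p0 (1 - p0)) / 2)` on continuity-corrected
#' prevalences — the absolute difference scaled by the pooled binary standard
#' deviation, making the measure approximately invariant to the underlying
#' prevalence.
#'
#' @param counts a [trial_counts()] object.
#' @return Non-negative standardized difference; symmetric under arm exchange.
#' @export
d2 <- function(counts) {
  p <- corrected_prevalences(counts)
  pooled_sd <- sqrt((p[["p1"]] * (1 - p[["p1"]]) + p[["p0"]] * (1 - p[["p0"]])) / 2)
  abs(p[["p1"]] - p[["p0"]]) / pooled_sd
}

# vectorized measures from factor-positive counts per arm
imbalance_measure <- function(m1, m0, n, measure) {
  p1 <- corrected_prevalence(m1, n)
  p0 <- corrected_prevalence(m0, n)
  D <- abs(p1 - p0)
  if (measure == "standardized") {
    D <- D / sqrt((p1 * (1 - p1) + p0 * (1 - p0)) / 2)
  }
  D
}

default_d1_thresholds <- function() c(0.005, 0.01, 0.025, 0.05, 0.10, 0.15, 0.20)

new_imbalance_distribution <- function(lam, n, measure, thresholds, probabilities,
                                       method, n_replicates = NA_integer_) {
  structure(
    list(lam = lam, n = as.integer(n), measure = measure,
         thresholds = thresholds, probabilities = probabilities,
         method = method, n_replicates = n_replicates),
    class = "imbalance_distribution"
  )
}

#' @export
print.imbalance_distribution <- function(x, ...) {
  cat(sprintf("Pr(D >= d), %s measure, lambda = %g, n = %d/arm (%s%s)\n",
              x$measure, x$lam, x$n, x$method,
              if (x$method == "monte_carlo") sprintf(", %d replicates", x$n_replicates) else ""))
  print(data.frame(d = x$thresholds, prob = x$probabilities), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.imbalance_distribution <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(lam = x$lam, n = x$n, measure = x$measure, d = x$thresholds,
             prob = x$probabilities, method = x$method)
}

#' Monte-Carlo exceedance curve for between-arm imbalance
#'
#' Draws factor-positive counts for the two arms from Binomial(n, lambda)
#' (the unconditional design; outcomes are irrelevant to imbalance) and
#' estimates `Pr(D >= d)` for each threshold. Thresholds are closed
#' (`>=`). Uses the current R random stream.
#'
#' @param lam prevalence of the prognostic factor.
#' @param n patients per arm.
#' @param thresholds vector of imbalance thresholds `d`.
#' @param n_replicates Monte-Carlo replicates.
#' @param measure `"absolute"` (D1) or `"standardized"` (D2).
#' @return An `imbalance_distribution` object.
#' @export
imbalance_curve_mc <- function(lam, n, thresholds = default_d1_thresholds(),
                               n_replicates = 10000L,
                               measure = c("absolute", "standardized")) {
  measure <- match.arg(measure)
  stopifnot(lam > 0, lam < 1, n >= 1, n_replicates >= 1)
  m1 <- stats::rbinom(n_replicates, n, lam)
  m0 <- stats::rbinom(n_replicates, n, lam)
  D <- imbalance_measure(m1, m0, n, measure)
  probs <- vapply(thresholds, function(d) mean(D >= d), numeric(1))
  new_imbalance_distribution(lam, n, measure, thresholds, probs,
                             "monte_carlo", as.integer(n_replicates))
}

#' Exact exceedance curve by double-binomial enumeration
#'
#' Computes `Pr(D >= d)` exactly as
#' \deqn{\sum_{k_1, k_0} \mathrm{Bin}(k_1; n, \lambda)\,
#'       \mathrm{Bin}(k_0; n, \lambda)\, 1[D(k_1, k_0) \ge d],}
#' enumerating all (n+1)^2 pairs of factor-positive counts. O(n^2) memory and
#' time; intended for n up to a few thousand (n = 2000 enumerates ~4e6 terms
#' in seconds).
#'
#' @inheritParams imbalance_curve_mc
#' @param n_max guard on the enumeration size.
#' @return An `imbalance_distribution` object.
#' @export
imbalance_curve_exact <- function(lam, n, thresholds = default_d1_thresholds(),
                                  measure = c("absolute", "standardized"),
                                  n_max = 4000L) {
  measure <- match.arg(measure)
  stopifnot(lam > 0, lam < 1, n >= 1)
  if (n > n_max) {
    stop("exact enumeration supports n <= ", n_max, " (O(n^2) terms)", call. = FALSE)
  }
  k <- 0:n
  pk <- stats::dbinom(k, n, lam)
  pc <- corrected_prevalence(k, n)
  P <- outer(pk, pk)
  D <- if (measure == "absolute") {
    # |p1c - p0c| with a common continuity correction: |k1 - k0| / (n + 1)
    abs(outer(pc, pc, "-"))
  } else {
    outer(pc, pc, function(a, b) {
      abs(a - b) / sqrt((a * (1 - a) + b * (1 - b)) / 2)
    })
  }
  probs <- vapply(thresholds, function(d) sum(P[D >= d]), numeric(1))
  probs <- pmin(pmax(probs, 0), 1)
  new_imbalance_distribution(lam, n, measure, thresholds, probs, "exact")
}
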