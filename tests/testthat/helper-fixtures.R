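# Shared fixtures and independent oracles for the test suite.

# quick trial_counts constructor from per-cell vectors (t0c0, t0c1, t1c0, t1c1)
make_counts <- function(patients, events) {
  trial_counts(matrix(patients, 2, 2, byrow = TRUE),
               matrix(events, 2, 2, byrow = TRUE))
}

# independent log-likelihood for the aggregated-binomial logistic model
loglik_cells <- function(beta, X, events, sizes) {
  eta <- as.vector(X %*% beta)
  p <- plogis(eta)
  sum(dbinom(events, sizes, p, log = TRUE))
}

# patient-level expansion of a trial: one Bernoulli row per patient
expand_patients <- function(counts) {
  df <- as.data.frame(counts)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    if (r$n_patients == 0) return(NULL)
    data.frame(t = r$t, c = r$c,
               y = rep(c(1L, 0L), c(r$n_events, r$n_patients - r$n_events)))
  })
  do.call(rbind, rows)
}

# brute-force double-binomial exceedance probability by explicit loops
brute_force_exceedance <- function(lam, n, d, measure = "absolute") {
  total <- 0
  for (k1 in 0:n) for (k0 in 0:n) {
    p1 <- (k1 + 0.5) / (n + 1)
    p0 <- (k0 + 0.5) / (n + 1)
    D <- abs(p1 - p0)
    if (measure == "standardized") {
      D <- D / sqrt((p1 * (1 - p1) + p0 * (1 - p0)) / 2)
    }
    if (D >= d) total <- total + dbinom(k1, n, lam) * dbinom(k0, n, lam)
  }
  total
}

scenario1 <- build_scenario(1, "unconditional")
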