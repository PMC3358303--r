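# Experiment orchestration: reproducible per-cell random streams, the
# replicate loop for one (scenario, setting, lambda, n) cell, the factorial
# driver over a plain-text configuration, and delimited-table writers.

#' Deterministic stream seed for one simulation cell
#'
#' Maps (base seed, scenario, setting, lambda, n) to a seed in
#' [0, 2^31 - 2], injectively over the default grids (lambda is encoded at
#' 3-decimal resolution, n up to 100,000). Every cell of every results table
#' can therefore be regenerated in isolation. Stable across versions.
#'
#' @param base_seed run-level seed.
#' @param scenario scenario id, 1..8.
#' @param setting `"unconditional"` or `"conditional"`.
#' @param lam prevalence (3-decimal resolution).
#' @param n per-arm sample size (< 100,000).
#' @return Integer seed for `set.seed()`.
#' @export
seed_for <- function(base_seed, scenario, setting, lam, n) {
  s <- match(setting, c("unconditional", "conditional")) - 1L
  stopifnot(!is.na(s), scenario %in% 1:8, lam > 0, lam < 1, n >= 1, n < 1e5)
  composite <- (((scenario - 1) * 2 + s) * 1001 + round(lam * 1000)) * 100001 + n
  as.integer((composite + as.numeric(base_seed) * 7919) %% 2147483647)
}

#' Simulate and fit all replicates of one grid cell
#'
#' Seeds the stream with [seed_for()], then for each replicate simulates one
#' trial under the spec's setting and fits the requested models. Returns a
#' long data.frame of per-replicate fits (plus the absolute imbalance `d1`
#' of each simulated trial for audit), ready for [summarize_fits()] and
#' [deviation_table()].
#'
#' @param spec a [build_scenario()] specification.
#' @param lam prevalence of the prognostic factor.
#' @param n patients per arm.
#' @param n_replicates number of replicates (defaults to the spec's).
#' @param models character subset of `c("unadjusted", "adjusted")`.
#' @param base_seed run-level seed (defaults to the spec's).
#' @return data.frame with columns `replicate`, `model`, `beta1_hat`, `se1`,
#'   `ci_low`, `ci_high`, `converged`, `corrected`, `orr_hat`, `d1`.
#' @export
run_cell <- function(spec, lam, n, n_replicates = spec$n_replicates,
                     models = c("unadjusted", "adjusted"),
                     base_seed = spec$seed) {
  models <- match.arg(models, several.ok = TRUE)
  set.seed(seed_for(base_seed, spec$scenario_id, spec$setting, lam, n))
  R <- n_replicates
  num <- c("beta1_hat", "se1", "ci_low", "ci_high", "orr_hat", "d1")
  store <- lapply(models, function(m) {
    list(num = matrix(NA_real_, R, length(num), dimnames = list(NULL, num)),
         converged = logical(R), corrected = logical(R))
  })
  names(store) <- models
  for (r in seq_len(R)) {
    counts <- simulate_trial(spec, lam, n)
    dd <- d1(counts)
    for (m in models) {
      fit <- fit_trial(counts, m)
      store[[m]]$num[r, ] <- c(fit$beta1_hat, fit$se1, fit$ci_low,
                               fit$ci_high, fit$orr_hat, dd)
      store[[m]]$converged[r] <- fit$converged
      store[[m]]$corrected[r] <- fit$corrected
    }
  }
  out <- lapply(models, function(m) {
    s <- store[[m]]
    cbind(data.frame(replicate = seq_len(R), model = m),
          as.data.frame(s$num),
          data.frame(converged = s$converged, corrected = s$corrected))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Read a run configuration
#'
#' A run configuration is a YAML document with a `scenarios` list (each entry:
#' `id`, `baseline_risk`, `treatment_rr`, `pf_rr`) plus run-level fields:
#' `settings`, optional `lambda_grid`/`n_grid` overrides, `n_replicates`,
#' `base_seed`, `d1_thresholds`, `d2_thresholds`, `models`,
#' `replicate_dump`. The packaged default (`prognosim_default_config()`)
#' encodes the eight study scenarios.
#'
#' @param path path to a YAML configuration.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Path to the packaged default scenario configuration
#' @return File path of the YAML shipped with the package.
#' @export
prognosim_default_config <- function() {
  system.file("extdata", "default_scenarios.yaml", package = "prognosim",
              mustWork = TRUE)
}

validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg), length(cfg$scenarios) >= 1)
  defaults <- list(
    settings = c("unconditional", "conditional"),
    lambda_grid = NULL, n_grid = default_n_grid(),
    n_replicates = 10000L, base_seed = 20120401L,
    d1_thresholds = default_d1_thresholds(),
    d2_thresholds = default_d2_thresholds(),
    models = c("unadjusted", "adjusted"),
    replicate_dump = FALSE
  )
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  stopifnot(cfg$n_replicates >= 1,
            all(cfg$settings %in% c("unconditional", "conditional")),
            all(cfg$models %in% c("unadjusted", "adjusted")))
  for (sc in cfg$scenarios) {
    stopifnot(!is.null(sc$id), !is.null(sc$baseline_risk),
              !is.null(sc$treatment_rr), !is.null(sc$pf_rr))
  }
  structure(cfg, class = c("run_config", "list"))
}

scenario_from_config <- function(sc, setting, cfg) {
  spec <- build_scenario(1L, setting,
                         n_replicates = cfg$n_replicates,
                         seed = cfg$base_seed,
                         lambda_grid = cfg$lambda_grid,
                         n_grid = cfg$n_grid)
  spec$scenario_id <- as.integer(sc$id)
  spec$effects <- effect_spec(sc$baseline_risk, sc$treatment_rr, sc$pf_rr)
  spec
}

#' Run the factorial simulation experiment
#'
#' Iterates scenarios x settings x lambda grid x n grid, simulating and
#' fitting `n_replicates` trials per cell, and aggregates into the result
#' bundle: a performance long table (both with and without separation-
#' corrected replicates), an odds-ratio-reduction deviation long table,
#' imbalance exceedance curves per (lambda, n) (exact enumeration up to the
#' documented bound, Monte Carlo beyond), and a run manifest. Conditional
#' cells where the imposed 5-point difference is infeasible are skipped with
#' a warning and recorded in the manifest. Deterministic given (config, base
#' seed).
#'
#' @param config a `run_config` (from [read_run_config()]) or a path to one.
#' @return List of class `run_result`: `performance`, `performance_strict`,
#'   `deviations`, `imbalance`, `replicates` (NULL unless `replicate_dump`),
#'   `manifest`.
#' @export
run_experiment <- function(config = prognosim_default_config()) {
  cfg <- if (is.character(config)) read_run_config(config) else validate_run_config(config)
  perf <- list(); perf_strict <- list(); devs <- list(); dump <- list()
  skipped <- list(); n_cells <- 0L
  for (setting in cfg$settings) {
    lam_grid <- if (is.null(cfg$lambda_grid)) default_lambda_grid(setting) else cfg$lambda_grid
    for (sc in cfg$scenarios) {
      spec <- scenario_from_config(sc, setting, cfg)
      spec$lambda_grid <- lam_grid
      true_b1 <- spec$effects$b1
      for (lam in lam_grid) for (n in spec$n_grid) {
        if (setting == "conditional") {
          feasible <- tryCatch({conditional_pf_counts(lam, n, spec$imbalance_delta); TRUE},
                               error = function(e) FALSE)
          if (!feasible) {
            warning(sprintf("skipping infeasible conditional cell: scenario %d, lambda=%g, n=%d",
                            spec$scenario_id, lam, n), call. = FALSE)
            skipped[[length(skipped) + 1L]] <-
              data.frame(scenario_id = spec$scenario_id, setting = setting, lam = lam, n = n)
            next
          }
        }
        fits <- run_cell(spec, lam, n, models = cfg$models)
        n_cells <- n_cells + 1L
        key <- data.frame(scenario_id = spec$scenario_id, setting = setting,
                          lam = lam, n = n)
        for (m in cfg$models) {
          mf <- fits[fits$model == m, , drop = FALSE]
          perf[[length(perf) + 1L]] <-
            cbind(key, model = m, summarize_fits(mf, true_b1))
          perf_strict[[length(perf_strict) + 1L]] <-
            cbind(key, model = m,
                  summarize_fits(mf, true_b1, include_corrected = FALSE))
          devs[[length(devs) + 1L]] <-
            cbind(key, model = m,
                  deviation_table(mf, exp(true_b1), cfg$d2_thresholds))
        }
        if (isTRUE(cfg$replicate_dump)) dump[[length(dump) + 1L]] <- cbind(key, fits)
      }
    }
  }
  imb <- list()
  if ("unconditional" %in% cfg$settings) {
    lam_grid <- if (is.null(cfg$lambda_grid)) default_lambda_grid("unconditional") else cfg$lambda_grid
    for (lam in lam_grid) for (n in cfg$n_grid) {
      curve <- if (n <= 4000) {
        imbalance_curve_exact(lam, n, cfg$d1_thresholds)
      } else {
        set.seed(seed_for(cfg$base_seed, 1L, "unconditional", lam, n))
        imbalance_curve_mc(lam, n, cfg$d1_thresholds, cfg$n_replicates)
      }
      imb[[length(imb) + 1L]] <- as.data.frame(curve)
    }
  }
  manifest <- list(
    package = "prognosim",
    version = as.character(utils::packageVersion("prognosim")),
    base_seed = cfg$base_seed,
    n_replicates = cfg$n_replicates,
    seed_rule = "seed_for(base_seed, scenario, setting, lambda, n); Mersenne-Twister per cell",
    n_cells_run = n_cells,
    n_cells_skipped = length(skipped),
    skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
    models = cfg$models,
    settings = cfg$settings
  )
  structure(
    list(performance = do.call(rbind, perf),
         performance_strict = do.call(rbind, perf_strict),
         deviations = do.call(rbind, devs),
         imbalance = if (length(imb)) do.call(rbind, imb) else NULL,
         replicates = if (length(dump)) do.call(rbind, dump) else NULL,
         manifest = manifest),
    class = "run_result"
  )
}

#' Write a run-result bundle to delimited tables
#'
#' Writes `performance.csv`, `performance_strict.csv`, `deviations.csv`,
#' `imbalance.csv` (and `replicates.csv` if dumped) plus `manifest.json`
#' under `dir`. Writing is an upsert keyed by the cell identifiers: rerunning
#' a partial grid overwrites exactly the cells it recomputed and leaves other
#' rows in place.
#'
#' @param result a `run_result` from [run_experiment()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "run_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  keys <- list(
    performance = c("scenario_id", "setting", "lam", "n", "model"),
    performance_strict = c("scenario_id", "setting", "lam", "n", "model"),
    deviations = c("scenario_id", "setting", "lam", "n", "model", "d"),
    imbalance = c("lam", "n", "measure", "d"),
    replicates = c("scenario_id", "setting", "lam", "n", "model", "replicate")
  )
  for (nm in names(keys)) {
    df <- result[[nm]]
    if (is.null(df)) next
    upsert_csv(file.path(dir, paste0(nm, ".csv")), df, keys[[nm]])
  }
  manifest <- result$manifest
  if (!is.null(manifest$skipped)) manifest$skipped <- as.list(manifest$skipped)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

# overwrite rows sharing a key, keep the rest, write back sorted by key
upsert_csv <- function(path, df, key_cols) {
  if (file.exists(path)) {
    old <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (identical(sort(names(old)), sort(names(df)))) {
      key <- function(x) do.call(paste, c(x[key_cols], sep = "\r"))
      old <- old[!(key(old) %in% key(df)), , drop = FALSE]
      df <- rbind(old[names(df)], df)
    }
  }
  ord <- do.call(order, df[key_cols])
  utils::write.csv(df[ord, , drop = FALSE], path, row.names = FALSE)
  invisible(path)
}
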