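## Simulation harness: run a roster of estimators over a grid of
## scenarios / settings / sample sizes and report mean MD indices with
## Monte-Carlo standard errors, mirroring the layout of a
## method-by-scenario results table.

## estimator roster usable in run_study; comb1/comb2/comb3 are the
## equal / kurtosis / maxnorm weighted combined estimators
study_methods <- function() {
  list(
    amuse = function(x) amuse(x, tau = 1),
    sobi = function(x) sobi(x, lags = 1:6),
    gfobi = function(x) gfobi(x, lags = 0:6),
    gjade = function(x) gjade(x, lags = 0:6),
    vsobi = function(x) vsobi(x, lags = 1:6),
    nss_sd = function(x) nss_sd(x),
    nss_jd = function(x) nss_jd(x, K = 6),
    nss_td_jd = function(x) nss_td_jd(x, K = 6, lags = 0:6),
    comb1 = function(x) nss_sobi_gfobi(x, K = 6, lags1 = 0:6, lags2 = 0:6,
                                       scheme = "equal"),
    comb2 = function(x) nss_sobi_gfobi(x, K = 6, lags1 = 0:6, lags2 = 0:6,
                                       scheme = "kurtosis"),
    comb3 = function(x) nss_sobi_gfobi(x, K = 6, lags1 = 0:6, lags2 = 0:6,
                                       scheme = "maxnorm")
  )
}

## internal: per-replicate seed derivation (counter-based, < 2^31)
derive_seed <- function(master, counter) {
  (as.numeric(master) * 48271 + counter * 16807) %% 2147483647 + 1
}

#' Run a separation-performance simulation study
#'
#' For each (scenario, setting, T) cell, `reps` independent data sets
#' are generated (with per-replicate seeds derived from the master seed
#' by a counter scheme, so any cell can be reproduced in isolation) and
#' every method in the roster is applied to the same mixed ilr series;
#' performance is the minimum distance index against the true mixing
#' matrix. The defaults follow the usual benchmarking choices: SOBI
#' with lags 1..6, gFOBI 0..6, NSS methods with K = 6 intervals, the
#' combined estimator with K = 6 and both lag sets 0..6.
#'
#' @param methods character vector of roster names (see Details);
#'   default the six table methods.
#' @param scenarios subset of `c("LP", "SV", "MIX")`.
#' @param settings subset of 1:3.
#' @param T_sizes vector of series lengths.
#' @param reps replicates per cell.
#' @param seed master seed.
#' @param Omega mixing matrix; NULL for identity (without loss of
#'   generality by affine equivariance).
#' @param verbose print per-cell progress to stderr.
#' @return data.frame with columns method, scenario, setting, T,
#'   mean_md, se_md, reps, seed.
#' @export
run_study <- function(methods = c("sobi", "gfobi", "nss_jd",
                                  "comb1", "comb2", "comb3"),
                      scenarios = c("LP", "SV", "MIX"),
                      settings = 1, T_sizes = c(1000, 2000, 10000),
                      reps = 200, seed = 1, Omega = NULL,
                      verbose = FALSE) {
  roster <- study_methods()
  unknown <- setdiff(methods, names(roster))
  if (length(unknown) > 0)
    stop("unknown methods: ", paste(unknown, collapse = ", "))
  out <- list()
  counter <- 0
  for (setting in settings) {
    for (scenario in scenarios) {
      for (Tn in T_sizes) {
        md <- matrix(NA_real_, reps, length(methods),
                     dimnames = list(NULL, methods))
        for (r in seq_len(reps)) {
          counter <- counter + 1
          spec <- scenario_spec(scenario, setting = setting, T = Tn)
          sim <- generate_scenario(spec, Omega = Omega,
                                   seed = derive_seed(seed, counter))
          for (m in methods) {
            fit <- roster[[m]](sim$ilr)
            md[r, m] <- md_index(fit$unmixing, sim$Omega)$value
          }
        }
        for (m in methods) {
          out[[length(out) + 1]] <- data.frame(
            method = m, scenario = scenario, setting = setting, T = Tn,
            mean_md = mean(md[, m]),
            se_md = stats::sd(md[, m]) / sqrt(reps),
            reps = reps, seed = seed, stringsAsFactors = FALSE)
        }
        if (verbose)
          message(sprintf("setting %d / %s / T=%d done", setting,
                          scenario, Tn))
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("study_result", class(res))
  res
}

#' Lay out study results as a method-by-cell table
#'
#' One row per method, one column per (scenario, T) combination of mean
#' MD values, the usual presentation of separation benchmarks.
#'
#' @param res a [run_study()] result.
#' @return data.frame, methods in rows.
#' @export
study_table <- function(res) {
  res <- as.data.frame(res)
  res$cell <- paste(res$scenario, res$T, sep = "_")
  cells <- unique(res$cell)
  methods <- unique(res$method)
  tab <- data.frame(method = methods, stringsAsFactors = FALSE)
  for (cl in cells) {
    tab[[cl]] <- vapply(methods, function(m) {
      v <- res$mean_md[res$method == m & res$cell == cl]
      if (length(v) == 0) NA_real_ else v[1]
    }, numeric(1))
  }
  tab
}
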