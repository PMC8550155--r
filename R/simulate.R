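## Synthetic source processes and simulation scenarios: linear (ARMA)
## sources, stochastic-volatility sources (GARCH or log-AR(1)
## volatility), and the LP / SV / MIX scenario builder that mixes the
## latent ilr components and maps them to the simplex.

## internal: innovation sampler; logistic is standardized to unit variance
innov_fn <- function(innovations = c("gaussian", "logistic")) {
  innovations <- match.arg(innovations)
  if (innovations == "gaussian") function(n, ...) stats::rnorm(n)
  else function(n, ...) stats::rlogis(n, scale = sqrt(3) / pi)
}

#' Simulate a unit-variance linear (ARMA) source
#'
#' Stationary ARMA(ar, ma) simulated with burn-in and standardized to
#' zero sample mean and unit sample variance.
#'
#' @param T series length.
#' @param ar,ma coefficient vectors (either may be empty for white
#'   noise); non-stationary `ar` raises an error.
#' @param innovations `"gaussian"` or `"logistic"` (unit variance).
#' @param burn_in burn-in length; default 10 * (order + 1) + 100.
#' @param seed optional local RNG seed.
#' @return numeric vector of length T.
#' @export
generate_lp_source <- function(T, ar = numeric(0), ma = numeric(0),
                               innovations = "gaussian", burn_in = NULL,
                               seed = NULL) {
  if (length(ar) > 0 && any(Mod(polyroot(c(1, -ar))) <= 1))
    stop("AR coefficients are not stationary")
  order <- length(ar) + length(ma)
  if (is.null(burn_in)) burn_in <- 10 * (order + 1) + 100
  rg <- innov_fn(innovations)
  x <- with_local_seed(seed, {
    model <- list()
    if (length(ar) > 0) model$ar <- ar
    if (length(ma) > 0) model$ma <- ma
    as.numeric(stats::arima.sim(model, n = T, n.start = burn_in + order,
                                rand.gen = rg))
  })
  (x - mean(x)) / stats::sd(x)
}

#' Simulate a unit-variance stochastic-volatility source
#'
#' Either a GARCH(1,1) recursion sigma^2_t = omega + a eps^2_{t-1} +
#' b sigma^2_{t-1}, eps_t = sigma_t eta_t (default; omega = 1 - a - b so
#' the unconditional variance is 1), or a log-AR(1) volatility model
#' h_t = mu + phi (h_{t-1} - mu) + sigma_h u_t, eps_t = exp(h_t/2)
#' eta_t. Levels are serially uncorrelated; squares are positively
#' autocorrelated. Output is standardized to unit sample variance.
#'
#' @param T series length.
#' @param model `"garch"` or `"logsv"`.
#' @param a,b GARCH coefficients; requires a, b >= 0 and a + b < 1.
#' @param mu_h,phi_h,sigma_h log-volatility parameters (`|phi_h| < 1`).
#' @param innovations `"gaussian"` or `"logistic"` (for the level
#'   innovations eta_t).
#' @param burn_in burn-in length (default 500).
#' @param seed optional local RNG seed.
#' @return numeric vector of length T.
#' @export
generate_sv_source <- function(T, model = c("garch", "logsv"),
                               a = 0.1, b = 0.85,
                               mu_h = 0, phi_h = 0.95, sigma_h = 0.2,
                               innovations = "gaussian", burn_in = 500,
                               seed = NULL) {
  model <- match.arg(model)
  rg <- innov_fn(innovations)
  n <- T + burn_in
  x <- with_local_seed(seed, {
    eta <- rg(n)
    if (model == "garch") {
      if (a < 0 || b < 0) stop("GARCH coefficients must be nonnegative")
      if (a + b >= 1) stop("explosive GARCH parameters: a + b must be < 1")
      omega <- 1 - a - b
      sig2 <- numeric(n)
      eps <- numeric(n)
      sig2[1] <- 1
      eps[1] <- sqrt(sig2[1]) * eta[1]
      for (t in 2:n) {
        sig2[t] <- omega + a * eps[t - 1]^2 + b * sig2[t - 1]
        eps[t] <- sqrt(sig2[t]) * eta[t]
      }
      eps
    } else {
      if (abs(phi_h) >= 1) stop("explosive log-volatility: |phi_h| must be < 1")
      u <- stats::rnorm(n)
      h <- numeric(n)
      h[1] <- mu_h + sigma_h / sqrt(1 - phi_h^2) * u[1]
      for (t in 2:n) h[t] <- mu_h + phi_h * (h[t - 1] - mu_h) + sigma_h * u[t]
      exp(h / 2) * eta
    }
  })
  x <- x[(burn_in + 1):n]
  (x - mean(x)) / stats::sd(x)
}

## default per-source process parameters: AR coefficients spread over
## [0.2, 0.9] with an MA(1) theta = 0.3 on even-indexed sources (distinct
## ACFs), GARCH (a, b) pairs spread over a in [0.05, 0.2], b in [0.9, 0.7]
## (distinct fourth-moment structure, a + b <= 0.95)
default_lp_params <- function(k) {
  phis <- if (k == 1) 0.55 else seq(0.2, 0.9, length.out = k)
  lapply(seq_len(k), function(i)
    list(ar = phis[i], ma = if (i %% 2 == 0) 0.3 else numeric(0)))
}

default_sv_params <- function(k) {
  as_ <- if (k == 1) 0.12 else seq(0.05, 0.2, length.out = k)
  bs_ <- if (k == 1) 0.8 else seq(0.9, 0.7, length.out = k)
  lapply(seq_len(k), function(i)
    list(model = "garch", a = as_[i], b = bs_[i]))
}

#' Specify a simulation scenario
#'
#' Three latent scenarios for the ilr components: `"LP"` (all linear
#' processes), `"SV"` (all stochastic-volatility processes) and `"MIX"`
#' (half LP, half SV). Three settings: 1 = p 4, Gaussian innovations;
#' 2 = p 4, logistic (heavy-tailed) innovations; 3 = p 8, Gaussian.
#'
#' @param scenario `"LP"`, `"SV"` or `"MIX"`.
#' @param setting 1, 2 or 3 (fixes p and innovations unless overridden).
#' @param T series length.
#' @param p override the number of latent components (ilr dimension).
#' @param innovations override the innovation family.
#' @param lp_params list of per-source `list(ar=, ma=)` for the LP
#'   sources (defaults documented in the package vignette).
#' @param sv_params list of per-source GARCH/log-SV parameter lists.
#' @param seed RNG seed used by [generate_scenario()].
#' @return list of class `"scenario_spec"`.
#' @export
scenario_spec <- function(scenario = c("LP", "SV", "MIX"), setting = 1,
                          T = 1000, p = NULL, innovations = NULL,
                          lp_params = NULL, sv_params = NULL, seed = NULL) {
  scenario <- match.arg(scenario)
  if (!setting %in% 1:3) stop("setting must be 1, 2 or 3")
  if (is.null(p)) p <- if (setting == 3) 8 else 4
  if (is.null(innovations))
    innovations <- if (setting == 2) "logistic" else "gaussian"
  n_lp <- switch(scenario, LP = p, SV = 0, MIX = p %/% 2)
  n_sv <- p - n_lp
  if (scenario == "MIX" && p %% 2 != 0)
    stop("MIX scenario requires an even number of components")
  if (is.null(lp_params)) lp_params <- default_lp_params(max(n_lp, 1))
  if (is.null(sv_params)) sv_params <- default_sv_params(max(n_sv, 1))
  structure(list(scenario = scenario, setting = setting, T = T, p = p,
                 n_lp = n_lp, n_sv = n_sv, innovations = innovations,
                 lp_params = lp_params, sv_params = sv_params, seed = seed),
            class = "scenario_spec")
}

#' Generate a synthetic compositional time series from a scenario
#'
#' Simulates the latent unit-variance sources, mixes them in ilr space
#' with `Omega` (identity by default, without loss of generality given
#' the affine equivariance of all estimators) and maps the mixture
#' through the inverse ilr transform to a strictly positive, closed
#' composition with p + 1 parts.
#'
#' @param spec a [scenario_spec()].
#' @param Omega p x p mixing matrix, or NULL for the identity.
#' @param seed RNG seed (overrides the one in `spec`).
#' @return list of class `"cts_sim"`: `x` (the [composition_series()]),
#'   `ilr` (T x p mixed coordinate matrix), `sources` (T x p ground
#'   truth), `Omega`, `spec`.
#' @export
generate_scenario <- function(spec, Omega = NULL, seed = NULL) {
  if (!inherits(spec, "scenario_spec")) stop("spec must be a scenario_spec")
  if (is.null(seed)) seed <- spec$seed
  p <- spec$p
  if (is.null(Omega)) Omega <- diag(p)
  if (nrow(Omega) != p || ncol(Omega) != p) stop("Omega must be p x p")
  Z <- with_local_seed(seed, {
    cols <- vector("list", p)
    i <- 0
    for (k in seq_len(spec$n_lp)) {
      pr <- spec$lp_params[[k]]
      i <- i + 1
      cols[[i]] <- generate_lp_source(spec$T, ar = pr$ar, ma = pr$ma,
                                      innovations = spec$innovations)
    }
    for (k in seq_len(spec$n_sv)) {
      pr <- spec$sv_params[[k]]
      i <- i + 1
      cols[[i]] <- do.call(generate_sv_source,
                           c(list(T = spec$T,
                                  innovations = spec$innovations), pr))
    }
    do.call(cbind, cols)
  })
  mixed <- Z %*% t(Omega)
  x <- ilr_inverse(mixed)
  structure(list(x = x, ilr = mixed, sources = Z, Omega = Omega,
                 spec = spec),
            class = "cts_sim")
}
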