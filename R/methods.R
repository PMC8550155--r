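## The BSS estimators. All take a coordinate series (a "cts_coord", a
## plain T x d matrix, or a composition series which is first expressed
## in pivot ilr coordinates), and return a "bss" object with the
## unmixing matrix Gamma, the location estimate and the source series
## z_t = Gamma (x_t - mu). Components are ordered by a method-specific
## statistic (eigenvalue or per-component criterion contribution) and
## row signs are fixed so the largest-magnitude entry of each row of
## Gamma is positive, making results deterministic despite the model's
## sign/order indeterminacy.

## internal: coerce method input to a coordinate series
coord_input <- function(x) {
  if (inherits(x, "cts")) ilr_transform(x) else x
}

## internal: deterministic sign convention on the rows of Gamma
fix_signs <- function(Gamma) {
  s <- apply(Gamma, 1, function(r) sign(r[which.max(abs(r))]))
  s[s == 0] <- 1
  Gamma * s
}

## internal: assemble a bss result
bss_result <- function(Gamma, x, method, params, diagnostics = list()) {
  s <- as_series(x)
  Gamma <- fix_signs(Gamma)
  center <- colMeans(s$values)
  sources <- sweep(s$values, 2, center) %*% t(Gamma)
  colnames(sources) <- paste0("z", seq_len(ncol(sources)))
  structure(list(unmixing = Gamma, center = center, sources = sources,
                 timestamps = s$timestamps, method = method,
                 params = params, diagnostics = diagnostics),
            class = "bss")
}

#' @export
print.bss <- function(x, ...) {
  cat(sprintf("BSS decomposition (%s): %d components, %d time points\n",
              x$method, ncol(x$sources), nrow(x$sources)))
  if (isTRUE(x$diagnostics$gap_warning))
    cat("Warning flag: near-degenerate eigenvalue spectrum\n")
  if (identical(x$diagnostics$converged, FALSE))
    cat("Warning flag: optimizer did not converge\n")
  invisible(x)
}

#' @export
coef.bss <- function(object, ...) object$unmixing

## internal: order the rows of an AJD rotation by descending criterion
## contribution against a stack, then compose with the whitener
order_rotation <- function(ajd, stack_mats, weights, W) {
  U <- ajd$rotation
  contrib <- numeric(nrow(U))
  for (k in seq_along(stack_mats)) {
    d <- diag(U %*% (stack_mats[[k]] * weights[k]) %*% t(U))
    contrib <- contrib + d^2
  }
  ord <- order(contrib, decreasing = TRUE)
  list(Gamma = U[ord, , drop = FALSE] %*% W, contrib = contrib[ord])
}

#' AMUSE: second-order separation with a single lag
#'
#' Jointly diagonalizes the covariance and the symmetrized lag-tau
#' autocovariance via a generalized eigendecomposition. Components are
#' ordered by descending eigenvalue; identifiability requires the
#' sources' lag-tau autocorrelations to be distinct, so near-equal
#' eigenvalues set a `gap_warning` diagnostic.
#'
#' @param x coordinate series (or composition series; then pivot ilr
#'   coordinates are used), or numeric matrix.
#' @param tau positive integer lag (default 1).
#' @return a `"bss"` object.
#' @export
amuse <- function(x, tau = 1) {
  x <- coord_input(x)
  if (tau < 1) stop("tau must be a positive lag")
  mc <- sample_mean_cov(x)
  S <- autocovariance(x, tau, symmetrize = TRUE)
  g <- gevd_two_matrices(mc$cov, S)
  bss_result(g$Gamma, x, "amuse", list(tau = tau),
             list(eigenvalues = g$eigenvalues, gap_warning = g$gap_warning))
}

#' SOBI: second-order separation with several lags
#'
#' Whitens the series and jointly diagonalizes the symmetrized
#' autocovariance matrices at the given lags (Jacobi rotations).
#' Components are ordered by descending sum of squared rotated
#' autocovariance diagonals.
#'
#' @param x coordinate series or matrix.
#' @param lags positive integer lags (default 1:6, the usual choice for
#'   short-range serial dependence).
#' @return a `"bss"` object.
#' @export
sobi <- function(x, lags = 1:6) {
  x <- coord_input(x)
  if (any(lags < 1)) stop("SOBI lags must be positive")
  w <- whiten(x)
  mats <- lapply(lags, function(tau)
    autocovariance(w, tau, symmetrize = TRUE, center = rep(0, ncol(w$values))))
  ajd <- jacobi_ajd(matrix_stack(mats, family = "S", lag = lags))
  o <- order_rotation(ajd, mats, rep(1, length(mats)), w$whitener)
  bss_result(o$Gamma, x, "sobi", list(lags = lags),
             list(objective = ajd$objective, converged = ajd$converged,
                  contrib = o$contrib))
}

#' gFOBI: separation through fourth-order cross-moments
#'
#' Whitens the series and jointly diagonalizes the fourth-order
#' cross-moment matrices B_tau at the given lags; with lags = 0 this is
#' FOBI. Aimed at stochastic-volatility-type sources whose
#' autocovariances carry no information.
#'
#' @param x coordinate series or matrix.
#' @param lags nonnegative integer lags (default 0:6).
#' @return a `"bss"` object.
#' @export
gfobi <- function(x, lags = 0:6) {
  x <- coord_input(x)
  if (any(lags < 0)) stop("gFOBI lags must be nonnegative")
  w <- whiten(x)
  mats <- lapply(lags, function(tau) {
    B <- fourth_moment_matrix(w, tau)
    (B + t(B)) / 2
  })
  ajd <- jacobi_ajd(matrix_stack(mats, family = "B", lag = lags))
  o <- order_rotation(ajd, mats, rep(1, length(mats)), w$whitener)
  p <- ncol(w$values)
  # on Gaussian data every B_tau is near (p+2) I at lag 0 / 0 otherwise:
  # no usable eigen-gaps
  degdev <- vapply(seq_along(lags), function(k) {
    tgt <- if (lags[k] == 0) (p + 2) * diag(p) else matrix(0, p, p)
    max(abs(mats[[k]] - tgt))
  }, numeric(1))
  bss_result(o$Gamma, x, "gfobi", list(lags = lags),
             list(objective = ajd$objective, converged = ajd$converged,
                  contrib = o$contrib,
                  gap_warning = all(degdev < 0.1)))
}

#' gJADE: separation through fourth-order cross-cumulants
#'
#' Whitens the series and jointly diagonalizes all p^2 cross-cumulant
#' matrices C^{jk}_tau per lag; with lags = 0 this is JADE. More
#' matrices than gFOBI (p^2 per lag), hence a cost warning for large p.
#'
#' @param x coordinate series or matrix.
#' @param lags nonnegative integer lags (default 0:6).
#' @return a `"bss"` object.
#' @export
gjade <- function(x, lags = 0:6) {
  x <- coord_input(x)
  if (any(lags < 0)) stop("gJADE lags must be nonnegative")
  w <- whiten(x)
  p <- ncol(w$values)
  if (p > 12)
    warning(sprintf("gJADE diagonalizes %d matrices for p = %d; this may be slow",
                    p^2 * length(lags), p))
  mats <- list()
  for (tau in lags) mats <- c(mats, cross_cumulant_matrices(w, tau))
  ajd <- jacobi_ajd(matrix_stack(mats, family = "C",
                                 lag = rep(lags, each = p^2)))
  o <- order_rotation(ajd, mats, rep(1, length(mats)), w$whitener)
  bss_result(o$Gamma, x, "gjade", list(lags = lags),
             list(objective = ajd$objective, converged = ajd$converged,
                  contrib = o$contrib))
}

#' vSOBI: separation through a nonquadratic lagged contrast
#'
#' Whitens the series and maximizes, over orthogonal U, the sum over
#' lags and components of
#' (E[G(u_i'x_t) G(u_i'x_{t+tau})] - E[G(u_i'x_t)]^2)^2, a variant of
#' SOBI sensitive to volatility clustering.
#'
#' @param x coordinate series or matrix.
#' @param lags positive integer lags (default 1:6).
#' @param G `"square"` or `"logcosh"`.
#' @param n_restarts random restarts beyond the identity start.
#' @param seed RNG seed for the restarts.
#' @return a `"bss"` object.
#' @export
vsobi <- function(x, lags = 1:6, G = c("square", "logcosh"),
                  n_restarts = 5, seed = 1) {
  x <- coord_input(x)
  G <- match.arg(G)
  w <- whiten(x)
  ajd <- maximize_nonquadratic(w, lags, G = G, n_restarts = n_restarts,
                               seed = seed)
  ord <- order(ajd$diag_contrib, decreasing = TRUE)
  Gamma <- ajd$rotation[ord, , drop = FALSE] %*% w$whitener
  bss_result(Gamma, x, "vsobi",
             list(lags = lags, G = G, n_restarts = n_restarts, seed = seed),
             list(objective = ajd$objective, converged = ajd$converged,
                  contrib = ajd$diag_contrib[ord]))
}

#' NSS-SD: nonstationary separation from two interval covariances
#'
#' Jointly diagonalizes the covariance matrices of two time intervals
#' (default: the two halves of the series) by a generalized
#' eigendecomposition. Separation requires the interval variances to
#' differ across components; on stationary input all eigenvalues are
#' near 1 and `gap_warning` is set. Source scale is not identifiable
#' under nonstationarity, so sources are normalized to unit variance
#' over the full range.
#'
#' @param x coordinate series or matrix.
#' @param T1,T2 length-2 inclusive timestamp ranges; default: halves of
#'   the observed range.
#' @return a `"bss"` object.
#' @export
nss_sd <- function(x, T1 = NULL, T2 = NULL) {
  x <- coord_input(x)
  s <- as_series(x)
  if (is.null(T1) || is.null(T2)) {
    halves <- partition_intervals(s$timestamps, 2)
    if (is.null(T1)) T1 <- halves[[1]]
    if (is.null(T2)) T2 <- halves[[2]]
  }
  S1 <- local_autocovariance(x, T1, 0, symmetrize = TRUE)
  S2 <- local_autocovariance(x, T2, 0, symmetrize = TRUE)
  g <- gevd_two_matrices(S1, S2)
  # normalize each source to unit variance over the full observed range
  z <- sweep(s$values, 2, colMeans(s$values)) %*% t(g$Gamma)
  sds <- sqrt(colMeans(z^2))
  Gamma <- g$Gamma / sds
  bss_result(Gamma, x, "nss_sd", list(T1 = T1, T2 = T2),
             list(eigenvalues = g$eigenvalues, gap_warning = g$gap_warning))
}

#' NSS-JD: nonstationary separation from K interval covariances
#'
#' Whitens with the global covariance and jointly diagonalizes the
#' covariance matrices of K nonoverlapping intervals of the whitened
#' series. Exploits variance nonstationarity only; on stationary input
#' the interval covariances are all near the identity and the method
#' carries no information.
#'
#' @param x coordinate series or matrix.
#' @param K number of intervals (default 6).
#' @return a `"bss"` object.
#' @export
nss_jd <- function(x, K = 6) {
  x <- coord_input(x)
  w <- whiten(x)
  ivs <- partition_intervals(w$timestamps, K,
                             min_length = ncol(w$values) + 1)
  mats <- lapply(ivs, function(iv)
    local_autocovariance(w, iv, 0, symmetrize = TRUE))
  ajd <- jacobi_ajd(matrix_stack(mats, family = "S",
                                 interval = seq_len(K), lag = 0))
  o <- order_rotation(ajd, mats, rep(1, K), w$whitener)
  bss_result(o$Gamma, x, "nss_jd", list(K = K, intervals = ivs),
             list(objective = ajd$objective, converged = ajd$converged,
                  contrib = o$contrib))
}

#' NSS-TD-JD: block-stationary separation from interval autocovariances
#'
#' Whitens globally and jointly diagonalizes the local autocovariance
#' matrices of K intervals at each of the given lags, combining variance
#' nonstationarity with within-block serial dependence. With lags = 0 it
#' reduces to NSS-JD.
#'
#' @param x coordinate series or matrix.
#' @param K number of intervals (default 6).
#' @param lags nonnegative integer lags (default 0:6).
#' @return a `"bss"` object.
#' @export
nss_td_jd <- function(x, K = 6, lags = 0:6) {
  x <- coord_input(x)
  w <- whiten(x)
  maxlag <- max(lags)
  ivs <- if (K == 1) list(range(w$timestamps))
         else partition_intervals(w$timestamps, K,
                                  min_length = maxlag + ncol(w$values) + 1)
  mats <- list(); labs_int <- integer(0); labs_lag <- integer(0)
  for (k in seq_len(K)) {
    for (tau in lags) {
      mats <- c(mats, list(local_autocovariance(w, ivs[[k]], tau,
                                                symmetrize = TRUE)))
      labs_int <- c(labs_int, k); labs_lag <- c(labs_lag, tau)
    }
  }
  ajd <- jacobi_ajd(matrix_stack(mats, family = "S",
                                 interval = labs_int, lag = labs_lag))
  o <- order_rotation(ajd, mats, rep(1, length(mats)), w$whitener)
  bss_result(o$Gamma, x, "nss_td_jd", list(K = K, lags = lags,
                                           intervals = ivs),
             list(objective = ajd$objective, converged = ajd$converged,
                  contrib = o$contrib))
}

#' Build the interval-wise matrix stack of the combined estimator
#'
#' For each of K intervals of the globally whitened series, the local
#' autocovariances at the lags in `lags1` (family "S") and the local
#' fourth-order cross-moment matrices at the lags in `lags2`
#' (family "B"), with weights per scheme: `"equal"` gives every matrix
#' weight 1; `"kurtosis"` divides B matrices by p + 2 (the factor making
#' the scatter matrix of fourth moments consistent for the covariance at
#' the Gaussian model); `"maxnorm"` uses 1/max|V[k,l]| whenever the
#' largest absolute entry exceeds 1, leaving small (possibly
#' uninformative, near-zero) matrices unweighted.
#'
#' @param w a whitened series ([whiten()]).
#' @param K number of intervals.
#' @param lags1 lags for autocovariance (S) matrices.
#' @param lags2 lags for fourth-moment (B) matrices.
#' @param scheme weight scheme.
#' @return a [matrix_stack()] (attribute `intervals` holds the ranges).
#' @export
combined_stack <- function(w, K = 6, lags1 = 0:6, lags2 = 0:6,
                           scheme = c("maxnorm", "equal", "kurtosis")) {
  scheme <- match.arg(scheme)
  p <- ncol(w$values)
  maxlag <- max(c(lags1, lags2, 0))
  ivs <- partition_intervals(w$timestamps, K, min_length = maxlag + p + 1)
  mats <- list(); fam <- character(0)
  labs_int <- integer(0); labs_lag <- integer(0)
  for (k in seq_len(K)) {
    iv <- ivs[[k]]
    n_in <- sum(w$timestamps >= iv[1] & w$timestamps <= iv[2])
    if (n_in <= maxlag)
      stop(sprintf("interval %d ([%s, %s]) is shorter than the maximum lag %d",
                   k, iv[1], iv[2], maxlag))
    for (tau in lags1) {
      mats <- c(mats, list(local_autocovariance(w, iv, tau, symmetrize = TRUE)))
      fam <- c(fam, "S"); labs_int <- c(labs_int, k); labs_lag <- c(labs_lag, tau)
    }
    for (tau in lags2) {
      B <- fourth_moment_matrix(w, tau, interval = iv)
      mats <- c(mats, list((B + t(B)) / 2))
      fam <- c(fam, "B"); labs_int <- c(labs_int, k); labs_lag <- c(labs_lag, tau)
    }
  }
  weights <- switch(scheme,
    equal = rep(1, length(mats)),
    kurtosis = ifelse(fam == "B", 1 / (p + 2), 1),
    maxnorm = vapply(mats, function(M) {
      m <- max(abs(M))
      if (m > 1) 1 / m else 1
    }, numeric(1)))
  st <- matrix_stack(mats, family = fam, interval = labs_int,
                     lag = labs_lag, weights = weights)
  attr(st, "intervals") <- ivs
  st
}

#' NSS-SOBI-gFOBI: the weighted combined estimator
#'
#' Whitens with the global covariance, builds for each of K intervals
#' both the local autocovariances (lags in `lags1`) and the local
#' fourth-order cross-moment matrices (lags in `lags2`), applies a
#' weight scheme to make the two matrix families comparable, and jointly
#' diagonalizes the whole weighted stack. Covers second-order,
#' volatility-driven and nonstationary source structure in one
#' estimator; the weighted variants (`"kurtosis"`, `"maxnorm"`) prevent
#' the large fourth-moment matrices from dominating.
#'
#' @param x coordinate series or matrix.
#' @param K number of intervals (default 6).
#' @param lags1 lags for the autocovariance family (default 0:6).
#' @param lags2 lags for the fourth-moment family (default 0:6).
#' @param scheme `"equal"`, `"kurtosis"` or `"maxnorm"` (default).
#' @return a `"bss"` object.
#' @export
nss_sobi_gfobi <- function(x, K = 6, lags1 = 0:6, lags2 = 0:6,
                           scheme = c("maxnorm", "equal", "kurtosis")) {
  scheme <- match.arg(scheme)
  x <- coord_input(x)
  w <- whiten(x)
  st <- combined_stack(w, K = K, lags1 = lags1, lags2 = lags2,
                       scheme = scheme)
  ajd <- jacobi_ajd(st)
  o <- order_rotation(ajd, st$matrices, st$weights, w$whitener)
  bss_result(o$Gamma, x, "nss_sobi_gfobi",
             list(K = K, lags1 = lags1, lags2 = lags2, scheme = scheme,
                  intervals = attr(st, "intervals")),
             list(objective = ajd$objective, converged = ajd$converged,
                  contrib = o$contrib))
}
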