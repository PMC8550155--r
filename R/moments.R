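## Matrix statistics that the BSS estimators jointly diagonalize:
## covariance, (local) lagged autocovariances, fourth-order cross-moment
## and cross-cumulant matrices. All lagged statistics use valid-pair
## logic: a pair (t, t + tau) enters only when both timestamps are
## observed and differ by exactly tau sampling steps, so series with
## missing time points are handled throughout.

## internal: indices of valid (t, t+tau) pairs for integer-grid timestamps
lag_pairs <- function(timestamps, tau) {
  if (tau == 0) {
    i <- seq_along(timestamps)
    return(cbind(i, i))
  }
  j <- match(timestamps + tau, timestamps)
  keep <- !is.na(j)
  cbind(which(keep), j[keep])
}

#' Sample mean and covariance of a coordinate series
#'
#' Covariance with divisor n (the pair count at lag 0), the convention
#' used consistently by all lagged moments in the package. Only observed
#' rows enter; timestamp gaps are irrelevant at lag 0.
#'
#' @param x `cts_coord`, `cts` or numeric matrix.
#' @return list with `mean` (length-p vector) and `cov` (p x p matrix).
#' @export
sample_mean_cov <- function(x) {
  s <- as_series(x)
  v <- s$values
  p <- ncol(v)
  if (nrow(v) < p + 1)
    stop(sprintf("need at least %d rows to estimate a %d x %d covariance",
                 p + 1, p, p))
  mu <- colMeans(v)
  vc <- sweep(v, 2, mu)
  list(mean = mu, cov = crossprod(vc) / nrow(v))
}

#' Lagged autocovariance matrix
#'
#' (1/n_pairs) * sum over valid pairs of (x_t - mu)(x_{t+tau} - mu)',
#' centered with the single global mean. With `pairing = TRUE` (default)
#' only pairs whose timestamps differ by exactly `tau` grid steps are
#' used, so pairs straddling a gap are excluded; with complete data this
#' coincides with the usual estimator with divisor T - tau.
#'
#' @param x series (`cts_coord`, `cts` or matrix).
#' @param tau nonnegative integer lag.
#' @param pairing use timestamp-aware pair matching (TRUE) or raw row
#'   adjacency (FALSE).
#' @param symmetrize return (M + M')/2.
#' @param center optional mean vector to center with (default: global mean).
#' @return p x p matrix.
#' @export
autocovariance <- function(x, tau, pairing = TRUE, symmetrize = FALSE,
                           center = NULL) {
  s <- as_series(x)
  v <- s$values
  p <- ncol(v)
  ts <- if (pairing) s$timestamps else seq_len(nrow(v))
  pr <- lag_pairs(ts, tau)
  if (nrow(pr) < p + 1)
    stop(sprintf("too few valid pairs (%d) at lag %d", nrow(pr), tau))
  if (is.null(center)) center <- colMeans(v)
  vc <- sweep(v, 2, center)
  M <- crossprod(vc[pr[, 1], , drop = FALSE],
                 vc[pr[, 2], , drop = FALSE]) / nrow(pr)
  if (symmetrize) M <- (M + t(M)) / 2
  M
}

#' Local (interval) autocovariance matrix
#'
#' The autocovariance at lag `tau` restricted to a time interval,
#' centered with the interval mean; both pair endpoints must fall in the
#' interval. With complete data the divisor is the interval length minus
#' tau (the interval pair count).
#'
#' @param x series.
#' @param interval length-2 vector `c(first, last)` of timestamps
#'   (inclusive).
#' @param tau nonnegative integer lag.
#' @param symmetrize return (M + M')/2.
#' @return p x p matrix.
#' @export
local_autocovariance <- function(x, interval, tau, symmetrize = FALSE) {
  s <- as_series(x)
  inside <- s$timestamps >= interval[1] & s$timestamps <= interval[2]
  if (sum(inside) <= tau)
    stop(sprintf("interval [%s, %s] too short for lag %d",
                 interval[1], interval[2], tau))
  sub <- list(values = s$values[inside, , drop = FALSE],
              timestamps = s$timestamps[inside])
  mu <- colMeans(sub$values)
  vc <- sweep(sub$values, 2, mu)
  pr <- lag_pairs(sub$timestamps, tau)
  if (nrow(pr) < 1)
    stop(sprintf("no valid pairs at lag %d in interval [%s, %s]",
                 tau, interval[1], interval[2]))
  M <- crossprod(vc[pr[, 1], , drop = FALSE],
                 vc[pr[, 2], , drop = FALSE]) / nrow(pr)
  if (symmetrize) M <- (M + t(M)) / 2
  M
}

#' Fourth-order cross-moment matrix at a lag
#'
#' B_tau = E[x_{t+tau} (x_t' x_t) x_{t+tau}'] on whitened data, estimated
#' over valid pairs; symmetric by construction. At lag 0 on iid standard
#' Gaussian data it approaches (p + 2) I. Used by gFOBI and the combined
#' estimator; with `interval` supplied only pairs inside the interval are
#' used while the data remain globally whitened.
#'
#' @param xst whitened series (see [whiten()]) or any series/matrix
#'   assumed already centered.
#' @param tau nonnegative integer lag.
#' @param interval optional length-2 timestamp range.
#' @return p x p symmetric matrix.
#' @export
fourth_moment_matrix <- function(xst, tau, interval = NULL) {
  s <- as_series(xst)
  v <- s$values
  ts <- s$timestamps
  if (!is.null(interval)) {
    inside <- ts >= interval[1] & ts <= interval[2]
    v <- v[inside, , drop = FALSE]
    ts <- ts[inside]
  }
  pr <- lag_pairs(ts, tau)
  if (nrow(pr) < ncol(v) + 1)
    stop(sprintf("too few valid pairs (%d) at lag %d", nrow(pr), tau))
  x0 <- v[pr[, 1], , drop = FALSE]
  xp <- v[pr[, 2], , drop = FALSE]
  r0 <- rowSums(x0 * x0)
  crossprod(xp, xp * r0) / nrow(pr)
}

#' Cross-cumulant matrices at a lag
#'
#' The p^2 matrices
#' C^{jk}_tau = E[x_{t+tau} x_t' E^{jk} x_t x_{t+tau}']
#'   - S_tau (E^{jk} + E^{kj}) S_tau' - trace(E^{jk}) I,
#' with E^{jk} = e_j e_k', estimated on whitened data over valid pairs and
#' symmetrized. All vanish on iid Gaussian input; gJADE jointly
#' diagonalizes them.
#'
#' @param xst whitened series.
#' @param tau nonnegative integer lag.
#' @return list of p^2 symmetric p x p matrices, ordered (j,k) = (1,1),
#'   (1,2), ..., (p,p).
#' @export
cross_cumulant_matrices <- function(xst, tau) {
  s <- as_series(xst)
  v <- s$values
  p <- ncol(v)
  pr <- lag_pairs(s$timestamps, tau)
  if (nrow(pr) < p + 1)
    stop(sprintf("too few valid pairs (%d) at lag %d", nrow(pr), tau))
  x0 <- v[pr[, 1], , drop = FALSE]
  xp <- v[pr[, 2], , drop = FALSE]
  n <- nrow(pr)
  S <- crossprod(x0, xp) / n      # S_tau = E[x_t x_{t+tau}']
  Ip <- diag(p)
  out <- vector("list", p * p)
  idx <- 0
  for (j in seq_len(p)) {
    for (k in seq_len(p)) {
      idx <- idx + 1
      Fjk <- crossprod(xp, xp * (x0[, j] * x0[, k])) / n
      Ejk <- outer(Ip[, j], Ip[, k])
      C <- Fjk - t(S) %*% (Ejk + t(Ejk)) %*% S
      if (j == k) C <- C - Ip
      out[[idx]] <- (C + t(C)) / 2
    }
  }
  names(out) <- paste0("C", rep(seq_len(p), each = p), rep(seq_len(p), p))
  out
}

#' Whiten a coordinate series
#'
#' Centers with the sample mean and multiplies by the symmetric inverse
#' square root of the sample covariance, so the whitened series has
#' sample covariance I (complete data). The symmetric root makes
#' downstream unmixing matrices reproducible and basis-independent up to
#' sign and permutation.
#'
#' @param x series.
#' @return list of class `"whitened"`: `values` (T x p), `timestamps`,
#'   `whitener` (COV^{-1/2}), `center` (mean vector), `cov`.
#' @export
whiten <- function(x) {
  s <- as_series(x)
  mc <- sample_mean_cov(s$values)
  ev <- eigen(mc$cov, symmetric = TRUE)
  if (min(ev$values) <= 1e-10 * max(ev$values))
    stop("covariance is numerically singular; apply PCA pre-reduction ",
         "(see pca_reduce) before whitening")
  W <- ev$vectors %*% (t(ev$vectors) / sqrt(ev$values))
  W <- (W + t(W)) / 2
  structure(list(values = sweep(s$values, 2, mc$mean) %*% W,
                 timestamps = s$timestamps,
                 whitener = W, center = mc$mean, cov = mc$cov),
            class = "whitened")
}

#' Partition a time range into K contiguous intervals
#'
#' Splits the observed time points into K consecutive blocks of
#' near-equal size floor(n/K); the last block absorbs the remainder.
#' Intervals are returned as inclusive timestamp ranges.
#'
#' @param timestamps observed timestamps (or a series object).
#' @param K number of intervals, >= 2.
#' @param min_length minimum points per interval (typically
#'   max lag + p + 1); violations raise an error.
#' @return list of K length-2 timestamp ranges.
#' @export
partition_intervals <- function(timestamps, K, min_length = 2) {
  if (inherits(timestamps, c("cts", "cts_coord", "whitened")))
    timestamps <- as_series(timestamps)$timestamps
  n <- length(timestamps)
  if (K < 2) stop("K must be >= 2")
  len <- n %/% K
  if (len < min_length)
    stop(sprintf("intervals of %d points are too short (need >= %d)",
                 len, min_length))
  starts <- (seq_len(K) - 1L) * len + 1L
  ends <- c(starts[-1L] - 1L, n)
  lapply(seq_len(K), function(i)
    c(timestamps[starts[i]], timestamps[ends[i]]))
}

## internal: extract (values, timestamps) from any series-like object
as_series <- function(x) {
  if (inherits(x, "whitened"))
    list(values = x$values, timestamps = x$timestamps)
  else if (inherits(x, "cts") || inherits(x, "cts_coord"))
    list(values = x$values, timestamps = x$timestamps)
  else {
    v <- as.matrix(x)
    list(values = v, timestamps = seq_len(nrow(v)))
  }
}

#' Build a labelled, weighted stack of symmetric matrices
#'
#' The container fed to the joint diagonalizer: symmetric p x p matrices
#' with family/interval/lag labels and positive weights. Weights scale
#' each matrix before diagonalization, so the effective weight on the
#' squared-diagonal criterion is the square of the stated weight.
#'
#' @param matrices list of symmetric p x p matrices.
#' @param family per-matrix family tag ("S", "B" or "C").
#' @param interval per-matrix interval id ("global" or an index).
#' @param lag per-matrix lag.
#' @param weights per-matrix positive weights (default all 1).
#' @return object of class `"matrix_stack"`.
#' @export
matrix_stack <- function(matrices, family = "S", interval = "global",
                         lag = NA_integer_, weights = 1) {
  m <- length(matrices)
  p <- nrow(matrices[[1]])
  for (M in matrices) {
    if (!is.matrix(M) || nrow(M) != p || ncol(M) != p)
      stop("all stack matrices must be square with equal dimension")
    if (max(abs(M - t(M))) > 1e-10)
      stop("stack matrices must be symmetric")
  }
  weights <- rep_len(weights, m)
  if (any(weights <= 0)) stop("weights must be positive")
  structure(list(matrices = matrices,
                 labels = data.frame(family = rep_len(family, m),
                                     interval = rep_len(as.character(interval), m),
                                     lag = rep_len(lag, m),
                                     stringsAsFactors = FALSE),
                 weights = weights),
            class = "matrix_stack")
}
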