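## Optimization engines shared by all estimators: two-matrix generalized
## eigendecomposition, orthogonal approximate joint diagonalization by
## cyclic Jacobi rotations, and a fixed-point maximizer on the orthogonal
## group for the vSOBI nonquadratic criterion.

## internal: run code with a local RNG state, restoring the global one
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generalized eigendecomposition of two symmetric matrices
#'
#' Finds rows gamma_i with Gamma A Gamma' = I and Gamma B Gamma' diagonal
#' with descending diagonal, by whitening with the symmetric inverse
#' square root of A and eigendecomposing the whitened B. The engine
#' behind AMUSE and NSS-SD, whose separation requires distinct
#' eigenvalues; a near-degenerate spectrum sets `gap_warning`.
#'
#' @param A symmetric positive definite p x p matrix.
#' @param B symmetric p x p matrix.
#' @param gap_tol relative eigen-gap below which `gap_warning` is set.
#' @return list of class `"gevd"`: `eigenvalues` (descending), `Gamma`
#'   (rows are the eigenvectors), `gap_warning`.
#' @export
gevd_two_matrices <- function(A, B, gap_tol = 1e-3) {
  if (max(abs(A - t(A))) > 1e-8) stop("A must be symmetric")
  if (max(abs(B - t(B))) > 1e-8) stop("B must be symmetric")
  ea <- eigen(A, symmetric = TRUE)
  if (min(ea$values) <= 1e-12 * max(ea$values))
    stop("A must be positive definite")
  W <- ea$vectors %*% (t(ea$vectors) / sqrt(ea$values))
  Bw <- W %*% B %*% W
  Bw <- (Bw + t(Bw)) / 2
  eb <- eigen(Bw, symmetric = TRUE)          # descending values
  Gamma <- t(eb$vectors) %*% W
  spread <- max(eb$values) - min(eb$values)
  gaps <- -diff(eb$values)
  # degenerate either when two eigenvalues nearly coincide relative to
  # the spread, or when the whole spectrum is flat relative to its scale
  # (e.g. p = 2 with equal population eigenvalues: the sampling gap is
  # the spread)
  scale <- max(abs(eb$values), 1)
  gap_warning <- spread <= 0 || min(gaps) < gap_tol * spread ||
    spread < 0.1 * scale
  structure(list(eigenvalues = eb$values, Gamma = Gamma,
                 gap_warning = gap_warning),
            class = "gevd")
}

#' Orthogonal approximate joint diagonalization (cyclic Jacobi)
#'
#' Finds the orthogonal U maximizing the sum over the stack of squared
#' diagonal elements of U M_j U', by cyclic sweeps over coordinate pairs
#' with the closed-form optimal Givens angle of the 2 x 2 subproblem.
#' Weights are applied by scaling each matrix before optimization (so a
#' weight alpha contributes alpha^2 to the squared-diagonal criterion).
#' The criterion is nondecreasing over rotations; iteration stops when
#' every rotation angle in a sweep falls below `tol`.
#'
#' @param stack a [matrix_stack()], or a plain list of symmetric
#'   matrices (weights then default to 1).
#' @param tol rotation-angle convergence threshold.
#' @param max_sweeps sweep cap.
#' @return list of class `"ajd"`: `rotation` (orthogonal U), `objective`
#'   (achieved criterion), `objective_start` (criterion at U = I),
#'   `sweeps`, `converged`, `diag_contrib` (per-row criterion
#'   contribution, useful for ordering components).
#' @export
jacobi_ajd <- function(stack, tol = 1e-10, max_sweeps = 100) {
  if (!inherits(stack, "matrix_stack")) stack <- matrix_stack(stack)
  mats <- stack$matrices
  m <- length(mats)
  p <- nrow(mats[[1]])
  A <- array(0, c(p, p, m))
  for (k in seq_len(m)) A[, , k] <- stack$matrices[[k]] * stack$weights[k]
  obj0 <- sum(apply(A, 3, function(M) sum(diag(M)^2)))
  U <- diag(p)
  sweeps <- 0
  converged <- FALSE
  if (p > 1) {
    repeat {
      sweeps <- sweeps + 1
      max_angle <- 0
      for (i in seq_len(p - 1)) {
        for (j in (i + 1):p) {
          g1 <- A[i, i, ] - A[j, j, ]
          g2 <- 2 * A[i, j, ]
          ton <- sum(g1 * g1) - sum(g2 * g2)
          toff <- 2 * sum(g1 * g2)
          theta <- 0.5 * atan2(toff, ton + sqrt(ton * ton + toff * toff))
          if (abs(theta) > tol) {
            cs <- cos(theta); sn <- sin(theta)
            # rows i, j of every matrix, then columns (symmetric update)
            ri <- A[i, , , drop = FALSE]; rj <- A[j, , , drop = FALSE]
            A[i, , ] <- cs * ri + sn * rj
            A[j, , ] <- -sn * ri + cs * rj
            ci <- A[, i, , drop = FALSE]; cj <- A[, j, , drop = FALSE]
            A[, i, ] <- cs * ci + sn * cj
            A[, j, ] <- -sn * ci + cs * cj
            ui <- U[i, ]; uj <- U[j, ]
            U[i, ] <- cs * ui + sn * uj
            U[j, ] <- -sn * ui + cs * uj
            max_angle <- max(max_angle, abs(theta))
          }
        }
      }
      if (max_angle < tol) { converged <- TRUE; break }
      if (sweeps >= max_sweeps) break
    }
  } else converged <- TRUE
  dg <- matrix(0, p, m)
  for (k in seq_len(m)) dg[, k] <- diag(A[, , k])
  contrib <- rowSums(dg^2)
  structure(list(rotation = U, objective = sum(contrib),
                 objective_start = obj0, sweeps = sweeps,
                 converged = converged, diag_contrib = contrib),
            class = "ajd")
}

## internal: G contrast functions for the nonquadratic criterion
contrast_fns <- function(G = c("square", "logcosh")) {
  G <- match.arg(G)
  if (G == "square") list(G = function(y) y^2, g = function(y) 2 * y)
  else list(G = function(y) log(cosh(y)), g = function(y) tanh(y))
}

## internal: criterion value and per-component contributions for vSOBI
nonquadratic_criterion <- function(U, X, pairs, fns) {
  Y <- X %*% t(U)
  GY <- fns$G(Y)
  gbar <- colMeans(GY)
  contrib <- numeric(ncol(X))
  for (pr in pairs) {
    m <- colMeans(GY[pr[, 1], , drop = FALSE] * GY[pr[, 2], , drop = FALSE])
    contrib <- contrib + (m - gbar^2)^2
  }
  contrib
}

#' Maximize the vSOBI nonquadratic criterion over the orthogonal group
#'
#' Maximizes sum over lags and components of
#' (E[G(u_i'x_t) G(u_i'x_{t+tau})] - E[G(u_i'x_t)]^2)^2 on whitened data
#' by fixed-point iteration: each step replaces U by the symmetric
#' orthogonalization of the criterion's matrix gradient. The best of an
#' identity start plus `n_restarts` random orthogonal starts is
#' returned; expectations use the same valid-pair convention as the
#' autocovariances.
#'
#' @param xst whitened series (see [whiten()]).
#' @param lags positive integer lags.
#' @param G contrast: `"square"` (y^2) or `"logcosh"` (log cosh y).
#' @param n_restarts random restarts in addition to the identity start.
#' @param max_iter iteration cap per start.
#' @param tol Frobenius-norm convergence threshold on successive U.
#' @param seed RNG seed for the random starts (local; the global RNG
#'   state is untouched).
#' @return list of class `"ajd"`: `rotation`, `objective`,
#'   `diag_contrib` (per-component criterion terms), `converged`,
#'   `iterations`.
#' @export
maximize_nonquadratic <- function(xst, lags, G = c("square", "logcosh"),
                                  n_restarts = 5, max_iter = 1000,
                                  tol = 1e-6, seed = 1) {
  s <- as_series(xst)
  X <- s$values
  p <- ncol(X)
  fns <- contrast_fns(G)
  lags <- sort(unique(as.integer(lags)))
  if (any(lags < 1)) stop("vSOBI lags must be positive")
  pairs <- lapply(lags, function(tau) {
    pr <- lag_pairs(s$timestamps, tau)
    if (nrow(pr) < p + 1)
      stop(sprintf("too few valid pairs (%d) at lag %d", nrow(pr), tau))
    pr
  })

  starts <- with_local_seed(seed, {
    c(list(diag(p)), lapply(seq_len(n_restarts), function(i) {
      qr.Q(qr(matrix(stats::rnorm(p * p), p, p)))
    }))
  })

  run_start <- function(U) {
    n_all <- nrow(X)
    for (it in seq_len(max_iter)) {
      Y <- X %*% t(U)
      GY <- fns$G(Y)
      GpY <- fns$g(Y)
      gbar <- colMeans(GY)
      dg <- crossprod(X, GpY) / n_all          # column i: d gbar_i / d u_i
      Grad <- matrix(0, p, p)                   # columns accumulate per-u_i grads
      for (pr in pairs) {
        i0 <- pr[, 1]; i1 <- pr[, 2]; n <- nrow(pr)
        m <- colMeans(GY[i0, , drop = FALSE] * GY[i1, , drop = FALSE])
        dm <- (crossprod(X[i0, , drop = FALSE],
                         GpY[i0, , drop = FALSE] * GY[i1, , drop = FALSE]) +
               crossprod(X[i1, , drop = FALSE],
                         GY[i0, , drop = FALSE] * GpY[i1, , drop = FALSE])) / n
        d <- m - gbar^2
        Grad <- Grad + 2 * sweep(dm, 2, d, `*`) -
          4 * sweep(dg, 2, d * gbar, `*`)
      }
      R <- t(Grad)                              # rows are gradients of u_i
      sv <- svd(R)
      if (min(sv$d) < 1e-12 * max(sv$d, 1e-300))
        return(list(U = U, converged = FALSE, iterations = it))
      Unew <- sv$u %*% t(sv$v)                  # (R R')^{-1/2} R
      sgn <- sign(diag(Unew %*% t(U)))
      sgn[sgn == 0] <- 1
      Unew <- Unew * sgn
      delta <- sqrt(sum((Unew - U)^2))
      U <- Unew
      if (delta < tol) return(list(U = U, converged = TRUE, iterations = it))
    }
    list(U = U, converged = FALSE, iterations = max_iter)
  }

  best <- NULL
  for (U0 in starts) {
    res <- run_start(U0)
    contrib <- nonquadratic_criterion(res$U, X, pairs, fns)
    res$objective <- sum(contrib)
    res$contrib <- contrib
    if (is.null(best) || res$objective > best$objective) best <- res
  }
  structure(list(rotation = best$U, objective = best$objective,
                 diag_contrib = best$contrib, converged = best$converged,
                 iterations = best$iterations),
            class = "ajd")
}
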