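## Minimum distance index for unmixing-matrix performance, with the
## linear assignment subproblem solved by a shortest-augmenting-path
## (Jonker-Volgenant style) algorithm.

#' Solve a linear assignment problem
#'
#' Minimizes the total cost of assigning each row to a distinct column
#' via shortest augmenting paths with dual potentials (O(n^3)).
#'
#' @param cost square numeric cost matrix.
#' @return integer vector `perm`, row i assigned to column `perm[i]`.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  if (ncol(cost) != n) stop("cost matrix must be square")
  if (anyNA(cost) || any(!is.finite(cost))) stop("cost must be finite")
  d <- n + 1L                      # dummy column playing the role of "no column"
  u <- numeric(n)                  # row potentials
  v <- numeric(d)                  # column potentials (incl. dummy)
  p <- integer(d)                  # p[j]: row currently assigned to column j
  way <- integer(d)
  for (i in seq_len(n)) {
    p[d] <- i
    j0 <- d
    minv <- rep(Inf, d)
    used <- rep(FALSE, d)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(d)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == d) break
    }
  }
  perm <- integer(n)
  for (j in seq_len(n)) perm[p[j]] <- j
  perm
}

#' Minimum distance index between an unmixing and a mixing matrix
#'
#' MD(Gamma_hat, Omega) = (p-1)^{-1/2} inf over C of
#' ||C Gamma_hat Omega - I||_F, where C ranges over matrices with
#' exactly one nonzero element per row and column, absorbing the sign,
#' permutation and scale indeterminacies of the BSS model. Values lie in
#' [0, 1]; 0 means Gamma_hat Omega is a scaled permutation, i.e. perfect
#' separation. The per-row optimal scale has a closed form, after which
#' the permutation is a linear assignment problem.
#'
#' @param G_hat estimated unmixing matrix (p x p, full rank).
#' @param Omega true mixing matrix (p x p, full rank).
#' @return list of class `"md"`: `value`, `permutation` (row i of the
#'   gain matrix matched to source `permutation[i]`), `scales` (optimal
#'   per-row scales).
#' @export
md_index <- function(G_hat, Omega) {
  G_hat <- as.matrix(G_hat); Omega <- as.matrix(Omega)
  p <- nrow(G_hat)
  if (ncol(G_hat) != p || nrow(Omega) != p || ncol(Omega) != p)
    stop("G_hat and Omega must be square matrices of the same dimension")
  Gm <- G_hat %*% Omega
  rn <- sqrt(rowSums(Gm^2))
  if (any(rn < 1e-300) || abs(det(Gm)) < 1e-300)
    stop("G_hat %*% Omega is singular")
  Gn <- Gm / rn
  cost <- 1 - Gn^2                 # cost[k, i]: use row k for source i
  perm <- solve_assignment(cost)
  total <- sum(cost[cbind(seq_len(p), perm)])
  value <- sqrt(max(total, 0) / (p - 1))
  scales <- Gm[cbind(seq_len(p), perm)] / rn^2
  structure(list(value = value, permutation = perm, scales = scales),
            class = "md")
}

#' @export
print.md <- function(x, ...) {
  cat(sprintf("Minimum distance index: %.4f\n", x$value))
  invisible(x)
}
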