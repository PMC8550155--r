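# Independent oracles and fixture builders shared across the suite.

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# brute-force minimum distance index: enumerate permutations, per-row
# closed-form optimal scale
md_bruteforce <- function(G_hat, Omega) {
  Gm <- G_hat %*% Omega
  p <- nrow(Gm)
  Gn <- Gm / sqrt(rowSums(Gm^2))
  cost <- 1 - Gn^2
  perms <- all_perms(p)
  totals <- apply(perms, 1, function(pp) sum(cost[cbind(seq_len(p), pp)]))
  sqrt(min(totals) / (p - 1))
}

# brute-force linear assignment (min cost) over all permutations
assignment_bruteforce <- function(cost) {
  n <- nrow(cost)
  perms <- all_perms(n)
  totals <- apply(perms, 1, function(pp) sum(cost[cbind(seq_len(n), pp)]))
  perms[which.min(totals), ]
}

# direct-summation lagged autocovariance (complete data, global mean,
# divisor = number of pairs)
autocov_direct <- function(X, tau) {
  Tn <- nrow(X); p <- ncol(X)
  mu <- colMeans(X)
  M <- matrix(0, p, p)
  for (t in seq_len(Tn - tau))
    M <- M + tcrossprod(X[t, ] - mu, X[t + tau, ] - mu)
  M / (Tn - tau)
}

# direct-summation fourth-order cross-moment matrix (no centering)
fourth_moment_direct <- function(X, tau) {
  Tn <- nrow(X); p <- ncol(X)
  M <- matrix(0, p, p)
  for (t in seq_len(Tn - tau)) {
    s <- sum(X[t, ]^2)
    M <- M + s * tcrossprod(X[t + tau, ])
  }
  M / (Tn - tau)
}

# direct-summation cross-cumulant matrix C^{jk}_tau (no centering),
# symmetrized as the implementation documents
cross_cumulant_direct <- function(X, tau, j, k) {
  Tn <- nrow(X); p <- ncol(X)
  n <- Tn - tau
  Ejk <- matrix(0, p, p); Ejk[j, k] <- 1
  M <- matrix(0, p, p)
  S <- matrix(0, p, p)
  for (t in seq_len(n)) {
    M <- M + drop(X[t, ] %*% Ejk %*% X[t, ]) * tcrossprod(X[t + tau, ])
    S <- S + tcrossprod(X[t, ], X[t + tau, ])
  }
  M <- M / n; S <- S / n
  C <- M - t(S) %*% (Ejk + t(Ejk)) %*% S - sum(diag(Ejk)) * diag(p)
  (C + t(C)) / 2
}

# random orthogonal matrix
rand_orth <- function(p) qr.Q(qr(matrix(rnorm(p * p), p, p)))

# match estimated sources to true sources by absolute correlation
# (assignment over all permutations); returns the matched, sign-aligned
# estimate and the mean absolute correlation achieved
match_sources <- function(est, truth) {
  p <- ncol(truth)
  cc <- cor(est, truth)               # cc[i, j] = cor(est_i, truth_j)
  perm <- assignment_bruteforce(1 - abs(t(cc)))  # truth j -> est perm[j]
  matched <- est[, perm, drop = FALSE]
  sgn <- sign(diag(cor(matched, truth)))
  matched <- sweep(matched, 2, sgn, `*`)
  list(est = matched, abscor = abs(diag(cor(matched, truth))))
}

# block-variance-modulated sources: the model class of the NSS methods
# (mild AR dependence, smoothly distinct block scale profiles per source)
gen_blockvar_sources <- function(Tn, p = 4, n_blocks = 8, amp = 1,
                                 seed = NULL) {
  ars <- if (p == 1) 0.5 else seq(0.1, 0.8, length.out = p)
  ctsbss:::with_local_seed(seed, {
    Z <- sapply(seq_len(p), function(i) {
      z <- as.numeric(arima.sim(list(ar = ars[i]), n = Tn))
      prof <- rep(exp(amp * sin(2 * pi * seq_len(n_blocks) / n_blocks + i)),
                  each = ceiling(Tn / n_blocks))[seq_len(Tn)]
      z * prof
    })
    scale(Z)
  })
}

# p = 2 angle-scan oracle for the joint diagonalization criterion
ajd_angle_scan <- function(mats, resolution = 1e-4) {
  thetas <- seq(0, pi / 2, by = resolution)
  best <- -Inf
  for (th in thetas) {
    U <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    obj <- sum(vapply(mats, function(M) sum(diag(U %*% M %*% t(U))^2),
                      numeric(1)))
    if (obj > best) best <- obj
  }
  best
}
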