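# Shared fixtures: one LP mixture and one SV mixture, reused across blocks.
lp_fixture <- local({
  set.seed(40)
  Z <- cbind(generate_lp_source(4000, ar = 0.9, seed = 41),
             generate_lp_source(4000, ar = 0.2, seed = 42),
             generate_lp_source(4000, ar = 0.6, ma = 0.3, seed = 43))
  Omega <- matrix(rnorm(9), 3, 3)
  list(Z = Z, Omega = Omega, X = Z %*% t(Omega))
})

sv_fixture <- local({
  set.seed(44)
  Z <- cbind(generate_sv_source(4000, a = 0.2, b = 0.7, seed = 45),
             generate_sv_source(4000, a = 0.05, b = 0.9, seed = 46))
  Omega <- matrix(rnorm(4), 2, 2)
  list(Z = Z, Omega = Omega, X = Z %*% t(Omega))
})

test_that("AMUSE separates AR sources and flags equal autocorrelations", {
  set.seed(47)
  Z <- cbind(generate_lp_source(10000, ar = 0.9, seed = 48),
             generate_lp_source(10000, ar = 0.2, seed = 49))
  Omega <- matrix(rnorm(4), 2, 2)
  fit <- amuse(Z %*% t(Omega), tau = 1)
  expect_lt(md_index(coef(fit), Omega)$value, 0.1)
  expect_false(fit$diagnostics$gap_warning)
  # Gamma COV Gamma' = I and eigenvalues descending
  COV <- sample_mean_cov(Z %*% t(Omega))$cov
  expect_lt(max(abs(coef(fit) %*% COV %*% t(coef(fit)) - diag(2))), 1e-8)
  expect_equal(fit$diagnostics$eigenvalues,
               sort(fit$diagnostics$eigenvalues, decreasing = TRUE))
  # two sources with the same lag-1 autocorrelation are not identifiable
  set.seed(50)
  Zeq <- cbind(generate_lp_source(5000, ar = 0.5, seed = 51),
               generate_lp_source(5000, ar = 0.5, seed = 52))
  expect_true(amuse(Zeq)$diagnostics$gap_warning)
})

test_that("SOBI with a single lag reduces to AMUSE", {
  f1 <- sobi(lp_fixture$X, lags = 2)
  f2 <- amuse(lp_fixture$X, tau = 2)
  expect_lt(md_index(coef(f1), solve(coef(f2)))$value, 1e-6)
})

test_that("whitening-based methods return unit-covariance sources", {
  for (fit in list(sobi(lp_fixture$X), gfobi(sv_fixture$X),
                   nss_jd(lp_fixture$X))) {
    expect_lt(max(abs(sample_mean_cov(fit$sources)$cov - diag(ncol(fit$sources)))),
              1e-6)
  }
})

test_that("gFOBI with lag 0 is FOBI: distinct-kurtosis iid sources separate", {
  set.seed(53)
  Z <- cbind(rexp(20000) - 1, runif(20000, -sqrt(3), sqrt(3)))
  Omega <- matrix(c(2, 1, -1, 1), 2, 2)
  fit <- gfobi(Z %*% t(Omega), lags = 0)
  expect_lt(md_index(coef(fit), Omega)$value, 0.1)
  # Gaussian iid input: B matrices are degenerate and flagged
  set.seed(54)
  G <- matrix(rnorm(20000 * 2), 20000, 2)
  expect_true(gfobi(G, lags = 0)$diagnostics$gap_warning)
})

test_that("gJADE: lag-0 reduction works and Gaussian cumulants vanish", {
  set.seed(55)
  Z <- cbind(rexp(20000) - 1, runif(20000, -sqrt(3), sqrt(3)))
  Omega <- matrix(c(2, 1, -1, 1), 2, 2)
  fit <- gjade(Z %*% t(Omega), lags = 0)
  expect_lt(md_index(coef(fit), Omega)$value, 0.1)
  # on Gaussian iid data the whole criterion is near zero for any U
  set.seed(56)
  G <- matrix(rnorm(50000 * 2), 50000, 2)
  w <- whiten(G)
  cc <- cross_cumulant_matrices(w, 0)
  obj <- sum(vapply(cc, function(M) sum(diag(M)^2), numeric(1)))
  expect_lt(obj, 0.01)
  # and gJADE matches gFOBI quality on the SV mixture
  md_gj <- md_index(coef(gjade(sv_fixture$X, lags = 0:3)), sv_fixture$Omega)$value
  md_gf <- md_index(coef(gfobi(sv_fixture$X, lags = 0:3)), sv_fixture$Omega)$value
  expect_lt(md_gj, md_gf + 0.1)
})

test_that("NSS-SD recovers block-variance structure and flags stationarity", {
  # population-level construction: two blocks with distinct per-component
  # variance ratios
  set.seed(57)
  Tn <- 20000
  z1 <- rnorm(Tn); z1[(Tn / 2 + 1):Tn] <- 3 * z1[(Tn / 2 + 1):Tn]
  z2 <- rnorm(Tn); z2[1:(Tn / 2)] <- 2 * z2[1:(Tn / 2)]
  Omega <- matrix(c(1, 0.5, -0.7, 2), 2, 2)
  X <- cbind(z1, z2) %*% t(Omega)
  fit <- nss_sd(X)                      # default: halves of the range
  expect_lt(md_index(coef(fit), Omega)$value, 0.05)
  expect_equal(fit$params$T1, c(1, Tn / 2))
  # sources normalized to unit overall variance
  expect_equal(unname(colMeans(fit$sources^2)), c(1, 1), tolerance = 1e-8)
  # stationary input: eigenvalues all near 1, degeneracy flagged
  set.seed(58)
  G <- matrix(rnorm(4000 * 2), 4000, 2)
  fs <- nss_sd(G)
  expect_true(fs$diagnostics$gap_warning)
  expect_equal(fs$diagnostics$eigenvalues, c(1, 1), tolerance = 0.2)
})

test_that("NSS-JD with K = 2 matches NSS-SD on the same split", {
  Z <- gen_blockvar_sources(4000, p = 3, seed = 59)
  Omega <- matrix(rnorm(9), 3, 3)
  X <- Z %*% t(Omega)
  f_jd <- nss_jd(X, K = 2)
  f_sd <- nss_sd(X)
  # agreement is exact up to the centering convention (NSS-SD centers per
  # interval, the global whitening per series), hence the loose-but-tiny
  # tolerance on finite data
  expect_lt(md_index(coef(f_jd), solve(coef(f_sd)))$value, 1e-3)
})

test_that("NSS-TD-JD reductions: lags 0 is NSS-JD; K = 1 is SOBI-like", {
  Z <- gen_blockvar_sources(4000, p = 3, seed = 60)
  Omega <- matrix(rnorm(9), 3, 3)
  X <- Z %*% t(Omega)
  f_td <- nss_td_jd(X, K = 4, lags = 0)
  f_jd <- nss_jd(X, K = 4)
  expect_lt(md_index(coef(f_td), solve(coef(f_jd)))$value, 1e-8)
  # K = 1 with lags {0..6}: covariance (trivial after whitening) plus
  # global autocovariances, i.e. essentially SOBI
  f_k1 <- nss_td_jd(lp_fixture$X, K = 1, lags = 0:6)
  f_so <- sobi(lp_fixture$X, lags = 1:6)
  expect_lt(md_index(coef(f_k1), solve(coef(f_so)))$value, 0.1)
  # and NSS-TD-JD beats NSS-JD on block-stationary AR sources
  # with mild variance modulation the within-block serial dependence is
  # where the information is: the lag-aware method wins
  set.seed(61)
  mds <- sapply(1:10, function(r) {
    Z <- gen_blockvar_sources(4000, p = 3, amp = 0.4, seed = 600 + r)
    X <- Z %*% t(Omega)
    c(td = md_index(coef(nss_td_jd(X, K = 4, lags = 0:3)), Omega)$value,
      jd = md_index(coef(nss_jd(X, K = 4)), Omega)$value)
  })
  expect_lt(mean(mds["td", ]), mean(mds["jd", ]))
})

test_that("combined estimator: stack reductions and weight schemes", {
  X <- lp_fixture$X
  # empty fourth-moment lag set + equal weights = NSS-TD-JD stack
  f_comb <- nss_sobi_gfobi(X, K = 4, lags1 = 0:3, lags2 = integer(0),
                           scheme = "equal")
  f_td <- nss_td_jd(X, K = 4, lags = 0:3)
  expect_lt(md_index(coef(f_comb), solve(coef(f_td)))$value, 1e-8)
  # kurtosis scheme divides exactly the B-family matrices by p + 2
  w <- whiten(X)
  st_eq <- combined_stack(w, K = 2, lags1 = 0:2, lags2 = 0:2, scheme = "equal")
  st_ku <- combined_stack(w, K = 2, lags1 = 0:2, lags2 = 0:2, scheme = "kurtosis")
  expect_equal(st_eq$weights, rep(1, 12))
  expect_equal(st_ku$weights,
               ifelse(st_ku$labels$family == "B", 1 / (3 + 2), 1))
  # maxnorm: 1/max|entry| only when that max exceeds 1
  st_mx <- combined_stack(w, K = 2, lags1 = 0:2, lags2 = 0:2, scheme = "maxnorm")
  mx <- vapply(st_mx$matrices, function(M) max(abs(M)), numeric(1))
  expect_equal(st_mx$weights, ifelse(mx > 1, 1 / mx, 1))
  # interval shorter than the maximum lag is refused by name
  expect_error(nss_sobi_gfobi(X[1:60, ], K = 4, lags1 = 0:20, lags2 = 0:2),
               "interval")
})

test_that("all nine estimators are affine equivariant", {
  set.seed(62)
  Z <- cbind(gen_blockvar_sources(2000, p = 2, seed = 63),
             generate_sv_source(2000, a = 0.15, b = 0.8, seed = 64))
  X <- Z                                 # 3-variate mixed-nature fixture
  A <- matrix(rnorm(9), 3, 3)
  XA <- X %*% t(A)
  fits <- list(
    closed = list(amuse(X), amuse(XA), sobi(X, 1:4), sobi(XA, 1:4),
                  gfobi(X, 0:3), gfobi(XA, 0:3), gjade(X, 0:2), gjade(XA, 0:2),
                  nss_sd(X), nss_sd(XA), nss_jd(X, 4), nss_jd(XA, 4),
                  nss_td_jd(X, 4, 0:3), nss_td_jd(XA, 4, 0:3),
                  nss_sobi_gfobi(X, 4, 0:3, 0:3, scheme = "kurtosis"),
                  nss_sobi_gfobi(XA, 4, 0:3, 0:3, scheme = "kurtosis")),
    iter = list(vsobi(X, 1:3, seed = 5), vsobi(XA, 1:3, seed = 5)))
  check_pair <- function(f1, f2, tol) {
    m <- match_sources(f2$sources, f1$sources)
    expect_lt(max(abs(m$est - f1$sources)), tol)
  }
  cl <- fits$closed
  for (i in seq(1, length(cl), by = 2)) check_pair(cl[[i]], cl[[i + 1]], 1e-6)
  check_pair(fits$iter[[1]], fits$iter[[2]], 1e-3)
  # maxnorm weights are data-adaptive (the largest absolute entry of a
  # matrix is not invariant under the orthogonal change of whitened
  # representation), so that scheme is equivariant only approximately
  f_mx <- nss_sobi_gfobi(X, 4, 0:3, 0:3, scheme = "maxnorm")
  f_mxA <- nss_sobi_gfobi(XA, 4, 0:3, 0:3, scheme = "maxnorm")
  m <- match_sources(f_mxA$sources, f_mx$sources)
  expect_lt(max(abs(m$est - f_mx$sources)), 0.25)
  expect_gt(min(m$abscor), 0.99)
})

test_that("estimators are deterministic and orderings are by contribution", {
  f1 <- sobi(lp_fixture$X)
  f2 <- sobi(lp_fixture$X)
  expect_identical(coef(f1), coef(f2))
  expect_equal(f1$diagnostics$contrib,
               sort(f1$diagnostics$contrib, decreasing = TRUE))
  # sign convention: largest-magnitude entry of each unmixing row positive
  idx <- apply(coef(f1), 1, function(r) which.max(abs(r)))
  expect_true(all(coef(f1)[cbind(seq_len(3), idx)] > 0))
})
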