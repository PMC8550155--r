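## End-to-end decomposition of a compositional time series: ilr-express,
## optionally PCA-reduce, run a BSS estimator, and report sources, clr
## loadings and reconstructions.

## registry of estimators usable by name in cts_decompose / run_study
bss_methods <- function() {
  list(amuse = amuse, sobi = sobi, gfobi = gfobi, gjade = gjade,
       vsobi = vsobi, nss_sd = nss_sd, nss_jd = nss_jd,
       nss_td_jd = nss_td_jd, nss_sobi_gfobi = nss_sobi_gfobi)
}

#' PCA reduction of an ilr coordinate series
#'
#' Covariance PCA (no scaling: ilr coordinates share units). Keeps the
#' smallest number of components whose cumulative explained variance
#' reaches `threshold`. Used to step past near-singular ilr covariance
#' before whitening when p is large relative to the information content.
#'
#' @param y ilr coordinate series or matrix.
#' @param threshold fraction of variance to retain, in (0, 1].
#' @return list: `scores` (T x q), `rotation` (d x q loading matrix W),
#'   `center` (d-vector mean), `explained` (all d explained-variance
#'   fractions, descending), `q`.
#' @export
pca_reduce <- function(y, threshold = 0.999) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  s <- as_series(y)
  mc <- sample_mean_cov(s$values)
  ev <- eigen(mc$cov, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  frac <- vals / sum(vals)
  if (threshold == 1) {
    q <- sum(vals > 1e-12 * max(vals))
  } else {
    q <- which(cumsum(frac) >= threshold)[1]
  }
  W <- ev$vectors[, seq_len(q), drop = FALSE]
  scores <- sweep(s$values, 2, mc$mean) %*% W
  list(scores = scores, rotation = W, center = mc$mean,
       explained = frac, q = q)
}

#' Decompose a compositional time series into latent sources
#'
#' The four-step recipe: (1) express the composition in ilr coordinates;
#' (2) optionally PCA-reduce the coordinates; (3) run the chosen BSS
#' estimator on the (scores of the) ilr series; (4) report sources plus
#' the clr-space loading matrix Gamma W' V', whose rows are the
#' zero-sum clr profiles each source loads on. Because every estimator
#' is affine equivariant, the choice of ilr basis changes sources at
#' most by sign and order.
#'
#' @param x a [composition_series()] (or positive matrix).
#' @param method estimator name: one of `"amuse"`, `"sobi"`, `"gfobi"`,
#'   `"gjade"`, `"vsobi"`, `"nss_sd"`, `"nss_jd"`, `"nss_td_jd"`,
#'   `"nss_sobi_gfobi"`.
#' @param ... parameters passed to the estimator (lags, K, scheme, ...).
#' @param pca_threshold fraction of ilr variance to retain before BSS,
#'   or `"off"` (default) to use all p - 1 coordinates.
#' @param basis contrast matrix (default: pivot).
#' @param seed recorded in the provenance and passed to stochastic
#'   estimators (vsobi) unless overridden in `...`.
#' @return object of class `"cts_bss"`: `bss` (the [amuse()]-style
#'   result on the reduced coordinates), `basis`, `pca` (NULL when off),
#'   `clr_loadings` (q x p, rows sum to 0), `parts`, `provenance`.
#' @export
cts_decompose <- function(x, method = "nss_sobi_gfobi", ...,
                          pca_threshold = "off", basis = NULL, seed = 1) {
  if (!inherits(x, "cts")) x <- composition_series(x)
  registry <- bss_methods()
  if (!method %in% names(registry))
    stop("unknown method: ", method, "; available: ",
         paste(names(registry), collapse = ", "))
  y <- ilr_transform(x, basis = basis)
  basis <- y$basis
  p <- ncol(x$values)
  args <- list(...)
  pca <- NULL
  if (identical(pca_threshold, "off") || is.null(pca_threshold)) {
    mc <- sample_mean_cov(y$values)
    ev <- eigen(mc$cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10 * max(ev))
      stop("ilr covariance is numerically singular; rerun with a ",
           "pca_threshold (e.g. 0.999) to reduce dimension first")
    W <- diag(p - 1L)
    series <- y
  } else {
    pca <- pca_reduce(y, pca_threshold)
    W <- pca$rotation
    series <- coordinate_series(pca$scores, y$timestamps, space = "ilr",
                                basis = NULL)
  }
  if (method == "vsobi" && is.null(args$seed)) args$seed <- seed
  bss <- do.call(registry[[method]], c(list(series), args))
  clr_loadings <- bss$unmixing %*% t(W) %*% t(basis)
  colnames(clr_loadings) <- x$parts
  rownames(clr_loadings) <- paste0("z", seq_len(nrow(clr_loadings)))
  structure(list(bss = bss, basis = basis, pca = pca,
                 clr_loadings = clr_loadings, parts = x$parts,
                 ilr_center = if (is.null(pca)) bss$center else pca$center,
                 provenance = list(method = method, params = args,
                                   pca_threshold = pca_threshold,
                                   basis_kind = attr(basis, "kind"),
                                   seed = seed, p = p,
                                   T = nrow(x$values))),
            class = "cts_bss")
}

#' @export
print.cts_bss <- function(x, ...) {
  cat(sprintf("CTS decomposition (%s): %d parts -> %d sources\n",
              x$provenance$method, x$provenance$p, ncol(x$bss$sources)))
  if (!is.null(x$pca))
    cat(sprintf("PCA: %d of %d ilr coordinates (%.2f%% variance)\n",
                x$pca$q, x$provenance$p - 1,
                100 * sum(x$pca$explained[seq_len(x$pca$q)])))
  invisible(x)
}

#' Reconstruct compositions from selected sources
#'
#' Inverts the chain: selected sources -> ilr scores (Gamma^{-1}) ->
#' ilr coordinates (PCA rotation + mean) -> composition (inverse ilr
#' with closure). With all components and PCA off this reproduces the
#' closed original series; with a subset it gives the compositional
#' signal carried by those sources; zeroing all components returns the
#' mean composition.
#'
#' @param d a `"cts_bss"` object.
#' @param components integer indices of sources to keep (default: all).
#' @param sources optional replacement source matrix (e.g. predictions),
#'   T x q, overriding the stored sources.
#' @return a [composition_series()] closed to sum 1.
#' @export
cts_reconstruct <- function(d, components = NULL, sources = NULL) {
  bss <- d$bss
  q <- ncol(bss$sources)
  z <- if (is.null(sources)) bss$sources else as.matrix(sources)
  if (ncol(z) != q) stop("sources must have ", q, " columns")
  if (!is.null(components)) {
    if (any(components < 1 | components > q))
      stop("component indices out of range 1..", q)
    zsel <- matrix(0, nrow(z), q)
    zsel[, components] <- z[, components, drop = FALSE]
    z <- zsel
  }
  scores <- sweep(z %*% t(solve(bss$unmixing)), 2, bss$center, `+`)
  if (is.null(d$pca)) {
    ilr_hat <- scores
  } else {
    ilr_hat <- sweep(scores %*% t(d$pca$rotation), 2, d$pca$center, `+`)
  }
  y <- coordinate_series(ilr_hat, bss$timestamps, space = "ilr",
                         basis = d$basis)
  ilr_inverse(y, parts = d$parts)
}
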