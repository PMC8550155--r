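#' Compositional time series container
#'
#' Bundles a strictly positive T x p matrix of compositional observations
#' with strictly increasing timestamps (integer grid indices; gaps allowed)
#' and part labels. All analysis functions in the package accept either a
#' \code{cts} object or a plain matrix (then timestamps default to
#' \code{1:T}).
#'
#' @param values numeric matrix (T x p), all entries strictly positive.
#' @param timestamps strictly increasing numeric/integer vector of length T.
#'   Units are sampling steps of the underlying regular grid, so a gap of
#'   one missing observation shows up as a jump of 2.
#' @param parts character vector of p part labels.
#' @return An object of class \code{"cts"}: a list with elements
#'   \code{values}, \code{timestamps}, \code{parts}.
#' @examples
#' x <- composition_series(matrix(rexp(30) + 0.1, 10, 3))
#' clr_transform(x)
#' @export
composition_series <- function(values, timestamps = NULL, parts = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("composition values contain NA")
  bad <- which(values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("nonpositive entry at time index %d, part %d (value %g)",
                 bad[1, 1], bad[1, 2], values[bad[1, 1], bad[1, 2]]))
  }
  if (is.null(timestamps)) timestamps <- seq_len(nrow(values))
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) != nrow(values))
    stop("timestamps length must match number of rows")
  if (any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  if (is.null(parts)) {
    parts <- colnames(values)
    if (is.null(parts)) parts <- paste0("part", seq_len(ncol(values)))
  }
  colnames(values) <- parts
  structure(list(values = values, timestamps = timestamps, parts = parts),
            class = "cts")
}

#' @export
print.cts <- function(x, ...) {
  cat(sprintf("Compositional time series: %d time points, %d parts\n",
              nrow(x$values), ncol(x$values)))
  cat("Parts:", paste(x$parts, collapse = ", "), "\n")
  tgaps <- sum(diff(x$timestamps) > 1)
  if (tgaps > 0) cat(sprintf("Timestamp gaps: %d\n", tgaps))
  invisible(x)
}

#' Coordinate-series container (clr or ilr space)
#'
#' @param values T x d numeric matrix; d = p for clr, p - 1 for ilr.
#' @param timestamps as in [composition_series()].
#' @param space `"clr"` or `"ilr"`.
#' @param basis the p x (p-1) contrast matrix used (ilr only).
#' @return Object of class `"cts_coord"`.
#' @export
coordinate_series <- function(values, timestamps = NULL,
                              space = c("ilr", "clr"), basis = NULL) {
  space <- match.arg(space)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(timestamps)) timestamps <- seq_len(nrow(values))
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) != nrow(values))
    stop("timestamps length must match number of rows")
  if (space == "clr") {
    rs <- rowSums(values)
    if (max(abs(rs)) > 1e-8) stop("clr rows must sum to 0")
  }
  structure(list(values = values, timestamps = timestamps, space = space,
                 basis = basis),
            class = "cts_coord")
}

#' @export
print.cts_coord <- function(x, ...) {
  cat(sprintf("%s coordinate series: %d time points, %d coordinates\n",
              x$space, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Closure operation
#'
#' Rescales a positive vector (or the rows of a positive matrix) to sum
#' to 1. The representative of a composition on the unit simplex.
#'
#' @param v positive numeric vector or matrix (rows are closed).
#' @return Same shape, rows/entries summing to 1.
#' @examples closure(c(1, 2, 7))
#' @export
closure <- function(v) {
  if (is.matrix(v)) {
    if (any(v <= 0)) stop("closure requires strictly positive entries")
    v / rowSums(v)
  } else {
    if (any(v <= 0)) stop("closure requires strictly positive entries")
    v / sum(v)
  }
}

#' Centered log-ratio (clr) transform
#'
#' Each part's log value minus the mean log over all parts at that time
#' point, i.e. the log ratio against the geometric mean. Rows sum to zero;
#' the map is invariant to per-time rescaling of the composition.
#'
#' @param x a [composition_series()] object or positive matrix.
#' @return A `"cts_coord"` object in clr space (T x p).
#' @export
clr_transform <- function(x) {
  if (!inherits(x, "cts")) x <- composition_series(x)
  lv <- log(x$values)
  clr <- lv - rowMeans(lv)
  coordinate_series(clr, x$timestamps, space = "clr")
}

#' Pivot contrast matrix
#'
#' The p x (p-1) column-orthonormal, zero-column-sum matrix V whose
#' columns define the pivot ilr coordinates: column j is
#' sqrt((p-j)/(p-j+1)) * (0,...,0, 1, -1/(p-j), ..., -1/(p-j)) with j-1
#' leading zeros. It links the clr and ilr representations through
#' clr = V ilr and ilr = V' clr.
#'
#' @param p number of parts, >= 2.
#' @return p x (p-1) matrix with attribute `kind = "pivot"`.
#' @export
make_pivot_contrast_matrix <- function(p) {
  if (!is.numeric(p) || length(p) != 1 || p < 2 || p != round(p))
    stop("p must be a single integer >= 2")
  p <- as.integer(p)
  V <- matrix(0, p, p - 1L)
  for (j in seq_len(p - 1L)) {
    r <- p - j
    V[j, j] <- 1
    V[(j + 1L):p, j] <- -1 / r
    V[, j] <- sqrt(r / (r + 1)) * V[, j]
  }
  attr(V, "kind") <- "pivot"
  V
}

## internal: validate a user-supplied contrast matrix
check_contrast_matrix <- function(V, p = nrow(V), tol = 1e-10) {
  V <- as.matrix(V)
  if (nrow(V) != p || ncol(V) != p - 1)
    stop(sprintf("contrast matrix must be %d x %d", p, p - 1))
  if (max(abs(crossprod(V) - diag(p - 1))) > tol)
    stop("contrast matrix columns must be orthonormal")
  if (max(abs(colSums(V))) > 1e-8)
    stop("contrast matrix columns must sum to 0")
  V
}

#' Isometric log-ratio (ilr) transform
#'
#' Expresses a composition in p - 1 orthonormal real coordinates,
#' computed as V' clr(x) for a contrast matrix V (pivot coordinates by
#' default). For the pivot basis, coordinate i is the scaled log ratio of
#' part i against the geometric mean of the remaining parts, and the first
#' coordinate equals sqrt(p/(p-1)) times the first clr coefficient.
#'
#' @param x a [composition_series()] object or positive matrix.
#' @param basis p x (p-1) contrast matrix; default pivot basis.
#' @return A `"cts_coord"` object in ilr space (T x (p-1)).
#' @export
ilr_transform <- function(x, basis = NULL) {
  if (!inherits(x, "cts")) x <- composition_series(x)
  p <- ncol(x$values)
  if (is.null(basis)) basis <- make_pivot_contrast_matrix(p)
  else basis <- check_contrast_matrix(basis, p)
  clr <- clr_transform(x)
  coordinate_series(clr$values %*% basis, x$timestamps,
                    space = "ilr", basis = basis)
}

#' Inverse ilr transform
#'
#' Maps ilr coordinates back to compositions: clr = V y, then entrywise
#' exp and closure to the unit simplex. Exact inverse of
#' [ilr_transform()] up to closure of the input.
#'
#' @param y `"cts_coord"` in ilr space, or a T x (p-1) matrix.
#' @param basis contrast matrix; defaults to the basis stored in `y`,
#'   else the pivot basis.
#' @param parts optional part labels for the output.
#' @return A [composition_series()] closed to sum 1 per time point.
#' @export
ilr_inverse <- function(y, basis = NULL, parts = NULL) {
  if (inherits(y, "cts_coord")) {
    if (y$space != "ilr") stop("ilr_inverse expects ilr coordinates")
    if (is.null(basis)) basis <- y$basis
    ts <- y$timestamps
    ym <- y$values
  } else {
    ym <- as.matrix(y)
    ts <- seq_len(nrow(ym))
  }
  p <- ncol(ym) + 1L
  if (is.null(basis)) basis <- make_pivot_contrast_matrix(p)
  else basis <- check_contrast_matrix(basis, p)
  comp <- closure(exp(ym %*% t(basis)))
  composition_series(comp, ts, parts = parts)
}

#' Replace zeros/nonpositive entries before log-ratio analysis
#'
#' Multiplicative replacement: nonpositive entries in each part are set to
#' delta (by default 65% of the smallest positive value observed in that
#' part) and positive entries in affected rows are scaled down to preserve
#' the row total. Emits a loud message; strictly positive data pass
#' through unchanged.
#'
#' @param values matrix possibly containing zeros/negatives.
#' @param delta replacement value(s); scalar or per-part vector. Default
#'   0.65 * min positive per part.
#' @return strictly positive matrix of the same shape.
#' @export
replace_nonpositive <- function(values, delta = NULL) {
  values <- as.matrix(values)
  bad <- values <= 0
  if (!any(bad)) return(values)
  p <- ncol(values)
  if (is.null(delta)) {
    delta <- vapply(seq_len(p), function(j) {
      pos <- values[values[, j] > 0, j]
      if (length(pos) == 0) stop(sprintf("part %d has no positive values", j))
      0.65 * min(pos)
    }, numeric(1))
  }
  delta <- rep_len(delta, p)
  message(sprintf("replace_nonpositive: imputing %d nonpositive entries (multiplicative replacement)",
                  sum(bad)))
  out <- values
  for (i in which(rowSums(bad) > 0)) {
    b <- bad[i, ]
    tot <- sum(values[i, ])
    out[i, b] <- delta[b]
    # scale the positive entries so the row total is preserved
    keep <- !b
    out[i, keep] <- values[i, keep] * (tot - sum(delta[b])) / sum(values[i, keep])
    if (any(out[i, ] <= 0))
      stop(sprintf("row %d cannot be repaired with the given delta", i))
  }
  out
}
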