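#' Eigenslope extraction: PCA on a slope matrix
#'
#' Performs PCA on the l x D slope matrix and retains either the smallest
#' number k of principal components explaining at least the requested
#' fraction \code{pvar} of the variance (k = min k such that
#' sum_{i<=k} lambda_i / sum_i lambda_i >= pvar) or a directly specified k.
#' The retained components -- the "eigenslopes" -- span the directions of
#' common longitudinal change across subjects.
#'
#' The slope rows are mean-centred across subjects before decomposition
#' (disable with \code{center = FALSE} for sensitivity analysis).  When
#' D exceeds l the eigen-decomposition is computed through the l x l Gram
#' matrix (the snapshot trick), which is exact for the nonzero spectrum.
#' Eigenvalues below 1e-12 of the largest are treated as numerical rank
#' loss.  For a deterministic sign convention, each basis column's entry of
#' largest magnitude is made positive.
#'
#' @param slopes a \linkS4class{SlopeMatrix} (or bare l x D matrix).
#' @param pvar explained-variance fraction in (0, 1]; exactly one of
#'   \code{pvar} / \code{k} must be given.
#' @param k number of components to retain; clipped to the available rank
#'   with a warning if larger.
#' @param center centre the slope rows before PCA (default TRUE).
#' @return an \linkS4class{EigenslopeBasis}.
#' @export
computeEigenslopes <- function(slopes, pvar = NULL, k = NULL, center = TRUE) {
  if (is(slopes, "SlopeMatrix")) slopes <- slopes@entries
  .assertMatrix(slopes, "slopes")
  if (is.null(pvar) == is.null(k))
    stop("exactly one of 'pvar' or 'k' must be given")
  if (!is.null(pvar) && (pvar <= 0 || pvar > 1))
    stop("pvar must lie in (0, 1]")
  l <- nrow(slopes)
  if (l < 2L) stop("need at least 2 subjects for PCA")
  if (any(!is.finite(slopes))) stop("slope matrix contains non-finite entries")
  Xc <- if (center) sweep(slopes, 2L, colMeans(slopes)) else slopes
  D <- ncol(Xc)
  if (D > l) {
    # snapshot route: eigen-decompose the l x l Gram matrix
    G <- tcrossprod(Xc)
    e <- eigen(G, symmetric = TRUE)
    d <- e$values
    keep <- d > max(d, 0) * 1e-12 & d > 0
    if (!any(keep)) stop("no slope variance")
    d <- d[keep]
    U <- crossprod(Xc, e$vectors[, keep, drop = FALSE]) %*%
      diag(1 / sqrt(d), length(d))
    lambda <- d / (l - 1)
  } else {
    S <- crossprod(Xc) / (l - 1)
    e <- eigen(S, symmetric = TRUE)
    lambda <- e$values
    keep <- lambda > max(lambda, 0) * 1e-12 & lambda > 0
    if (!any(keep)) stop("no slope variance")
    lambda <- lambda[keep]
    U <- e$vectors[, keep, drop = FALSE]
  }
  r <- length(lambda)
  if (!is.null(pvar)) {
    cum <- cumsum(lambda) / sum(lambda)
    kk <- which(cum >= pvar - 1e-12)[1]
    if (is.na(kk)) kk <- r
  } else {
    kk <- as.integer(k)
    if (kk < 1L) stop("k must be >= 1")
    if (kk > r) {
      warning(sprintf("k = %d exceeds rank %d; clipped", kk, r))
      kk <- r
    }
  }
  U <- U[, seq_len(kk), drop = FALSE]
  # sign convention: largest-magnitude entry of each column made positive
  for (j in seq_len(kk)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  new("EigenslopeBasis", basis = U, eigenvalues = lambda, k = kk,
      pvar = if (is.null(pvar)) NA_real_ else pvar, centered = center)
}

#' Accessors for EigenslopeBasis
#'
#' @param x an \linkS4class{EigenslopeBasis}.
#' @name EigenslopeBasis-accessors
NULL

#' @rdname EigenslopeBasis-accessors
#' @export
setMethod("basisMatrix", "EigenslopeBasis", function(x) x@basis)

#' @rdname EigenslopeBasis-accessors
#' @export
setMethod("eigenValues", "EigenslopeBasis", function(x) x@eigenvalues)

#' @rdname EigenslopeBasis-accessors
#' @export
setMethod("retainedK", "EigenslopeBasis", function(x) x@k)

#' Cumulative explained-variance profile
#'
#' Entry j is the fraction of total slope variance explained by the top j
#' eigenslopes; the profile is non-decreasing and ends at 1.
#'
#' @param x an \linkS4class{EigenslopeBasis}.
#' @return numeric vector of cumulative fractions, one per positive
#'   eigenvalue.
#' @rdname explainedVarianceProfile
#' @export
setMethod("explainedVarianceProfile", "EigenslopeBasis", function(x)
  cumsum(x@eigenvalues) / sum(x@eigenvalues))

setMethod("show", "EigenslopeBasis", function(object) {
  cum <- explainedVarianceProfile(object)
  cat(sprintf(
    "EigenslopeBasis: D = %d, k = %d of rank %d (%.1f%% variance%s)\n",
    nrow(object@basis), object@k, length(object@eigenvalues),
    100 * cum[object@k],
    if (is.na(object@pvar)) "" else sprintf(", pvar = %.2f", object@pvar)))
})
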