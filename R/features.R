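#' Project cross-sectional samples onto the eigenslope subspace
#'
#' Right-multiplies a samples x D matrix by the rank-k projector U_k U_k'
#' (\code{space = "ambient"}: result stays D-dimensional, rank <= k, easing
#' interpretation of weight vectors as images) or by U_k alone
#' (\code{space = "compact"}: result is k-dimensional).  Both forms give
#' identical linear kernels because U_k has orthonormal columns.
#'
#' @param X n x D numeric matrix of cross-sectional samples.
#' @param basis an \linkS4class{EigenslopeBasis}.
#' @param space output space.
#' @return projected matrix (n x D or n x k) with attribute \code{"space"}.
#' @export
projectFeatures <- function(X, basis, space = c("ambient", "compact")) {
  space <- match.arg(space)
  stopifnot(is(basis, "EigenslopeBasis"))
  X <- as.matrix(X)
  if (ncol(X) != nrow(basis@basis))
    stop(sprintf("feature dimension %d does not match basis D = %d",
                 ncol(X), nrow(basis@basis)))
  scores <- X %*% basis@basis
  out <- if (space == "ambient") tcrossprod(scores, basis@basis) else scores
  rownames(out) <- rownames(X)
  attr(out, "space") <- space
  out
}

#' Mean-centre features using the training data
#'
#' Subtracts the training matrix's column means from the training matrix
#' and from every other matrix supplied (test sets are centred with the
#' TRAINING means, never their own).  Centring is applied after projection,
#' on the features fed to the classifier.
#'
#' @param train n x d training feature matrix.
#' @param ... further matrices of the same width to centre with the
#'   training means.
#' @return list with \code{train}, \code{others} (list, in input order) and
#'   \code{means} (the stored training column means).
#' @export
centerFeatures <- function(train, ...) {
  train <- as.matrix(train)
  if (nrow(train) == 0L) stop("empty training matrix")
  others <- list(...)
  mu <- colMeans(train)
  sw <- function(m) {
    m <- as.matrix(m)
    if (ncol(m) != length(mu)) stop("matrix widths must match")
    sweep(m, 2L, mu)
  }
  list(train = sweep(train, 2L, mu), others = lapply(others, sw), means = mu)
}

#' Linear kernel between feature matrices
#'
#' K = A B' (with B defaulting to A, giving the symmetric training
#' kernel).  Feature matrices must live in the same space; ambient
#' projected features and their compact counterparts give identical
#' kernels.
#'
#' @param A n x d feature matrix.
#' @param B n' x d feature matrix (default \code{A}).
#' @return n x n' kernel matrix.
#' @export
linearKernel <- function(A, B = NULL) {
  A <- as.matrix(A)
  sa <- attr(A, "space")
  if (is.null(B)) return(tcrossprod(A))
  B <- as.matrix(B)
  sb <- attr(B, "space")
  if (!is.null(sa) && !is.null(sb) && !identical(sa, sb))
    stop(sprintf("feature space mismatch: '%s' vs '%s'", sa, sb))
  if (ncol(A) != ncol(B)) stop("feature widths must match")
  tcrossprod(A, B)
}
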