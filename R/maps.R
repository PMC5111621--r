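#' Classifier weight map (primal weights from the dual solution)
#'
#' Reconstructs the primal weight vector w = X' alphaSigned from a trained
#' linear SVC, where X is the mean-centred training feature matrix.  With
#' ambient (D-dimensional) features the weights are directly interpretable
#' as an image over masked voxels, and <w, x> + bias reproduces the dual
#' decision values exactly.
#'
#' @param clf a \linkS4class{TrainedSVC} trained on ambient-space features.
#' @param normalize scale so the maximum absolute value is 1 (figure
#'   style); default FALSE so the decision-function identity holds.
#' @return a \linkS4class{BrainMap} of kind \code{"weight"}.
#' @export
weightMap <- function(clf, normalize = FALSE) {
  stopifnot(is(clf, "TrainedSVC"))
  if (clf@space != "ambient")
    stop("weight maps need an ambient-space classifier; reconstruct ",
         "ambient features via the eigenslope basis (X U_k U_k') first")
  w <- as.numeric(crossprod(clf@trainFeatures, clf@alphaSigned))
  .brainMap(w, "weight", normalize)
}

#' Covariance forward map of classifier outputs
#'
#' The encoding (forward-model) counterpart of the weight map: entry j is
#' proportional to the sample covariance between feature column j and the
#' classifier's continuous decision values, scaled so the maximum absolute
#' value is 1.  Unlike the weight map, it represents the group-difference
#' pattern the classifier output encodes.
#'
#' @param X n x D feature matrix (rows aligned with the decision values).
#' @param decisionValues length-n classifier outputs.
#' @param normalize max-abs-1 scaling (default TRUE, figure style).
#' @return a \linkS4class{BrainMap} of kind \code{"forward"}.
#' @export
forwardMap <- function(X, decisionValues, normalize = TRUE) {
  X <- as.matrix(X)
  decisionValues <- as.numeric(decisionValues)
  if (nrow(X) != length(decisionValues))
    stop("feature rows and decision values must align")
  if (stats::sd(decisionValues) == 0)
    stop("no output variance: decision values are constant")
  yc <- decisionValues - mean(decisionValues)
  a <- as.numeric(crossprod(X, yc)) / (length(yc) - 1)
  .brainMap(a, "forward", normalize)
}

#' Mass-univariate two-sample t-map
#'
#' Per-dimension pooled-variance two-sample t statistics between the
#' positive (disease) and negative (control) groups' features; positive
#' values mean larger in the disease group.  Dimensions with zero pooled
#' variance get t = 0 with a warning.
#'
#' @param groupPos matrix of positive-class rows (>= 2).
#' @param groupNeg matrix of negative-class rows (>= 2).
#' @return a \linkS4class{BrainMap} of kind \code{"tstat"}.
#' @export
tMap <- function(groupPos, groupNeg) {
  groupPos <- as.matrix(groupPos); groupNeg <- as.matrix(groupNeg)
  if (ncol(groupPos) != ncol(groupNeg))
    stop("groups must share the feature dimension")
  n1 <- nrow(groupPos); n2 <- nrow(groupNeg)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 rows")
  m1 <- colMeans(groupPos); m2 <- colMeans(groupNeg)
  v1 <- apply(groupPos, 2L, var); v2 <- apply(groupNeg, 2L, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  if (any(se == 0)) {
    warning(sprintf("%d dimension(s) with zero pooled variance set to t = 0",
                    sum(se == 0)))
    t[se == 0] <- 0
  }
  .brainMap(t, "tstat", normalize = FALSE)
}

.brainMap <- function(values, kind, normalize) {
  norm <- "none"
  if (normalize) {
    mx <- max(abs(values))
    if (mx > 0) values <- values / mx
    norm <- "max-abs-1"
  }
  new("BrainMap", values = as.numeric(values), kind = kind,
      normalization = norm)
}

#' @rdname BrainMap-accessors
#' @param x a \linkS4class{BrainMap}.
#' @export
setMethod("mapValues", "BrainMap", function(x) x@values)

#' Export / import a brain map as a NIfTI volume
#'
#' \code{writeBrainMap} unflattens the map through the mask (zeros outside)
#' and writes a double-precision NIfTI volume carrying the mask's affine,
#' so values round-trip exactly; \code{readBrainMap} masks such a volume
#' back into a \linkS4class{BrainMap}.
#'
#' @param map a \linkS4class{BrainMap}.
#' @param mask the \linkS4class{BrainMask} defining the vectorization.
#' @param path output NIfTI path (.nii or .nii.gz).
#' @param kind,normalization tags for the re-imported map.
#' @return \code{writeBrainMap}: \code{path}, invisibly;
#'   \code{readBrainMap}: a \linkS4class{BrainMap}.
#' @export
writeBrainMap <- function(map, mask, path) {
  stopifnot(is(map, "BrainMap"), is(mask, "BrainMask"))
  vol <- unmask(mask, map@values)
  img <- RNifti::asNifti(vol)
  img <- RNifti::`sform<-`(img, structure(mask@affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname writeBrainMap
#' @export
readBrainMap <- function(path, mask, kind = "weight",
                         normalization = "none") {
  stopifnot(is(mask, "BrainMask"))
  img <- RNifti::readNifti(path)
  new("BrainMap", values = applyMask(img, mask), kind = kind,
      normalization = normalization)
}

setMethod("show", "BrainMap", function(object) {
  cat(sprintf("BrainMap: kind '%s', D = %d, range [%.3g, %.3g]%s\n",
              object@kind, length(object@values), min(object@values),
              max(object@values),
              if (object@normalization == "max-abs-1") " (max-abs-1)" else ""))
})
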