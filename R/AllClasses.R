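#' @import methods
#' @importFrom stats cov predict rnorm runif sd var
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom Rcpp evalCpp
#' @useDynLib eigenslopes, .registration = TRUE
NULL

#' LongitudinalCohort: subjects with time-stamped high-dimensional samples
#'
#' A \linkS4class{SummarizedExperiment} holding one assay \code{"features"}
#' (a D x n matrix, features in rows, scans in columns) whose column metadata
#' carries \code{subject} (id), \code{label} (+1 disease / -1 control, constant
#' within subject) and \code{time} (years since the subject's first scan, so
#' every subject's first scan is at time 0).  Columns are ordered by subject
#' (order of first appearance) and, within subject, by strictly increasing
#' time.  \code{metadata()$featureSpace} tags the feature space
#' (\code{"masked-voxels"} or \code{"generic"}).
#'
#' @seealso [longitudinalCohort()], [readSubjectTable()], [simulateCohort()]
#' @export
setClass("LongitudinalCohort", contains = "SummarizedExperiment")

setValidity("LongitudinalCohort", function(object) {
  cd <- colData(object)
  need <- c("subject", "label", "time")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(sprintf("missing colData column(s): %s", paste(miss, collapse = ", ")))
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' is required")
  lab <- cd$label
  if (!all(lab %in% c(-1, 1)))
    return("label must be +1 or -1")
  tm <- cd$time
  if (!is.numeric(tm) || any(!is.finite(tm)) || any(tm < 0))
    return("time must be finite, non-negative years since first scan")
  sj <- as.character(cd$subject)
  for (s in unique(sj)) {
    i <- which(sj == s)
    if (length(unique(lab[i])) != 1L)
      return(sprintf("subject '%s' has inconsistent labels", s))
    if (tm[i][1] != 0)
      return(sprintf("subject '%s': first scan time must be 0 (times are relative)", s))
    if (length(i) > 1L && any(diff(tm[i]) <= 0))
      return(sprintf("subject '%s': times must be strictly increasing", s))
    if (any(diff(i) != 1L))
      return(sprintf("subject '%s': scans must occupy contiguous columns", s))
  }
  TRUE
})

#' SlopeMatrix: per-subject trajectory coefficients of one polynomial order
#'
#' An l x D matrix whose row i holds the order-p trajectory coefficients of
#' subject i across all D feature dimensions: the matrix B(1) when estimated
#' by per-subject least squares (LTC), or the interval-scaled difference
#' matrix D_L in the two-time-point special case (LM).
#'
#' @slot entries l x D numeric matrix of coefficients.
#' @slot subjectIds character vector of length l (row provenance).
#' @slot order integer, the extracted coefficient order p (>= 1).
#' @slot scaling one of \code{"ltc"}, \code{"lm-balanced"}, \code{"lm-unbalanced"}.
#' @export
setClass("SlopeMatrix",
  representation(entries = "matrix", subjectIds = "character",
                 order = "integer", scaling = "character"))

setValidity("SlopeMatrix", function(object) {
  if (nrow(object@entries) != length(object@subjectIds))
    return("row count must equal number of subject ids")
  if (anyDuplicated(object@subjectIds))
    return("subject ids must be unique")
  if (any(!is.finite(object@entries)))
    return("slope matrix contains non-finite entries")
  if (object@order < 1L)
    return("extracted order must be >= 1")
  if (!object@scaling %in% c("ltc", "lm-balanced", "lm-unbalanced"))
    return("unknown scaling tag")
  TRUE
})

#' EigenslopeBasis: orthonormal basis of the longitudinal subspace
#'
#' Holds the D x k matrix U_k of retained eigenslopes (principal components
#' of a \linkS4class{SlopeMatrix}), all positive eigenvalues of the slope
#' covariance in non-increasing order, the retained count k and the requested
#' explained-variance fraction pvar (NA when k was given directly).
#'
#' @slot basis D x k numeric matrix with orthonormal columns.
#' @slot eigenvalues positive eigenvalues, non-increasing.
#' @slot k integer, retained component count.
#' @slot pvar requested explained-variance fraction in (0, 1], or NA.
#' @slot centered logical: was the slope matrix row-centered before PCA?
#' @export
setClass("EigenslopeBasis",
  representation(basis = "matrix", eigenvalues = "numeric", k = "integer",
                 pvar = "numeric", centered = "logical"))

setValidity("EigenslopeBasis", function(object) {
  k <- object@k
  if (ncol(object@basis) != k) return("basis must have k columns")
  if (k > length(object@eigenvalues)) return("k exceeds number of eigenvalues")
  ev <- object@eigenvalues
  if (any(ev <= 0)) return("stored eigenvalues must be positive")
  if (is.unsorted(rev(ev))) return("eigenvalues must be non-increasing")
  g <- crossprod(object@basis)
  if (max(abs(g - diag(k))) > 1e-10)
    return("basis columns must be orthonormal (tolerance 1e-10)")
  TRUE
})

#' TrainedSVC: a fitted linear soft-margin support-vector classifier
#'
#' Stores the signed support-vector coefficients (alpha_i * y_i, zero for
#' non-SVs), the bias and the cost C, together with the (mean-centred)
#' training feature matrix so that primal weight maps and kernel-form
#' decision values can both be reproduced.  The decision value of a sample x
#' is sum_i alphaSigned_i <x_i, x> + bias; positive values predict +1, exact
#' ties predict -1.
#'
#' @slot alphaSigned numeric vector, one entry per training sample.
#' @slot bias numeric scalar.
#' @slot cost the C cost parameter (default 1).
#' @slot trainFeatures the (centred) training feature matrix, n x d (for
#'   kernel-trained classifiers: the n x n training kernel).
#' @slot labels numeric +/-1 training labels.
#' @slot space \code{"ambient"}, \code{"compact"} or \code{"kernel"}
#'   (pseudo-features factorized from a precomputed kernel).
#' @export
setClass("TrainedSVC",
  representation(alphaSigned = "numeric", bias = "numeric", cost = "numeric",
                 trainFeatures = "matrix", labels = "numeric",
                 space = "character"))

setValidity("TrainedSVC", function(object) {
  n <- nrow(object@trainFeatures)
  if (length(object@alphaSigned) != n || length(object@labels) != n)
    return("alphaSigned and labels must match training rows")
  if (!all(object@labels %in% c(-1, 1))) return("labels must be +/-1")
  if (any(object@alphaSigned * object@labels < -1e-8))
    return("signed coefficients must satisfy alpha_i * y_i >= 0")
  if (any(abs(object@alphaSigned) > object@cost + 1e-6))
    return("|alpha_i| must not exceed the cost C")
  TRUE
})

#' MetricsReport: confusion counts and derived classification metrics
#'
#' @slot tp,fp,tn,fn confusion counts (positives = disease, +1).
#' @slot sensitivity,specificity,balancedAccuracy,ppv,npv fractions in [0,1];
#'   PPV/NPV are NA when their denominator is zero (undefined, not 0).
#' @slot rocAuc ROC area under the curve (ties counted 1/2); NA when no
#'   decision values were supplied.
#' @slot nPos,nNeg class sizes.
#' @export
setClass("MetricsReport",
  representation(tp = "integer", fp = "integer", tn = "integer", fn = "integer",
                 sensitivity = "numeric", specificity = "numeric",
                 balancedAccuracy = "numeric", ppv = "numeric", npv = "numeric",
                 rocAuc = "numeric", nPos = "integer", nNeg = "integer"))

setValidity("MetricsReport", function(object) {
  if (any(c(object@tp, object@fp, object@tn, object@fn) < 0L))
    return("confusion counts must be non-negative")
  if (object@tp + object@fn != object@nPos) return("TP + FN must equal nPos")
  if (object@tn + object@fp != object@nNeg) return("TN + FP must equal nNeg")
  TRUE
})

#' PermutationResult: label-permutation null distribution and p-value
#'
#' @slot observed observed balanced accuracy.
#' @slot nullBas balanced accuracies under label permutation.
#' @slot nPerm number of permutations.
#' @slot pValue fraction of null balanced accuracies that match or exceed the
#'   observed one (optionally with (b+1)/(m+1) smoothing).
#' @slot smoothed logical, whether the smoothed estimator was used.
#' @slot seed integer seed used (length 0 if none).
#' @export
setClass("PermutationResult",
  representation(observed = "numeric", nullBas = "numeric", nPerm = "integer",
                 pValue = "numeric", smoothed = "logical", seed = "integer"))

#' BrainMask: binary volume defining the masked feature vectorization
#'
#' @slot volume 3-D array; nonzero voxels are retained.
#' @slot affine 4 x 4 voxel-to-world matrix.
#' @slot D number of nonzero voxels (the feature dimensionality).
#' @export
setClass("BrainMask",
  representation(volume = "array", affine = "matrix", D = "integer"))

setValidity("BrainMask", function(object) {
  if (length(dim(object@volume)) != 3L) return("mask volume must be 3-D")
  if (!identical(dim(object@affine), c(4L, 4L))) return("affine must be 4 x 4")
  if (object@D != sum(object@volume != 0)) return("D must count nonzero voxels")
  if (object@D < 1L) return("empty mask")
  TRUE
})

#' BrainMap: a length-D statistical image over masked voxels
#'
#' @slot values numeric vector of length D.
#' @slot kind \code{"weight"}, \code{"forward"} or \code{"tstat"}.
#' @slot normalization \code{"none"} or \code{"max-abs-1"}.
#' @export
setClass("BrainMap",
  representation(values = "numeric", kind = "character",
                 normalization = "character"))

setValidity("BrainMap", function(object) {
  if (!object@kind %in% c("weight", "forward", "tstat"))
    return("unknown map kind")
  if (!object@normalization %in% c("none", "max-abs-1"))
    return("unknown normalization tag")
  if (object@normalization == "max-abs-1" && any(object@values != 0) &&
      abs(max(abs(object@values)) - 1) > 1e-12)
    return("max-abs-1 map must have maximum absolute value 1")
  TRUE
})

#' CVResult: outcome of a (nested) leave-one-out cross-validation run
#'
#' @slot predictions data.frame with one row per classification subject:
#'   \code{subject}, \code{label}, \code{decision}, \code{predicted},
#'   \code{pvar} (explained variance chosen in the inner loop) and \code{k}.
#' @slot metrics a \linkS4class{MetricsReport} aggregated over outer folds.
#' @slot config the [cvConfig()] list used.
#' @slot mode \code{"within"} or \code{"transfer"}.
#' @export
setClass("CVResult",
  representation(predictions = "data.frame", metrics = "MetricsReport",
                 config = "list", mode = "character"))
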