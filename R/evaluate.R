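#' Classification metrics from labels, predictions and decision values
#'
#' Builds the confusion counts (positives = disease, +1) and the derived
#' metrics: sensitivity TP/(TP+FN), specificity TN/(TN+FP), balanced
#' accuracy (sensitivity + specificity)/2, PPV TP/(TP+FP), NPV TN/(TN+FN)
#' and the ROC AUC.  PPV/NPV with a zero denominator are reported as NA
#' (undefined), never as 0.
#'
#' @param labels +/-1 true labels (both classes must be present).
#' @param predictions +/-1 predicted labels.
#' @param decisionValues optional real decision values for the AUC.
#' @return a \linkS4class{MetricsReport}.
#' @export
computeMetrics <- function(labels, predictions, decisionValues = NULL) {
  labels <- as.numeric(labels); predictions <- as.numeric(predictions)
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  if (!all(c(labels, predictions) %in% c(-1, 1)))
    stop("labels and predictions must be +/-1")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in the labels")
  tp <- sum(labels == 1 & predictions == 1)
  fn <- sum(labels == 1 & predictions == -1)
  tn <- sum(labels == -1 & predictions == -1)
  fp <- sum(labels == -1 & predictions == 1)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  ppv <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
  npv <- if (tn + fn == 0L) NA_real_ else tn / (tn + fn)
  auc <- if (is.null(decisionValues)) NA_real_
         else rocAuc(labels, decisionValues)
  new("MetricsReport", tp = as.integer(tp), fp = as.integer(fp),
      tn = as.integer(tn), fn = as.integer(fn),
      sensitivity = sens, specificity = spec,
      balancedAccuracy = (sens + spec) / 2, ppv = ppv, npv = npv,
      rocAuc = auc, nPos = as.integer(tp + fn), nNeg = as.integer(tn + fp))
}

#' ROC area under the curve
#'
#' The probability that a randomly drawn positive's decision value exceeds
#' a randomly drawn negative's, with ties counted 1/2 (midrank form of the
#' Mann-Whitney statistic; equivalent to the trapezoidal ROC area).
#'
#' @param labels +/-1 true labels.
#' @param decisionValues real classifier outputs (larger = more positive).
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(labels, decisionValues) {
  labels <- as.numeric(labels)
  if (length(labels) != length(decisionValues))
    stop("labels and decision values must have equal length")
  nPos <- sum(labels == 1); nNeg <- sum(labels == -1)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present in the labels")
  r <- rank(decisionValues)
  (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Label-permutation significance test of a cross-validated classifier
#'
#' Repeatedly rearranges the subjects' class labels uniformly at random
#' (preserving the class counts), reruns the supplied cross-validation
#' runner on each permuted label vector, and estimates the p-value as the
#' fraction of null balanced accuracies that match or exceed the observed
#' one.  The unsmoothed counting estimator can return exactly 0 when no
#' null value reaches the observed accuracy; \code{smoothed = TRUE}
#' switches to the (b+1)/(m+1) estimator.
#'
#' @param cvRunner function taking a label vector (named per subject) and
#'   returning a balanced accuracy; see [nestedCvRunner()] and
#'   [fixedPvarRunner()].
#' @param labels the observed +/-1 labels (named per subject).
#' @param nPerm number of permutations (>= 1; the study default is 1000).
#' @param seed integer seed for the permutation RNG.
#' @param smoothed use the (b+1)/(m+1) estimator.
#' @return a \linkS4class{PermutationResult}.
#' @export
permutationTest <- function(cvRunner, labels, nPerm = 1000L, seed = NULL,
                            smoothed = FALSE) {
  nPerm <- as.integer(nPerm)
  if (nPerm < 1L) stop("nPerm must be >= 1")
  labels <- unlist(labels)
  observed <- cvRunner(labels)
  nullBas <- .withSeed(seed, {
    vapply(seq_len(nPerm), function(b) {
      yp <- labels
      yp[] <- sample(as.numeric(labels))
      cvRunner(yp)
    }, numeric(1))
  })
  b <- sum(nullBas >= observed - 1e-12)
  p <- if (smoothed) (b + 1) / (nPerm + 1) else b / nPerm
  new("PermutationResult", observed = observed, nullBas = nullBas,
      nPerm = nPerm, pValue = p, smoothed = isTRUE(smoothed),
      seed = if (is.null(seed)) integer(0) else as.integer(seed))
}

#' Cross-validation runners for permutation testing
#'
#' \code{nestedCvRunner} wraps [nestedLooCv()] as a function of the label
#' vector, rerunning the full nested scheme (including inner pvar
#' selection) per call.  \code{fixedPvarRunner} wraps the much cheaper
#' plain LOO at one fixed explained-variance fraction (a one-point grid),
#' which is the practical choice for building large permutation null
#' distributions on a single CPU.  \code{unprojectedRunner} wraps
#' [looCvUnprojected()].
#'
#' @param cohort classification cohort.
#' @param config a [cvConfig()].
#' @param mode,longitudinal see [nestedLooCv()].
#' @param pvar fixed explained-variance fraction.
#' @return a function mapping a label vector to a balanced accuracy.
#' @export
nestedCvRunner <- function(cohort, config = cvConfig(),
                           mode = c("within", "transfer"),
                           longitudinal = NULL) {
  mode <- match.arg(mode)
  function(labels)
    cvMetrics(nestedLooCv(cohort, config, mode = mode,
                          longitudinal = longitudinal,
                          labels = labels))@balancedAccuracy
}

#' @rdname nestedCvRunner
#' @export
fixedPvarRunner <- function(cohort, pvar, config = cvConfig(),
                            mode = c("within", "transfer"),
                            longitudinal = NULL) {
  mode <- match.arg(mode)
  pvar <- as.numeric(pvar)
  stopifnot(length(pvar) == 1L)
  config$pvarGrid <- pvar
  # the per-fold subspaces and kernels never depend on the labels, so they
  # are computed once; each call only re-solves the SVC duals
  pre <- .looFoldKernels(cohort, pvar, config, mode, longitudinal)
  nsub <- length(pre$subjects)
  function(labels) {
    y <- .cvLabels(cohort, labels)[pre$subjects]
    dec <- vapply(seq_len(nsub), function(t) {
      f <- pre$folds[[t]]
      ytr <- y[-t]
      if (length(unique(ytr)) < 2L)
        return((if (sum(ytr == 1) > sum(ytr == -1)) 1 else -1) * 1e-6)
      s <- .Call_smo_solve(f$Ktr, ytr, config$cost)
      sum(f$kte * s$alphaSigned) + s$bias
    }, numeric(1))
    p <- ifelse(dec > 0, 1, -1)
    (mean(p[y == 1] == 1) + mean(p[y == -1] == -1)) / 2
  }
}

#' @rdname nestedCvRunner
#' @export
unprojectedRunner <- function(cohort, config = cvConfig()) {
  function(labels)
    cvMetrics(looCvUnprojected(cohort, config,
                               labels = labels))@balancedAccuracy
}

setMethod("show", "MetricsReport", function(object) {
  fmt <- function(x) ifelse(is.na(x), "  NA", sprintf("%4.1f", .percent1(x)))
  cat(sprintf(
    "MetricsReport: n = %d (+: %d, -: %d)\n", object@nPos + object@nNeg,
    object@nPos, object@nNeg))
  cat(sprintf("  BA %s%%  Sens %s%%  Spec %s%%  PPV %s%%  NPV %s%%  AUC %s\n",
              fmt(object@balancedAccuracy), fmt(object@sensitivity),
              fmt(object@specificity), fmt(object@ppv), fmt(object@npv),
              ifelse(is.na(object@rocAuc), "NA",
                     sprintf("%.3f", .roundHalfUp(object@rocAuc, 3)))))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    "PermutationResult: observed BA %.3f, %d permutations, p = %.4g%s\n",
    object@observed, object@nPerm, object@pValue,
    if (object@smoothed) " (smoothed)" else ""))
})
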