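#' Construct a LongitudinalCohort
#'
#' Assembles scans into a \linkS4class{LongitudinalCohort}.  Scan times are
#' re-expressed relative to each subject's first scan (so every subject's
#' first sample is at time 0); columns are reordered by subject and
#' ascending time.
#'
#' @param features D x n numeric matrix, one column per scan (features in
#'   rows, Bioconductor orientation).
#' @param subject character/factor of length n, subject id per scan.
#' @param label +/-1 per scan (+1 = disease class); must be constant within
#'   subject.
#' @param time acquisition time in years per scan (any origin; stored
#'   relative to each subject's first scan).
#' @param featureSpace tag recorded in \code{metadata()}:
#'   \code{"masked-voxels"} or \code{"generic"}.
#' @return a \linkS4class{LongitudinalCohort}.
#' @export
longitudinalCohort <- function(features, subject, label, time,
                               featureSpace = c("generic", "masked-voxels")) {
  featureSpace <- match.arg(featureSpace)
  .assertMatrix(features, "features")
  n <- ncol(features)
  subject <- as.character(subject)
  if (length(subject) != n || length(label) != n || length(time) != n)
    stop("subject, label and time must have one entry per feature column")
  label <- as.numeric(label)
  if (!all(label %in% c(-1, 1))) stop("label must be +1 or -1")
  if (anyDuplicated(cbind(subject, time)))
    stop("duplicate (subject, time) pair")
  # order by subject first appearance, then time
  sOrd <- match(subject, unique(subject))
  o <- order(sOrd, time)
  features <- features[, o, drop = FALSE]
  subject <- subject[o]; label <- label[o]; time <- time[o]
  rel <- stats::ave(time, subject, FUN = function(t) t - t[1])
  colnames(features) <- sprintf("%s_t%g", subject, rel)
  se <- SummarizedExperiment(
    assays = list(features = features),
    colData = DataFrame(subject = subject, label = label, time = rel))
  obj <- new("LongitudinalCohort", se)
  S4Vectors::metadata(obj)$featureSpace <- featureSpace
  validObject(obj)
  obj
}

#' Accessors for LongitudinalCohort
#'
#' \code{subjectIds} returns the unique subject ids in column order;
#' \code{classLabels} one +/-1 label per subject (named); \code{scanTimes}
#' a named list of per-subject relative scan times; \code{nScans} the number
#' of scans per subject; \code{featureDim} the feature dimensionality D;
#' \code{featureMatrix} the scans-by-features (n x D) matrix.
#'
#' @param x a \linkS4class{LongitudinalCohort}.
#' @param ... unused.
#' @name LongitudinalCohort-accessors
NULL

#' @rdname LongitudinalCohort-accessors
#' @export
setMethod("subjectIds", "LongitudinalCohort", function(x, ...)
  unique(as.character(colData(x)$subject)))

#' @rdname LongitudinalCohort-accessors
#' @export
setMethod("classLabels", "LongitudinalCohort", function(x, ...) {
  cd <- colData(x)
  sj <- as.character(cd$subject)
  i <- !duplicated(sj)
  stats::setNames(as.numeric(cd$label[i]), sj[i])
})

#' @rdname LongitudinalCohort-accessors
#' @export
setMethod("scanTimes", "LongitudinalCohort", function(x, ...) {
  cd <- colData(x)
  split(as.numeric(cd$time), factor(as.character(cd$subject),
                                    levels = subjectIds(x)))
})

#' @rdname LongitudinalCohort-accessors
#' @export
setMethod("nScans", "LongitudinalCohort", function(x, ...)
  lengths(scanTimes(x)))

#' @rdname LongitudinalCohort-accessors
#' @export
setMethod("featureDim", "LongitudinalCohort", function(x) nrow(x))

#' @rdname LongitudinalCohort-accessors
#' @export
setMethod("featureMatrix", "LongitudinalCohort", function(x, ...)
  t(assay(x, "features")))

#' Cross-sectional sample matrix at a named time-point
#'
#' Extracts one scan per subject -- the first (\code{"baseline"}), second
#' (\code{"followup"}) or last (\code{"final"}) -- as a subjects x D matrix
#' with subject ids as row names.
#'
#' @param x a \linkS4class{LongitudinalCohort}.
#' @param timepoint which scan to take per subject.
#' @param subjects subject ids to include (default: all that have the
#'   requested time-point).
#' @return numeric matrix, one row per subject.
#' @rdname crossSection
#' @export
setMethod("crossSection", "LongitudinalCohort",
  function(x, timepoint = c("followup", "baseline", "final"), subjects = NULL) {
    timepoint <- match.arg(timepoint)
    cd <- colData(x)
    sj <- as.character(cd$subject)
    if (is.null(subjects)) subjects <- subjectIds(x)
    idx <- vapply(subjects, function(s) {
      i <- which(sj == s)
      if (!length(i)) stop(sprintf("unknown subject '%s'", s))
      switch(timepoint,
        baseline = i[1],
        final = i[length(i)],
        followup = {
          if (length(i) < 2L)
            stop(sprintf("subject '%s' has no follow-up scan", s))
          i[2]
        })
    }, integer(1))
    m <- t(assay(x, "features")[, idx, drop = FALSE])
    rownames(m) <- subjects
    m
  })

#' Subset a cohort to a set of subjects
#'
#' @param x a \linkS4class{LongitudinalCohort}.
#' @param subjects subject ids to keep (order preserved as given).
#' @return a \linkS4class{LongitudinalCohort}.
#' @export
subsetSubjects <- function(x, subjects) {
  stopifnot(is(x, "LongitudinalCohort"))
  sj <- as.character(colData(x)$subject)
  unknown <- setdiff(subjects, sj)
  if (length(unknown))
    stop(sprintf("unknown subject(s): %s", paste(unknown, collapse = ", ")))
  keep <- unlist(lapply(subjects, function(s) which(sj == s)))
  x[, keep]
}

setMethod("show", "LongitudinalCohort", function(object) {
  m <- nScans(object)
  lb <- classLabels(object)
  cat(sprintf(
    "LongitudinalCohort: %d subjects (%d disease / %d control), D = %d\n",
    length(m), sum(lb == 1), sum(lb == -1), featureDim(object)))
  cat(sprintf("  scans per subject: %d-%d (total %d); feature space: %s\n",
              min(m), max(m), ncol(object),
              S4Vectors::metadata(object)$featureSpace))
})
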