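#' Polynomial longitudinal design matrix
#'
#' Builds the m x (P+1) design matrix Z for a subject scanned at the given
#' times: column p+1 holds the times raised to power p, with a leading
#' constant column.  Raw (uncentered) powers of relative time are used.
#'
#' @param times strictly increasing scan times (years since first scan).
#' @param order polynomial model order P (>= 0).
#' @return an m x (P+1) numeric matrix.
#' @export
buildDesignMatrix <- function(times, order) {
  times <- as.numeric(times)
  if (any(diff(times) <= 0) && length(times) > 1L)
    stop("times must be strictly increasing (repeated times lose rank)")
  if (order < 0) stop("model order must be >= 0")
  outer(times, 0:order, `^`)
}

#' Fit a subject's polynomial trajectory by least squares
#'
#' Solves X = Z B for one subject, where X is the m x D matrix of the
#' subject's samples and Z the design matrix of [buildDesignMatrix()].  One
#' QR solve covers all D dimensions, so residuals are orthogonal to the
#' columns of Z in every dimension.  An exact fit at m = P+1 is allowed.
#'
#' @param times strictly increasing scan times.
#' @param values m x D matrix of the subject's samples (rows follow
#'   \code{times}).
#' @param order polynomial model order P.
#' @return the (P+1) x D coefficient matrix B (row p+1 = order-p
#'   coefficients).
#' @export
fitTrajectory <- function(times, values, order = 1L) {
  values <- as.matrix(values)
  if (length(times) != nrow(values))
    stop("times and sample rows must align")
  if (length(times) < order + 1L)
    stop(sprintf("insufficient time-points: %d samples for order %d (need >= %d)",
                 length(times), order, order + 1L))
  Z <- buildDesignMatrix(times, order)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) stop("rank-deficient design matrix")
  B <- qr.coef(qz, values)
  dimnames(B) <- NULL
  B
}

#' Assemble the order-p coefficient matrix across subjects (LTC)
#'
#' Fits an order-P trajectory to every eligible subject and stacks the
#' order-\code{extract} coefficient rows into an l x D
#' \linkS4class{SlopeMatrix} (the matrix B(p); B(1) with
#' \code{order = extract = 1} is the slope matrix decomposed by
#' LTC-PCA).  Subjects with fewer than P+1 scans are excluded with a
#' warning and listed in the result's provenance; fewer than 2 eligible
#' subjects is an error since no PCA is then possible.
#'
#' @param cohort a \linkS4class{LongitudinalCohort}.
#' @param order polynomial model order P (default 1).
#' @param extract which coefficient order p to stack (1 <= p <= P).
#' @param subjects subject ids to consider (default all).
#' @return a \linkS4class{SlopeMatrix} with scaling tag \code{"ltc"}.
#' @export
assembleCoefficientMatrix <- function(cohort, order = 1L, extract = 1L,
                                      subjects = NULL) {
  stopifnot(is(cohort, "LongitudinalCohort"))
  order <- as.integer(order); extract <- as.integer(extract)
  if (extract < 1L || extract > order)
    stop("extract must satisfy 1 <= extract <= order")
  if (is.null(subjects)) subjects <- subjectIds(cohort)
  tms <- scanTimes(cohort)[subjects]
  eligible <- subjects[lengths(tms) >= order + 1L]
  dropped <- setdiff(subjects, eligible)
  if (length(dropped))
    warning(sprintf("excluding %d subject(s) with fewer than %d time-points: %s",
                    length(dropped), order + 1L,
                    paste(dropped, collapse = ", ")))
  if (length(eligible) < 2L)
    stop("fewer than 2 eligible subjects: PCA impossible")
  X <- assay(cohort, "features")
  sj <- as.character(colData(cohort)$subject)
  rows <- t(vapply(eligible, function(s) {
    i <- which(sj == s)
    B <- fitTrajectory(colData(cohort)$time[i], t(X[, i, drop = FALSE]), order)
    B[extract + 1L, ]
  }, numeric(featureDim(cohort))))
  dimnames(rows) <- NULL
  new("SlopeMatrix", entries = rows, subjectIds = eligible,
      order = extract, scaling = "ltc")
}

#' Interval-scaled difference matrix (two-time-point LM slopes)
#'
#' Forms the slope matrix D_L = (X^(t2) - X^(t1)) / tDelta from paired
#' baseline and follow-up sample matrices.  With a common scalar interval
#' this is the balanced two-time-point solution and equals the first-order
#' coefficient matrix B(1); with a per-subject interval vector it is the
#' unbalanced variant, scaling each subject's difference by its own
#' interval.
#'
#' @param baseline,followup l x D matrices, rows aligned by subject.
#' @param intervals positive scalar (balanced) or length-l vector
#'   (unbalanced) of time intervals in years.
#' @param subjectIds optional row provenance (default rownames of
#'   \code{baseline} or \code{"s1"..."sl"}).
#' @return a \linkS4class{SlopeMatrix} with scaling tag
#'   \code{"lm-balanced"} or \code{"lm-unbalanced"}.
#' @export
lmDifferenceMatrix <- function(baseline, followup, intervals,
                               subjectIds = NULL) {
  baseline <- as.matrix(baseline); followup <- as.matrix(followup)
  if (!identical(dim(baseline), dim(followup)))
    stop("baseline and followup must have matching shapes")
  l <- nrow(baseline)
  if (!length(intervals) %in% c(1L, l))
    stop("intervals must be a scalar or one value per subject")
  if (any(intervals <= 0)) stop("intervals must be positive")
  scaling <- if (length(intervals) == 1L) "lm-balanced" else "lm-unbalanced"
  entries <- (followup - baseline) / intervals
  dimnames(entries) <- NULL
  if (is.null(subjectIds))
    subjectIds <- rownames(baseline)
  if (is.null(subjectIds))
    subjectIds <- paste0("s", seq_len(l))
  new("SlopeMatrix", entries = entries, subjectIds = as.character(subjectIds),
      order = 1L, scaling = scaling)
}

#' Per-subject slope matrix from a cohort
#'
#' Convenience wrapper building the l x D slope matrix from a cohort by
#' one of three routes: \code{"ltc"} (order-1 least squares over all
#' scans), \code{"lm-balanced"} (two-scan difference scaled by the common
#' interval; errors if intervals differ by more than 1e-6 relative) or
#' \code{"lm-unbalanced"} (two-scan difference scaled per subject).  For the
#' LM routes \code{lmPair} selects which pair of scans: the first and last
#' (longest interval) or the last two (shortest interval, as when mimicking
#' a minimal follow-up design).  Subjects with too few scans are excluded
#' with a warning.
#'
#' @param cohort a \linkS4class{LongitudinalCohort}.
#' @param source slope construction route.
#' @param lmPair scan pair for the LM routes.
#' @param subjects subject ids to consider (default all).
#' @return a \linkS4class{SlopeMatrix}.
#' @export
slopeMatrix <- function(cohort,
                        source = c("lm-balanced", "lm-unbalanced", "ltc"),
                        lmPair = c("first-last", "last-two"),
                        subjects = NULL) {
  source <- match.arg(source)
  lmPair <- match.arg(lmPair)
  stopifnot(is(cohort, "LongitudinalCohort"))
  if (is.null(subjects)) subjects <- subjectIds(cohort)
  if (source == "ltc")
    return(assembleCoefficientMatrix(cohort, order = 1L, extract = 1L,
                                     subjects = subjects))
  tms <- scanTimes(cohort)[subjects]
  eligible <- subjects[lengths(tms) >= 2L]
  dropped <- setdiff(subjects, eligible)
  if (length(dropped))
    warning(sprintf("excluding %d subject(s) with fewer than 2 time-points: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  if (length(eligible) < 2L)
    stop("fewer than 2 eligible subjects: PCA impossible")
  X <- assay(cohort, "features")
  sj <- as.character(colData(cohort)$subject)
  tm <- as.numeric(colData(cohort)$time)
  pick <- vapply(eligible, function(s) {
    i <- which(sj == s)
    if (lmPair == "first-last") c(i[1], i[length(i)])
    else c(i[length(i) - 1L], i[length(i)])
  }, integer(2))
  ints <- tm[pick[2, ]] - tm[pick[1, ]]
  if (source == "lm-balanced") {
    if (diff(range(ints)) > 1e-6 * max(ints))
      stop("intervals are not constant across subjects; use source = 'lm-unbalanced'")
    ints <- ints[1]
  }
  lmDifferenceMatrix(t(X[, pick[1, ], drop = FALSE]),
                     t(X[, pick[2, ], drop = FALSE]),
                     intervals = ints, subjectIds = eligible)
}

#' Accessors for SlopeMatrix
#'
#' @param x a \linkS4class{SlopeMatrix}.
#' @name SlopeMatrix-accessors
NULL

#' @rdname SlopeMatrix-accessors
#' @export
setMethod("slopeValues", "SlopeMatrix", function(x) x@entries)

#' @rdname SlopeMatrix-accessors
#' @export
setMethod("slopeSubjects", "SlopeMatrix", function(x) x@subjectIds)

setMethod("show", "SlopeMatrix", function(object) {
  cat(sprintf("SlopeMatrix: %d subjects x %d dims, order %d, scaling '%s'\n",
              nrow(object@entries), ncol(object@entries), object@order,
              object@scaling))
})
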