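#' @rdname LongitudinalCohort-accessors
#' @export
setGeneric("subjectIds", function(x, ...) standardGeneric("subjectIds"))

#' @rdname LongitudinalCohort-accessors
#' @export
setGeneric("classLabels", function(x, ...) standardGeneric("classLabels"))

#' @rdname LongitudinalCohort-accessors
#' @export
setGeneric("scanTimes", function(x, ...) standardGeneric("scanTimes"))

#' @rdname LongitudinalCohort-accessors
#' @export
setGeneric("nScans", function(x, ...) standardGeneric("nScans"))

#' @rdname LongitudinalCohort-accessors
#' @export
setGeneric("featureDim", function(x) standardGeneric("featureDim"))

#' @rdname LongitudinalCohort-accessors
#' @export
setGeneric("featureMatrix", function(x, ...) standardGeneric("featureMatrix"))

#' @rdname crossSection
#' @export
setGeneric("crossSection",
  function(x, timepoint = c("followup", "baseline", "final"), subjects = NULL)
    standardGeneric("crossSection"))

#' @rdname SlopeMatrix-accessors
#' @export
setGeneric("slopeValues", function(x) standardGeneric("slopeValues"))

#' @rdname SlopeMatrix-accessors
#' @export
setGeneric("slopeSubjects", function(x) standardGeneric("slopeSubjects"))

#' @rdname EigenslopeBasis-accessors
#' @export
setGeneric("basisMatrix", function(x) standardGeneric("basisMatrix"))

#' @rdname EigenslopeBasis-accessors
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))

#' @rdname EigenslopeBasis-accessors
#' @export
setGeneric("retainedK", function(x) standardGeneric("retainedK"))

#' @rdname explainedVarianceProfile
#' @export
setGeneric("explainedVarianceProfile",
  function(x) standardGeneric("explainedVarianceProfile"))

#' @rdname BrainMap-accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname cvMetrics
#' @export
setGeneric("cvMetrics", function(x) standardGeneric("cvMetrics"))

#' @rdname cvPredictions
#' @export
setGeneric("cvPredictions", function(x) standardGeneric("cvPredictions"))
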