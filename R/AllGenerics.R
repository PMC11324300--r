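#' @rdname CutoffSet-class
#' @param object,x An object.
#' @export
setGeneric("cutoffValues", function(x) standardGeneric("cutoffValues"))

#' @rdname CutoffSet-class
#' @export
setGeneric("referenceNorms", function(x) standardGeneric("referenceNorms"))

#' @rdname StagedCohort-class
#' @export
setGeneric("stageLabels", function(x) standardGeneric("stageLabels"))

#' @rdname StagedCohort-class
#' @export
setGeneric("patternLabels", function(x) standardGeneric("patternLabels"))

#' @rdname StagedCohort-class
#' @export
setGeneric("deficitCounts", function(x) standardGeneric("deficitCounts"))

#' @rdname StagedCohort-class
#' @export
setGeneric("deficitFlags", function(x) standardGeneric("deficitFlags"))

#' @rdname StagedCohort-class
#' @export
setGeneric("ageBrackets", function(x) standardGeneric("ageBrackets"))

#' @rdname GroupComparisonResult-class
#' @export
setGeneric("decisionPath", function(x) standardGeneric("decisionPath"))

#' @rdname GroupComparisonResult-class
#' @export
setGeneric("pairwiseResults", function(x) standardGeneric("pairwiseResults"))

#' @rdname GroupComparisonResult-class
#' @export
setGeneric("omnibusResult", function(x) standardGeneric("omnibusResult"))
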