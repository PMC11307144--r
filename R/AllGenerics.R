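#' @rdname TumorCohort-accessors
#' @export
setGeneric("expressionMatrix", function(x) standardGeneric("expressionMatrix"))

#' @rdname TumorCohort-accessors
#' @export
setGeneric("microbeCounts", function(x) standardGeneric("microbeCounts"))

#' @rdname TumorCohort-accessors
#' @export
setGeneric("humanReads", function(x) standardGeneric("humanReads"))

#' @rdname TumorCohort-accessors
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname TumorCohort-accessors
#' @export
setGeneric("sampleData<-", function(x, value) standardGeneric("sampleData<-"))

#' @rdname TumorCohort-accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname TumorCohort-accessors
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' @rdname CVReport-accessors
#' @export
setGeneric("meanAUROC", function(x) standardGeneric("meanAUROC"))

#' @rdname CVReport-accessors
#' @export
setGeneric("perModelAUROC", function(x) standardGeneric("perModelAUROC"))

#' @rdname ValidationReport-class
#' @export
setGeneric("balancedAccuracyOf", function(x) standardGeneric("balancedAccuracyOf"))
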