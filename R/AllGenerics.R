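#' @rdname regulonEdges
#' @export
setGeneric("regulonEdges", function(x) standardGeneric("regulonEdges"))

#' @rdname regulonEdges
#' @export
setGeneric("regulators", function(x) standardGeneric("regulators"))

#' @rdname regulonEdges
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname regulonEdges
#' @export
setGeneric("targetsOf", function(x, tf) standardGeneric("targetsOf"))

#' @rdname activityScores
#' @export
setGeneric("activityScores", function(x) standardGeneric("activityScores"))

#' @rdname activityScores
#' @export
setGeneric("activityPvalues", function(x) standardGeneric("activityPvalues"))

#' @rdname activityScores
#' @export
setGeneric("targetCounts", function(x) standardGeneric("targetCounts"))

#' @rdname medianAuroc
#' @export
setGeneric("medianAuroc", function(x) standardGeneric("medianAuroc"))

#' @rdname medianAuroc
#' @export
setGeneric("medianAuprc", function(x) standardGeneric("medianAuprc"))

#' @rdname medianAuroc
#' @export
setGeneric("metricSamples", function(x) standardGeneric("metricSamples"))

#' @rdname tfClasses
#' @export
setGeneric("tfClasses", function(x) standardGeneric("tfClasses"))

#' @rdname tfClasses
#' @export
setGeneric("priorRoles", function(x) standardGeneric("priorRoles"))
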