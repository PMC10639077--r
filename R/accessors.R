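#' Access the edge table of a RegulonNetwork
#'
#' \code{regulonEdges} returns the edge data.frame; \code{regulators} the
#' unique TF symbols; \code{nEdges} the edge count; \code{targetsOf} the
#' target genes of one TF.
#'
#' @param x a [RegulonNetwork-class].
#' @param tf a TF symbol.
#' @return \code{regulonEdges}: data.frame; \code{regulators},
#'   \code{targetsOf}: character vector; \code{nEdges}: integer.
#' @name regulonEdges
#' @aliases regulators nEdges targetsOf
NULL

#' @rdname regulonEdges
#' @export
setMethod("regulonEdges", "RegulonNetwork", function(x) x@edges)

#' @rdname regulonEdges
#' @export
setMethod("regulators", "RegulonNetwork", function(x) unique(x@edges$tf))

#' @rdname regulonEdges
#' @export
setMethod("nEdges", "RegulonNetwork", function(x) nrow(x@edges))

#' @rdname regulonEdges
#' @export
setMethod("targetsOf", "RegulonNetwork", function(x, tf) {
  x@edges$target[x@edges$tf == tf]
})

setMethod("show", "RegulonNetwork", function(object) {
  ed <- object@edges
  cat(sprintf(
    "RegulonNetwork: %d edges, %d regulators, %d targets\n",
    nrow(ed), length(unique(ed$tf)), length(unique(ed$target))
  ))
  if (nrow(ed)) {
    cat(sprintf(
      "  signs: %d activating (+1), %d repressing (-1)\n",
      sum(ed$sign == 1L), sum(ed$sign == -1L)
    ))
    pv <- table(ed$provenance)
    cat("  provenance:", paste(names(pv), pv, sep = "=", collapse = ", "),
        "\n")
  }
  if (length(object@metadata)) {
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' Access entries of an ActivityMatrix
#'
#' @param x an [ActivityMatrix-class].
#' @return \code{activityScores}, \code{activityPvalues}: numeric matrix
#'   (experiments x TFs, NA = unscored); \code{targetCounts}: integer matrix
#'   of measured targets behind each entry.
#' @name activityScores
#' @aliases activityPvalues targetCounts
NULL

#' @rdname activityScores
#' @export
setMethod("activityScores", "ActivityMatrix", function(x) x@scores)

#' @rdname activityScores
#' @export
setMethod("activityPvalues", "ActivityMatrix", function(x) x@pvalues)

#' @rdname activityScores
#' @export
setMethod("targetCounts", "ActivityMatrix", function(x) x@nTargets)

setMethod("show", "ActivityMatrix", function(object) {
  cat(sprintf(
    "ActivityMatrix: %d experiments x %d TFs (minTargets = %d)\n",
    nrow(object@scores), ncol(object@scores), object@minTargets
  ))
  cat(sprintf(
    "  scored entries: %d of %d\n",
    sum(!is.na(object@scores)), length(object@scores)
  ))
  invisible(NULL)
})

#' Summaries of a BenchmarkResult
#'
#' \code{medianAuroc}/\code{medianAuprc} are the medians of the
#' per-permutation sample vectors; \code{metricSamples} returns the raw
#' samples as a data.frame.
#'
#' @param x a [BenchmarkResult-class].
#' @return numeric(1) medians, or a data.frame with columns
#'   \code{permutation}, \code{auroc}, \code{auprc}.
#' @name medianAuroc
#' @aliases medianAuprc metricSamples
NULL

#' @rdname medianAuroc
#' @export
setMethod("medianAuroc", "BenchmarkResult", function(x) {
  stats::median(x@aurocSamples)
})

#' @rdname medianAuroc
#' @export
setMethod("medianAuprc", "BenchmarkResult", function(x) {
  stats::median(x@auprcSamples)
})

#' @rdname medianAuroc
#' @export
setMethod("metricSamples", "BenchmarkResult", function(x) {
  data.frame(
    permutation = seq_along(x@aurocSamples),
    auroc = x@aurocSamples, auprc = x@auprcSamples
  )
})

setMethod("show", "BenchmarkResult", function(object) {
  cat(sprintf(
    "BenchmarkResult: %d permutations, %d positives / %d negatives (seed %d)\n",
    length(object@aurocSamples), object@nPositives, object@nNegatives,
    object@seed
  ))
  cat(sprintf(
    "  median AUROC %.4f, median AUPRC %.4f\n",
    medianAuroc(object), medianAuprc(object)
  ))
  invisible(NULL)
})

#' Access a TFClassification
#'
#' @param x a [TFClassification-class].
#' @return \code{tfClasses}: named list symbol -> class set;
#'   \code{priorRoles}: data.frame of TF-level prior roles.
#' @name tfClasses
#' @aliases priorRoles
NULL

#' @rdname tfClasses
#' @export
setMethod("tfClasses", "TFClassification", function(x) x@classes)

#' @rdname tfClasses
#' @export
setMethod("priorRoles", "TFClassification", function(x) x@priors)

setMethod("show", "TFClassification", function(object) {
  cat(sprintf(
    "TFClassification: %d classified symbols, %d with prior roles\n",
    length(object@classes), nrow(object@priors)
  ))
  invisible(NULL)
})

setMethod("show", "PerturbationExperiment", function(object) {
  cat(sprintf(
    "PerturbationExperiment %s: %s %s (logFC %.3g), %d genes\n",
    object@id,
    if (object@direction == -1L) "knockdown of" else "overexpression of",
    object@perturbedTf, object@perturbedTfLogfc, length(object@signature)
  ))
  invisible(NULL)
})
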