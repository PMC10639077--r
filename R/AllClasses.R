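#' @import methods
NULL

#' RegulonNetwork: a signed, weighted TF-target network
#'
#' Container for a collection of TF regulons. Each edge links a regulator
#' (a transcription factor or an explicitly named complex such as AP1 or
#' NFKB) to a target gene with a sign of regulation (+1 activating, -1
#' repressing), a positive weight (1 for unweighted networks, or a
#' motif-binding weight in (0, 1]), and a provenance label recording which
#' stage of the sign-assignment cascade produced the sign.
#'
#' @slot edges data.frame with columns \code{tf}, \code{target} (character),
#'   \code{sign} (integer, +1/-1), \code{weight} (positive numeric),
#'   \code{provenance} (one of \code{"pmid"}, \code{"regulon_majority"},
#'   \code{"prior_knowledge"}, \code{"default"}, \code{"truth"},
#'   \code{"permuted"}, \code{"input"}).
#' @slot metadata list of free-form provenance (strategy, seed, ...).
#'
#' @seealso [RegulonNetwork()] for construction, [assignMor()] which builds
#'   one from aggregated evidence, [regulonEdges()] and friends for access.
#' @export
setClass("RegulonNetwork",
  representation(edges = "data.frame", metadata = "list"),
  prototype(
    edges = data.frame(
      tf = character(), target = character(), sign = integer(),
      weight = numeric(), provenance = character(),
      stringsAsFactors = FALSE
    ),
    metadata = list()
  )
)

.validRegulonNetwork <- function(object) {
  ed <- object@edges
  msgs <- character()
  need <- c("tf", "target", "sign", "weight", "provenance")
  if (!all(need %in% names(ed))) {
    return(paste(
      "edges must have columns", paste(need, collapse = ", ")
    ))
  }
  if (nrow(ed)) {
    if (!all(ed$sign %in% c(-1L, 1L))) {
      msgs <- c(msgs, "edge signs must be +1 or -1")
    }
    if (!all(is.finite(ed$weight) & ed$weight > 0)) {
      msgs <- c(msgs, "edge weights must be finite and positive")
    }
    if (anyDuplicated(paste(ed$tf, ed$target, sep = "\r"))) {
      msgs <- c(msgs, "duplicate (tf, target) pairs are not allowed")
    }
    if (any(!nzchar(ed$tf)) || any(!nzchar(ed$target))) {
      msgs <- c(msgs, "tf and target symbols must be non-empty")
    }
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("RegulonNetwork", .validRegulonNetwork)

#' Construct a RegulonNetwork
#'
#' @param edges data.frame with columns \code{tf}, \code{target},
#'   \code{sign}; optional \code{weight} (default 1) and \code{provenance}
#'   (default \code{"input"}).
#' @param metadata list of provenance entries.
#' @return A [RegulonNetwork-class] object.
#' @examples
#' net <- RegulonNetwork(data.frame(
#'   tf = "TP53", target = c("CDKN1A", "BAX"), sign = c(1L, 1L)
#' ))
#' net
#' @export
RegulonNetwork <- function(edges, metadata = list()) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))
  if (is.null(edges$provenance)) {
    edges$provenance <- rep("input", nrow(edges))
  }
  edges$tf <- as.character(edges$tf)
  edges$target <- as.character(edges$target)
  edges$sign <- as.integer(edges$sign)
  edges$weight <- as.numeric(edges$weight)
  edges$provenance <- as.character(edges$provenance)
  rownames(edges) <- NULL
  new("RegulonNetwork",
    edges = edges[, c("tf", "target", "sign", "weight", "provenance")],
    metadata = metadata
  )
}

#' TFClassification: regulator classes and TF-level prior roles
#'
#' Static classification of gene symbols into the three transcription-factor
#' classes used to filter regulators — DNA-binding (dbTF), co-regulatory
#' (coTF) and general initiation (GTF) — plus optional TF-level prior-role
#' annotations (GO-derived role, UniProt-keyword role, KRAB-domain flag,
#' effector-domain role) that feed the prior-knowledge stage of the
#' sign-assignment cascade.
#'
#' @slot classes named list; symbol -> character vector, a subset of
#'   \code{c("dbTF", "coTF", "GTF")}.
#' @slot priors data.frame with columns \code{symbol}, \code{go_role},
#'   \code{uniprot_role}, \code{effector_role} (each one of
#'   \code{"activator"}, \code{"repressor"}, \code{"unknown"}) and
#'   \code{krab} (logical). Symbols absent from this table are treated as
#'   all-unknown with \code{krab = FALSE}.
#'
#' @seealso [loadClassification()], [filterRegulators()],
#'   [classifyTfFromPrior()]
#' @export
setClass("TFClassification",
  representation(classes = "list", priors = "data.frame"),
  prototype(
    classes = list(),
    priors = data.frame(
      symbol = character(), go_role = character(),
      uniprot_role = character(), krab = logical(),
      effector_role = character(), stringsAsFactors = FALSE
    )
  )
)

.validTFClassification <- function(object) {
  universe <- c("dbTF", "coTF", "GTF")
  bad <- vapply(
    object@classes, function(cl) !all(cl %in% universe), logical(1)
  )
  if (any(bad)) {
    return(paste(
      "unknown TF class for:",
      paste(names(object@classes)[bad], collapse = ", ")
    ))
  }
  pr <- object@priors
  roles <- c("activator", "repressor", "unknown")
  rolecols <- c("go_role", "uniprot_role", "effector_role")
  if (!all(c("symbol", rolecols, "krab") %in% names(pr))) {
    return("priors must have symbol, go_role, uniprot_role, krab, effector_role")
  }
  for (cc in rolecols) {
    if (!all(pr[[cc]] %in% roles)) {
      return(sprintf("%s must be activator/repressor/unknown", cc))
    }
  }
  TRUE
}
setValidity("TFClassification", .validTFClassification)

#' PerturbationExperiment: one TF-perturbation signature
#'
#' A gene-level differential-expression signature (logFC or t-statistics)
#' from a single TF knockdown/knockout or overexpression experiment, with
#' the identity of the perturbed TF, the perturbation direction, and the
#' perturbed TF's own log fold change (used to filter out ineffective
#' knockdowns).
#'
#' @slot id character experiment identifier.
#' @slot perturbedTf character, the perturbed TF symbol.
#' @slot direction integer, -1 for knockdown/knockout, +1 for
#'   overexpression.
#' @slot signature named numeric vector, gene -> statistic.
#' @slot perturbedTfLogfc numeric(1), the perturbed TF's own logFC
#'   (NA when unavailable).
#'
#' @seealso [PerturbationExperiment()], [filterExperiments()],
#'   [simulatePerturbation()]
#' @export
setClass("PerturbationExperiment",
  representation(
    id = "character", perturbedTf = "character", direction = "integer",
    signature = "numeric", perturbedTfLogfc = "numeric"
  )
)

.validPerturbationExperiment <- function(object) {
  msgs <- character()
  if (!object@direction %in% c(-1L, 1L)) {
    msgs <- c(msgs, "direction must be -1 (knockdown) or +1 (overexpression)")
  }
  if (!nzchar(object@perturbedTf)) {
    msgs <- c(msgs, "perturbedTf must be non-empty")
  }
  if (is.null(names(object@signature)) ||
      any(!nzchar(names(object@signature)))) {
    msgs <- c(msgs, "signature must be a named numeric vector")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("PerturbationExperiment", .validPerturbationExperiment)

#' Construct a PerturbationExperiment
#'
#' @param id experiment identifier.
#' @param perturbedTf perturbed TF symbol.
#' @param direction -1 (knockdown/knockout) or +1 (overexpression).
#' @param signature named numeric vector of gene-level statistics.
#' @param perturbedTfLogfc the perturbed TF's own logFC; NA if unknown.
#' @return A [PerturbationExperiment-class] object.
#' @export
PerturbationExperiment <- function(id, perturbedTf, direction, signature,
                                   perturbedTfLogfc = NA_real_) {
  new("PerturbationExperiment",
    id = as.character(id), perturbedTf = as.character(perturbedTf),
    direction = as.integer(direction),
    signature = signature,
    perturbedTfLogfc = as.numeric(perturbedTfLogfc)
  )
}

#' ActivityMatrix: TF activity scores across experiments
#'
#' Rows are experiments, columns are TFs (lexicographic order). Entries are
#' univariate-linear-model activity t-values; \code{NA} marks (experiment,
#' TF) pairs where the TF did not reach the minimum number of measured
#' targets and was therefore not scored.
#'
#' @slot scores numeric matrix of activity t-values (NA = unscored).
#' @slot pvalues numeric matrix of two-sided p-values (same shape).
#' @slot nTargets integer matrix: number of measured targets behind each
#'   scored entry (0 where unscored).
#' @slot minTargets integer, the threshold that was applied.
#'
#' @seealso [inferActivities()], [globalBenchmark()]
#' @export
setClass("ActivityMatrix",
  representation(
    scores = "matrix", pvalues = "matrix", nTargets = "matrix",
    minTargets = "integer"
  )
)

.validActivityMatrix <- function(object) {
  d <- dim(object@scores)
  if (!identical(d, dim(object@pvalues)) ||
      !identical(d, dim(object@nTargets))) {
    return("scores, pvalues and nTargets must share dimensions")
  }
  sc <- object@scores
  nt <- object@nTargets
  if (any(!is.na(sc) & nt < object@minTargets)) {
    return("every scored entry must meet the minTargets threshold")
  }
  TRUE
}
setValidity("ActivityMatrix", .validActivityMatrix)

#' BenchmarkResult: downsampled AUROC/AUPRC distributions
#'
#' Per-permutation AUROC and AUPRC samples from the class-balanced
#' downsampling benchmark, together with the class sizes and the seed that
#' produced them. Medians are recomputed from the sample vectors by the
#' accessors, so they can never drift from the samples.
#'
#' @slot aurocSamples numeric vector in [0, 1], one value per permutation.
#' @slot auprcSamples numeric vector in [0, 1], same length.
#' @slot nPositives integer, positives available before downsampling.
#' @slot nNegatives integer, negatives available before downsampling.
#' @slot seed integer seed used for the permutation draws.
#'
#' @seealso [globalBenchmark()], [perTfBenchmark()], [medianAuroc()]
#' @export
setClass("BenchmarkResult",
  representation(
    aurocSamples = "numeric", auprcSamples = "numeric",
    nPositives = "integer", nNegatives = "integer", seed = "integer"
  )
)

.validBenchmarkResult <- function(object) {
  msgs <- character()
  if (length(object@aurocSamples) != length(object@auprcSamples)) {
    msgs <- c(msgs, "sample vectors must have equal length")
  }
  rng <- c(object@aurocSamples, object@auprcSamples)
  if (length(rng) && (any(rng < 0) || any(rng > 1))) {
    msgs <- c(msgs, "AUROC/AUPRC samples must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("BenchmarkResult", .validBenchmarkResult)
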