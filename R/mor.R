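# Mode-of-regulation assignment: the decision cascade that turns aggregated
# literature evidence into a signed network.

#' Sign an interaction from PMID prevalence
#'
#' The edge-level rule: the mode of regulation backed by strictly more
#' PMIDs wins. Ties (including the no-evidence 0-0 case) are left
#' undetermined and fall through to the next cascade stage.
#'
#' @param interaction one row of an aggregated interaction data.frame
#'   (a list or single-row data.frame with \code{pmids_activation} and
#'   \code{pmids_repression}).
#' @return +1, -1, or NA (undetermined).
#' @export
signFromPmids <- function(interaction) {
  act <- interaction$pmids_activation
  rep_ <- interaction$pmids_repression
  if (is.list(act)) act <- act[[1L]]
  if (is.list(rep_)) rep_ <- rep_[[1L]]
  nA <- length(act)
  nR <- length(rep_)
  if (nA > nR) 1L else if (nR > nA) -1L else NA_integer_
}

#' Classify a TF from its PMID-signed edges
#'
#' The regulon-majority rule: a TF whose PMID-signed edges are mostly
#' activating is classified an activator (and symmetrically a repressor).
#' A tie or an empty input (no PMID-signed edge at all) is undetermined.
#'
#' @param pmidSigns integer vector of +1/-1 signs, one per PMID-signed edge
#'   of the TF.
#' @return \code{"activator"}, \code{"repressor"} or
#'   \code{"undetermined"}.
#' @export
classifyTfFromRegulon <- function(pmidSigns) {
  nA <- sum(pmidSigns == 1L)
  nR <- sum(pmidSigns == -1L)
  if (nA > nR) "activator" else if (nR > nA) "repressor" else "undetermined"
}

#' Classify a TF from prior knowledge
#'
#' Collects the non-unknown votes from the GO-derived role, the
#' UniProt-keyword role and the effector-domain role, plus a "repressor"
#' vote when the TF carries a KRAB domain. The TF is classified only when
#' at least one vote exists and all votes agree; missing sources abstain
#' rather than veto.
#'
#' @param prior list with \code{go_role}, \code{uniprot_role},
#'   \code{krab}, \code{effector_role} (see [priorEntry()]).
#' @return \code{"activator"}, \code{"repressor"} or
#'   \code{"undetermined"}.
#' @export
classifyTfFromPrior <- function(prior) {
  votes <- c(prior$go_role, prior$uniprot_role, prior$effector_role)
  votes <- votes[votes != "unknown"]
  if (isTRUE(prior$krab)) votes <- c(votes, "repressor")
  if (!length(votes)) return("undetermined")
  if (all(votes == votes[1L])) votes[1L] else "undetermined"
}

#' Assign a mode of regulation to every interaction
#'
#' Runs the sign-assignment cascade over aggregated interactions. Stages
#' are tried in order and the first one that resolves an edge fixes its
#' sign and provenance:
#' \describe{
#'   \item{\code{pmid}}{PMID prevalence per edge ([signFromPmids()]).}
#'   \item{\code{regulon_majority}}{the TF's overall role from the majority
#'     of its PMID-signed edges ([classifyTfFromRegulon()]), computed on
#'     this same input.}
#'   \item{\code{prior_knowledge}}{the TF's role from GO/UniProt/KRAB/
#'     effector-domain priors ([classifyTfFromPrior()]).}
#' }
#' Edges no stage resolves receive \code{defaultSign} with provenance
#' \code{default}. The published cascade is
#' \code{c("pmid", "regulon_majority")} with an activating default; the
#' prior-knowledge stage is available but off by default because it
#' degrades perturbation-benchmark performance.
#'
#' @param interactions aggregated interaction data.frame.
#' @param classification a [TFClassification-class]; only needed when
#'   \code{"prior_knowledge"} is in \code{strategy}.
#' @param strategy ordered character subset of
#'   \code{c("pmid", "regulon_majority", "prior_knowledge")}.
#' @param defaultSign +1 or -1 for edges no stage resolves.
#' @return A [RegulonNetwork-class] with per-edge sign and provenance.
#' @export
assignMor <- function(interactions,
                      classification = TFClassification(),
                      strategy = c("pmid", "regulon_majority"),
                      defaultSign = 1L) {
  known <- c("pmid", "regulon_majority", "prior_knowledge")
  if (length(strategy) && !all(strategy %in% known)) {
    stop("unknown cascade stage: ",
         paste(setdiff(strategy, known), collapse = ", "))
  }
  if (!length(strategy) && is.na(defaultSign)) {
    stop("empty strategy requires a default sign")
  }
  if (!defaultSign %in% c(-1L, 1L)) stop("defaultSign must be +1 or -1")
  n <- nrow(interactions)
  sign <- rep(NA_integer_, n)
  prov <- rep(NA_character_, n)

  # PMID prevalence is always computed: the regulon-majority stage is
  # defined over PMID-stage results even when "pmid" itself is not applied.
  pmidSign <- vapply(seq_len(n), function(i) {
    signFromPmids(list(
      pmids_activation = interactions$pmids_activation[[i]],
      pmids_repression = interactions$pmids_repression[[i]]
    ))
  }, integer(1))

  for (stage in strategy) {
    open <- is.na(sign)
    if (!any(open)) break
    if (stage == "pmid") {
      hit <- open & !is.na(pmidSign)
      sign[hit] <- pmidSign[hit]
      prov[hit] <- "pmid"
    } else if (stage == "regulon_majority") {
      roles <- vapply(
        split(pmidSign, interactions$tf),
        function(s) classifyTfFromRegulon(s[!is.na(s)]),
        character(1)
      )
      tfRole <- roles[interactions$tf]
      hit <- open & tfRole != "undetermined"
      sign[hit] <- ifelse(tfRole[hit] == "activator", 1L, -1L)
      prov[hit] <- "regulon_majority"
    } else if (stage == "prior_knowledge") {
      tfs <- unique(interactions$tf[open])
      roles <- vapply(
        tfs,
        function(tf) classifyTfFromPrior(priorEntry(classification, tf)),
        character(1)
      )
      tfRole <- setNames(roles, tfs)[interactions$tf]
      hit <- open & !is.na(tfRole) & tfRole != "undetermined"
      sign[hit] <- ifelse(tfRole[hit] == "activator", 1L, -1L)
      prov[hit] <- "prior_knowledge"
    }
  }
  open <- is.na(sign)
  sign[open] <- as.integer(defaultSign)
  prov[open] <- "default"
  RegulonNetwork(
    data.frame(
      tf = interactions$tf, target = interactions$target,
      sign = sign, weight = 1, provenance = prov,
      stringsAsFactors = FALSE
    ),
    metadata = list(strategy = strategy, defaultSign = defaultSign)
  )
}

#' Summarize the signs of a network
#'
#' Edge-level and TF-level composition of a signed network: counts,
#' activating/repressing fractions, how many TFs act purely as activators,
#' purely as repressors, or with a dual role (at least one edge of each
#' sign), and how many edges each cascade stage signed.
#'
#' @param network a non-empty [RegulonNetwork-class].
#' @return list with \code{n_tfs}, \code{n_edges}, \code{frac_activating},
#'   \code{frac_repressing}, \code{tf_role_fractions} (named numeric:
#'   pure_activator, pure_repressor, dual) and \code{provenance_counts}.
#' @export
summarizeNetwork <- function(network) {
  ed <- regulonEdges(network)
  if (!nrow(ed)) stop("cannot summarize an empty network")
  byTf <- split(ed$sign, ed$tf)
  hasAct <- vapply(byTf, function(s) any(s == 1L), logical(1))
  hasRep <- vapply(byTf, function(s) any(s == -1L), logical(1))
  nTf <- length(byTf)
  roles <- c(
    pure_activator = sum(hasAct & !hasRep) / nTf,
    pure_repressor = sum(hasRep & !hasAct) / nTf,
    dual = sum(hasAct & hasRep) / nTf
  )
  prov <- table(ed$provenance)
  list(
    n_tfs = nTf,
    n_edges = nrow(ed),
    frac_activating = mean(ed$sign == 1L),
    frac_repressing = mean(ed$sign == -1L),
    tf_role_fractions = roles,
    provenance_counts = setNames(as.integer(prov), names(prov))
  )
}
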