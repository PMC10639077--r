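#' @importFrom stats median setNames quantile pt sd cor complete.cases
#' @importFrom utils read.delim write.table head
NULL

# Evidence records travel as a data.frame with columns
#   tf, target, resource : character
#   pmids                : list-column of character vectors (possibly empty)
#   mor                  : "activation" | "repression" | "unknown"
# Aggregated interactions add list-columns pmids_all / pmids_activation /
# pmids_repression / resources keyed by unique (tf, target).

.morLevels <- c("activation", "repression", "unknown")

#' Build an evidence-record table
#'
#' Convenience constructor for the evidence data.frame used throughout the
#' build pipeline: one row per assertion of a TF-gene link by one resource,
#' carrying that record's PubMed identifiers and its mode-of-regulation
#' annotation.
#'
#' @param tf,target,resource character vectors (recycled to equal length).
#' @param pmids list of character vectors (or a single `;`-separated
#'   character vector); PMIDs are stored as strings and deduplicated within
#'   a record.
#' @param mor character, each \code{"activation"}, \code{"repression"} or
#'   \code{"unknown"}.
#' @return data.frame of evidence records with a \code{pmids} list-column.
#' @examples
#' evidenceRecords(
#'   tf = "JUN", target = "MMP1", resource = "dbA",
#'   pmids = list(c("111", "222")), mor = "activation"
#' )
#' @export
evidenceRecords <- function(tf, target, resource, pmids = NULL,
                            mor = "unknown") {
  n <- max(length(tf), length(target), length(resource), length(mor))
  if (is.null(pmids)) pmids <- rep(list(character()), n)
  if (is.character(pmids)) pmids <- strsplit(pmids, ";", fixed = TRUE)
  pmids <- lapply(pmids, function(p) unique(as.character(p[nzchar(p)])))
  if (length(pmids) == 1L && n > 1L) pmids <- rep(pmids, n)
  bad <- setdiff(unique(mor), .morLevels)
  if (length(bad)) {
    stop("invalid mode-of-regulation annotation: ", paste(bad, collapse = ", "))
  }
  out <- data.frame(
    tf = rep_len(as.character(tf), n),
    target = rep_len(as.character(target), n),
    resource = rep_len(as.character(resource), n),
    mor = rep_len(as.character(mor), n),
    stringsAsFactors = FALSE
  )
  out$pmids <- pmids
  out[, c("tf", "target", "resource", "pmids", "mor")]
}

#' Normalize gene symbols in evidence records
#'
#' Uppercases every regulator and target symbol and then applies a
#' user-supplied alias map (old symbol -> current symbol), standing in for
#' live nomenclature/orthology services. Records with an empty symbol are
#' dropped with a warning rather than an error.
#'
#' @param records evidence data.frame (see [evidenceRecords()]).
#' @param aliasMap named character vector mapping uppercased symbols to
#'   replacement symbols; may be empty.
#' @return The records with rewritten symbols; row multiplicity preserved
#'   (minus any empty-symbol rejects).
#' @export
normalizeRecords <- function(records, aliasMap = character()) {
  bad <- !nzchar(records$tf) | !nzchar(records$target)
  if (any(bad)) {
    warning(sum(bad), " record(s) with empty symbols dropped")
    records <- records[!bad, , drop = FALSE]
  }
  remap <- function(sym) {
    sym <- toupper(sym)
    if (length(aliasMap)) {
      hit <- match(sym, names(aliasMap))
      sym[!is.na(hit)] <- unname(aliasMap[hit[!is.na(hit)]])
    }
    sym
  }
  records$tf <- remap(records$tf)
  records$target <- remap(records$target)
  rownames(records) <- NULL
  records
}

#' Share evidence between complex members and the complex entry
#'
#' For dimeric regulators that the literature names both by the complex
#' (AP1, NFKB) and by their member subunits (JUN/FOS families, NFKB
#' subunits), evidence recorded under a member for a given target gene is
#' also attributed to the complex, and vice versa: for each target, the
#' PMID-set union is bidirectional and both the member and complex edges are
#' emitted. Records of members without any complex-level counterpart for
#' that target gain a mirrored complex record (and vice versa), so the
#' complex regulon is the union over its members.
#'
#' @param records evidence data.frame.
#' @param complexMap named character vector, member symbol -> complex name
#'   (see [defaultComplexMap()]); may be empty.
#' @return Evidence records with mirrored complex/member rows appended.
#' @export
expandComplexMembers <- function(records, complexMap = defaultComplexMap()) {
  if (!length(complexMap)) return(records)
  overlap <- intersect(names(complexMap), unname(complexMap))
  if (length(overlap)) {
    stop(
      "symbols both complex name and member key: ",
      paste(overlap, collapse = ", ")
    )
  }
  members <- names(complexMap)
  extra <- list()
  # member -> complex mirror
  isMember <- records$tf %in% members
  if (any(isMember)) {
    mirrored <- records[isMember, , drop = FALSE]
    mirrored$tf <- unname(complexMap[mirrored$tf])
    extra[[length(extra) + 1L]] <- mirrored
  }
  # complex -> member mirror: complex evidence flows to every member that
  # asserts the same target (not to members silent on that target)
  for (cx in unique(unname(complexMap))) {
    cxMembers <- members[complexMap[members] == cx]
    isCx <- records$tf == cx
    if (!any(isCx)) next
    memRows <- records[records$tf %in% cxMembers, , drop = FALSE]
    for (i in which(isCx)) {
      hitMembers <- unique(memRows$tf[memRows$target == records$target[i]])
      for (m in hitMembers) {
        mirrored <- records[i, , drop = FALSE]
        mirrored$tf <- m
        extra[[length(extra) + 1L]] <- mirrored
      }
    }
  }
  if (length(extra)) {
    records <- do.call(rbind, c(list(records), extra))
    rownames(records) <- NULL
  }
  records
}

#' Default complex-membership map
#'
#' Jun/Fos-family members map to the AP1 dimer and NFKB subunits to NFKB.
#' The lists are a pragmatic default and can be overridden with any named
#' character vector (or a two-column TSV via [readComplexMap()]).
#'
#' @return named character vector, member symbol -> complex name.
#' @export
defaultComplexMap <- function() {
  c(
    JUN = "AP1", JUNB = "AP1", JUND = "AP1",
    FOS = "AP1", FOSB = "AP1", FOSL1 = "AP1", FOSL2 = "AP1",
    NFKB1 = "NFKB", NFKB2 = "NFKB", RELA = "NFKB", RELB = "NFKB",
    REL = "NFKB"
  )
}

#' Aggregate evidence records into unique TF-gene interactions
#'
#' Collapses all records for one (tf, target) pair across resources into a
#' single interaction. PMIDs are deduplicated across resources — a PMID
#' counts as evidence for an interaction only once no matter how many
#' databases curated it — except that a PMID asserted with different modes
#' of regulation in different resources is kept in both the activation and
#' the repression evidence sets. Records annotated \code{unknown}
#' contribute their PMIDs to the overall evidence pool only.
#'
#' @param records normalized evidence data.frame.
#' @return data.frame with one row per (tf, target) and list-columns
#'   \code{pmids_all}, \code{pmids_activation}, \code{pmids_repression},
#'   \code{resources}.
#' @export
aggregateEvidence <- function(records) {
  if (!nrow(records)) {
    out <- data.frame(
      tf = character(), target = character(), stringsAsFactors = FALSE
    )
    out$pmids_all <- list()
    out$pmids_activation <- list()
    out$pmids_repression <- list()
    out$resources <- list()
    return(out)
  }
  key <- paste(records$tf, records$target, sep = "\r")
  idx <- split(seq_len(nrow(records)), factor(key, levels = unique(key)))
  rows <- lapply(idx, function(ii) {
    rec <- records[ii, , drop = FALSE]
    allP <- unique(unlist(rec$pmids, use.names = FALSE))
    act <- unique(unlist(rec$pmids[rec$mor == "activation"],
                         use.names = FALSE))
    rep_ <- unique(unlist(rec$pmids[rec$mor == "repression"],
                          use.names = FALSE))
    list(
      tf = rec$tf[1L], target = rec$target[1L],
      pmids_all = if (is.null(allP)) character() else allP,
      pmids_activation = if (is.null(act)) character() else act,
      pmids_repression = if (is.null(rep_)) character() else rep_,
      resources = unique(rec$resource)
    )
  })
  out <- data.frame(
    tf = vapply(rows, `[[`, character(1), "tf"),
    target = vapply(rows, `[[`, character(1), "target"),
    stringsAsFactors = FALSE
  )
  out$pmids_all <- lapply(rows, `[[`, "pmids_all")
  out$pmids_activation <- lapply(rows, `[[`, "pmids_activation")
  out$pmids_repression <- lapply(rows, `[[`, "pmids_repression")
  out$resources <- lapply(rows, `[[`, "resources")
  rownames(out) <- NULL
  out
}

#' Drop interactions lacking any literature reference
#'
#' Interactions whose deduplicated PMID pool is empty carry no literature
#' support and are removed; input order is preserved.
#'
#' @param interactions aggregated interaction data.frame
#'   (see [aggregateEvidence()]).
#' @return The referenced subset, in input order.
#' @export
dropUnreferenced <- function(interactions) {
  keep <- vapply(interactions$pmids_all, length, integer(1)) > 0L
  out <- interactions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
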