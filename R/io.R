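# TSV dialect used throughout: tab-separated, header row, UTF-8, NA for
# missing; PMID lists are `;`-delimited within a cell.

#' Read an evidence table
#'
#' Parses a tab-separated evidence file with header
#' \code{tf  target  resource  pmids  mor}; \code{pmids} is a
#' `;`-delimited list (empty allowed) and \code{mor} must be one of
#' \code{activation}/\code{repression}/\code{unknown}. CRLF line endings
#' are handled transparently. A missing column or an invalid mor literal
#' is a parse error naming the offending line.
#'
#' @param path file path.
#' @return evidence data.frame (see [evidenceRecords()]).
#' @export
readEvidenceTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = NULL)
  need <- c("tf", "target", "resource", "pmids", "mor")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  }
  bad <- which(!tab$mor %in% .morLevels)
  if (length(bad)) {
    stop(sprintf(
      "%s: invalid mor literal '%s' at line %d",
      path, tab$mor[bad[1L]], bad[1L] + 1L  # +1 for the header row
    ))
  }
  evidenceRecords(
    tf = tab$tf, target = tab$target, resource = tab$resource,
    pmids = tab$pmids, mor = tab$mor
  )
}

#' Write an evidence table
#'
#' @param records evidence data.frame.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeEvidenceTable <- function(records, path) {
  out <- records
  out$pmids <- vapply(records$pmids, paste, character(1), collapse = ";")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column symbol map
#'
#' Generic reader for alias maps (old symbol -> current symbol) and
#' complex maps (member symbol -> complex name): a headered two-column
#' TSV.
#'
#' @param path file path.
#' @return named character vector (first column names, second values).
#' @export
readSymbolMap <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop(path, ": expected two columns")
  setNames(tab[[2L]], tab[[1L]])
}

#' @rdname readSymbolMap
#' @export
readComplexMap <- readSymbolMap

#' Write a signed network as TSV
#'
#' Columns \code{source  target  weight  mor  provenance}, where
#' \code{weight} carries sign x magnitude (unweighted networks use +-1)
#' and \code{mor} the bare sign.
#'
#' @param network a [RegulonNetwork-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeNetworkTsv <- function(network, path) {
  ed <- regulonEdges(network)
  out <- data.frame(
    source = ed$tf, target = ed$target,
    weight = ed$sign * ed$weight, mor = ed$sign,
    provenance = ed$provenance, stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signed network TSV
#'
#' @param path file written by [writeNetworkTsv()] (or any TSV with
#'   \code{source}, \code{target} and a signed \code{weight} column).
#' @return A [RegulonNetwork-class].
#' @export
readNetworkTsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source", "target", "weight") %in% names(tab))) {
    stop(path, ": expected columns source, target, weight")
  }
  sgn <- ifelse(tab$weight < 0, -1L, 1L)
  RegulonNetwork(data.frame(
    tf = tab$source, target = tab$target, sign = sgn,
    weight = abs(tab$weight),
    provenance = if ("provenance" %in% names(tab)) tab$provenance else "input",
    stringsAsFactors = FALSE
  ))
}

#' Export regulons as GMT gene sets
#'
#' One line per TF: name, a description placeholder, then the target
#' genes; signs are dropped (GMT is unsigned).
#'
#' @param network a [RegulonNetwork-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeGmt <- function(network, path) {
  ed <- regulonEdges(network)
  lines <- vapply(split(ed$target, ed$tf), function(tg) {
    paste(c(tg), collapse = "\t")
  }, character(1))
  writeLines(
    paste(names(lines), "regulon", lines, sep = "\t"),
    path
  )
  invisible(path)
}

#' Read a gene-level signature
#'
#' @param path TSV with header \code{gene  value}.
#' @return named numeric vector.
#' @export
readSignature <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "value") %in% names(tab))) {
    stop(path, ": expected columns gene, value")
  }
  setNames(as.numeric(tab$value), as.character(tab$gene))
}

#' Write a gene-level signature
#'
#' @param signature named numeric vector.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSignature <- function(signature, path) {
  write.table(
    data.frame(gene = names(signature), value = as.numeric(signature)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write a perturbation compendium to a directory
#'
#' Emits one signature TSV per experiment plus an \code{experiments.tsv}
#' metadata table (\code{id  perturbed_tf  direction  perturbed_tf_logfc
#' signature_path}).
#'
#' @param experiments list of [PerturbationExperiment-class] objects.
#' @param dir output directory (created if needed).
#' @return invisibly, the metadata file path.
#' @export
writeCompendium <- function(experiments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- data.frame(
    id = vapply(experiments, function(e) e@id, character(1)),
    perturbed_tf = vapply(experiments, function(e) e@perturbedTf,
                          character(1)),
    direction = vapply(experiments, function(e) e@direction, integer(1)),
    perturbed_tf_logfc = vapply(experiments, function(e) e@perturbedTfLogfc,
                                numeric(1)),
    stringsAsFactors = FALSE
  )
  meta$signature_path <- paste0(meta$id, ".tsv")
  for (i in seq_along(experiments)) {
    writeSignature(experiments[[i]]@signature,
                   file.path(dir, meta$signature_path[i]))
  }
  path <- file.path(dir, "experiments.tsv")
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a perturbation compendium
#'
#' @param dir directory written by [writeCompendium()] (or following the
#'   same layout).
#' @return list of [PerturbationExperiment-class] objects.
#' @export
readCompendium <- function(dir) {
  meta <- read.delim(file.path(dir, "experiments.tsv"),
                     stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i) {
    PerturbationExperiment(
      id = meta$id[i], perturbedTf = meta$perturbed_tf[i],
      direction = meta$direction[i],
      signature = readSignature(file.path(dir, meta$signature_path[i])),
      perturbedTfLogfc = meta$perturbed_tf_logfc[i]
    )
  })
}

#' Write an activity matrix as TSV
#'
#' Experiments x TFs, \code{NA} for masked entries, experiment ids in the
#' first column.
#'
#' @param activities an [ActivityMatrix-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeActivityTsv <- function(activities, path) {
  sc <- activityScores(activities)
  out <- data.frame(experiment = rownames(sc), sc, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
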