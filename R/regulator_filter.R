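#' Load TF classification and prior-role files
#'
#' Reads the static regulator-class snapshot (symbol, class with class in
#' dbTF/coTF/GTF; duplicate rows merged by set union) and, optionally, the
#' TF-level prior-role table (GO-derived role, UniProt-keyword role, KRAB
#' flag, effector-domain role) used by the prior-knowledge stage of the
#' sign-assignment cascade.
#'
#' @param classFile path to a tab-separated file with header
#'   \code{symbol  class}.
#' @param priorFile optional path to a tab-separated file with header
#'   \code{symbol  go_role  uniprot_role  krab  effector_role}; roles are
#'   \code{activator}/\code{repressor}/\code{unknown}, krab is
#'   \code{true}/\code{false}.
#' @return A [TFClassification-class] object.
#' @export
loadClassification <- function(classFile, priorFile = NULL) {
  cls <- read.delim(classFile, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (!all(c("symbol", "class") %in% names(cls))) {
    stop("classification file must have columns 'symbol' and 'class'")
  }
  bad <- which(!cls$class %in% c("dbTF", "coTF", "GTF"))
  if (length(bad)) {
    stop(sprintf(
      "unknown class label '%s' in row %d of %s",
      cls$class[bad[1L]], bad[1L], classFile
    ))
  }
  classes <- lapply(split(cls$class, cls$symbol), unique)
  priors <- new("TFClassification")@priors
  if (!is.null(priorFile)) {
    pr <- read.delim(priorFile, stringsAsFactors = FALSE,
                     colClasses = "character")
    need <- c("symbol", "go_role", "uniprot_role", "krab", "effector_role")
    if (!all(need %in% names(pr))) {
      stop("prior-role file must have columns ", paste(need, collapse = ", "))
    }
    pr$krab <- pr$krab %in% c("true", "TRUE", "True")
    priors <- pr[, need]
  }
  new("TFClassification", classes = classes, priors = priors)
}

#' Build a TFClassification in code
#'
#' @param classes named list, symbol -> character vector of classes
#'   (subset of dbTF/coTF/GTF).
#' @param priors optional data.frame of prior roles (see
#'   [TFClassification-class]).
#' @return A [TFClassification-class] object.
#' @export
TFClassification <- function(classes = list(), priors = NULL) {
  if (is.null(priors)) priors <- new("TFClassification")@priors
  new("TFClassification", classes = classes, priors = priors)
}

#' Restrict interactions to classified regulators
#'
#' Keeps interactions whose regulator is classified as a DNA-binding,
#' co-regulatory or general-initiation TF (membership in any one class
#' suffices). Complex regulators such as AP1 and NFKB are not gene symbols
#' and never appear in class snapshots, so they are retained through an
#' explicit whitelist instead. Target genes are never filtered.
#'
#' @param interactions aggregated interaction data.frame.
#' @param classification a [TFClassification-class].
#' @param complexWhitelist character vector of complex names always kept
#'   as regulators.
#' @return The subset with classified (or whitelisted) regulators, order
#'   preserved.
#' @export
filterRegulators <- function(interactions, classification,
                             complexWhitelist = c("AP1", "NFKB")) {
  classed <- names(tfClasses(classification))
  classed <- classed[vapply(tfClasses(classification), length, integer(1)) > 0L]
  keep <- interactions$tf %in% c(classed, complexWhitelist)
  out <- interactions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Look up a TF's prior-role entry
#'
#' @param classification a [TFClassification-class].
#' @param tf TF symbol.
#' @return list with go_role, uniprot_role, krab, effector_role; an
#'   all-unknown entry when the TF has no prior annotation.
#' @keywords internal
priorEntry <- function(classification, tf) {
  pr <- priorRoles(classification)
  i <- match(tf, pr$symbol)
  if (is.na(i)) {
    list(go_role = "unknown", uniprot_role = "unknown", krab = FALSE,
         effector_role = "unknown")
  } else {
    list(go_role = pr$go_role[i], uniprot_role = pr$uniprot_role[i],
         krab = pr$krab[i], effector_role = pr$effector_role[i])
  }
}
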