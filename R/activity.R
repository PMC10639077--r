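# TF activity inference with the univariate linear model (ulm): per TF, an
# ordinary least-squares regression of the whole gene-level signature on the
# TF's signed target-indicator vector; the activity is the slope t-value.

#' Score TF activities for one signature
#'
#' For each TF the signature genes form the regression universe: the
#' predictor x places the TF's signed edge weight on its measured targets
#' and 0 on every other measured gene, and the signature values y are
#' regressed on x with an intercept. The activity is the slope divided by
#' its standard error (t-value on n-2 degrees of freedom), with a
#' two-sided p-value. Only TFs with at least \code{minTargets} measured
#' targets are scored; the network is first filtered to genes present in
#' the signature.
#'
#' Duplicate gene rows are averaged with a warning; non-finite values are
#' dropped. A fit with zero residual variance yields a signed infinite
#' activity with a warning; a constant predictor (the TF targets every
#' measured gene, or none) leaves the TF unscored.
#'
#' @param signature named numeric vector, gene -> statistic (logFC, t, or
#'   normalized expression); at least 3 genes after cleaning.
#' @param network a [RegulonNetwork-class].
#' @param minTargets minimum measured targets per scored TF (default 5,
#'   must be >= 2).
#' @return data.frame with columns \code{tf}, \code{activity},
#'   \code{pvalue}, \code{n_targets}, one row per scored TF
#'   (lexicographic TF order).
#' @examples
#' net <- RegulonNetwork(data.frame(
#'   tf = "TF1", target = paste0("G", 1:5), sign = 1L
#' ))
#' sig <- setNames(c(2, 1, 0.5, 1.5, 1, -0.2, 0.1, 0), paste0("G", 1:8))
#' ulmActivity(sig, net, minTargets = 5)
#' @export
ulmActivity <- function(signature, network, minTargets = 5L) {
  if (minTargets < 2L) stop("minTargets must be >= 2")
  if (is.null(names(signature))) stop("signature must be named by gene")
  signature <- signature[is.finite(signature)]
  if (anyDuplicated(names(signature))) {
    warning("duplicate gene rows in signature averaged")
    signature <- tapply(signature, names(signature), mean)
    signature <- setNames(as.numeric(signature), names(signature))
  }
  if (length(signature) < 3L) {
    stop("signature must contain at least 3 genes after cleaning")
  }
  genes <- names(signature)
  y <- as.numeric(signature)
  nGene <- length(y)

  ed <- regulonEdges(network)
  ed <- ed[ed$target %in% genes, , drop = FALSE]
  tfs <- sort(unique(ed$tf))
  out <- data.frame(
    tf = character(), activity = numeric(), pvalue = numeric(),
    n_targets = integer(), stringsAsFactors = FALSE
  )
  if (!length(tfs)) return(out)

  sy <- sum(y)
  syy <- sum(y * y)
  meanY <- sy / nGene
  rows <- vector("list", length(tfs))
  for (k in seq_along(tfs)) {
    sub <- ed[ed$tf == tfs[k], , drop = FALSE]
    nt <- nrow(sub)
    if (nt < minTargets) next
    gi <- match(sub$target, genes)
    xv <- sub$sign * sub$weight
    # moments of the sparse predictor over the full gene universe
    sx <- sum(xv)
    sxx <- sum(xv * xv)
    sxy <- sum(xv * y[gi])
    Sxx <- sxx - sx * sx / nGene
    if (Sxx <= .Machine$double.eps * max(1, sxx)) next  # constant predictor
    Sxy <- sxy - sx * sy / nGene
    Syy <- syy - sy * sy / nGene
    slope <- Sxy / Sxx
    df <- nGene - 2L
    sse <- Syy - slope * Sxy
    if (sse < 0) sse <- 0
    if (sse <= .Machine$double.eps * max(1, abs(Syy))) {
      warning(sprintf(
        "zero residual variance for TF %s; activity is signed infinity",
        tfs[k]
      ))
      tval <- sign(slope) * Inf
      pval <- 0
    } else {
      se <- sqrt(sse / df / Sxx)
      tval <- slope / se
      pval <- 2 * pt(abs(tval), df = df, lower.tail = FALSE)
    }
    rows[[k]] <- data.frame(
      tf = tfs[k], activity = tval, pvalue = pval, n_targets = nt,
      stringsAsFactors = FALSE
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(out)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Infer an activity matrix over a compendium
#'
#' Applies [ulmActivity()] to every experiment and assembles the
#' experiments x TFs activity matrix. Columns are the union of scored TFs
#' in lexicographic order; entries where a TF did not reach
#' \code{minTargets} measured targets in that experiment are \code{NA}
#' (masked).
#'
#' @param experiments list of [PerturbationExperiment-class] objects.
#' @param network a [RegulonNetwork-class].
#' @param minTargets minimum measured targets per scored TF.
#' @return An [ActivityMatrix-class].
#' @export
inferActivities <- function(experiments, network, minTargets = 5L) {
  if (!length(experiments)) stop("need at least one experiment")
  perExp <- lapply(experiments, function(ex) {
    tryCatch(
      ulmActivity(ex@signature, network, minTargets = minTargets),
      error = function(e) {
        stop(sprintf("experiment %s: %s", ex@id, conditionMessage(e)))
      }
    )
  })
  tfs <- sort(unique(unlist(lapply(perExp, `[[`, "tf"))))
  ids <- vapply(experiments, function(ex) ex@id, character(1))
  m <- matrix(NA_real_, length(experiments), length(tfs),
              dimnames = list(ids, tfs))
  pv <- m
  nt <- matrix(0L, length(experiments), length(tfs),
               dimnames = list(ids, tfs))
  for (i in seq_along(perExp)) {
    res <- perExp[[i]]
    j <- match(res$tf, tfs)
    m[i, j] <- res$activity
    pv[i, j] <- res$pvalue
    nt[i, j] <- res$n_targets
  }
  new("ActivityMatrix", scores = m, pvalues = pv, nTargets = nt,
      minTargets = as.integer(minTargets))
}
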