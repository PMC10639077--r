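# Synthetic ground truth: networks with known signs, noisy multi-resource
# evidence tables, and knockdown/overexpression signature compendia. Every
# generator is deterministic under its seed.

#' Simulate a ground-truth regulon network
#'
#' Each of \code{nTf} regulators (TF1, TF2, ...) receives
#' \code{targetsPerTf} distinct targets sampled uniformly from \code{nGenes}
#' genes (G1, G2, ...); each edge is repressing (-1) independently with
#' probability \code{repressorFraction} and activating (+1) otherwise.
#'
#' @param nTf number of TFs.
#' @param targetsPerTf targets per TF; a single integer or a vector
#'   recycled across TFs (none may exceed \code{nGenes}).
#' @param repressorFraction probability of a repressing edge, in [0, 1].
#' @param nGenes size of the target-gene universe.
#' @param seed integer seed.
#' @return A [RegulonNetwork-class] with provenance \code{"truth"}.
#' @export
simulateNetwork <- function(nTf, targetsPerTf, repressorFraction = 0.3,
                            nGenes = 200L, seed = 1L) {
  if (any(targetsPerTf > nGenes)) stop("targetsPerTf must not exceed nGenes")
  if (repressorFraction < 0 || repressorFraction > 1) {
    stop("repressorFraction must lie in [0, 1]")
  }
  nTargets <- rep_len(as.integer(targetsPerTf), nTf)
  genes <- paste0("G", seq_len(nGenes))
  tfs <- paste0("TF", seq_len(nTf))
  withr::with_seed(seed, {
    edges <- do.call(rbind, lapply(seq_len(nTf), function(k) {
      data.frame(
        tf = tfs[k], target = sample(genes, nTargets[k]),
        stringsAsFactors = FALSE
      )
    }))
    edges$sign <- ifelse(
      stats::runif(nrow(edges)) < repressorFraction, -1L, 1L
    )
  })
  edges$weight <- 1
  edges$provenance <- "truth"
  RegulonNetwork(edges, metadata = list(
    seed = seed, n_genes = nGenes, repressor_fraction = repressorFraction
  ))
}

#' Simulate multi-resource literature evidence for a network
#'
#' Emulates the statistical structure of aggregated curation: each edge
#' owns a pool of \code{pmidsPerEdge} unique synthetic PMIDs, each of which
#' mis-annotates the true sign independently with probability
#' \code{signErrorRate} (the flip travels with the PMID, so resources that
#' share it agree). The edge is asserted by 1..\code{nResources} resources;
#' the first carries the full pool and later resources re-draw each pool
#' member with probability \code{sharedPool}, creating cross-resource PMID
#' overlap while keeping the deduplicated union equal to the pool. Each
#' record is finally stripped of its PMIDs with probability
#' \code{unreferencedFraction}.
#'
#' @param network a [RegulonNetwork-class] ground truth.
#' @param nResources maximum resources asserting an edge.
#' @param pmidsPerEdge unique PMIDs per edge.
#' @param signErrorRate per-PMID sign-flip probability, in [0, 1].
#' @param unreferencedFraction per-record probability of carrying no
#'   PMIDs, in [0, 1].
#' @param sharedPool probability that a later resource re-draws a pool
#'   PMID (controls cross-resource overlap).
#' @param seed integer seed.
#' @return evidence data.frame (see [evidenceRecords()]).
#' @export
simulateEvidence <- function(network, nResources = 3L, pmidsPerEdge = 3L,
                             signErrorRate = 0, unreferencedFraction = 0,
                             sharedPool = 0.5, seed = 1L) {
  stopifnot(
    signErrorRate >= 0, signErrorRate <= 1,
    unreferencedFraction >= 0, unreferencedFraction <= 1
  )
  ed <- regulonEdges(network)
  nextPmid <- 0L
  recs <- list()
  withr::with_seed(seed, {
    for (i in seq_len(nrow(ed))) {
      pool <- as.character(nextPmid + seq_len(pmidsPerEdge))
      nextPmid <- nextPmid + pmidsPerEdge
      flipped <- stats::runif(pmidsPerEdge) < signErrorRate
      trueMor <- if (ed$sign[i] == 1L) "activation" else "repression"
      flipMor <- if (ed$sign[i] == 1L) "repression" else "activation"
      mor <- ifelse(flipped, flipMor, trueMor)
      nRes <- sample.int(nResources, 1L)
      for (r in seq_len(nRes)) {
        take <- if (r == 1L) {
          rep(TRUE, pmidsPerEdge)
        } else {
          stats::runif(pmidsPerEdge) < sharedPool
        }
        if (!any(take)) next
        for (m in unique(mor[take])) {
          p <- pool[take & mor == m]
          if (stats::runif(1) < unreferencedFraction) p <- character()
          recs[[length(recs) + 1L]] <- evidenceRecords(
            tf = ed$tf[i], target = ed$target[i],
            resource = paste0("resource", r),
            pmids = list(p), mor = m
          )
        }
      }
    }
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Simulate one TF-perturbation signature
#'
#' A gene-level logFC signature for perturbing one TF: targets of the TF
#' shift by direction x edge sign x \code{effectSize} plus Gaussian noise,
#' all other genes are pure noise, and the perturbed TF's own entry is set
#' to \code{perturbedTfLogfc} (default -2, so a default knockdown survives
#' the effectiveness filter at threshold -1).
#'
#' @param network a [RegulonNetwork-class] ground truth.
#' @param perturbedTf TF symbol present in the network.
#' @param effectSize absolute shift of true targets.
#' @param noiseSd Gaussian noise standard deviation (>= 0).
#' @param direction -1 knockdown (default), +1 overexpression.
#' @param perturbedTfLogfc the perturbed TF's own logFC entry.
#' @param id experiment identifier.
#' @param seed integer seed.
#' @return A [PerturbationExperiment-class].
#' @export
simulatePerturbation <- function(network, perturbedTf, effectSize = 3,
                                 noiseSd = 0.5, direction = -1L,
                                 perturbedTfLogfc = -2,
                                 id = paste0("exp_", perturbedTf),
                                 seed = 1L) {
  ed <- regulonEdges(network)
  if (!perturbedTf %in% ed$tf) stop("unknown TF: ", perturbedTf)
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  nGenes <- network@metadata$n_genes
  genes <- if (is.null(nGenes)) {
    sort(unique(ed$target))
  } else {
    paste0("G", seq_len(nGenes))
  }
  withr::with_seed(seed, {
    y <- stats::rnorm(length(genes), 0, noiseSd)
  })
  names(y) <- genes
  sub <- ed[ed$tf == perturbedTf, , drop = FALSE]
  hit <- match(sub$target, genes)
  y[hit] <- y[hit] + direction * sub$sign * effectSize
  y[perturbedTf] <- perturbedTfLogfc
  PerturbationExperiment(
    id = id, perturbedTf = perturbedTf, direction = direction,
    signature = y, perturbedTfLogfc = perturbedTfLogfc
  )
}

#' Simulate a knockdown compendium
#'
#' One knockdown [PerturbationExperiment-class] per requested TF (by
#' default every TF in the network), with per-experiment seeds derived
#' from the master seed.
#'
#' @param network a [RegulonNetwork-class] ground truth.
#' @param tfs TFs to perturb (default: all regulators).
#' @param effectSize,noiseSd,direction,perturbedTfLogfc forwarded to
#'   [simulatePerturbation()].
#' @param seed integer master seed.
#' @return list of [PerturbationExperiment-class] objects.
#' @export
simulateCompendium <- function(network, tfs = regulators(network),
                               effectSize = 3, noiseSd = 0.5,
                               direction = -1L, perturbedTfLogfc = -2,
                               seed = 1L) {
  lapply(seq_along(tfs), function(k) {
    simulatePerturbation(
      network, tfs[k], effectSize = effectSize, noiseSd = noiseSd,
      direction = direction, perturbedTfLogfc = perturbedTfLogfc,
      id = sprintf("exp_%03d_%s", k, tfs[k]),
      seed = seed * 1000L + k
    )
  })
}
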