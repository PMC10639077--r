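# Perturbation benchmark: can a regulon collection place the perturbed TF
# above the unperturbed ones? Sign-corrected activities are flattened and
# ranked; class imbalance is neutralized by repeated balanced downsampling.

#' Filter out ineffective knockdown experiments
#'
#' Knockdown/knockout experiments only enter the benchmark when the
#' perturbation visibly worked: the perturbed TF's own log fold change must
#' be at most \code{logfcThreshold} (default -1; experiments with a logFC
#' greater than -1 are excluded, the boundary itself is retained).
#' Overexpression experiments pass unfiltered. Knockdowns lacking the
#' perturbed-TF logFC are excluded with a warning.
#'
#' @param experiments list of [PerturbationExperiment-class] objects.
#' @param logfcThreshold numeric, default -1.
#' @return The retained experiments, in input order.
#' @export
filterExperiments <- function(experiments, logfcThreshold = -1) {
  keep <- vapply(experiments, function(ex) {
    if (ex@direction == 1L) return(TRUE)
    if (is.na(ex@perturbedTfLogfc)) {
      warning(sprintf(
        "knockdown experiment %s lacks perturbed-TF logFC; excluded", ex@id
      ))
      return(FALSE)
    }
    ex@perturbedTfLogfc <= logfcThreshold
  }, logical(1))
  experiments[keep]
}

#' Tie-aware AUROC and average-precision AUPRC
#'
#' AUROC is computed by pair counting: the fraction of (positive,
#' negative) pairs where the positive scores higher, ties contributing
#' 1/2. AUPRC is step-wise average precision: scores are sorted in
#' descending order (ties broken deterministically by input position) and
#' the precisions at each positive's rank are averaged.
#'
#' @param scores numeric vector.
#' @param labels binary vector (1 = positive) of the same length, with at
#'   least one positive and one negative.
#' @return named numeric c(auroc = , auprc = ).
#' @examples
#' rankMetrics(c(0.9, 0.6, 0.4, 0.2), c(1, 0, 0, 1))  # AUROC 0.5, AP 0.75
#' @export
rankMetrics <- function(scores, labels) {
  labels <- as.integer(labels != 0)
  nPos <- sum(labels == 1L)
  nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L) {
    stop("need at least one positive and one negative label")
  }
  # AUROC via the rank-sum identity; average ranks give ties weight 1/2
  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  # average precision, descending scores, stable tie order
  ord <- order(-scores, seq_along(scores))
  labOrd <- labels[ord]
  cumPos <- cumsum(labOrd)
  prec <- cumPos / seq_along(labOrd)
  auprc <- mean(prec[labOrd == 1L])
  c(auroc = auroc, auprc = auprc)
}

# Sign-correct and flatten an activity matrix against experiment metadata.
# Returns scores/labels plus bookkeeping columns; drops experiments whose
# perturbed TF is unscored (masked or absent) in that experiment.
.flattenScores <- function(activities, experiments) {
  sc <- activityScores(activities)
  ids <- vapply(experiments, function(ex) ex@id, character(1))
  i <- match(ids, rownames(sc))
  if (anyNA(i)) stop("experiments missing from the activity matrix")
  rows <- list()
  for (k in seq_along(experiments)) {
    ex <- experiments[[k]]
    row <- sc[i[k], ]
    pt <- ex@perturbedTf
    if (!pt %in% colnames(sc) || is.na(row[pt])) next
    scored <- !is.na(row)
    rows[[length(rows) + 1L]] <- data.frame(
      experiment = ex@id,
      tf = colnames(sc)[scored],
      score = unname(row[scored]) * ex@direction,
      label = as.integer(colnames(sc)[scored] == pt),
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop("no experiment has a scored perturbed TF")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.downsampledMetrics <- function(scores, labels, nPerm, seed) {
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  if (!length(pos) || !length(neg)) {
    stop("need both positive and negative classes after flattening")
  }
  n <- min(length(pos), length(neg))
  auroc <- numeric(nPerm)
  auprc <- numeric(nPerm)
  withr::with_seed(seed, {
    for (p in seq_len(nPerm)) {
      take <- c(
        if (length(pos) == n) pos else sample(pos, n),
        if (length(neg) == n) neg else sample(neg, n)
      )
      m <- rankMetrics(scores[take], labels[take])
      auroc[p] <- m[["auroc"]]
      auprc[p] <- m[["auprc"]]
    }
  })
  new("BenchmarkResult",
    aurocSamples = auroc, auprcSamples = auprc,
    nPositives = length(pos), nNegatives = length(neg),
    seed = as.integer(seed)
  )
}

#' Global downsampled perturbation benchmark
#'
#' Each scored (experiment, TF) entry is multiplied by the perturbation
#' direction (knockdown -1, overexpression +1) so that a correctly
#' recovered perturbed TF always scores high, and the matrix is flattened
#' into one score vector with label 1 for the perturbed TF of each
#' experiment. Experiments whose perturbed TF was not scored are dropped.
#' Per permutation, min(#positives, #negatives) items are drawn without
#' replacement from each class and tie-aware AUROC / average-precision
#' AUPRC are computed; the result holds all permutation samples.
#'
#' @param activities an [ActivityMatrix-class].
#' @param experiments the list of [PerturbationExperiment-class] objects
#'   the matrix was inferred from.
#' @param nPerm number of downsampling permutations (default 1000).
#' @param seed integer seed; identical seed and inputs give an identical
#'   result.
#' @return A [BenchmarkResult-class].
#' @export
globalBenchmark <- function(activities, experiments, nPerm = 1000L,
                            seed = 1L) {
  flat <- .flattenScores(activities, experiments)
  .downsampledMetrics(flat$score, flat$label, nPerm, seed)
}

#' Per-TF downsampled benchmark
#'
#' For each TF perturbed in at least \code{minExperiments} retained
#' experiments, the benchmark is restricted to that TF's sign-corrected
#' column: positives are the experiments in which the TF itself was
#' perturbed, negatives all others where it was scored. The same balanced
#' downsampling machinery as [globalBenchmark()] applies.
#'
#' @param activities an [ActivityMatrix-class].
#' @param experiments list of [PerturbationExperiment-class] objects.
#' @param minExperiments minimum perturbation experiments per evaluated TF
#'   (default 5).
#' @param nPerm,seed as in [globalBenchmark()].
#' @return named list of [BenchmarkResult-class], one per evaluated TF;
#'   empty (with a warning) when no TF qualifies.
#' @export
perTfBenchmark <- function(activities, experiments, minExperiments = 5L,
                           nPerm = 1000L, seed = 1L) {
  flat <- .flattenScores(activities, experiments)
  perturbedBy <- table(flat$tf[flat$label == 1L])
  tfs <- names(perturbedBy)[perturbedBy >= minExperiments]
  if (!length(tfs)) {
    warning("no TF is perturbed in enough experiments")
    return(setNames(list(), character()))
  }
  res <- lapply(seq_along(tfs), function(k) {
    sub <- flat[flat$tf == tfs[k], , drop = FALSE]
    .downsampledMetrics(sub$score, sub$label, nPerm, seed + k - 1L)
  })
  setNames(res, tfs)
}

#' Degree-preserving network permutation
#'
#' The no-biology baseline: the multiset of (target, sign) pairs is
#' shuffled jointly against the fixed regulator column, so per-TF edge
#' counts are preserved while target identity and sign lose any relation
#' to the TF. Duplicate (tf, target) collisions created by the shuffle are
#' resolved by re-drawing the colliding assignments among themselves (with
#' a final deterministic swap pass for stragglers).
#'
#' @param network a non-empty [RegulonNetwork-class].
#' @param seed integer seed; same seed gives the identical permuted
#'   network.
#' @return A [RegulonNetwork-class] with provenance \code{"permuted"}.
#' @export
permuteNetwork <- function(network, seed = 1L) {
  ed <- regulonEdges(network)
  if (!nrow(ed)) stop("cannot permute an empty network")
  n <- nrow(ed)
  withr::with_seed(seed, {
    perm <- sample.int(n)
    # random-transposition walk: each colliding assignment is swapped with
    # a uniformly drawn partner until no (tf, target) pair repeats
    for (iter in seq_len(10000L)) {
      key <- paste(ed$tf, ed$target[perm], sep = "\r")
      dup <- which(duplicated(key))
      if (!length(dup)) break
      for (i in dup) {
        j <- sample.int(n, 1L)
        tmp <- perm[i]
        perm[i] <- perm[j]
        perm[j] <- tmp
      }
    }
    if (anyDuplicated(paste(ed$tf, ed$target[perm], sep = "\r"))) {
      stop("could not resolve duplicate edges while permuting the network")
    }
  })
  RegulonNetwork(
    data.frame(
      tf = ed$tf, target = ed$target[perm], sign = ed$sign[perm],
      weight = ed$weight[perm], provenance = "permuted",
      stringsAsFactors = FALSE
    ),
    metadata = c(network@metadata, list(permuted_seed = seed))
  )
}

#' Size-bias diagnostics
#'
#' Two checks that network performance is not an artefact of regulon size:
#' per experiment, the Pearson correlation between the absolute activity
#' scores and the number of measured targets behind them (summarized by
#' the mean over experiments); and a two-sided two-sample t statistic
#' comparing the total target counts of TFs that appear in the benchmark
#' against those that do not.
#'
#' @param activities an [ActivityMatrix-class].
#' @param network the [RegulonNetwork-class] the activities came from.
#' @param benchmarkTfs character vector of TFs covered by the benchmark.
#' @return list with \code{mean_correlation},
#'   \code{per_experiment_correlations} (named numeric; experiments with
#'   constant |activity| are skipped with a warning) and
#'   \code{target_count_test} (htest from [stats::t.test()], or NULL when
#'   one group is too small).
#' @export
sizeBias <- function(activities, network, benchmarkTfs) {
  sc <- activityScores(activities)
  nt <- targetCounts(activities)
  cors <- rep(NA_real_, nrow(sc))
  names(cors) <- rownames(sc)
  for (i in seq_len(nrow(sc))) {
    ok <- !is.na(sc[i, ])
    if (sum(ok) < 3L) next
    a <- abs(sc[i, ok])
    k <- nt[i, ok]
    if (sd(a) == 0 || sd(k) == 0) {
      warning(sprintf(
        "experiment %s: constant values, correlation undefined",
        rownames(sc)[i]
      ))
      next
    }
    cors[i] <- cor(a, k)
  }
  degree <- table(regulonEdges(network)$tf)
  inBench <- names(degree) %in% benchmarkTfs
  tt <- NULL
  if (sum(inBench) >= 2L && sum(!inBench) >= 2L) {
    tt <- stats::t.test(
      as.integer(degree[inBench]), as.integer(degree[!inBench])
    )
  }
  list(
    mean_correlation = mean(cors, na.rm = TRUE),
    per_experiment_correlations = cors,
    target_count_test = tt
  )
}
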