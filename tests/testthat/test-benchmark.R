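test_that("rank metrics reproduce the hand-derived examples", {
  m <- rankMetrics(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(unname(m), c(1, 1))
  m2 <- rankMetrics(c(0.9, 0.6, 0.4, 0.2), c(1, 0, 0, 1))
  expect_equal(m2[["auroc"]], 0.5)
  expect_equal(m2[["auprc"]], 0.75)
  # all-tied scores: every pair contributes 1/2
  expect_equal(rankMetrics(c(1, 1), c(1, 0))[["auroc"]], 0.5)
  expect_error(rankMetrics(1:3, c(1, 1, 1)), "one positive and one negative")
})

test_that("rank metrics match exhaustive enumeration over all labelings", {
  set.seed(13)
  scores <- c(0.9, 0.7, 0.7, 0.5, 0.31, 0.31, 0.31, 0.1)  # with ties
  n <- length(scores)
  for (mask in 1:(2^n - 2)) {
    labels <- as.integer(intToBits(mask)[1:n])
    m <- rankMetrics(scores, labels)
    expect_equal(m[["auroc"]], aurocOracle(scores, labels))
    expect_equal(m[["auprc"]], auprcOracle(scores, labels))
  }
  # and against pROC on tie-free random scores
  scores2 <- rnorm(40)
  labels2 <- rep(c(1, 0), 20)
  expect_equal(
    rankMetrics(scores2, labels2)[["auroc"]],
    as.numeric(pROC::auc(pROC::roc(labels2, scores2, quiet = TRUE,
                                   direction = "<")))
  )
})

test_that("ineffective knockdowns are filtered at the -1 boundary", {
  mk <- function(id, dir, logfc) {
    PerturbationExperiment(id, "TF1", dir,
                           setNames(rnorm(5), paste0("g", 1:5)), logfc)
  }
  exps <- list(
    mk("weak", -1L, -0.5),      # excluded: logFC > -1
    mk("boundary", -1L, -1.0),  # retained: boundary kept
    mk("strong", -1L, -1.2),    # retained
    mk("oe", 1L, NA)            # overexpression passes unfiltered
  )
  kept <- filterExperiments(exps)
  expect_equal(vapply(kept, function(e) e@id, character(1)),
               c("boundary", "strong", "oe"))
  noLogfc <- mk("nolfc", -1L, NA)
  expect_warning(out <- filterExperiments(list(noLogfc)), "lacks")
  expect_length(out, 0L)
})

makeBenchFixture <- function(scoreFor) {
  # 3 experiments x 3 TFs, all knockdowns; scoreFor(tf, exp) gives the raw
  # (pre-correction) activity
  tfs <- c("TF1", "TF2", "TF3")
  sc <- outer(tfs, tfs, Vectorize(function(pt, tf) scoreFor(tf, pt)))
  dimnames(sc) <- list(paste0("e_", tfs), tfs)
  act <- new("ActivityMatrix",
    scores = sc, pvalues = sc * 0 + 0.5,
    nTargets = matrix(5L, 3, 3, dimnames = dimnames(sc)),
    minTargets = 5L
  )
  exps <- lapply(tfs, function(pt) {
    PerturbationExperiment(paste0("e_", pt), pt, -1L,
                           setNames(rnorm(5), paste0("g", 1:5)), -2)
  })
  list(act = act, exps = exps)
}

test_that("a perfect predictor yields all-ones metric samples", {
  fx <- makeBenchFixture(function(tf, pt) if (tf == pt) -10 else 0)
  res <- globalBenchmark(fx$act, fx$exps, nPerm = 50, seed = 3)
  expect_equal(medianAuroc(res), 1)
  expect_equal(medianAuprc(res), 1)
  expect_true(all(res@aurocSamples == 1))
  expect_true(all(res@auprcSamples == 1))
})

test_that("balanced classes make every permutation the full-data value", {
  # flattening: per experiment the perturbed TF is positive. Build a 3x3
  # with one TF masked per row to get 3 positives / 3 negatives.
  sc <- matrix(c(3, 2.5, NA,  1.5, 2, NA,  0.5, NA, 1),
               nrow = 3, byrow = TRUE,
               dimnames = list(c("e_TF1", "e_TF2", "e_TF3"),
                               c("TF1", "TF2", "TF3")))
  act <- new("ActivityMatrix",
    scores = sc, pvalues = sc * 0 + 0.5,
    nTargets = matrix(5L, 3, 3, dimnames = dimnames(sc)),
    minTargets = 5L
  )
  exps <- lapply(c("TF1", "TF2", "TF3"), function(pt) {
    PerturbationExperiment(paste0("e_", pt), pt, 1L,
                           setNames(rnorm(5), paste0("g", 1:5)), NA)
  })
  # positives: 3, 2, 1; negatives: 2.5, 1.5, 0.5 -> 6 of 9 pairs correct
  res <- globalBenchmark(act, exps, nPerm = 25, seed = 9)
  expect_equal(unique(res@aurocSamples), 6 / 9)
  expect_equal(res@nPositives, 3L)
  expect_equal(res@nNegatives, 3L)
})

test_that("knockdown sign correction flips raw activities before ranking", {
  # perturbed TF has the most NEGATIVE raw activity (knockdown) -> after
  # correction it must rank on top
  fx <- makeBenchFixture(function(tf, pt) if (tf == pt) -3 else -1)
  res <- globalBenchmark(fx$act, fx$exps, nPerm = 10, seed = 1)
  expect_equal(medianAuroc(res), 1)
})

test_that("benchmark results are bit-identical under a fixed seed", {
  net <- simulateNetwork(8, 8, 0.3, nGenes = 60, seed = 4)
  exps <- simulateCompendium(net, effectSize = 1, noiseSd = 3, seed = 4)
  act <- inferActivities(exps, net)
  r1 <- globalBenchmark(act, exps, nPerm = 40, seed = 11)
  r2 <- globalBenchmark(act, exps, nPerm = 40, seed = 11)
  expect_identical(r1@aurocSamples, r2@aurocSamples)
  expect_identical(r1@auprcSamples, r2@auprcSamples)
  r3 <- globalBenchmark(act, exps, nPerm = 40, seed = 12)
  expect_false(identical(r1@aurocSamples, r3@aurocSamples))
})

test_that("experiments with an unscored perturbed TF are dropped", {
  sc <- matrix(c(1, 2, NA, 4), 2, 2,
               dimnames = list(c("e1", "e2"), c("TF1", "TF2")))
  act <- new("ActivityMatrix",
    scores = sc, pvalues = sc * 0 + 0.5,
    nTargets = matrix(c(5L, 5L, 0L, 5L), 2, 2, dimnames = dimnames(sc)),
    minTargets = 5L
  )
  exps <- list(
    PerturbationExperiment("e1", "TF2", 1L,
                           setNames(rnorm(5), paste0("g", 1:5)), NA),
    PerturbationExperiment("e2", "TF1", 1L,
                           setNames(rnorm(5), paste0("g", 1:5)), NA)
  )
  flat <- regulonbench:::.flattenScores(act, exps)
  # e1's perturbed TF2 is masked -> e1 dropped entirely, negatives included
  expect_false("e1" %in% flat$experiment)
  expect_equal(sort(flat$score), c(2, 4))
})

test_that("per-TF benchmark separates and respects the threshold", {
  tfs <- c("A", "B")
  ids <- paste0("e", 1:7)
  pert <- c("A", "A", "A", "A", "A", "B", "B")
  sc <- matrix(rnorm(14), 7, 2, dimnames = list(ids, tfs))
  # TF A: perturbed experiments score high (post-correction), others low
  sc[, "A"] <- c(5, 4, 6, 5, 7, 1, 2)
  act <- new("ActivityMatrix",
    scores = sc, pvalues = sc * 0 + 0.5,
    nTargets = matrix(5L, 7, 2, dimnames = dimnames(sc)),
    minTargets = 5L
  )
  exps <- lapply(1:7, function(i) {
    PerturbationExperiment(ids[i], pert[i], 1L,
                           setNames(rnorm(5), paste0("g", 1:5)), NA)
  })
  res <- perTfBenchmark(act, exps, minExperiments = 5, nPerm = 20, seed = 2)
  expect_equal(names(res), "A")        # B: 2 experiments < 5
  expect_equal(medianAuroc(res$A), 1)  # 5,4,6,5,7 all above 1,2
  expect_warning(
    empty <- perTfBenchmark(act, exps, minExperiments = 10, nPerm = 5,
                            seed = 2),
    "no TF"
  )
  expect_length(empty, 0L)
})

test_that("per-TF results match the pair-count oracle on interleaved scores", {
  ids <- paste0("e", 1:8)
  pert <- c(rep("A", 5), rep("B", 3))
  colA <- c(3, 1, 4, 2, 5, 2.5, 3.5, 0.5)
  sc <- cbind(A = colA, B = rnorm(8))
  rownames(sc) <- ids
  act <- new("ActivityMatrix",
    scores = sc, pvalues = sc * 0 + 0.5,
    nTargets = matrix(5L, 8, 2, dimnames = dimnames(sc)),
    minTargets = 5L
  )
  exps <- lapply(1:8, function(i) {
    PerturbationExperiment(ids[i], pert[i], 1L,
                           setNames(rnorm(5), paste0("g", 1:5)), NA)
  })
  res <- perTfBenchmark(act, exps, minExperiments = 5, nPerm = 200,
                        seed = 5)
  labels <- as.integer(pert == "A")
  # positives 5 > negatives 3: downsampling draws 3 of 5 positives, so the
  # samples must average to the oracle value over many permutations only
  # when classes are balanced; check the balanced sub-oracle instead by
  # exhausting all 3-positive subsets.
  subsets <- combn(which(labels == 1), 3)
  vals <- apply(subsets, 2, function(ss) {
    idx <- c(ss, which(labels == 0))
    aurocOracle(colA[idx], labels[idx])
  })
  expect_true(all(res$A@aurocSamples %in% vals))
  expect_equal(mean(res$A@aurocSamples), mean(vals), tolerance = 0.05)
})

test_that("network permutation preserves degrees and determinism", {
  net <- simulateNetwork(10, 12, 0.4, nGenes = 80, seed = 6)
  perm <- permuteNetwork(net, seed = 42)
  expect_equal(nEdges(perm), nEdges(net))
  expect_equal(table(regulonEdges(perm)$tf), table(regulonEdges(net)$tf))
  # the multiset of (target, sign) pairs is conserved
  expect_equal(
    sort(paste(regulonEdges(perm)$target, regulonEdges(perm)$sign)),
    sort(paste(regulonEdges(net)$target, regulonEdges(net)$sign))
  )
  expect_identical(regulonEdges(permuteNetwork(net, seed = 42)),
                   regulonEdges(perm))
  # no duplicate pairs after collision resolution
  expect_equal(anyDuplicated(paste(regulonEdges(perm)$tf,
                                   regulonEdges(perm)$target)), 0L)
})

test_that("size-bias diagnostics recover hand-set correlations", {
  # |activity| exactly proportional to target count -> r = 1 everywhere
  nt <- matrix(c(5L, 10L, 20L, 5L, 10L, 20L), 2, 3, byrow = TRUE,
               dimnames = list(c("e1", "e2"), c("A", "B", "C")))
  sc <- matrix(c(0.5, 1, 2, -0.5, -1, -2), 2, 3, byrow = TRUE,
               dimnames = dimnames(nt))
  act <- new("ActivityMatrix", scores = sc, pvalues = sc * 0 + 0.5,
             nTargets = nt, minTargets = 5L)
  net <- RegulonNetwork(data.frame(
    tf = rep(c("A", "B", "C", "D"), times = c(5, 10, 20, 2)),
    target = paste0("G", 1:37), sign = 1L
  ))
  sb <- sizeBias(act, net, benchmarkTfs = c("A", "B"))
  expect_equal(sb$mean_correlation, 1)
  expect_equal(unname(sb$per_experiment_correlations), c(1, 1))
  # hand-set second fixture against the closed-form Pearson formula
  sc2 <- matrix(c(1, -3, 2, 0.5, 2, -1), 2, 3, byrow = TRUE,
                dimnames = dimnames(nt))
  act2 <- new("ActivityMatrix", scores = sc2, pvalues = sc2 * 0 + 0.5,
              nTargets = nt, minTargets = 5L)
  sb2 <- sizeBias(act2, net, benchmarkTfs = c("A", "B"))
  expect_equal(unname(sb2$per_experiment_correlations[1]),
               cor(abs(sc2[1, ]), nt[1, ]))
  # constant |activity| rows are skipped with a warning
  sc3 <- matrix(c(1, -1, 1, 0.5, 2, -1), 2, 3, byrow = TRUE,
                dimnames = dimnames(nt))
  act3 <- new("ActivityMatrix", scores = sc3, pvalues = sc3 * 0 + 0.5,
              nTargets = nt, minTargets = 5L)
  expect_warning(sb3 <- sizeBias(act3, net, "A"), "constant")
  expect_true(is.na(sb3$per_experiment_correlations[1]))
})

test_that("|activity| uncorrelated with size stays near zero on nulls", {
  set.seed(99)
  n <- 400
  nt <- matrix(sample(5:50, n, replace = TRUE), 1, n,
               dimnames = list("e1", paste0("T", 1:n)))
  sc <- matrix(rnorm(n), 1, n, dimnames = dimnames(nt))
  act <- new("ActivityMatrix", scores = sc, pvalues = sc * 0 + 0.5,
             nTargets = nt, minTargets = 5L)
  net <- RegulonNetwork(data.frame(
    tf = "T1", target = paste0("G", 1:5), sign = 1L
  ))
  sb <- sizeBias(act, net, benchmarkTfs = character())
  expect_lt(abs(sb$mean_correlation), 3 / sqrt(n))
})
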