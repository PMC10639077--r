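test_that("PMID prevalence signs edges, ties fall through", {
  mk <- function(act, rep_) {
    list(pmids_activation = as.character(act),
         pmids_repression = as.character(rep_))
  }
  expect_equal(signFromPmids(mk(1:2, 3)), 1L)
  expect_equal(signFromPmids(mk(1, 2:3)), -1L)
  expect_true(is.na(signFromPmids(mk(1, 2))))       # 1-1 tie
  expect_true(is.na(signFromPmids(mk(NULL, NULL)))) # 0-0 tie
})

test_that("regulon-majority classification needs a strict majority", {
  expect_equal(classifyTfFromRegulon(c(1L, 1L, -1L)), "activator")
  expect_equal(classifyTfFromRegulon(c(-1L, -1L, 1L)), "repressor")
  expect_equal(classifyTfFromRegulon(c(1L, -1L)), "undetermined")
  expect_equal(classifyTfFromRegulon(integer()), "undetermined")
})

test_that("prior-knowledge votes agree or abstain", {
  mk <- function(go = "unknown", up = "unknown", krab = FALSE,
                 eff = "unknown") {
    list(go_role = go, uniprot_role = up, krab = krab, effector_role = eff)
  }
  expect_equal(
    classifyTfFromPrior(mk("activator", "activator", FALSE, "activator")),
    "activator"
  )
  expect_equal(classifyTfFromPrior(mk("activator", "repressor")),
               "undetermined")
  # a lone KRAB vote suffices: missing sources abstain, they do not veto
  expect_equal(classifyTfFromPrior(mk(krab = TRUE)), "repressor")
  expect_equal(classifyTfFromPrior(mk()), "undetermined")
  # KRAB disagreeing with an activator annotation blocks classification
  expect_equal(classifyTfFromPrior(mk("activator", krab = TRUE)),
               "undetermined")
})

test_that("the cascade assigns the forced sign and provenance per row", {
  agg <- dropUnreferenced(aggregateEvidence(cascadeFixture()))
  net <- assignMor(agg)
  ed <- regulonEdges(net)
  get <- function(tf, tg) ed[ed$tf == tf & ed$target == tg, ]

  expect_equal(get("TFA", "G1")[, c("sign", "provenance")],
               data.frame(sign = 1L, provenance = "pmid"),
               ignore_attr = TRUE)
  expect_equal(get("TFA", "G2")[, c("sign", "provenance")],
               data.frame(sign = -1L, provenance = "pmid"),
               ignore_attr = TRUE)
  # TFA G3 ties at PMID level and TFA's regulon majority also ties
  expect_equal(get("TFA", "G3")$provenance, "default")
  expect_equal(get("TFA", "G3")$sign, 1L)
  # TFB G3 has no mode PMIDs but its regulon majority is activating
  expect_equal(get("TFB", "G3")[, c("sign", "provenance")],
               data.frame(sign = 1L, provenance = "regulon_majority"),
               ignore_attr = TRUE)
  # TFC has nothing anywhere
  expect_equal(get("TFC", "G1")$provenance, "default")
  expect_equal(get("TFC", "G1")$sign, 1L)
  # cascade completeness: every interaction got exactly one sign
  expect_equal(nrow(ed), nrow(agg))
  expect_false(anyNA(ed$sign))
})

test_that("prior-knowledge stage slots in after the majority stage", {
  agg <- dropUnreferenced(aggregateEvidence(cascadeFixture()))
  cls <- TFClassification(
    classes = list(),
    priors = data.frame(
      symbol = "TFC", go_role = "repressor", uniprot_role = "unknown",
      krab = TRUE, effector_role = "unknown", stringsAsFactors = FALSE
    )
  )
  net <- assignMor(agg, cls,
                   strategy = c("pmid", "regulon_majority",
                                "prior_knowledge"))
  ed <- regulonEdges(net)
  expect_equal(ed$sign[ed$tf == "TFC"], -1L)
  expect_equal(ed$provenance[ed$tf == "TFC"], "prior_knowledge")
  # stage monotonicity: pmid-stage edges identical with or without it
  base <- regulonEdges(assignMor(agg))
  expect_equal(ed[ed$provenance == "pmid", ],
               base[base$provenance == "pmid", ])
})

test_that("flipping the default sign flips exactly the default edges", {
  agg <- dropUnreferenced(aggregateEvidence(cascadeFixture()))
  plus <- regulonEdges(assignMor(agg, defaultSign = 1L))
  minus <- regulonEdges(assignMor(agg, defaultSign = -1L))
  isDefault <- plus$provenance == "default"
  expect_true(any(isDefault))
  expect_equal(minus$sign[isDefault], -plus$sign[isDefault])
  expect_equal(minus$sign[!isDefault], plus$sign[!isDefault])
})

test_that("invalid cascade configurations error", {
  agg <- dropUnreferenced(aggregateEvidence(cascadeFixture()))
  expect_error(assignMor(agg, strategy = "votes"), "unknown cascade stage")
  expect_error(assignMor(agg, strategy = character(), defaultSign = NA),
               "default")
})

test_that("network summaries match hand counts", {
  net <- RegulonNetwork(data.frame(
    tf = c("A", "A", "A", "B", "B", "C", "C", "C", "C", "C"),
    target = paste0("G", 1:10),
    sign = c(1L, 1L, -1L, 1L, 1L, -1L, -1L, -1L, -1L, 1L),
    provenance = c(rep("pmid", 4), rep("regulon_majority", 3),
                   rep("default", 3))
  ))
  s <- summarizeNetwork(net)
  expect_equal(s$n_tfs, 3L)
  expect_equal(s$n_edges, 10L)
  expect_equal(s$frac_activating, 5 / 10)
  expect_equal(s$frac_repressing, 5 / 10)
  expect_equal(s$frac_activating + s$frac_repressing, 1)
  # A dual, B pure activator, C dual
  expect_equal(unname(s$tf_role_fractions["dual"]), 2 / 3)
  expect_equal(unname(s$tf_role_fractions["pure_activator"]), 1 / 3)
  expect_equal(sum(s$tf_role_fractions), 1)
  expect_equal(sum(s$provenance_counts), 10L)
  expect_equal(unname(s$provenance_counts["pmid"]), 4L)

  one <- RegulonNetwork(data.frame(
    tf = "A", target = c("G1", "G2", "G3"), sign = c(1L, 1L, -1L)
  ))
  s1 <- summarizeNetwork(one)
  expect_equal(unname(s1$tf_role_fractions["dual"]), 1)
  expect_equal(s1$frac_activating, 2 / 3)

  expect_error(summarizeNetwork(RegulonNetwork(data.frame(
    tf = character(), target = character(), sign = integer()
  ))), "empty")
})

test_that("noiseless synthetic evidence reproduces the true signs", {
  truth <- simulateNetwork(8, 12, repressorFraction = 0.4, nGenes = 60,
                           seed = 3)
  ev <- simulateEvidence(truth, signErrorRate = 0,
                         unreferencedFraction = 0, seed = 3)
  built <- assignMor(dropUnreferenced(aggregateEvidence(ev)))
  tEd <- regulonEdges(truth)
  bEd <- regulonEdges(built)
  m <- match(paste(tEd$tf, tEd$target), paste(bEd$tf, bEd$target))
  expect_false(anyNA(m))
  expect_equal(bEd$sign[m], tEd$sign)
  expect_true(all(bEd$provenance == "pmid"))
})
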