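# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation so they stay independent of the
# package's vectorized implementations.

# AUROC by explicit pair counting: every (positive, negative) pair
# contributes 1 if the positive scores higher, 1/2 on a tie.
aurocOracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Average precision by literal rank walking (descending scores, stable
# tie order by input position).
auprcOracle <- function(scores, labels) {
  ord <- order(-scores, seq_along(scores))
  lab <- labels[ord]
  precAtPos <- c()
  seen <- 0
  for (i in seq_along(lab)) {
    if (lab[i] == 1) {
      seen <- seen + 1
      precAtPos <- c(precAtPos, seen / i)
    }
  }
  mean(precAtPos)
}

# Simple-regression t-value via stats::lm, the independent OLS oracle.
ulmOracle <- function(y, x) {
  fit <- summary(stats::lm(y ~ x))
  unname(fit$coefficients["x", "t value"])
}

# A tiny hand-checkable evidence fixture exercising every cascade branch.
cascadeFixture <- function() {
  rbind(
    # PMID prevalence: 2 activation vs 1 repression -> +1 via pmid
    evidenceRecords("TFA", "G1", "dbA", list(c("1", "2")), "activation"),
    evidenceRecords("TFA", "G1", "dbB", list("3"), "repression"),
    # prevalence repression -> -1 via pmid
    evidenceRecords("TFA", "G2", "dbA", list(c("4", "5")), "repression"),
    evidenceRecords("TFA", "G2", "dbB", list("6"), "activation"),
    # tie 1-1 -> falls to regulon majority; TFA has +1 and -1 pmid edges
    # -> tie again -> default +1
    evidenceRecords("TFA", "G3", "dbA", list("7"), "activation"),
    evidenceRecords("TFA", "G3", "dbB", list("8"), "repression"),
    # TFB: two pmid-signed activating edges, one unknown-only edge that
    # should resolve via regulon majority -> +1
    evidenceRecords("TFB", "G1", "dbA", list("9"), "activation"),
    evidenceRecords("TFB", "G2", "dbA", list("10"), "activation"),
    evidenceRecords("TFB", "G3", "dbA", list("11"), "unknown"),
    # TFC: no mode information at all -> default
    evidenceRecords("TFC", "G1", "dbB", list("12"), "unknown")
  )
}

makeTinyNetwork <- function() {
  RegulonNetwork(data.frame(
    tf = rep(c("TF1", "TF2"), each = 3),
    target = c("G1", "G2", "G3", "G2", "G3", "G4"),
    sign = c(1L, 1L, -1L, 1L, -1L, 1L)
  ))
}
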