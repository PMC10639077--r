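---
title: "Building and benchmarking signed TF regulons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and benchmarking signed TF regulons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonbench)
```

## The problem

Transcription factors (TFs) steer gene expression programmes, and a TF's
activity in a sample can be estimated from the expression of its target
genes — its *regulon* — provided the regulon is reliable and each edge
carries a correct mode of regulation (MoR): activating (+1) or repressing
(−1). Literature-curated resources provide edges of high precision but
disagree on coverage, overlap in their underlying publications, and often
omit the sign. This package implements a complete, reproducible path from
heterogeneous per-resource evidence tables to a signed network, from the
network to TF activity scores, and from activity scores to a quantitative
benchmark against TF-perturbation experiments.

## Evidence model

The atomic observation is an *evidence record*: one resource asserting one
TF→gene link, with a (possibly empty) set of PubMed identifiers and a
per-record MoR annotation (`activation`, `repression`, `unknown`).
Aggregation collapses records into unique (TF, target) interactions under
two rules:

* **A PMID counts once per interaction.** Databases copy from each other;
  deduplicating by PMID across resources prevents double counting of the
  same underlying publication.
* **Dual-mode PMIDs count twice.** In the infrequent case where the same
  PMID is curated as activating in one database and repressing in another,
  it enters both mode-evidence sets — neither curation is discarded.

Records annotated `unknown` support the interaction's existence (its PMID
pool) but abstain from the sign. Interactions whose pooled PMID set is
empty are removed: an edge no publication supports is not trusted.

Dimeric regulators need special handling. AP1 and NFKB are routinely named
in the literature by the dimer rather than the subunits, so evidence
recorded under a member (JUN/FOS-family, NFKB subunits) for some target is
also attributed to the complex for that target and vice versa, as a
bidirectional PMID-set union per target. Both the member edge and the
complex edge are kept. The member lists ship as an editable map
(`defaultComplexMap()`); the exact Jun/Fos and NFKB membership is a
pragmatic default, not a canonical gene set, and can be overridden.
Symbol updating is delegated to a user-supplied alias map rather than a
live nomenclature service, keeping builds reproducible and offline.

Regulators are then restricted to symbols classified as DNA-binding
(dbTF), co-regulatory (coTF) or general-initiation (GTF) factors in a
static snapshot file; membership in any one class suffices. Complex names
cannot appear in gene-symbol class lists, so they pass through an explicit
whitelist. Targets are never filtered.

## The sign-assignment cascade

Each interaction receives its sign from the first stage that resolves it:

1. **PMID prevalence** — the mode with strictly more PMIDs wins. A tie
   (including 0–0) resolves nothing; prevalence gives no basis for picking
   a winner, so ties fall through.
2. **Regulon majority** — a TF whose PMID-signed edges are mostly
   activating is treated as an activator and its unresolved edges signed
   +1 (symmetrically for repressors). The majority is always computed
   over the PMID-stage results on the same input, so removing a later
   stage can never change an earlier stage's output. At least one
   PMID-signed edge is required; ties fall through.
3. **Prior knowledge** (optional) — a TF-level vote from the GO-derived
   role, the UniProt-keyword role, the effector-domain role, and a
   repressor vote when a KRAB domain is present. The TF is classified only
   when at least one vote exists and all votes agree. Missing sources
   abstain rather than veto — a veto reading would make TF-level
   classification nearly impossible since few TFs are annotated by all
   four sources.
4. **Default** — remaining edges are signed with `defaultSign`
   (activating by default, matching the empirical predominance of
   activating edges in curated resources).

The published default cascade is `c("pmid", "regulon_majority")` with an
activating default. The prior-knowledge stage is fully implemented but
excluded from that default because blanket TF-level signs degrade
perturbation-benchmark performance — many TFs act in both directions, and
edge-level evidence beats TF-level generalization. Complex regulators
participate in the regulon-majority stage exactly like ordinary TFs; the
alternative (excluding them) has no principled basis and is noted here as
a deliberate choice.

Every edge records its provenance (`pmid`, `regulon_majority`,
`prior_knowledge`, `default`), and `summarizeNetwork()` reports edge- and
TF-level composition:

```{r cascade-demo}
agg <- dropUnreferenced(aggregateEvidence(rbind(
  evidenceRecords("TFA", "G1", "dbA", list(c("1", "2")), "activation"),
  evidenceRecords("TFA", "G1", "dbB", list("3"), "repression"),
  evidenceRecords("TFA", "G2", "dbA", list("4"), "activation"),
  evidenceRecords("TFA", "G3", "dbB", list("5"), "unknown")
)))
net <- assignMor(agg)
regulonEdges(net)
```

## Activity inference: the univariate linear model

For one experiment's gene-level signature $y$ (logFC, t-values, or
normalized expression) and one TF, the predictor $x$ is defined over *all*
measured genes: $x_g = \mathrm{sign} \times \mathrm{weight}$ if $g$ is a
target of the TF, else $0$. Ordinary least squares of $y$ on $x$ with an
intercept gives the activity as the slope t-value
$t = \hat\beta / \mathrm{SE}(\hat\beta)$ on $n - 2$ degrees of freedom.
Regressing the whole signature (rather than only the targets) is what
makes the score a *contrast* of the regulon against the transcriptome-wide
background; the non-target zeros anchor the baseline.

Rules and edge cases:

* The network is first filtered to genes measured in the experiment, and
  only TFs with at least `minTargets = 5` measured targets are scored —
  below that the slope estimate is dominated by noise.
* t-values are invariant under affine rescaling $y \to a y + b$ ($a > 0$),
  so signatures on different scales are comparable.
* Duplicate gene rows are averaged with a warning (rejecting them would
  make the common case of collapsed probe sets an error); non-finite
  values are dropped per experiment.
* A perfectly fit signature (zero residual variance) gives a signed
  infinite activity with a warning; a constant predictor (the TF targets
  every measured gene, or none) leaves the TF unscored.

`inferActivities()` assembles per-experiment scores into an
experiments × TFs matrix with `NA` marking unscored entries and
lexicographic column order, so results are deterministic regardless of
input order.

Binding weights, when available, enter the predictor directly as
sign × weight. Raw motif scores are made comparable by a pseudocount
shift (+1 by default, applied uniformly to all scores) and division by
the group maximum, either per TF or per gene, giving weights in (0, 1]
with exactly one 1 per group. Low-weight edges can be pruned at a global
weight quantile (strictly-below removal, so a degenerate all-equal
distribution removes nothing).

## The perturbation benchmark

The premise: if a regulon is faithful, knocking a TF down should depress
its targets, and the inferred activity of *that* TF should stand out among
all scored TFs. The machinery:

* **Effectiveness filter.** Knockdowns where the perturbed TF's own logFC
  is greater than −1 are excluded (the perturbation likely failed); the
  boundary value −1 itself is retained, reading the exclusion rule
  strictly. Overexpression experiments pass unfiltered.
* **Sign correction and flattening.** Each activity is multiplied by the
  perturbation direction (knockdown −1, overexpression +1), then the
  matrix is flattened into one score vector labelled 1 at each
  experiment's perturbed TF. Experiments whose perturbed TF was not
  scored are dropped entirely rather than kept as pure negatives: an
  experiment the network cannot even attempt is not evidence against it.
* **Balanced downsampling.** Positives are vastly outnumbered, and AUPRC
  especially depends on class balance, so each of `nPerm = 1000`
  permutations draws min(#pos, #neg) items per class without replacement
  and computes both metrics; results are reported as distributions and
  summarized by medians. When classes are already balanced every
  permutation reproduces the full-data value exactly.
* **Metrics.** AUROC by pair counting with ties worth ½ (equivalently the
  rank-sum formula with average ranks); AUPRC as step-wise average
  precision with a deterministic tie order — average precision is used
  because trapezoidal PR interpolation is optimistically biased. The
  downsample count, replacement policy and AP estimator are deliberate
  implementation choices recorded here, not claims about any particular
  upstream tool's internals.
* **Per-TF variant.** For TFs perturbed in ≥ 5 experiments, the same
  machinery runs on that TF's column alone: positives are its own
  perturbation experiments.
* **Permuted baseline.** `permuteNetwork()` shuffles the multiset of
  (target, sign) pairs against the fixed TF column, preserving per-TF
  edge counts; collisions are resolved by randomly re-drawing the
  colliding assignments. Scoring with this network bounds what regulon
  *size structure alone* achieves.
* **Size bias.** Per experiment, the Pearson correlation between
  |activity| and the number of measured targets, averaged over
  experiments; plus a two-sample t-test comparing target counts of
  benchmark versus non-benchmark TFs. Both diagnose whether apparent
  performance merely tracks regulon size.

## What the synthetic generator emulates — and what it does not

`simulateNetwork()` draws, for each TF, a fixed number (or per-TF vector)
of distinct uniform targets and independent edge signs (repressing with
probability `repressorFraction`, default 0.3, near the repressing fraction
observed in curated collections). `simulateEvidence()` emulates
multi-resource curation: each edge owns a pool of unique PMIDs (3 by
default), each PMID flips its sign annotation independently with
probability `signErrorRate`, the flip travelling with the PMID so
resources that share it agree; 1–3 resources assert the edge, later ones
re-drawing pool members with probability 0.5 (cross-resource overlap); and
records lose their PMIDs with probability `unreferencedFraction`. With 3
PMIDs per edge and flip rate 0.1 the PMID stage's error is the exact
binomial majority-vote error $P(\geq 2 \text{ of } 3) = 0.028$, which the
tests verify empirically.

`simulatePerturbation()` produces knockdown signatures where each true
target shifts by direction × sign × `effectSize` (default 3) plus
Gaussian noise (`noiseSd`, default 0.5), non-targets are pure noise, and
the perturbed TF's own entry is −2 so a default knockdown passes the
effectiveness filter. The defaults — 20 TFs × 10 targets over 200 genes,
one knockdown each — keep every simulation in the test suite and the
acceptance script in the seconds range while leaving clear statistical
margins.

These generators capture the *statistical* structure the pipeline assumes:
additive effects, symmetric noise, independent sign errors, uniform
target sampling. They do not emulate correlated gene expression,
off-target and indirect effects, hub-biased degree distributions,
curation bias toward well-studied TFs, or platform-specific logFC
distributions. Passing tests therefore demonstrate correctness of the
machinery and sensible behaviour under the assumed noise model — not that
any particular real-world collection will reach a given AUROC.

## Numerical choices

* PMID prevalence and majorities use strict inequalities; all ties fall
  through (eventually to the default sign).
* The ulm is computed in closed form from sufficient statistics
  (equivalent to `lm()` to ~1e−15 relative error, verified against it in
  the tests) rather than per-TF model objects, keeping a full
  compendium × network scoring inside a second.
* Quantile pruning uses the default continuous sample quantile and
  removes weights strictly below it.
* All generators and the benchmark take explicit seeds and scope RNG
  state locally (`withr::with_seed`), so identical inputs and seed give
  bit-identical results and no global RNG state is disturbed.
* Derived seeds (per-experiment, per-TF) are small offsets of the master
  seed, keeping runs reproducible from a single integer.

## Limitations

Signs are assigned from literature evidence only, never learned from
expression data, and are context-free: a TF that activates a target in
one cell type and represses it in another gets a single consensus sign.
The prior-knowledge stage inherits the coverage and biases of GO/UniProt
annotation snapshots. The benchmark can only evaluate TFs present in both
the network and the perturbation compendium, and treats the perturbed TF
as the sole true positive, ignoring genuine downstream activity changes
of other TFs.
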