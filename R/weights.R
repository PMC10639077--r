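# Motif-binding weights: raw occupancy / best-match scores are shifted by a
# pseudocount and normalized by the group maximum so weights live in (0, 1].

#' Normalize raw binding scores into edge weights
#'
#' Each raw score is shifted by the pseudocount and divided by the maximum
#' shifted score of its group: the TF's targets (\code{per_tf}) or the
#' gene's regulators (\code{per_gene}). Exactly one weight per group equals
#' 1 and all weights lie in (0, 1].
#'
#' @param scores data.frame with columns \code{tf}, \code{target},
#'   \code{score} (finite, non-negative raw motif-binding scores).
#' @param pseudocount non-negative shift added to every score before
#'   normalization (default 1; 0 makes the operation idempotent on
#'   already-normalized weights).
#' @param mode \code{"per_tf"} or \code{"per_gene"}.
#' @return The input with a \code{weight} column appended.
#' @examples
#' normalizeWeights(data.frame(
#'   tf = "TF1", target = c("G1", "G2"), score = c(0, 4)
#' ))  # weights 0.2, 1.0
#' @export
normalizeWeights <- function(scores, pseudocount = 1,
                             mode = c("per_tf", "per_gene")) {
  mode <- match.arg(mode)
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  if (any(!is.finite(scores$score)) || any(scores$score < 0)) {
    stop("raw scores must be finite and non-negative")
  }
  shifted <- scores$score + pseudocount
  if (any(shifted <= 0)) {
    stop("shifted scores must be positive; increase the pseudocount")
  }
  grp <- if (mode == "per_tf") scores$tf else scores$target
  gmax <- tapply(shifted, grp, max)
  scores$weight <- shifted / as.numeric(gmax[grp])
  scores
}

#' Attach normalized weights to a signed network
#'
#' Multiplies each edge's unit weight by its normalized binding weight;
#' edges without a binding score keep weight 1.
#'
#' @param network a [RegulonNetwork-class].
#' @param weights data.frame with \code{tf}, \code{target}, \code{weight}
#'   (e.g. from [normalizeWeights()]).
#' @return The reweighted [RegulonNetwork-class].
#' @export
applyWeights <- function(network, weights) {
  ed <- regulonEdges(network)
  key <- paste(ed$tf, ed$target, sep = "\r")
  wkey <- paste(weights$tf, weights$target, sep = "\r")
  hit <- match(key, wkey)
  ed$weight[!is.na(hit)] <- weights$weight[hit[!is.na(hit)]]
  RegulonNetwork(ed, metadata = network@metadata)
}

#' Prune low-weight edges by global quantile
#'
#' Removes edges whose weight is strictly below the q-quantile of the
#' network-wide weight distribution. q = 0 is the identity; with all
#' weights equal nothing is removed (the strict inequality never fires).
#' The quantile is taken globally over all edges; the published pruning
#' levels are q in 0.1/0.2/0.3.
#'
#' @param network a weighted [RegulonNetwork-class].
#' @param q quantile in [0, 1).
#' @return The pruned [RegulonNetwork-class].
#' @export
pruneByQuantile <- function(network, q) {
  if (q < 0 || q >= 1) stop("q must lie in [0, 1)")
  ed <- regulonEdges(network)
  if (q == 0 || !nrow(ed)) return(network)
  cut <- as.numeric(quantile(ed$weight, q))
  RegulonNetwork(ed[!(ed$weight < cut), , drop = FALSE],
                 metadata = network@metadata)
}
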