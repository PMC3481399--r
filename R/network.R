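#' Expand a disease seed list over the interaction network
#'
#' Starting from the seed genes, collects every protein within `depth`
#' interaction hops and returns the induced subgraph on that node set.
#' Seeds absent from the network are kept as isolated nodes (reported
#' via a message) so that downstream steps can see the full seed list;
#' `depth = 0` gives the induced subgraph on the seeds alone.
#'
#' @param seeds a [SeedList-class] (or character vector of gene ids).
#' @param network a [WeightedNetwork-class].
#' @param depth non-negative integer number of hops (default 1).
#' @return A [WeightedNetwork-class] induced on the expanded node set.
#' @examples
#' net <- WeightedNetwork(data.frame(
#'   protein_a = c("a", "b", "c"), protein_b = c("b", "c", "d"),
#'   conf = c(0.9, 0.8, 0.7)))
#' numNodes(expandSubnetwork(SeedList("a"), net, depth = 2))
#' @export
expandSubnetwork <- function(seeds, network, depth = 1) {
  if (is.character(seeds)) seeds <- SeedList(seeds)
  stopifnot(is(seeds, "SeedList"), is(network, "WeightedNetwork"))
  if (!is.numeric(depth) || length(depth) != 1 || depth < 0 ||
      depth != round(depth))
    stop("depth must be a non-negative integer")
  genes <- seedGenes(seeds)
  if (length(genes) == 0) stop("empty seed list")
  present <- intersect(genes, networkNodes(network))
  absent <- setdiff(genes, networkNodes(network))
  if (length(absent) > 0)
    message(length(absent), " seed(s) absent from the network, ",
            "kept as isolated nodes")
  keep <- present
  if (depth > 0 && length(present) > 0 && numEdges(network) > 0) {
    g <- asIgraph(network)
    nb <- igraph::ego(g, order = depth, nodes = present)
    keep <- unique(c(present, unlist(lapply(nb, function(v) v$name))))
  }
  ed <- networkEdges(network)
  sel <- ed$protein_a %in% keep & ed$protein_b %in% keep
  WeightedNetwork(ed[sel, , drop = FALSE], nodes = c(keep, absent))
}

#' Network relevance score of a protein
#'
#' The disease relevance of protein p in a confidence-weighted
#' subnetwork is
#' \deqn{r_p = k \ln\Big(\sum_q \mathrm{conf}(p,q)\Big) -
#'       \ln\Big(\sum_q N(p,q)\Big)}
#' where the sums run over p's interaction partners q in the
#' subnetwork, conf(p,q) is the interaction confidence, N(p,q) = 1 per
#' partner (so the second sum is p's degree) and k is an empirical
#' constant, 2 by default.  Scores can be negative; with all
#' confidences equal to 1 the score reduces to `ln(degree)`.
#'
#' @param protein protein id (vectorised).
#' @param subnetwork a [WeightedNetwork-class].
#' @param k weight on the confidence term (default 2).
#' @return numeric vector of scores.
#' @examples
#' net <- WeightedNetwork(data.frame(protein_a = c("p", "p"),
#'   protein_b = c("q", "r"), conf = c(0.9, 0.8)))
#' relevanceScore("p", net)  # 2*log(1.7) - log(2)
#' @seealso [rankProteins()]
#' @export
relevanceScore <- function(protein, subnetwork, k = 2) {
  stopifnot(is(subnetwork, "WeightedNetwork"))
  ed <- networkEdges(subnetwork)
  vapply(as.character(protein), function(p) {
    inc <- ed$protein_a == p | ed$protein_b == p
    deg <- sum(inc)
    if (deg == 0)
      stop("protein '", p, "' has no incident edge in the subnetwork")
    k * log(sum(ed$conf[inc])) - log(deg)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Rank proteins by relevance score
#'
#' Computes [relevanceScore()] for every connected node and orders the
#' table by descending score, breaking ties lexicographically by
#' protein id.  Degree-zero nodes have no defined score (log of zero)
#' and are omitted with a warning.
#'
#' @param subnetwork a [WeightedNetwork-class] with at least one node.
#' @param k passed to [relevanceScore()].
#' @param seeds optional [SeedList-class] or character vector used to
#'   flag seed proteins in the output.
#' @return data.frame with columns `protein`, `r_p`, `is_seed`, ordered
#'   by decreasing `r_p`.
#' @export
rankProteins <- function(subnetwork, k = 2, seeds = NULL) {
  stopifnot(is(subnetwork, "WeightedNetwork"))
  if (numNodes(subnetwork) == 0) stop("empty subnetwork")
  ed <- networkEdges(subnetwork)
  connected <- intersect(networkNodes(subnetwork),
                         c(ed$protein_a, ed$protein_b))
  n_iso <- numNodes(subnetwork) - length(connected)
  if (n_iso > 0)
    warning(n_iso, " degree-zero node(s) omitted from ranking")
  if (is(seeds, "SeedList")) seeds <- seedGenes(seeds)
  if (length(connected) == 0)
    return(data.frame(protein = character(), r_p = numeric(),
                      is_seed = logical()))
  rp <- relevanceScore(connected, subnetwork, k = k)
  out <- data.frame(protein = connected, r_p = rp,
                    is_seed = connected %in% seeds)
  out <- out[order(-out$r_p, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}
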