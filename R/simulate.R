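#' Simulate a confidence-weighted interaction network
#'
#' Erdos-Renyi topology with interaction confidences drawn from a Beta
#' distribution (curated PPI confidence grades are left-skewed toward
#' high values, hence the default shape parameters 5 and 2).  Pure
#' function of its parameters and seed.
#'
#' @param n_nodes number of proteins (named P001, P002, ...).
#' @param edge_prob edge probability in (0, 1].
#' @param conf_shape Beta shape parameters, length 2.
#' @param seed optional integer seed.
#' @return A [WeightedNetwork-class].
#' @examples
#' numEdges(genNetwork(4, 1, seed = 1))  # complete graph: 6 edges
#' @export
genNetwork <- function(n_nodes, edge_prob, conf_shape = c(5, 2),
                       seed = NULL) {
  if (!is.numeric(edge_prob) || edge_prob <= 0 || edge_prob > 1)
    stop("edge_prob must lie in (0, 1]")
  if (n_nodes < 2) stop("need at least 2 nodes")
  ids <- sprintf("P%03d", seq_len(n_nodes))
  pairs <- utils::combn(ids, 2)
  withSeed(seed, {
    keep <- stats::runif(ncol(pairs)) < edge_prob
    conf <- stats::rbeta(sum(keep), conf_shape[1], conf_shape[2])
    # Beta support is open (0,1); guard the measure-zero boundary
    conf <- pmin(pmax(conf, .Machine$double.eps), 1)
    WeightedNetwork(data.frame(protein_a = pairs[1, keep],
                               protein_b = pairs[2, keep],
                               conf = conf),
                    nodes = ids)
  })
}

#' Simulate a retrieved/background corpus pair
#'
#' Generates two corpora of `n_docs_each` documents in which every
#' vocabulary term is present in each document independently at a
#' corpus-specific rate: `base_rate` in both corpora for non-enriched
#' terms, and the pair `(rate_net, rate_bg)` for terms listed in
#' `enriched_terms`.  Setting `rate_net = rate_bg` everywhere yields a
#' null configuration for type-I-error studies.
#'
#' @param n_docs_each documents per corpus.
#' @param vocab character vector of drug terms.
#' @param enriched_terms named list mapping a term to
#'   `c(rate_net, rate_bg)`; may be empty.
#' @param base_rate presence rate for all other terms, in [0, 1].
#' @param seed optional integer seed.
#' @return list with elements `retrieved` and `background`, both
#'   [Corpus-class].
#' @export
genCorpusPair <- function(n_docs_each, vocab, enriched_terms = list(),
                          base_rate = 0.1, seed = NULL) {
  vocab <- as.character(vocab)
  rates_net <- rates_bg <- rep(base_rate, length(vocab))
  names(rates_net) <- names(rates_bg) <- vocab
  for (term in names(enriched_terms)) {
    if (!term %in% vocab) stop("enriched term '", term, "' not in vocab")
    rr <- enriched_terms[[term]]
    rates_net[term] <- rr[1]
    rates_bg[term] <- rr[2]
  }
  if (any(c(rates_net, rates_bg) < 0) || any(c(rates_net, rates_bg) > 1))
    stop("term rates must lie in [0, 1]")
  draw <- function(rates, prefix) {
    m <- vapply(rates, function(r)
      stats::runif(n_docs_each) < r, logical(n_docs_each))
    m <- matrix(m, nrow = n_docs_each)
    terms <- apply(m, 1, function(row) vocab[row], simplify = FALSE)
    Corpus(sprintf("%s%05d", prefix, seq_len(n_docs_each)), terms,
           label = if (prefix == "NET") "retrieved" else "background")
  }
  withSeed(seed, list(retrieved = draw(rates_net, "NET"),
                      background = draw(rates_bg, "BG")))
}

#' Simulate per-abstract directionality evidence
#'
#' For every (drug, protein) pair, emits `n_records_per_pair` evidence
#' records carrying the pair's true direction with probability
#' `1 - flip_prob` and the opposite direction with probability
#' `flip_prob` (pairs with true direction 0 always emit direction 0).
#'
#' @param pairs data.frame with columns `drug` and `protein`.
#' @param true_direction integer vector (one per pair) in \{-1, 0, +1\}.
#' @param n_records_per_pair records per pair.
#' @param flip_prob noise rate, must be below 0.5 so the majority vote
#'   is consistent.
#' @param seed optional integer seed.
#' @return evidence data.frame as produced by [readEvidence()].
#' @export
genEvidence <- function(pairs, true_direction, n_records_per_pair,
                        flip_prob = 0, seed = NULL) {
  stopifnot(nrow(pairs) == length(true_direction))
  if (flip_prob < 0 || flip_prob >= 0.5)
    stop("flip_prob must lie in [0, 0.5)")
  if (!all(true_direction %in% c(-1L, 0L, 1L)))
    stop("true directions must be -1, 0 or +1")
  n <- nrow(pairs) * n_records_per_pair
  withSeed(seed, {
    dir0 <- rep(as.integer(true_direction), each = n_records_per_pair)
    flip <- stats::runif(n) < flip_prob
    dir <- ifelse(flip, -dir0, dir0)
    checkEvidence(data.frame(
      drug = rep(pairs$drug, each = n_records_per_pair),
      protein = rep(pairs$protein, each = n_records_per_pair),
      doc_id = sprintf("SIM%07d", seq_len(n)),
      direction = as.integer(dir),
      category = categoryFromDirection(dir),
      stringsAsFactors = FALSE))
  })
}

#' Simulate an expression-status profile
#'
#' Assigns exactly `round(frac_over * n)` genes the status over and
#' `round(frac_under * n)` genes under, chosen by sampling without
#' replacement; the remainder are unchanged.
#'
#' @param genes character vector of gene ids.
#' @param frac_over,frac_under fractions with
#'   `frac_over + frac_under <= 1`.
#' @param seed optional integer seed.
#' @return An [ExpressionProfile-class].
#' @export
genExpression <- function(genes, frac_over, frac_under, seed = NULL) {
  genes <- as.character(genes)
  n <- length(genes)
  if (frac_over < 0 || frac_under < 0 || frac_over + frac_under > 1)
    stop("fractions must be non-negative and sum to at most 1")
  n_over <- round(frac_over * n)
  n_under <- round(frac_under * n)
  withSeed(seed, {
    shuffled <- sample(genes)
    status <- rep("unchanged", n)
    names(status) <- shuffled
    if (n_over > 0) status[seq_len(n_over)] <- "over"
    if (n_under > 0) status[n_over + seq_len(n_under)] <- "under"
    ExpressionProfile(status[genes], genes = genes)
  })
}
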