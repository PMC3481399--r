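#' @import methods
NULL

EXPRESSION_STATES <- c("over", "under", "unchanged")
EFFECT_LABELS <- c("therapeutic", "toxic", "neutral", "ambiguous")
DIRECTION_LABELS <- c("only-up", "only-down", "primarily-up",
                      "primarily-down", "ambiguous")
EVIDENCE_CATEGORIES <- c("activation", "inhibition", "indirect",
                         "ambiguous", "unknown")
CORPUS_LABELS <- c("retrieved", "background")

#' Confidence-weighted undirected protein-protein interaction network
#'
#' A `WeightedNetwork` stores an undirected interaction graph as a
#' canonical edge table plus an explicit node set.  Each undirected pair
#' is stored exactly once (endpoints in lexicographic order), self-loops
#' are not representable, and every confidence lies in the half-open
#' interval (0, 1].  The node set always contains every edge endpoint and
#' may additionally hold isolated nodes (e.g. disease seed genes absent
#' from the interaction data).
#'
#' @slot edges data.frame with columns `protein_a`, `protein_b`
#'   (character) and `conf` (numeric in (0,1]); one row per undirected
#'   edge, `protein_a < protein_b`.
#' @slot nodes character vector of all node identifiers.
#'
#' @seealso [WeightedNetwork()], [readNetwork()], [expandSubnetwork()],
#'   [relevanceScore()]
#' @exportClass WeightedNetwork
setClass("WeightedNetwork",
         representation(edges = "data.frame", nodes = "character"))

setValidity("WeightedNetwork", function(object) {
  ed <- object@edges
  msgs <- character()
  need <- c("protein_a", "protein_b", "conf")
  if (!all(need %in% names(ed)))
    return(paste("edges must have columns", paste(need, collapse = ", ")))
  if (nrow(ed) > 0) {
    if (any(!nzchar(ed$protein_a)) || any(!nzchar(ed$protein_b)))
      msgs <- c(msgs, "protein ids must be non-empty strings")
    if (any(ed$protein_a == ed$protein_b))
      msgs <- c(msgs, "self-loops are not allowed")
    if (any(ed$protein_a > ed$protein_b))
      msgs <- c(msgs, "edges must be stored with protein_a < protein_b")
    if (anyDuplicated(paste(ed$protein_a, ed$protein_b, sep = "\r")))
      msgs <- c(msgs, "duplicate undirected edges")
    if (any(!is.finite(ed$conf)) || any(ed$conf <= 0) || any(ed$conf > 1))
      msgs <- c(msgs, "confidences must lie in (0, 1]")
    if (!all(c(ed$protein_a, ed$protein_b) %in% object@nodes))
      msgs <- c(msgs, "node set must contain every edge endpoint")
  }
  if (anyDuplicated(object@nodes))
    msgs <- c(msgs, "duplicated node ids")
  if (length(msgs)) msgs else TRUE
})

#' Construct a WeightedNetwork from an edge table
#'
#' Normalises an arbitrary edge list into the canonical undirected form:
#' endpoints are ordered lexicographically within each row, self-loops
#' are dropped with a warning, and duplicate undirected pairs are
#' collapsed keeping the maximum confidence.  Confidences outside (0, 1]
#' are an error, never clamped.
#'
#' @param edges data.frame with columns `protein_a`, `protein_b`, `conf`
#'   (extra columns are ignored).
#' @param nodes optional character vector of additional node ids to keep
#'   as isolated nodes; always unioned with the edge endpoints.
#' @return A [WeightedNetwork-class] object.
#' @examples
#' net <- WeightedNetwork(data.frame(protein_a = c("B", "A"),
#'                                   protein_b = c("A", "C"),
#'                                   conf = c(0.9, 0.8)))
#' numEdges(net)
#' @export
WeightedNetwork <- function(edges = data.frame(protein_a = character(),
                                               protein_b = character(),
                                               conf = numeric()),
                            nodes = character()) {
  edges <- as.data.frame(edges)[, c("protein_a", "protein_b", "conf")]
  edges$protein_a <- as.character(edges$protein_a)
  edges$protein_b <- as.character(edges$protein_b)
  edges$conf <- as.numeric(edges$conf)
  if (nrow(edges) > 0) {
    if (any(!is.finite(edges$conf)) ||
        any(edges$conf <= 0) || any(edges$conf > 1))
      stop("edge confidences must lie in (0, 1]")
    loop <- edges$protein_a == edges$protein_b
    if (any(loop)) {
      warning(sum(loop), " self-loop(s) dropped")
      edges <- edges[!loop, , drop = FALSE]
    }
    swap <- edges$protein_a > edges$protein_b
    tmp <- edges$protein_a[swap]
    edges$protein_a[swap] <- edges$protein_b[swap]
    edges$protein_b[swap] <- tmp
    # duplicate undirected pairs: keep max confidence
    key <- paste(edges$protein_a, edges$protein_b, sep = "\r")
    if (anyDuplicated(key)) {
      keep <- vapply(split(seq_len(nrow(edges)), key), function(i)
        i[which.max(edges$conf[i])], integer(1))
      edges <- edges[sort(unname(keep)), , drop = FALSE]
    }
    o <- order(edges$protein_a, edges$protein_b)
    edges <- edges[o, , drop = FALSE]
  }
  rownames(edges) <- NULL
  nodes <- sort(unique(c(as.character(nodes),
                         edges$protein_a, edges$protein_b)))
  new("WeightedNetwork", edges = edges, nodes = nodes)
}

#' Disease seed-gene list
#'
#' @slot disease character(1) disease name.
#' @slot genes character vector of unique protein/gene identifiers.
#' @seealso [SeedList()], [expandSubnetwork()]
#' @exportClass SeedList
setClass("SeedList",
         representation(disease = "character", genes = "character"))

setValidity("SeedList", function(object) {
  msgs <- character()
  if (length(object@genes) == 0)
    msgs <- c(msgs, "seed list must be non-empty")
  if (anyDuplicated(object@genes))
    msgs <- c(msgs, "seed gene ids must be unique")
  if (any(!nzchar(object@genes)))
    msgs <- c(msgs, "seed gene ids must be non-empty strings")
  if (length(object@disease) != 1)
    msgs <- c(msgs, "disease must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' @rdname SeedList-class
#' @param genes character vector of seed gene ids (duplicates removed,
#'   first occurrence order kept).
#' @param disease disease name.
#' @return A [SeedList-class] object.
#' @export
SeedList <- function(genes, disease = "disease") {
  new("SeedList", disease = as.character(disease),
      genes = unique(as.character(genes)))
}

#' Term-annotated abstract corpus
#'
#' A `Corpus` holds one record per document (PubMed-style abstract),
#' each annotated with the set of drug terms and protein identifiers it
#' mentions.  The text itself is never stored; enrichment works on term
#' presence only.  A corpus is labelled either `"retrieved"` (abstracts
#' pulled for disease-relevant proteins) or `"background"` (random
#' sample of the whole literature).
#'
#' @slot doc_ids character vector of unique document ids (PMID-like).
#' @slot drug_terms list of character vectors, one per document.
#' @slot protein_terms list of character vectors, one per document.
#' @slot label `"retrieved"` or `"background"`.
#' @seealso [Corpus()], [readCorpus()], [enrichDrugs()]
#' @exportClass Corpus
setClass("Corpus",
         representation(doc_ids = "character", drug_terms = "list",
                        protein_terms = "list", label = "character"))

setValidity("Corpus", function(object) {
  msgs <- character()
  n <- length(object@doc_ids)
  if (n == 0)
    msgs <- c(msgs, "corpus must contain at least one record")
  if (anyDuplicated(object@doc_ids))
    msgs <- c(msgs, "doc_ids must be unique within a corpus")
  if (length(object@drug_terms) != n || length(object@protein_terms) != n)
    msgs <- c(msgs, "term lists must match the number of documents")
  if (length(object@label) != 1 || !object@label %in% CORPUS_LABELS)
    msgs <- c(msgs, sprintf("label must be one of: %s",
                            paste(CORPUS_LABELS, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' @rdname Corpus-class
#' @param doc_ids character vector of document identifiers.
#' @param drug_terms list of character vectors (drug terms per document).
#' @param protein_terms list of character vectors (protein ids per
#'   document); defaults to empty sets.
#' @param label corpus label, `"retrieved"` or `"background"`.
#' @return A [Corpus-class] object.
#' @export
Corpus <- function(doc_ids, drug_terms,
                   protein_terms = rep(list(character()), length(doc_ids)),
                   label = "retrieved") {
  new("Corpus", doc_ids = as.character(doc_ids),
      drug_terms = lapply(drug_terms, as.character),
      protein_terms = lapply(protein_terms, as.character),
      label = label)
}

#' Per-gene differential expression status
#'
#' Maps gene/protein identifiers to one of `"over"`, `"under"` or
#' `"unchanged"` relative to the healthy reference.  Genes absent from
#' the profile are treated as `"unchanged"` by [geneStatus()], which is
#' how non-differential interaction partners enter the drug-effect
#' classification.
#'
#' @slot status named character vector with values in
#'   over/under/unchanged.
#' @seealso [ExpressionProfile()], [geneStatus()], [classifyEffect()]
#' @exportClass ExpressionProfile
setClass("ExpressionProfile", representation(status = "character"))

setValidity("ExpressionProfile", function(object) {
  msgs <- character()
  st <- object@status
  if (length(st) > 0) {
    if (is.null(names(st)) || any(!nzchar(names(st))))
      msgs <- c(msgs, "status vector must be named by gene id")
    if (anyDuplicated(names(st)))
      msgs <- c(msgs, "each gene may appear only once")
    if (!all(st %in% EXPRESSION_STATES))
      msgs <- c(msgs, sprintf("statuses must be one of: %s",
                              paste(EXPRESSION_STATES, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname ExpressionProfile-class
#' @param status named character vector of statuses, or unnamed vector
#'   with `genes` supplied.
#' @param genes optional gene ids naming `status`.
#' @return An [ExpressionProfile-class] object.
#' @export
ExpressionProfile <- function(status, genes = names(status)) {
  genes <- genes
  status <- as.character(status)
  names(status) <- genes
  new("ExpressionProfile", status = status)
}

#' Drug-effect assessment against an expression profile
#'
#' Result of [assessDrug()]: per-pair effect calls for one drug, the
#' effect counts, and the relevance-weighted net efficacy score
#' `net_score = sum(r_p | therapeutic) - sum(r_p | toxic)`.
#'
#' @slot drug character(1) drug term.
#' @slot pairs data.frame with columns `protein`, `r_p`, `direction`,
#'   `status`, `effect` (one row per annotated partner).
#' @slot counts named integer vector over
#'   therapeutic/toxic/neutral/ambiguous.
#' @slot net_score numeric(1).
#' @slot overall `"therapeutic"`, `"toxic"` or `"neutral"`.
#' @slot tau numeric(1) neutrality band used for the overall call.
#' @seealso [assessDrug()], [buildDrugSubnetwork()], [writeSubnetwork()]
#' @exportClass DrugEffectAssessment
setClass("DrugEffectAssessment",
         representation(drug = "character", pairs = "data.frame",
                        counts = "integer", net_score = "numeric",
                        overall = "character", tau = "numeric"))

setValidity("DrugEffectAssessment", function(object) {
  msgs <- character()
  if (!identical(sort(names(object@counts)), sort(EFFECT_LABELS)))
    msgs <- c(msgs, "counts must be named over the four effect labels")
  else if (sum(object@counts) != nrow(object@pairs))
    msgs <- c(msgs, "effect counts must sum to the number of pairs")
  if (!object@overall %in% c("therapeutic", "toxic", "neutral"))
    msgs <- c(msgs, "invalid overall call")
  if (length(msgs)) msgs else TRUE
})

#' Confusion-matrix performance metrics
#'
#' Sensitivity, specificity, positive predictive value, F-score
#' (harmonic mean of PPV and sensitivity) and accuracy for a predicted
#' set against a gold standard within a fixed universe, all on [0, 1].
#'
#' @slot sensitivity,specificity,ppv,f_score,acc numeric(1) in [0, 1].
#' @slot tp,fp,fn,tn numeric(1) cell counts of the underlying 2x2 table
#'   (NA when the metrics were supplied directly rather than computed).
#' @seealso [confusionMetrics()], [impliedPrevalenceAcc()]
#' @exportClass ConfusionMetrics
setClass("ConfusionMetrics",
         representation(sensitivity = "numeric", specificity = "numeric",
                        ppv = "numeric", f_score = "numeric",
                        acc = "numeric", tp = "numeric", fp = "numeric",
                        fn = "numeric", tn = "numeric"))

setValidity("ConfusionMetrics", function(object) {
  vals <- c(object@sensitivity, object@specificity, object@ppv,
            object@f_score, object@acc)
  if (any(is.na(vals)) || any(vals < 0) || any(vals > 1))
    "all metrics must lie in [0, 1]" else TRUE
})
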