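#' @rdname WeightedNetwork-class
setMethod("networkEdges", "WeightedNetwork", function(x) x@edges)

#' @rdname WeightedNetwork-class
setMethod("networkNodes", "WeightedNetwork", function(x) x@nodes)

#' @rdname WeightedNetwork-class
setMethod("numEdges", "WeightedNetwork", function(x) nrow(x@edges))

#' @rdname WeightedNetwork-class
setMethod("numNodes", "WeightedNetwork", function(x) length(x@nodes))

#' @rdname WeightedNetwork-class
setMethod("asIgraph", "WeightedNetwork", function(x) {
  g <- igraph::graph_from_data_frame(
    x@edges[, c("protein_a", "protein_b")],
    directed = FALSE, vertices = x@nodes)
  if (numEdges(x) > 0)
    igraph::E(g)$conf <- x@edges$conf
  g
})

setMethod("show", "WeightedNetwork", function(object) {
  cat("WeightedNetwork with", numNodes(object), "nodes and",
      numEdges(object), "edges\n")
  if (numEdges(object) > 0) {
    cat("  conf range: [", format(min(object@edges$conf), digits = 3),
        ", ", format(max(object@edges$conf), digits = 3), "]\n", sep = "")
  }
  iso <- sum(!object@nodes %in%
               c(object@edges$protein_a, object@edges$protein_b))
  if (iso > 0) cat("  isolated nodes:", iso, "\n")
})

#' @rdname SeedList-class
setMethod("seedGenes", "SeedList", function(x) x@genes)

#' @rdname SeedList-class
setMethod("diseaseName", "SeedList", function(x) x@disease)

setMethod("show", "SeedList", function(object) {
  cat("SeedList for '", object@disease, "': ", length(object@genes),
      " genes\n", sep = "")
})

#' @rdname Corpus-class
setMethod("length", "Corpus", function(x) length(x@doc_ids))

#' @rdname Corpus-class
setMethod("docIDs", "Corpus", function(x) x@doc_ids)

#' @rdname Corpus-class
setMethod("drugTerms", "Corpus", function(x) x@drug_terms)

#' @rdname Corpus-class
setMethod("proteinTerms", "Corpus", function(x) x@protein_terms)

#' @rdname Corpus-class
setMethod("corpusLabel", "Corpus", function(x) x@label)

setMethod("show", "Corpus", function(object) {
  cat("Corpus (", object@label, "): ", length(object@doc_ids),
      " documents, ", length(unique(unlist(object@drug_terms))),
      " distinct drug terms\n", sep = "")
})

#' @rdname ExpressionProfile-class
#' @param x,object an `ExpressionProfile`.
setMethod("length", "ExpressionProfile", function(x) length(x@status))

setMethod("geneStatus", "ExpressionProfile", function(x, genes) {
  out <- x@status[as.character(genes)]
  out[is.na(out)] <- "unchanged"
  names(out) <- genes
  out
})

setMethod("show", "ExpressionProfile", function(object) {
  tab <- table(factor(object@status, levels = EXPRESSION_STATES))
  cat("ExpressionProfile:", length(object@status), "genes (",
      paste(names(tab), as.integer(tab), collapse = ", "), ")\n")
})

#' @rdname DrugEffectAssessment-class
setMethod("effectPairs", "DrugEffectAssessment", function(x) x@pairs)

#' @rdname DrugEffectAssessment-class
setMethod("effectCounts", "DrugEffectAssessment", function(x) x@counts)

#' @rdname DrugEffectAssessment-class
setMethod("netScore", "DrugEffectAssessment", function(x) x@net_score)

#' @rdname DrugEffectAssessment-class
setMethod("overallEffect", "DrugEffectAssessment", function(x) x@overall)

setMethod("show", "DrugEffectAssessment", function(object) {
  cat("DrugEffectAssessment for", object@drug, "\n")
  cat("  pairs:", nrow(object@pairs), "(",
      paste(names(object@counts), object@counts, collapse = ", "), ")\n")
  cat("  net score:", format(object@net_score, digits = 6),
      "->", object@overall, "\n")
})

setMethod("show", "ConfusionMetrics", function(object) {
  cat("ConfusionMetrics\n")
  m <- c(sensitivity = object@sensitivity, specificity = object@specificity,
         ppv = object@ppv, f_score = object@f_score, acc = object@acc)
  for (nm in names(m))
    cat(sprintf("  %-12s %6.2f%%\n", nm, 100 * m[[nm]]))
  if (!is.na(object@tp))
    cat(sprintf("  (TP=%g FP=%g FN=%g TN=%g)\n",
                object@tp, object@fp, object@fn, object@tn))
})
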