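#' @rdname WeightedNetwork-class
#' @param x,object a `WeightedNetwork`.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname WeightedNetwork-class
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname WeightedNetwork-class
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname WeightedNetwork-class
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname WeightedNetwork-class
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname SeedList-class
#' @param x,object a `SeedList`.
#' @export
setGeneric("seedGenes", function(x) standardGeneric("seedGenes"))

#' @rdname SeedList-class
#' @export
setGeneric("diseaseName", function(x) standardGeneric("diseaseName"))

#' @rdname Corpus-class
#' @param x,object a `Corpus`.
#' @export
setGeneric("docIDs", function(x) standardGeneric("docIDs"))

#' @rdname Corpus-class
#' @export
setGeneric("drugTerms", function(x) standardGeneric("drugTerms"))

#' @rdname Corpus-class
#' @export
setGeneric("proteinTerms", function(x) standardGeneric("proteinTerms"))

#' @rdname Corpus-class
#' @export
setGeneric("corpusLabel", function(x) standardGeneric("corpusLabel"))

#' Status lookup in an expression profile
#'
#' @param x an [ExpressionProfile-class].
#' @param genes character vector of gene ids.
#' @return character vector of statuses; genes not present in the
#'   profile are reported as `"unchanged"`.
#' @examples
#' pr <- ExpressionProfile(c(TP53 = "over"))
#' geneStatus(pr, c("TP53", "MYC"))
#' @export
setGeneric("geneStatus", function(x, genes) standardGeneric("geneStatus"))

#' @rdname DrugEffectAssessment-class
#' @param x,object a `DrugEffectAssessment`.
#' @export
setGeneric("effectPairs", function(x) standardGeneric("effectPairs"))

#' @rdname DrugEffectAssessment-class
#' @export
setGeneric("effectCounts", function(x) standardGeneric("effectCounts"))

#' @rdname DrugEffectAssessment-class
#' @export
setGeneric("netScore", function(x) standardGeneric("netScore"))

#' @rdname DrugEffectAssessment-class
#' @export
setGeneric("overallEffect", function(x) standardGeneric("overallEffect"))
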