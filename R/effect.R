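#' Classify a drug-protein pair as therapeutic or toxic
#'
#' Implements the expression-reversal rule: a drug that pushes a
#' disease-perturbed gene back toward the healthy range acts
#' therapeutically, one that pushes it further acts toxically.
#' \itemize{
#'   \item therapeutic: activates (+1) an under-expressed gene, or
#'     inhibits (-1) an over-expressed gene
#'   \item toxic: activates an over-expressed gene, or inhibits an
#'     under-expressed gene
#'   \item ambiguous: direction 0 (missing directionality), any status
#'   \item neutral: directed effect on an unchanged gene
#' }
#'
#' @param direction integer vector in \{-1, 0, +1\}.
#' @param status character vector in over/under/unchanged (recycled
#'   against `direction`).
#' @return character vector of effect labels.
#' @examples
#' classifyEffect(-1, "over")   # therapeutic
#' classifyEffect(1, "over")    # toxic
#' classifyEffect(0, "over")    # ambiguous
#' @seealso [assessDrug()]
#' @export
classifyEffect <- function(direction, status) {
  direction <- as.integer(direction)
  status <- as.character(status)
  if (!all(direction %in% c(-1L, 0L, 1L)))
    stop("direction must be -1, 0 or +1")
  if (!all(status %in% EXPRESSION_STATES))
    stop("status must be over, under or unchanged")
  k <- max(length(direction), length(status))
  direction <- rep_len(direction, k)
  status <- rep_len(status, k)
  ifelse(direction == 0L, "ambiguous",
         ifelse(status == "unchanged", "neutral",
                ifelse((direction == 1L) == (status == "under"),
                       "therapeutic", "toxic")))
}

#' Assess a drug's net effect against an expression profile
#'
#' Classifies every annotated interaction partner of `drug` with
#' [classifyEffect()] and aggregates into a relevance-weighted net
#' efficacy score `net_score = sum(r_p | therapeutic) -
#' sum(r_p | toxic)`.  The overall call is therapeutic when
#' `net_score > tau`, toxic when `net_score < -tau`, neutral otherwise.
#' Proteins missing from the profile count as unchanged; proteins
#' missing from `scores` get `r_p = 0` with a warning.
#'
#' @param drug drug term to assess.
#' @param annotations directionality annotation data.frame (see
#'   [aggregateAll()]); rows for other drugs are ignored.
#' @param profile an [ExpressionProfile-class].
#' @param scores named numeric vector of relevance scores, or a
#'   data.frame with `protein` and `r_p` columns (e.g. from
#'   [rankProteins()]).
#' @param tau non-negative neutrality band for the overall call
#'   (default 0).
#' @return A [DrugEffectAssessment-class].
#' @examples
#' ann <- data.frame(drug = "D", protein = c("A", "B"),
#'                   direction = c(-1L, 1L))
#' pr <- ExpressionProfile(c(A = "over", B = "under"))
#' assessDrug("D", ann, pr, c(A = 2, B = 1))
#' @export
assessDrug <- function(drug, annotations, profile, scores, tau = 0) {
  stopifnot(is(profile, "ExpressionProfile"), tau >= 0)
  ann <- annotations[annotations$drug == drug, , drop = FALSE]
  if (nrow(ann) == 0) stop("no annotations for drug '", drug, "'")
  if (is.data.frame(scores)) {
    sc <- scores$r_p
    names(sc) <- scores$protein
    scores <- sc
  }
  r_p <- unname(scores[ann$protein])
  if (anyNA(r_p)) {
    warning(sum(is.na(r_p)), " protein(s) without relevance score, ",
            "using r_p = 0")
    r_p[is.na(r_p)] <- 0
  }
  status <- unname(geneStatus(profile, ann$protein))
  effect <- classifyEffect(ann$direction, status)
  pairs <- data.frame(protein = ann$protein, r_p = r_p,
                      direction = as.integer(ann$direction),
                      status = status, effect = effect,
                      stringsAsFactors = FALSE)
  counts <- vapply(EFFECT_LABELS, function(e) sum(effect == e),
                   integer(1))
  net <- sum(pairs$r_p[pairs$effect == "therapeutic"]) -
    sum(pairs$r_p[pairs$effect == "toxic"])
  overall <- if (net > tau) "therapeutic"
             else if (net < -tau) "toxic" else "neutral"
  new("DrugEffectAssessment", drug = as.character(drug), pairs = pairs,
      counts = counts, net_score = net, overall = overall,
      tau = as.numeric(tau))
}

#' Build the drug-target star subnetwork
#'
#' Constructs the attributed graph behind [writeSubnetwork()]: a star
#' with the drug at the centre (`shape = "hexagon"`) and one node per
#' annotated protein regardless of its effect call.  Protein nodes
#' carry `rp` (drawn proportional to relevance), `status` and a
#' `color` (over = red, under = green, unchanged = grey); each edge
#' carries its `direction`, `effect` and `color` (activation = red,
#' inhibition = green, unknown = grey).
#'
#' @param assessment a non-empty [DrugEffectAssessment-class].
#' @return an igraph graph.
#' @export
buildDrugSubnetwork <- function(assessment) {
  stopifnot(is(assessment, "DrugEffectAssessment"))
  pr <- effectPairs(assessment)
  if (nrow(pr) == 0) stop("assessment has no annotated pairs")
  drug <- assessment@drug
  status_col <- c(over = "red", under = "green", unchanged = "grey")
  dir_col <- function(d) ifelse(d == 1L, "red",
                                ifelse(d == -1L, "green", "grey"))
  vertices <- data.frame(
    name = c(drug, pr$protein),
    type = c("drug", rep("protein", nrow(pr))),
    shape = c("hexagon", rep("circle", nrow(pr))),
    rp = c(NA_real_, pr$r_p),
    status = c(NA_character_, pr$status),
    color = c("white", unname(status_col[pr$status])),
    stringsAsFactors = FALSE)
  edges <- data.frame(from = drug, to = pr$protein,
                      direction = pr$direction, effect = pr$effect,
                      color = dir_col(pr$direction),
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = vertices)
}
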