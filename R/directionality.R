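#' Aggregate directionality evidence for one drug-protein pair
#'
#' Majority vote over the per-abstract evidence records of a single
#' drug-protein pair.  Records with direction +1 (activation) and -1
#' (inhibition) vote; indirect/ambiguous/unknown records (direction 0)
#' do not vote and are tallied as `n_other`.  The aggregated direction
#' is the sign of `n_up - n_down`, and the curation label is
#' \itemize{
#'   \item `only-up`: up-votes only (`n_up > 0`, `n_down = 0`)
#'   \item `only-down`: down-votes only
#'   \item `primarily-up`: strict majority up (`n_up > n_down > 0`)
#'   \item `primarily-down`: strict majority down
#'   \item `ambiguous`: tied votes (including no votes at all)
#' }
#'
#' @param records evidence data.frame (see [readEvidence()]) whose rows
#'   all share one (drug, protein) pair; non-empty.
#' @return one-row data.frame with columns `drug`, `protein`,
#'   `direction`, `n_up`, `n_down`, `n_other`, `label`.
#' @seealso [aggregateAll()], [directionalitySummary()]
#' @export
aggregateDirection <- function(records) {
  records <- checkEvidence(records)
  if (nrow(records) == 0) stop("no evidence records supplied")
  if (length(unique(records$drug)) != 1 ||
      length(unique(records$protein)) != 1)
    stop("records must all belong to one (drug, protein) pair")
  n_up <- sum(records$direction == 1L)
  n_down <- sum(records$direction == -1L)
  n_other <- sum(records$direction == 0L)
  direction <- sign(n_up - n_down)
  label <- if (n_up > 0 && n_down == 0) "only-up"
  else if (n_down > 0 && n_up == 0) "only-down"
  else if (n_up > n_down) "primarily-up"
  else if (n_down > n_up) "primarily-down"
  else "ambiguous"
  data.frame(drug = records$drug[1], protein = records$protein[1],
             direction = as.integer(direction), n_up = n_up,
             n_down = n_down, n_other = n_other, label = label,
             stringsAsFactors = FALSE)
}

#' Aggregate all evidence records per drug-protein pair
#'
#' Groups an evidence table by (drug, protein) and applies
#' [aggregateDirection()] to each group.  The result is independent of
#' the input record order; pairs whose records are all indirect/
#' ambiguous/unknown aggregate to direction 0 with label `ambiguous`.
#'
#' @param records evidence data.frame (possibly empty).
#' @return data.frame with one row per distinct pair, ordered by drug
#'   then protein.
#' @export
aggregateAll <- function(records) {
  records <- checkEvidence(records)
  if (nrow(records) == 0)
    return(data.frame(drug = character(), protein = character(),
                      direction = integer(), n_up = integer(),
                      n_down = integer(), n_other = integer(),
                      label = character(), stringsAsFactors = FALSE))
  key <- paste(records$drug, records$protein, sep = "\r")
  parts <- split(seq_len(nrow(records)), key)
  out <- do.call(rbind, lapply(parts, function(i)
    aggregateDirection(records[i, , drop = FALSE])))
  out <- out[order(out$drug, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Histogram of directionality labels
#'
#' @param annotations data.frame from [aggregateAll()].
#' @return named integer vector with one count per label
#'   (only-up, only-down, primarily-up, primarily-down, ambiguous) plus
#'   `directional`, the number of pairs with non-zero aggregated
#'   direction.
#' @export
directionalitySummary <- function(annotations) {
  counts <- table(factor(annotations$label, levels = DIRECTION_LABELS))
  out <- c(as.integer(counts),
           sum(annotations$direction != 0L))
  names(out) <- c(DIRECTION_LABELS, "directional")
  out
}
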