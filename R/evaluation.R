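#' Confusion-matrix metrics for predicted versus gold-standard sets
#'
#' Computes sensitivity TP/(TP+FN), specificity TN/(TN+FP), positive
#' predictive value TP/(TP+FP), F-score (harmonic mean of PPV and
#' sensitivity) and accuracy (TP+TN)/|universe| for a predicted item
#' set against a gold standard within a fixed universe.  PPV and
#' F-score are defined as 0 when nothing is predicted.
#'
#' @param predicted character vector (subset of `universe`).
#' @param gold character vector (subset of `universe`).
#' @param universe character vector of all candidate items.
#' @return A [ConfusionMetrics-class].
#' @examples
#' confusionMetrics(c("a", "b"), c("a", "c"), letters[1:6])
#' @seealso [impliedPrevalenceAcc()]
#' @export
confusionMetrics <- function(predicted, gold, universe) {
  predicted <- unique(as.character(predicted))
  gold <- unique(as.character(gold))
  universe <- unique(as.character(universe))
  if (!all(gold %in% universe))
    stop("gold standard must be a subset of the universe")
  if (!all(predicted %in% universe))
    stop("predicted set must be a subset of the universe")
  tp <- length(intersect(predicted, gold))
  fp <- length(setdiff(predicted, gold))
  fn <- length(setdiff(gold, predicted))
  tn <- length(universe) - tp - fp - fn
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
  f <- if (ppv + sens > 0) 2 * ppv * sens / (ppv + sens) else 0
  acc <- (tp + tn) / length(universe)
  new("ConfusionMetrics", sensitivity = sens, specificity = spec,
      ppv = ppv, f_score = f, acc = acc,
      tp = tp, fp = fp, fn = fn, tn = tn)
}

#' F-score from sensitivity and PPV
#'
#' Harmonic mean `2 * ppv * sens / (ppv + sens)`; 0 when both are 0.
#' Useful for checking the internal consistency of published metric
#' tables.
#'
#' @param sens,ppv numeric in [0, 1] (vectorised).
#' @return numeric F-scores.
#' @export
fScore <- function(sens, ppv) {
  ifelse(ppv + sens > 0, 2 * ppv * sens / (ppv + sens), 0)
}

#' Prevalence and accuracy implied by sensitivity, specificity and PPV
#'
#' The three rate metrics of a 2x2 table determine the class prevalence
#' pi through `PPV = sens * pi / (sens * pi + (1 - spec) * (1 - pi))`,
#' and hence the accuracy `ACC = sens * pi + spec * (1 - pi)`.  This is
#' an algebraic consistency check: given three printed metrics it
#' recovers the fourth without the underlying counts.
#'
#' @param sens,spec,ppv numeric(1) in (0, 1).
#' @return named numeric vector with elements `prevalence` and `acc`.
#' @examples
#' impliedPrevalenceAcc(0.798, 0.8491, 0.4301)  # acc ~ 0.8427
#' @export
impliedPrevalenceAcc <- function(sens, spec, ppv) {
  stopifnot(length(sens) == 1, length(spec) == 1, length(ppv) == 1)
  if (any(c(sens, spec, ppv) <= 0) || any(c(sens, spec, ppv) >= 1))
    stop("sens, spec and ppv must lie strictly in (0, 1)")
  a <- sens * (1 - ppv)
  b <- ppv * (1 - spec)
  pi_hat <- b / (a + b)
  if (!is.finite(pi_hat) || pi_hat <= 0 || pi_hat >= 1)
    stop("no feasible prevalence for the supplied metrics")
  c(prevalence = pi_hat, acc = sens * pi_hat + spec * (1 - pi_hat))
}
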