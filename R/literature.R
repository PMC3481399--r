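#' Document frequency of a drug term
#'
#' Fraction of documents whose drug-term annotation contains `term`.
#'
#' @param term a single drug term.
#' @param docs a [Corpus-class] or a list of per-document drug-term
#'   character vectors; must be non-empty.
#' @return numeric(1) in [0, 1].
#' @examples
#' co <- Corpus(c("d1", "d2"), list("aspirin", character()))
#' documentFrequency("aspirin", co)  # 0.5
#' @export
documentFrequency <- function(term, docs) {
  if (is(docs, "Corpus")) docs <- drugTerms(docs)
  if (!is.list(docs) || length(docs) == 0)
    stop("docs must be a non-empty corpus or list of term sets")
  mean(vapply(docs, function(s) term %in% s, logical(1)))
}

#' Resample a corpus into document subsets
#'
#' Draws `n_samples` index sets of `sample_size` documents each,
#' reproducibly for a given seed.  Sampling is with replacement by
#' default (bootstrap-style resampling of the retrieved abstract set);
#' without replacement, `sample_size` may not exceed the corpus size.
#'
#' @param corpus a [Corpus-class].
#' @param n_samples number of resampled sets (>= 1).
#' @param sample_size documents per set (>= 1).
#' @param seed optional integer seed; global RNG state is untouched.
#' @param replace sample with replacement (default TRUE).
#' @return list of `n_samples` integer vectors of document indices into
#'   the corpus.
#' @seealso [enrichDrugs()]
#' @export
sampleCorpus <- function(corpus, n_samples, sample_size, seed = NULL,
                         replace = TRUE) {
  stopifnot(is(corpus, "Corpus"))
  n <- length(corpus)
  if (!is.numeric(n_samples) || n_samples < 1 ||
      n_samples != round(n_samples))
    stop("n_samples must be a positive integer")
  if (!is.numeric(sample_size) || sample_size < 1 ||
      sample_size != round(sample_size))
    stop("sample_size must be a positive integer")
  if (!replace && sample_size > n)
    stop("sample_size exceeds corpus size for sampling without ",
         "replacement")
  withSeed(seed, lapply(seq_len(n_samples), function(i)
    sample.int(n, size = sample_size, replace = replace)))
}

#' Drug-enrichment statistic
#'
#' Two-sample t-type statistic comparing a drug term's average document
#' frequency between the retrieved (disease) corpus samples and the
#' background corpus samples:
#' \deqn{\Delta = \frac{\bar{df}_{net} - \bar{df}_{bg}}
#'   {\sqrt{Var_{net}/N_{net} + Var_{bg}/N_{bg}}}}
#'
#' When both variances are zero the statistic is 0 for equal means and
#' a signed infinity otherwise (a degenerate, noise-free difference).
#'
#' @param mean_net,mean_bg average document frequencies.
#' @param var_net,var_bg non-negative variances.
#' @param n_net,n_bg counts (>= 2) dividing the variances.
#' @return numeric vector of statistics (vectorised over its inputs).
#' @seealso [drugPvalue()], [enrichDrugs()]
#' @export
enrichmentStatistic <- function(mean_net, mean_bg, var_net, var_bg,
                                n_net, n_bg) {
  if (any(n_net < 2) || any(n_bg < 2))
    stop("counts must be at least 2")
  if (any(var_net < 0) || any(var_bg < 0))
    stop("variances must be non-negative")
  num <- mean_net - mean_bg
  den <- sqrt(var_net / n_net + var_bg / n_bg)
  out <- ifelse(den == 0, ifelse(num == 0, 0, sign(num) * Inf),
                num / den)
  as.numeric(out)
}

#' Two-sided p-value for the enrichment statistic
#'
#' Refers the statistic to a t distribution with Welch-Satterthwaite
#' degrees of freedom
#' \deqn{\nu = \frac{(v_1/n_1 + v_2/n_2)^2}
#'   {(v_1/n_1)^2/(n_1-1) + (v_2/n_2)^2/(n_2-1)}}
#' A zero statistic gives p = 1; an infinite statistic gives p = 0; if
#' both variances vanish the p-value is 1 for a zero statistic and 0
#' otherwise.
#'
#' @param delta statistic from [enrichmentStatistic()].
#' @param n_net,n_bg,var_net,var_bg as in [enrichmentStatistic()].
#' @return numeric vector of p-values in [0, 1].
#' @export
drugPvalue <- function(delta, n_net, n_bg, var_net, var_bg) {
  if (any(n_net < 2) || any(n_bg < 2))
    stop("counts must be at least 2")
  se1 <- var_net / n_net
  se2 <- var_bg / n_bg
  k <- pmax(length(delta), length(se1), length(se2))
  delta <- rep_len(delta, k); se1 <- rep_len(se1, k)
  se2 <- rep_len(se2, k)
  n_net <- rep_len(n_net, k); n_bg <- rep_len(n_bg, k)
  p <- numeric(k)
  degen <- (se1 + se2) == 0
  p[degen] <- ifelse(delta[degen] == 0, 1, 0)
  inf <- !degen & is.infinite(delta)
  p[inf] <- 0
  ok <- !degen & !inf
  if (any(ok)) {
    df <- (se1[ok] + se2[ok])^2 /
      (se1[ok]^2 / (n_net[ok] - 1) + se2[ok]^2 / (n_bg[ok] - 1))
    p[ok] <- 2 * stats::pt(-abs(delta[ok]), df = df)
  }
  p
}

# docs x vocabulary term-presence matrix for a corpus
termMembership <- function(corpus, vocabulary) {
  n <- length(corpus)
  mat <- matrix(FALSE, nrow = n, ncol = length(vocabulary),
                dimnames = list(NULL, vocabulary))
  terms <- drugTerms(corpus)
  di <- rep(seq_len(n), lengths(terms))
  tv <- unlist(terms, use.names = FALSE)
  j <- match(tv, vocabulary)
  keep <- !is.na(j)
  if (any(keep)) mat[cbind(di[keep], j[keep])] <- TRUE
  mat
}

# per-term mean document frequency and mean within-sample Bernoulli
# variance over a list of resampled index sets
resampleDfStats <- function(membership, samples, sample_size) {
  dfs <- vapply(samples,
                function(idx) colMeans(membership[idx, , drop = FALSE]),
                numeric(ncol(membership)))
  dfs <- matrix(dfs, nrow = ncol(membership))
  bessel <- if (sample_size > 1) sample_size / (sample_size - 1) else 1
  list(mean = rowMeans(dfs),
       var = rowMeans(dfs * (1 - dfs)) * bessel)
}

#' Literature enrichment of drug terms in a disease corpus
#'
#' For every vocabulary term, compares its document frequency between
#' resampled sets of the retrieved (disease-specific) corpus and of the
#' background corpus, and reports the [enrichmentStatistic()] with a
#' two-sided t-test p-value.
#'
#' @details Each corpus is resampled `n_samples` times into sets of
#' `sample_size` documents.  Per sample the term's document frequency
#' `df` and its within-sample Bernoulli variance `df (1 - df)` (with
#' the small-sample Bessel correction) are recorded; the per-corpus
#' mean frequency and mean variance over the resamples enter the
#' statistic with `N` equal to the sample size.  This makes the
#' statistic the unpooled two-proportion t comparing the corpora, so
#' its null distribution accounts for the document-level sampling noise
#' of the corpora themselves and p-values are calibrated when the two
#' corpora are drawn from the same generating distribution.
#'
#' @param retrieved,background [Corpus-class] objects.
#' @param vocabulary character vector of drug terms to test.
#' @param n_samples resampled sets per corpus (default 100).
#' @param sample_size documents per resampled set; default
#'   `min(1000, corpus size)` per corpus.
#' @param seed optional integer seed for the resampling.
#' @param replace sample with replacement (default TRUE).
#' @param p_adjust `"none"` (default, as in the original procedure) or
#'   `"BH"` to append a Benjamini-Hochberg adjusted column `p_adj`.
#' @return data.frame with one row per vocabulary term: `drug`,
#'   `delta`, `p_value`, `mean_df_net`, `mean_df_bg`, `var_df_net`,
#'   `var_df_bg`, `n_net`, `n_bg`, `rel_freq` (document frequency over
#'   the whole retrieved corpus), ordered by ascending p, then
#'   descending delta, then term.
#' @seealso [selectTopPairs()]
#' @export
enrichDrugs <- function(retrieved, background, vocabulary,
                        n_samples = 100, sample_size = NULL,
                        seed = NULL, replace = TRUE,
                        p_adjust = c("none", "BH")) {
  stopifnot(is(retrieved, "Corpus"), is(background, "Corpus"))
  p_adjust <- match.arg(p_adjust)
  vocabulary <- unique(as.character(vocabulary))
  if (length(vocabulary) == 0) {
    message("empty drug vocabulary; nothing to test")
    return(data.frame(drug = character(), delta = numeric(),
                      p_value = numeric(), mean_df_net = numeric(),
                      mean_df_bg = numeric(), var_df_net = numeric(),
                      var_df_bg = numeric(), n_net = integer(),
                      n_bg = integer(), rel_freq = numeric()))
  }
  m_net <- if (is.null(sample_size)) min(1000L, length(retrieved))
           else as.integer(sample_size)
  m_bg <- if (is.null(sample_size)) min(1000L, length(background))
          else as.integer(sample_size)
  M_net <- termMembership(retrieved, vocabulary)
  M_bg <- termMembership(background, vocabulary)
  stats_pair <- withSeed(seed, {
    s_net <- sampleCorpus(retrieved, n_samples, m_net, replace = replace)
    s_bg <- sampleCorpus(background, n_samples, m_bg, replace = replace)
    list(net = resampleDfStats(M_net, s_net, m_net),
         bg = resampleDfStats(M_bg, s_bg, m_bg))
  })
  delta <- enrichmentStatistic(stats_pair$net$mean, stats_pair$bg$mean,
                               stats_pair$net$var, stats_pair$bg$var,
                               m_net, m_bg)
  pval <- drugPvalue(delta, m_net, m_bg,
                     stats_pair$net$var, stats_pair$bg$var)
  out <- data.frame(drug = vocabulary, delta = delta, p_value = pval,
                    mean_df_net = stats_pair$net$mean,
                    mean_df_bg = stats_pair$bg$mean,
                    var_df_net = stats_pair$net$var,
                    var_df_bg = stats_pair$bg$var,
                    n_net = m_net, n_bg = m_bg,
                    rel_freq = colMeans(M_net))
  if (p_adjust == "BH")
    out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, -out$delta, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the top drug-protein pairs
#'
#' Combines the protein ranking with the drug enrichment: pairs must
#' have at least one co-mentioning document, and are ordered by the
#' drug's p-value (ascending), then the protein's relevance score
#' (descending), with drug/protein id as the final deterministic
#' tie-break, truncated to the first `n`.
#'
#' @param ranked_proteins data.frame from [rankProteins()] (columns
#'   `protein`, `r_p`).
#' @param enriched_drugs data.frame from [enrichDrugs()] (columns
#'   `drug`, `p_value`).
#' @param pair_counts data.frame with columns `drug`, `protein`,
#'   `n_docs` (number of co-mentioning documents).
#' @param n maximum number of pairs to return.
#' @return data.frame with columns `drug`, `protein`, `p_value`, `r_p`,
#'   `n_docs`.
#' @export
selectTopPairs <- function(ranked_proteins, enriched_drugs, pair_counts,
                           n) {
  pc <- pair_counts[pair_counts$n_docs >= 1, , drop = FALSE]
  pc <- pc[pc$drug %in% enriched_drugs$drug &
             pc$protein %in% ranked_proteins$protein, , drop = FALSE]
  pc$p_value <- enriched_drugs$p_value[match(pc$drug,
                                             enriched_drugs$drug)]
  pc$r_p <- ranked_proteins$r_p[match(pc$protein,
                                      ranked_proteins$protein)]
  o <- order(pc$p_value, -pc$r_p, pc$drug, pc$protein)
  out <- pc[o, c("drug", "protein", "p_value", "r_p", "n_docs"),
            drop = FALSE]
  out <- utils::head(out, n)
  rownames(out) <- NULL
  out
}
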