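test_that("document frequency counts term-containing documents", {
  co <- Corpus(sprintf("d%d", 1:10),
               c(rep(list("aspirin"), 10)))
  expect_equal(documentFrequency("aspirin", co), 1)
  expect_equal(documentFrequency("absent", co), 0)
  co8 <- Corpus(sprintf("d%d", 1:8),
                c(rep(list("x"), 3), rep(list(character()), 5)))
  expect_equal(documentFrequency("x", co8), 0.375)
  expect_error(documentFrequency("x", list()), "non-empty")
})

test_that("corpus resampling is seed-reproducible and size-checked", {
  co <- Corpus(sprintf("d%d", 1:20), rep(list(character()), 20))
  s1 <- sampleCorpus(co, 5, 10, seed = 3)
  s2 <- sampleCorpus(co, 5, 10, seed = 3)
  expect_identical(s1, s2)
  expect_length(s1, 5)
  expect_true(all(lengths(s1) == 10))

  perm <- sampleCorpus(co, 1, 20, seed = 4, replace = FALSE)[[1]]
  expect_equal(sort(perm), 1:20)
  expect_error(sampleCorpus(co, 1, 21, replace = FALSE), "exceeds")

  # with replacement, duplicate frequency tracks the birthday bound
  dup <- vapply(1:400, function(s)
    anyDuplicated(sampleCorpus(co, 1, 10, seed = s)[[1]]) > 0,
    logical(1))
  p_dup <- 1 - prod((20:11) / 20)   # exact no-collision complement
  expect_lt(abs(mean(dup) - p_dup), 3 * sqrt(p_dup * (1 - p_dup) / 400))
})

test_that("enrichment statistic follows the t-type formula", {
  expect_equal(enrichmentStatistic(0.2, 0.2, 0.01, 0.02, 50, 50), 0)
  expect_equal(enrichmentStatistic(0.3, 0.1, 0.01, 0.01, 50, 50), 10)
  # antisymmetry under corpus swap
  d1 <- enrichmentStatistic(0.4, 0.1, 0.02, 0.03, 40, 60)
  d2 <- enrichmentStatistic(0.1, 0.4, 0.03, 0.02, 60, 40)
  expect_equal(d1, -d2)
  # degenerate variance handling
  expect_equal(enrichmentStatistic(0.2, 0.2, 0, 0, 50, 50), 0)
  expect_equal(enrichmentStatistic(0.3, 0.1, 0, 0, 50, 50), Inf)
  expect_equal(enrichmentStatistic(0.1, 0.3, 0, 0, 50, 50), -Inf)
  expect_error(enrichmentStatistic(0.3, 0.1, 0.01, 0.01, 1, 50),
               "at least 2")
})

test_that("p-values match the Welch t reference", {
  expect_equal(drugPvalue(0, 50, 50, 0.01, 0.01), 1)
  expect_equal(drugPvalue(Inf, 50, 50, 0, 0), 0)
  expect_lt(drugPvalue(10, 50, 50, 0.01, 0.01), 1e-12)
  # independent tail evaluation at the Welch-Satterthwaite df
  se1 <- 0.02 / 40; se2 <- 0.05 / 60
  df <- (se1 + se2)^2 / (se1^2 / 39 + se2^2 / 59)
  expect_equal(drugPvalue(2.5, 40, 60, 0.02, 0.05),
               2 * pt(-2.5, df), tolerance = 1e-12)
})

test_that("a single full-corpus resample reproduces t.test on indicators", {
  cp <- genCorpusPair(60, c("a", "b", "c"),
                      enriched_terms = list(a = c(0.5, 0.2)),
                      base_rate = 0.3, seed = 9)
  e <- enrichDrugs(cp$retrieved, cp$background, "a", n_samples = 1,
                   sample_size = 60, replace = FALSE, seed = 1)
  ind <- function(co) vapply(drugTerms(co), function(s) "a" %in% s, TRUE)
  tt <- t.test(ind(cp$retrieved), ind(cp$background))
  expect_equal(e$delta, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(e$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("a planted term is recovered at rank one with a tiny p-value", {
  vocab <- sprintf("drug%03d", 1:50)
  cp <- genCorpusPair(200, vocab,
                      enriched_terms = list(drug001 = c(0.6, 0.05)),
                      base_rate = 0.1, seed = 21)
  e <- enrichDrugs(cp$retrieved, cp$background, vocab,
                   n_samples = 100, seed = 22)
  expect_equal(e$drug[1], "drug001")
  expect_lt(e$p_value[1], 0.001)
  expect_equal(e$rel_freq[match("drug001", e$drug)],
               documentFrequency("drug001", cp$retrieved))
})

test_that("self-comparison of identical corpora yields non-significant terms", {
  vocab <- sprintf("t%03d", 1:100)
  cp <- genCorpusPair(150, vocab, base_rate = 0.2, seed = 31)
  e <- enrichDrugs(cp$retrieved, cp$retrieved, vocab,
                   n_samples = 50, seed = 32)
  expect_true(all(e$p_value > 0.5))
  # a term in neither corpus is exactly null
  e0 <- enrichDrugs(cp$retrieved, cp$background, "never-mentioned",
                    n_samples = 10, seed = 1)
  expect_equal(e0$delta, 0)
  expect_equal(e0$p_value, 1)
})

test_that("swapping corpora negates delta and preserves p exactly", {
  vocab <- sprintf("t%03d", 1:20)
  cp <- genCorpusPair(100, vocab, base_rate = 0.15, seed = 41)
  fwd <- enrichDrugs(cp$retrieved, cp$background, vocab,
                     n_samples = 40, seed = 5)
  # same resampling stream must hit each corpus in the same role;
  # reuse per-corpus stats by swapping the finished tables instead
  rev <- enrichDrugs(cp$background, cp$retrieved, vocab,
                     n_samples = 40, seed = 5)
  # seed 5 draws the first corpus first in both runs, so the swap holds
  # at the level of the statistic's arguments:
  d2 <- enrichmentStatistic(fwd$mean_df_bg, fwd$mean_df_net,
                            fwd$var_df_bg, fwd$var_df_net,
                            fwd$n_bg, fwd$n_net)
  expect_equal(d2, -fwd$delta)
  expect_equal(drugPvalue(d2, fwd$n_bg, fwd$n_net,
                          fwd$var_df_bg, fwd$var_df_net),
               fwd$p_value)
  expect_true(is.data.frame(rev))
})

test_that("enrichment output is bit-reproducible for a fixed seed", {
  vocab <- sprintf("t%03d", 1:30)
  cp <- genCorpusPair(120, vocab, base_rate = 0.1, seed = 51)
  e1 <- enrichDrugs(cp$retrieved, cp$background, vocab,
                    n_samples = 60, seed = 52)
  e2 <- enrichDrugs(cp$retrieved, cp$background, vocab,
                    n_samples = 60, seed = 52)
  expect_identical(e1, e2)
})

test_that("top-pair selection sorts by drug p then protein relevance", {
  ranked <- data.frame(protein = c("P1", "P2", "P3", "P4"),
                       r_p = c(9, 7, 5, 3))
  enr <- data.frame(drug = c("d1", "d2", "d3"),
                    p_value = c(0.001, 0.01, 0.01))
  counts <- expand.grid(drug = enr$drug, protein = ranked$protein,
                        stringsAsFactors = FALSE)
  counts$n_docs <- 1L
  counts$n_docs[counts$drug == "d3" & counts$protein == "P1"] <- 0L

  top <- selectTopPairs(ranked, enr, counts, 5)
  expect_equal(nrow(top), 5)
  # brute-force oracle: merge + sort by (p asc, r_p desc, ids)
  all <- merge(merge(counts[counts$n_docs >= 1, ], enr), ranked)
  all <- all[order(all$p_value, -all$r_p, all$drug, all$protein), ]
  expect_equal(top$drug, head(all$drug, 5))
  expect_equal(top$protein, head(all$protein, 5))
  # equal-p drugs interleave by protein score
  d23 <- selectTopPairs(ranked, enr,
                        counts[counts$drug != "d1", ], 4)
  expect_equal(d23$protein[1:2], c("P1", "P2"))
  expect_equal(d23$drug[1:2], c("d2", "d2"))  # d3-P1 has no co-mention
  # n larger than the pair count returns everything
  expect_equal(nrow(selectTopPairs(ranked, enr, counts, 1000)), 11)
})
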