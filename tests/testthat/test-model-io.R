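test_that("network reading deduplicates reversed edges and validates confidences", {
  f <- writeNetworkFile(c("A\tB\t0.9", "B\tA\t0.7", "A\tC\t0.5"))
  net <- readNetwork(f)
  expect_equal(numEdges(net), 2)
  # max confidence kept for the duplicated undirected pair
  ed <- networkEdges(net)
  expect_equal(ed$conf[ed$protein_a == "A" & ed$protein_b == "B"], 0.9)

  bad <- writeNetworkFile(c("A\tB\t0.0"))
  expect_error(readNetwork(bad), "\\(0, 1\\]")
  bad2 <- writeNetworkFile(c("A\tB\t1.2"))
  expect_error(readNetwork(bad2), "\\(0, 1\\]")
  mal <- writeNetworkFile(c("A\tB\t0.5", "Aonly"))
  expect_error(readNetwork(mal), "line 3")
})

test_that("min_conf drops low-confidence edges after validation", {
  f <- writeNetworkFile(c("A\tB\t0.9", "A\tC\t0.8", "B\tC\t0.76",
                          "C\tD\t0.5", "D\tE\t0.74"))
  expect_equal(numEdges(readNetwork(f, min_conf = 0.75)), 3)
  expect_equal(numEdges(readNetwork(f)), 5)
})

test_that("self-loops are dropped with a warning, never kept", {
  f <- writeNetworkFile(c("A\tA\t0.9", "A\tB\t0.8"))
  expect_warning(net <- readNetwork(f), "self-loop")
  expect_equal(numEdges(net), 1)
})

test_that("network write/read round-trips under undirected equality", {
  net <- genNetwork(15, 0.3, seed = 7)
  for (fmt in c("tsv", "sif")) {
    f <- tempfile(fileext = paste0(".", fmt))
    writeNetwork(net, f, format = fmt)
    back <- readNetwork(f, format = fmt)
    expect_equal(networkEdges(back)[c("protein_a", "protein_b")],
                 networkEdges(net)[c("protein_a", "protein_b")])
    expect_equal(networkEdges(back)$conf, networkEdges(net)$conf,
                 tolerance = 1e-6)
  }
})

test_that("evidence reading maps direction words and infers categories", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("drug\tprotein\tpmid\tdirection",
               "drugX\tproteinY\t123\tup",
               "drugX\tproteinZ\t124\tinhibition",
               "drugX\tproteinW\t125\tindirect"), f)
  ev <- readEvidence(f)
  expect_equal(ev$direction, c(1L, -1L, 0L))
  expect_equal(ev$category, c("activation", "inhibition", "indirect"))

  empty <- tempfile(fileext = ".tsv")
  writeLines("drug\tprotein\tpmid\tdirection", empty)
  expect_equal(nrow(readEvidence(empty)), 0)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("drug\tprotein\tpmid\tdirection", "d\tp\t1\tsideways"),
             bad)
  expect_error(readEvidence(bad), "unrecognised direction")
})

test_that("packaged evidence fixture holds the nine curated records", {
  ev <- loadFixture("table3_tamoxifen_esr1")
  expect_equal(nrow(ev), 9)
  expect_true(all(ev$drug == "Tamoxifen" & ev$protein == "ESR1_HUMAN"))
  expect_equal(sum(ev$direction == -1L), 7)
  expect_equal(sum(ev$direction == 1L), 2)
})

test_that("expression tables load from statuses or thresholded logFC", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tstatus", "G1\tover", "G2\tunder", "G3\tunchanged"),
             f)
  pr <- readExpression(f)
  expect_equal(unname(geneStatus(pr, c("G1", "G2", "G3", "G4"))),
               c("over", "under", "unchanged", "unchanged"))

  g <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tlogFC", "G1\t1.5", "G2\t-2.0", "G3\t0.3"), g)
  pr2 <- readExpression(g, logfc_threshold = 1)
  expect_equal(unname(geneStatus(pr2, c("G1", "G2", "G3"))),
               c("over", "under", "unchanged"))
  expect_error(readExpression(g), "threshold")
})

test_that("corpus JSONL round-trips including empty term sets", {
  co <- Corpus(c("d1", "d2", "d3"),
               list(c("aspirin", "tamoxifen"), character(), "aspirin"),
               list("P1", c("P1", "P2"), character()))
  f <- tempfile(fileext = ".jsonl")
  writeCorpus(co, f)
  back <- readCorpus(f)
  expect_equal(docIDs(back), docIDs(co))
  expect_equal(drugTerms(back), drugTerms(co))
  expect_equal(proteinTerms(back), proteinTerms(co))
})

test_that("subnetwork export writes attributed graphs and round-trips", {
  t5 <- loadFixture("table5_directionality")
  lum <- loadFixture("luminalA_status")
  sc <- setNames(t5$r_p, t5$protein)
  a <- assessDrug("Tamoxifen", t5, lum, sc)

  f <- tempfile(fileext = ".graphml")
  writeSubnetwork(a, f)
  g <- readSubnetwork(f)
  expect_equal(igraph::vcount(g), 16)  # 1 drug hexagon + 15 proteins
  expect_equal(sum(igraph::V(g)$type == "drug"), 1)
  expect_equal(igraph::V(g)$shape[igraph::V(g)$type == "drug"],
               "hexagon")
  # attribute round-trip against the assessment table
  pr <- effectPairs(a)
  vi <- match(pr$protein, igraph::V(g)$name)
  expect_equal(igraph::V(g)$rp[vi], pr$r_p)
  expect_equal(igraph::V(g)$status[vi], pr$status)
  expect_equal(igraph::V(g)$color[vi],
               unname(c(over = "red", under = "green",
                        unchanged = "grey")[pr$status]))
  ends <- igraph::ends(g, igraph::E(g))
  prot <- ifelse(ends[, 1] == "Tamoxifen", ends[, 2], ends[, 1])
  expect_equal(igraph::E(g)$direction[match(pr$protein, prot)],
               pr$direction)

  s <- tempfile(fileext = ".sif")
  writeSubnetwork(a, s, format = "sif")
  expect_equal(length(readLines(s)), 15)
  expect_error(writeSubnetwork(a, s, format = "dot"))

  empty <- new("DrugEffectAssessment", drug = "D",
               pairs = effectPairs(a)[0, ],
               counts = c(therapeutic = 0L, toxic = 0L, neutral = 0L,
                          ambiguous = 0L),
               net_score = 0, overall = "neutral", tau = 0)
  expect_error(writeSubnetwork(empty, tempfile()), "no annotated pairs")
})
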