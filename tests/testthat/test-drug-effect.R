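test_that("the direction-by-status truth table is exactly as defined", {
  grid <- expand.grid(direction = c(-1L, 0L, 1L),
                      status = c("over", "under", "unchanged"),
                      stringsAsFactors = FALSE)
  grid$effect <- classifyEffect(grid$direction, grid$status)
  lookup <- function(d, s) grid$effect[grid$direction == d &
                                         grid$status == s]
  expect_equal(lookup(1L, "under"), "therapeutic")
  expect_equal(lookup(-1L, "over"), "therapeutic")
  expect_equal(lookup(1L, "over"), "toxic")
  expect_equal(lookup(-1L, "under"), "toxic")
  expect_equal(lookup(0L, "over"), "ambiguous")
  expect_equal(lookup(0L, "under"), "ambiguous")
  expect_equal(lookup(0L, "unchanged"), "ambiguous")
  expect_equal(lookup(1L, "unchanged"), "neutral")
  expect_equal(lookup(-1L, "unchanged"), "neutral")
  tab <- table(grid$effect)
  expect_equal(unname(tab[c("therapeutic", "toxic", "ambiguous",
                            "neutral")]), c(2L, 2L, 3L, 2L),
               ignore_attr = TRUE)
  expect_error(classifyEffect(2L, "over"))
  expect_error(classifyEffect(1L, "sideways"))
})

test_that("relabelling over/under while flipping directions is a symmetry", {
  grid <- expand.grid(direction = c(-1L, 0L, 1L),
                      status = c("over", "under", "unchanged"),
                      stringsAsFactors = FALSE)
  swap <- c(over = "under", under = "over", unchanged = "unchanged")
  expect_equal(classifyEffect(grid$direction, grid$status),
               classifyEffect(-grid$direction,
                              unname(swap[grid$status])))
})

test_that("Tamoxifen assessment against luminal A matches the case study", {
  t5 <- loadFixture("table5_directionality")
  lum <- loadFixture("luminalA_status")
  sc <- setNames(t5$r_p, t5$protein)
  a <- assessDrug("Tamoxifen", t5, lum, sc)
  cnt <- effectCounts(a)
  expect_equal(unname(cnt["therapeutic"]), 3L)
  expect_equal(unname(cnt["toxic"]), 1L)
  expect_equal(sum(cnt), 15L)
  # therapeutic: inhibits over ESR1, activates under JUN and MYC;
  # toxic: activates over ERBB2
  pr <- effectPairs(a)
  expect_setequal(pr$protein[pr$effect == "therapeutic"],
                  c("ESR1_HUMAN", "JUN_HUMAN", "MYC_HUMAN"))
  expect_equal(pr$protein[pr$effect == "toxic"], "ERBB2_HUMAN")
  expect_equal(netScore(a), (72.39 + 2.91 + 3.49) - 2.07,
               tolerance = 1e-12)
  expect_equal(overallEffect(a), "therapeutic")
})

test_that("Tamoxifen against basal-like is toxic-leaning as reported", {
  t5 <- loadFixture("table5_directionality")
  bas <- loadFixture("basal_status")
  sc <- setNames(t5$r_p, t5$protein)
  a <- assessDrug("Tamoxifen", t5, bas, sc)
  expect_equal(unname(effectCounts(a)["therapeutic"]), 1L)
  expect_equal(unname(effectCounts(a)["toxic"]), 2L)
  pr <- effectPairs(a)
  expect_equal(pr$protein[pr$effect == "therapeutic"], "JUN_HUMAN")
  expect_setequal(pr$protein[pr$effect == "toxic"],
                  c("E2F1_HUMAN", "IRS1_HUMAN"))
})

test_that("Plicamycin against luminal A is toxic overall", {
  t5 <- loadFixture("table5_directionality")
  lum <- loadFixture("luminalA_status")
  sc <- setNames(t5$r_p, t5$protein)
  a <- assessDrug("Plicamycin", t5, lum, sc)
  expect_equal(unname(effectCounts(a)["therapeutic"]), 0L)
  expect_equal(unname(effectCounts(a)["toxic"]), 1L)
  expect_false(overallEffect(a) == "therapeutic")
  expect_equal(effectPairs(a)$protein[effectPairs(a)$effect == "toxic"],
               "MYC_HUMAN")
})

test_that("net score is additive and ignores neutral/ambiguous pairs", {
  ann <- data.frame(drug = "D",
                    protein = c("A", "B", "C", "E", "F"),
                    direction = c(-1L, 1L, 1L, 0L, 1L))
  pr <- ExpressionProfile(c(A = "over", B = "over", C = "under",
                            E = "over", F = "unchanged"))
  sc <- c(A = 5, B = 2, C = 1, E = 100, F = 100)
  a <- assessDrug("D", ann, pr, sc)
  expect_equal(netScore(a), (5 + 1) - 2)
  # removing the neutral and ambiguous pairs leaves the score unchanged
  a2 <- assessDrug("D", ann[1:3, ], pr, sc)
  expect_equal(netScore(a2), netScore(a))
  # additivity over disjoint subsets
  s1 <- netScore(assessDrug("D", ann[1:2, ], pr, sc))
  s2 <- netScore(assessDrug("D", ann[c(3, 5), ], pr, sc))
  expect_equal(s1 + s2 + 0, netScore(a))  # pair E is ambiguous: adds 0
  expect_error(assessDrug("other", ann, pr, sc), "no annotations")
  expect_warning(assessDrug("D", ann, pr, sc[1:3]), "r_p = 0")
})

test_that("the overall call respects the neutrality band tau", {
  ann <- data.frame(drug = "D", protein = c("A", "B"),
                    direction = c(-1L, 1L))
  pr <- ExpressionProfile(c(A = "over", B = "over"))
  sc <- c(A = 3, B = 2)  # net = +1
  expect_equal(overallEffect(assessDrug("D", ann, pr, sc)), "therapeutic")
  expect_equal(overallEffect(assessDrug("D", ann, pr, sc, tau = 2)),
               "neutral")
  sc2 <- c(A = 2, B = 5)  # net = -3
  expect_equal(overallEffect(assessDrug("D", ann, pr, sc2)), "toxic")
})

test_that("drug subnetworks keep all annotated partners regardless of effect", {
  t5 <- loadFixture("table5_directionality")
  lum <- loadFixture("luminalA_status")
  sc <- setNames(t5$r_p, t5$protein)
  g <- buildDrugSubnetwork(assessDrug("Plicamycin", t5, lum, sc))
  expect_equal(igraph::vcount(g), 3)  # drug + MYC + SP1
  expect_setequal(igraph::V(g)$name[igraph::V(g)$type == "protein"],
                  c("MYC_HUMAN", "SP1_HUMAN"))
  # all-neutral assessment still yields the full star
  ann <- data.frame(drug = "D", protein = c("X", "Y", "Z"),
                    direction = 1L)
  pr <- ExpressionProfile(character())
  a <- assessDrug("D", ann, pr, c(X = 1, Y = 1, Z = 1))
  expect_equal(unname(effectCounts(a)["neutral"]), 3L)
  gg <- buildDrugSubnetwork(a)
  expect_equal(igraph::ecount(gg), nrow(effectPairs(a)))
  expect_equal(igraph::vcount(gg), 4)
})
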