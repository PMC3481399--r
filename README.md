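# netpharm

Network-pharmacology toolkit for building **disease-specific
connectivity maps** between proteins and drugs. Complex diseases are
rarely driven by a single gene, so single-target screening misses both
efficacy and toxicity that only appear at the network level. `netpharm`
is aimed at computational biologists who want to rank disease-relevant
proteins from a weighted interaction network, find drugs enriched in the
disease literature, attach a curated direction (activation/inhibition)
to each drug–protein pair, and ask whether a drug pushes a patient's
expression profile back toward the healthy range — the
expression-reversal hypothesis.

## The model

**Protein relevance.** Disease seed genes are expanded over a
confidence-weighted protein–protein interaction (PPI) network, and each
protein *p* in the resulting subnetwork is scored

    r_p = k · ln( Σ_q conf(p, q) ) − ln( Σ_q N(p, q) )

where the sums run over *p*'s interaction partners *q*, `conf(p, q) ∈
(0, 1]` is the interaction confidence, `N(p, q) = 1` per partner (the
second sum is *p*'s degree), and *k* = 2 by default. With all
confidences 1 the score is exactly `ln(degree)`.

**Drug enrichment.** For every drug term *d*, document frequencies are
compared between resampled sets of the retrieved (disease-specific)
abstract corpus and of a background corpus:

    Δ = ( df̄_net − df̄_bg ) / sqrt( Var_net / N_net + Var_bg / N_bg )

with `Var` the within-sample Bernoulli variance of the term-presence
indicator averaged over resamples and `N` the sample size, referred to a
two-sided t distribution with Welch–Satterthwaite degrees of freedom.

**Directionality.** Per-abstract evidence records (+1 activation, −1
inhibition, 0 indirect/ambiguous/unknown) are aggregated per
drug–protein pair by majority vote; pairs are labelled `only-up`,
`only-down`, `primarily-up`, `primarily-down` or `ambiguous`.

**Drug effect.** Against an expression profile (over / under /
unchanged per gene), a pair is *therapeutic* when the drug opposes the
disease change (activates an under-expressed or inhibits an
over-expressed protein), *toxic* when it reinforces it, *neutral* on
unchanged genes, *ambiguous* without direction. The drug's net efficacy
is relevance-weighted:

    net_score = Σ r_p (therapeutic pairs) − Σ r_p (toxic pairs)

## Worked example

The package ships the published breast-cancer case-study fixtures:
Tamoxifen's 15 annotated interaction partners with their relevance
scores, and the luminal A expression statuses (over: ESR1, ERBB2;
under: JUN, MYC).

```r
library(netpharm)

t5  <- loadFixture("table5_directionality")
lum <- loadFixture("luminalA_status")
a   <- assessDrug("Tamoxifen", t5, lum, setNames(t5$r_p, t5$protein))
a
#> DrugEffectAssessment for Tamoxifen
#>   pairs: 15 ( therapeutic 3, toxic 1, neutral 11, ambiguous 0 )
#>   net score: 76.72 -> therapeutic

subset(effectPairs(a), effect != "neutral")
#>        protein   r_p direction status      effect
#> 6  ERBB2_HUMAN  2.07         1   over       toxic
#> 7   ESR1_HUMAN 72.39        -1   over therapeutic
#> 9    JUN_HUMAN  2.91         1  under therapeutic
#> 10   MYC_HUMAN  3.49         1  under therapeutic
```

Tamoxifen inhibits over-expressed ESR1 and activates under-expressed
JUN and MYC (therapeutic, reversal of the disease change), while
activating over-expressed ERBB2 (toxic). The net score 76.72 =
(72.39 + 2.91 + 3.49) − 2.07 is dominated by ESR1, so the overall call
is therapeutic — the expected pharmacology of an estrogen-receptor
antagonist in luminal A disease.

Aggregating the nine curated Tamoxifen–ESR1 abstracts:

```r
aggregateDirection(loadFixture("table3_tamoxifen_esr1"))
#>        drug    protein direction n_up n_down n_other          label
#> 1 Tamoxifen ESR1_HUMAN        -1    2      7       0 primarily-down
```

A command-line front-end over the same functions is installed at
`inst/scripts/netpharm` (subcommands `rank-proteins`, `enrich-drugs`,
`aggregate-directions`, `assess-drug`, `evaluate`, `simulate`, `run`).

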