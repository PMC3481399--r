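---
title: "Disease-gene-drug connectivity maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease-gene-drug connectivity maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The problem

For a complex disease, the therapeutic and toxic profile of a drug is a
network property: a drug acts on many proteins, and those proteins
matter to the disease to very different degrees. `netpharm` builds a
disease-specific connectivity map in four stages — protein relevance
ranking on a weighted interaction network, literature enrichment of
drug terms, directionality curation of drug–protein pairs, and
effect assessment against a disease expression profile — and this
vignette documents the model behind each stage, the parameters that
matter, and the design decisions taken where the method left room.

The guiding hypothesis is expression reversal: an ideal drug moves a
patient's expression profile back toward the healthy range, inhibiting
what the disease over-expresses and activating what it under-expresses.
The refinement added here over plain signature matching is that genes
are not interchangeable — each effect is weighted by the protein's
network relevance score.

## Protein relevance on a weighted PPI network

A disease seed list (e.g. from a curated disease-gene catalogue) is
expanded over the interaction network: `expandSubnetwork()` takes all
proteins within `depth` hops of a seed and induces the subgraph on that
set. The default `depth = 1` reflects that one interaction hop
("partner proteins") is the scale at which interaction evidence is
usually interpreted; deeper expansion rapidly absorbs most of a
connected PPI network and dilutes disease specificity. Seeds absent
from the network are kept as isolated nodes so the seed list remains
visible downstream.

Each connected protein is scored

$$ r_p = k \ln \sum_{q} \mathrm{conf}(p,q) \;-\; \ln \sum_q N(p,q), $$

with $\mathrm{conf}(p,q) \in (0,1]$ the interaction confidence,
$N(p,q)=1$ per partner, and $k$ an empirical constant defaulting to 2.
The score rewards many high-confidence interactions: with all
confidences 1 it is exactly $\ln(\mathrm{degree})$, and for $n$ edges
of equal confidence $c$ it is $\ln(n c^k)$, so low-confidence
interactions can push the score negative. The sums run over the
*expanded subnetwork*, not the full network: the score is meant to
measure importance within the disease-relevant neighbourhood, and that
is also the only choice under which the ranking is self-contained once
the subnetwork is built. Degree-zero nodes have no defined score (log
of zero) and are omitted from rankings with a warning rather than
carried as $-\infty$, which keeps score vectors finite and sortable.
Ties are broken lexicographically by protein id so rankings are
deterministic. Scores are kept at full double precision; any rounding
(two decimals in published tables) belongs to writers, not to the
model.

Interaction confidences are accepted as given in $(0,1]$; mapping a
database's star-grade system onto numeric confidences is left to the
user, since grade definitions vary by source. When the same undirected
pair appears twice the maximum confidence is kept — under a
"confidence above threshold" data model the strongest annotation is
the defensible one — and self-loops are dropped, because a
partner-counting score has no meaningful contract for them.

## Drug enrichment in the disease literature

Each abstract is a document record annotated with the drug and protein
terms it mentions; the retrieved corpus collects abstracts found for
the disease-relevant proteins, the background corpus a random sample of
the literature. For a drug term $d$, both corpora are resampled
`n_samples` times into sets of `sample_size` documents and the
per-sample document frequency $df$ (fraction of documents mentioning
$d$) is recorded. The enrichment statistic is

$$ \Delta = \frac{\overline{df}_{net} - \overline{df}_{bg}}
  {\sqrt{ \mathrm{Var}_{net}/N_{net} + \mathrm{Var}_{bg}/N_{bg} }}, $$

and the p-value is two-sided from a t distribution with
Welch–Satterthwaite degrees of freedom.

The load-bearing design choice is what $\mathrm{Var}$ and $N$ mean.
`netpharm` takes $\mathrm{Var}$ as the *within-sample Bernoulli
variance* of the term-presence indicator, $df(1-df)$ with the
small-sample Bessel correction, averaged over the resamples, and $N$ as
the *sample size*. Under this reading $\Delta$ is the standard unpooled
two-proportion t statistic comparing the corpora, and its denominator
estimates the document-level binomial noise of the corpora themselves.
The alternative reading — across-sample variance of $df$ divided by the
number of resamples — makes the denominator measure only resampling
noise, which shrinks with the number of resamples while the real
corpus-to-corpus variation does not; with 100 resamples of
corpus-sized samples that statistic is inflated roughly tenfold and
essentially every null term becomes "significant". Only the
two-proportion reading yields a calibrated t-test, which the package
verifies empirically: over 600 null terms (both corpora generated at
the same rate) the fraction of $p < \alpha$ stays within three binomial
standard errors of $\alpha$.

Defaults: `n_samples = 100`, `sample_size = min(1000, corpus size)`,
sampling with replacement, one seedable RNG stream per run (recorded in
the pipeline manifest). Degenerate cases are fixed by definition: a
term absent from both corpora (or any zero-variance, equal-means
configuration) has $\Delta = 0$, $p = 1$; zero variance with unequal
means yields a signed infinity and $p = 0$. Significance is reported at
$p < 0.05$ with no multiple-testing correction by default, matching the
original reporting practice; a Benjamini–Hochberg column is available
via `p_adjust = "BH"` for users screening large vocabularies.

Candidate drug–protein pairs require at least one co-mentioning
document and are ordered by drug p-value, then protein relevance, then
ids (`selectTopPairs()`), so the "top 500 pairs" of a disease query are
reproducible. As an association display score the package exposes
$-\log_{10}(p)$ where one is needed; this is an artifact definition of
this toolkit, not a published quantity.

## Directionality aggregation

Curated evidence records carry one direction per abstract: +1
(activation / up-regulation), −1 (inhibition / down-regulation), or 0
(indirect, ambiguous, unknown). Aggregation per pair is a majority
vote in which only directed records vote; indirect/ambiguous/unknown
records are tallied separately as `n_other`, because an indirect or
conflicting mention is evidence of a relationship but not of its sign.
The aggregated direction is $\mathrm{sign}(n_{up} - n_{down})$ and the
label is `only-up`/`only-down` for unanimous directed evidence,
`primarily-up`/`primarily-down` for a strict majority with dissent,
and `ambiguous` for ties (including all-undirected pairs). A strict
majority — rather than a supermajority — is used for "primarily"
because the reference curation resolves conflicting evidence by simple
abstract counts (7 inhibitory vs 2 stimulatory abstracts suffice to
call Tamoxifen–ESR1 inhibition). Symmetric conflicts are left
ambiguous: breaking them properly needs tissue and disease context
that per-abstract term annotations do not carry, so the package does
not guess.

## Effect classification and net efficacy

Against an expression profile mapping genes to over / under /
unchanged (genes missing from the profile count as unchanged), each
annotated pair is classified by the reversal rule:

| direction | over | under | unchanged |
|-----------|------|-------|-----------|
| +1 (activates) | toxic | therapeutic | neutral |
| −1 (inhibits) | therapeutic | toxic | neutral |
| 0 | ambiguous | ambiguous | ambiguous |

The `neutral` label is deliberate: annotated partners that are not
differentially expressed are silently invisible in published effect
counts, and making them an explicit category keeps
`sum(counts) == number of pairs` as an invariant. The table is
symmetric under swapping over↔under while flipping all directions, a
property the tests assert exhaustively.

The drug-level summary is
$\mathrm{net} = \sum_{\mathrm{therapeutic}} r_p -
\sum_{\mathrm{toxic}} r_p$: effects on important disease proteins
dominate. The weights are the relevance scores exactly — the method
motivates weighting by importance without prescribing a transform, and
using $r_p$ unmodified keeps the score additive over disjoint pair sets
and invariant to removing neutral or ambiguous pairs. Per-pair
evidence counts are carried through but do not enter the score. The
overall call is therapeutic when $\mathrm{net} > \tau$, toxic below
$-\tau$, neutral in between, with $\tau = 0$ by default since the
reference calls are qualitative; users wanting a conservative band can
raise $\tau$.

In the shipped case study this machinery reproduces the published
calls exactly: Tamoxifen vs luminal A gives 3 therapeutic + 1 toxic
pairs (net 76.72, dominated by ESR1), Tamoxifen vs basal-like 1 + 2
(all three differential partners of low relevance), and Plicamycin vs
luminal A 0 + 1 — toxic overall, by inhibiting under-expressed MYC.

## Synthetic data: what it emulates, and what it does not

All stages are testable offline through seeded generators:

- `genNetwork()` — Erdős–Rényi topology with Beta(5, 2) confidences,
  emulating a curated PPI slice whose confidences skew high. Real PPI
  networks are scale-free with hubs; an Erdős–Rényi graph is not, so
  passing tests say the score algebra is right, not that degree
  distributions are realistic.
- `genCorpusPair()` — per-document independent term presence at
  corpus-specific rates (base rate 0.1 unless planted), emulating
  retrieved-vs-background frequency structure. Real abstracts have
  correlated term co-occurrence and bursty topics; independence is the
  null the statistic assumes, so calibration results transfer only to
  the extent that real term occurrences are exchangeable across
  documents.
- `genEvidence()` — per-record direction flips with probability
  `flip_prob < 0.5` around a planted truth, emulating curation noise.
  With 9 records per pair and a 20% flip rate, the majority vote
  recovers the truth for ~98% of pairs (binomial tail
  $\Pr[\mathrm{Bin}(9, 0.2) \ge 5] \approx 0.0196$), which the tests
  check against a 95% floor.
- `genExpression()` — exact allocation of over/under fractions by
  sampling without replacement.

Every generator is a pure function of its parameters and seed, and
restores the global RNG state. The study conditions used in the test
suite — 200-document corpora, 100 resamples, 600 null terms, a planted
term at rates 0.6 vs 0.05 over a 20-seed panel, 500 evidence pairs —
are the package's chosen desk-scale testbed: large enough for the
binomial error bands to be meaningful, small enough to run in seconds.

## Numerical and interface choices

- Confidence bounds are enforced, never clamped; violating inputs are
  rejected with the offending line number.
- Edge-list order never matters: networks are canonicalised
  (lexicographic endpoint order, one row per undirected pair) on
  construction, and ranking/aggregation outputs carry deterministic
  tie-breaks.
- Directions in files may be numeric (−1/0/1) or curation vocabulary
  (up/up-regulated/activation, down/down-regulated/inhibition,
  indirect/ambiguous/unknown); protein ids are case-sensitive UTF-8 as
  given.
- GraphML is the attribute-preserving subnetwork format (node size
  from $r_p$, red/green status and direction colours); SIF is a lossy
  convenience export.
- The pipeline writes a manifest (package version, seed, parameters,
  MD5 per artifact) so any run can be audited; with a fixed seed the
  tabular payloads are byte-identical across runs.
- An optional per-record weight column is accepted in evidence tables
  for users who wish to encode manual tie-break judgments; it is not
  used by the default vote.

## Limitations

- The relevance score depends on the confidence scale of the source
  interaction database; scores from differently-calibrated networks
  are not comparable, and the published score magnitudes for specific
  proteins are reproducible only with the original database (they ship
  here as fixture inputs).
- Enrichment works on pre-annotated term sets; no text mining or named
  entity recognition is performed, and the original multi-million
  abstract corpus is represented only by its statistical shape.
- Directionality has no tissue or subtype context; symmetric conflicts
  stay ambiguous by design.
- Benchmark utilities (`confusionMetrics()`, `impliedPrevalenceAcc()`)
  check metric algebra and internal consistency of published
  performance tables; reproducing those tables' absolute values would
  require the original gold-standard drug lists, which are out of
  scope.
- Net efficacy scores are descriptive network-level quantities, not
  clinical efficacy claims.
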