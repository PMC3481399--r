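Package: netpharm
Title: Disease-Gene-Drug Connectivity Maps from Protein Networks and
    Literature Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Network-pharmacology toolkit for building disease-specific
    connectivity maps between proteins and drugs. Ranks proteins in a
    disease-expanded protein-protein interaction subnetwork with a
    confidence-weighted relevance score, tests drug terms for enrichment
    in a retrieved abstract corpus against a background corpus with a
    resampled two-sample t statistic, aggregates per-abstract drug-to-
    protein directionality evidence by majority vote, classifies each
    annotated drug-protein pair as therapeutic or toxic against a disease
    expression profile under the expression-reversal hypothesis, and
    scores a drug's net effect weighted by protein relevance. Includes
    seeded synthetic-data generators for every input type and
    confusion-matrix benchmarking utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
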