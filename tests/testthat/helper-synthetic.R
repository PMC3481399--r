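# small builders shared across test files

makeNet <- function(a, b, conf) {
  WeightedNetwork(data.frame(protein_a = a, protein_b = b, conf = conf))
}

# independent per-node recomputation of the relevance score from a raw
# edge data.frame (the brute-force oracle; no package graph code)
bruteScore <- function(edges, node, k = 2) {
  conf <- c(edges$conf[edges$protein_a == node],
            edges$conf[edges$protein_b == node])
  k * log(sum(conf)) - log(length(conf))
}

bruteRank <- function(edges, k = 2) {
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  rp <- vapply(nodes, bruteScore, numeric(1), edges = edges, k = k)
  data.frame(protein = nodes, r_p = unname(rp))[order(-rp, nodes), ]
}

writeNetworkFile <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("protein_a\tprotein_b\tconfidence", lines), f)
  f
}
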