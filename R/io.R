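#' Read a confidence-weighted interaction network
#'
#' Ingests an edge list in either tab-separated form (header columns
#' `protein_a`, `protein_b`, `confidence`) or the SIF dialect
#' `protein_a conf protein_b` (no header).  The result is a canonical
#' undirected graph: reversed duplicates are collapsed (keeping the
#' maximum confidence), self-loops are dropped with a warning, and any
#' confidence outside (0, 1] is an error — inputs are rejected, never
#' clamped.
#'
#' @param path path to the edge-list file; `.sif` selects the SIF
#'   dialect, anything else is read as TSV with a header.
#' @param min_conf edges with confidence strictly below this threshold
#'   are dropped after validation (default 0, keep all).
#' @param format `"auto"` (by extension), `"tsv"` or `"sif"`.
#' @return A [WeightedNetwork-class].
#' @seealso [writeNetwork()], [expandSubnetwork()]
#' @export
readNetwork <- function(path, min_conf = 0, format = c("auto", "tsv", "sif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "tsv") {
    if (length(lines) == 0) stop("empty network file: ", path)
    header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
    idx <- match(c("protein_a", "protein_b", "confidence"), header)
    if (anyNA(idx))
      stop("network TSV must have header columns protein_a, protein_b, ",
           "confidence")
    body <- lines[-1]
    rows <- strsplit(body, "\t", fixed = TRUE)
    lineno <- seq_along(body) + 1L
    bad <- lengths(rows) < max(idx)
    if (any(bad))
      stop("malformed network row at line ", lineno[which(bad)[1]])
    a <- vapply(rows, `[[`, "", idx[1])
    b <- vapply(rows, `[[`, "", idx[2])
    conf_chr <- vapply(rows, `[[`, "", idx[3])
  } else {
    rows <- strsplit(trimws(lines), "[ \t]+")
    lineno <- seq_along(lines)
    bad <- lengths(rows) != 3
    if (any(bad))
      stop("malformed SIF row at line ", lineno[which(bad)[1]])
    a <- vapply(rows, `[[`, "", 1)
    conf_chr <- vapply(rows, `[[`, "", 2)
    b <- vapply(rows, `[[`, "", 3)
    lineno <- lineno  # SIF has no header offset
  }
  conf <- suppressWarnings(as.numeric(conf_chr))
  if (anyNA(conf))
    stop("non-numeric confidence at line ", lineno[which(is.na(conf))[1]])
  if (any(conf <= 0 | conf > 1))
    stop("confidence outside (0, 1] at line ",
         lineno[which(conf <= 0 | conf > 1)[1]])
  net <- WeightedNetwork(data.frame(protein_a = a, protein_b = b,
                                    conf = conf))
  if (min_conf > 0) {
    ed <- networkEdges(net)
    net <- WeightedNetwork(ed[ed$conf >= min_conf, , drop = FALSE])
  }
  net
}

#' Write a network edge list
#'
#' @param network a [WeightedNetwork-class].
#' @param path output path.
#' @param format `"tsv"` (header protein_a/protein_b/confidence) or
#'   `"sif"` (`a conf b`).
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(network, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  ed <- networkEdges(network)
  if (format == "tsv") {
    out <- data.frame(protein_a = ed$protein_a, protein_b = ed$protein_b,
                      confidence = ed$conf)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    writeLines(paste(ed$protein_a, format(ed$conf, trim = TRUE),
                     ed$protein_b), path)
  }
  invisible(path)
}

#' Read a disease seed-gene list
#'
#' One gene id per line; blank lines and `#` comments are ignored.
#'
#' @param path path to the list.
#' @param disease disease name attached to the list.
#' @return A [SeedList-class].
#' @export
readSeedList <- function(path, disease = "disease") {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("seed list is empty: ", path)
  SeedList(lines, disease)
}

#' Read per-abstract directionality evidence
#'
#' TSV with header columns `drug`, `protein`, `pmid` (or `doc_id`) and
#' `direction`.  Direction may be coded numerically (-1/0/1) or with the
#' curation vocabulary (activation/up/up-regulated, inhibition/down/
#' down-regulated, indirect, ambiguous, unknown).  When no explicit
#' `category` column is present the category is inferred from the
#' direction word or code.
#'
#' @param path path to the evidence TSV.
#' @return data.frame with columns `drug`, `protein`, `doc_id`,
#'   `direction` (integer in -1/0/1) and `category`.
#' @seealso [aggregateDirection()], [aggregateAll()]
#' @export
readEvidence <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  if (nrow(df) == 0) return(emptyEvidence())
  if ("pmid" %in% names(df) && !"doc_id" %in% names(df))
    names(df)[names(df) == "pmid"] <- "doc_id"
  need <- c("drug", "protein", "doc_id", "direction")
  if (!all(need %in% names(df)))
    stop("evidence TSV must have columns drug, protein, pmid|doc_id, ",
         "direction")
  dir <- directionFromWord(df$direction)
  if (anyNA(dir))
    stop("unrecognised direction value(s): ",
         paste(unique(df$direction[is.na(dir)]), collapse = ", "))
  cat <- if ("category" %in% names(df))
    categoryFromWord(df$category, dir)
  else categoryFromWord(df$direction, dir)
  checkEvidence(data.frame(drug = df$drug, protein = df$protein,
                           doc_id = df$doc_id, direction = dir,
                           category = cat, stringsAsFactors = FALSE))
}

#' Read an expression-status table
#'
#' TSV with header `gene` plus either a `status` column
#' (over/under/unchanged) or a numeric `logFC` column, in which case a
#' symmetric threshold converts fold changes to statuses
#' (`logFC >= threshold` is over, `logFC <= -threshold` is under).
#'
#' @param path path to the TSV.
#' @param logfc_threshold positive threshold, required when the file
#'   carries `logFC` instead of `status`.
#' @return An [ExpressionProfile-class].
#' @export
readExpression <- function(path, logfc_threshold = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  if (!"gene" %in% names(df))
    stop("expression TSV must have a 'gene' column")
  if ("status" %in% names(df)) {
    status <- as.character(df$status)
    if (!all(status %in% EXPRESSION_STATES))
      stop("statuses must be over/under/unchanged")
  } else {
    fc_col <- intersect(c("logFC", "logfc", "log_fc"), names(df))
    if (length(fc_col) == 0)
      stop("expression TSV needs a 'status' or 'logFC' column")
    if (is.null(logfc_threshold) || logfc_threshold <= 0)
      stop("a positive logfc_threshold is required for logFC input")
    fc <- as.numeric(df[[fc_col[1]]])
    status <- ifelse(fc >= logfc_threshold, "over",
                     ifelse(fc <= -logfc_threshold, "under", "unchanged"))
  }
  ExpressionProfile(status, genes = as.character(df$gene))
}

#' Read / write a term-annotated abstract corpus (JSONL)
#'
#' One JSON object per line with fields `doc_id` (string), `drug_terms`
#' and `protein_terms` (arrays of strings, possibly empty).
#'
#' @param path path to the JSONL file.
#' @param label corpus label, `"retrieved"` or `"background"`.
#' @return `readCorpus`: a [Corpus-class]; `writeCorpus`: `path`,
#'   invisibly.
#' @export
readCorpus <- function(path, label = "retrieved") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("corpus file is empty: ", path)
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  ids <- vapply(recs, function(r) as.character(r$doc_id), "")
  grab <- function(r, f)
    if (is.null(r[[f]])) character() else as.character(r[[f]])
  Corpus(ids,
         lapply(recs, grab, "drug_terms"),
         lapply(recs, grab, "protein_terms"),
         label = label)
}

#' @rdname readCorpus
#' @param corpus a [Corpus-class] to serialise.
#' @export
writeCorpus <- function(corpus, path) {
  n <- length(corpus)
  lines <- vapply(seq_len(n), function(i) {
    jsonlite::toJSON(list(doc_id = docIDs(corpus)[i],
                          drug_terms = drugTerms(corpus)[[i]],
                          protein_terms = proteinTerms(corpus)[[i]]),
                     auto_unbox = TRUE)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Export a drug-target subnetwork with effect attributes
#'
#' Serialises the star graph of [buildDrugSubnetwork()]: the drug node
#' carries `shape = "hexagon"`, protein nodes carry their relevance
#' score `rp` (display size), expression `status` and a `color`
#' (over = red, under = green, unchanged = grey); edges carry the
#' `direction` and a `color` (activation = red, inhibition = green).
#'
#' @param assessment a [DrugEffectAssessment-class] with at least one
#'   pair.
#' @param path output path.
#' @param format `"graphml"` (round-trippable, attribute-preserving) or
#'   `"sif"` (`drug activates|inhibits|associates protein`).
#' @return `path`, invisibly.
#' @seealso [readSubnetwork()]
#' @export
writeSubnetwork <- function(assessment, path,
                            format = c("graphml", "sif")) {
  format <- match.arg(format)
  g <- buildDrugSubnetwork(assessment)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    pr <- effectPairs(assessment)
    word <- ifelse(pr$direction == 1L, "activates",
                   ifelse(pr$direction == -1L, "inhibits", "associates"))
    writeLines(paste(assessment@drug, word, pr$protein, sep = "\t"), path)
  }
  invisible(path)
}

#' Read back a GraphML drug-target subnetwork
#'
#' @param path path to a GraphML file written by [writeSubnetwork()].
#' @return an igraph graph with the node/edge attributes described in
#'   [writeSubnetwork()].
#' @export
readSubnetwork <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
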