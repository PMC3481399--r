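# Evaluate expr under a fixed RNG seed, restoring global RNG state after.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Canonical direction vocabulary -> {+1, -1, 0} and evidence category.
directionFromWord <- function(word) {
  raw <- trimws(tolower(word))
  w <- gsub("[^a-z]", "", raw)
  up <- c("activation", "activate", "activates", "up", "upregulated",
          "upregulation")
  down <- c("inhibition", "inhibit", "inhibits", "down", "downregulated",
            "downregulation")
  zero <- c("indirect", "indirectyes", "ambiguous", "unknown")
  ifelse(raw %in% c("1", "+1"), 1L,
         ifelse(raw == "-1", -1L,
                ifelse(raw == "0", 0L,
                       ifelse(w %in% up, 1L,
                              ifelse(w %in% down, -1L,
                                     ifelse(w %in% zero, 0L,
                                            NA_integer_))))))
}

categoryFromWord <- function(word, direction) {
  w <- gsub("[^a-z]", "", tolower(word))
  cat <- rep(NA_character_, length(w))
  cat[w %in% c("indirect", "indirectyes")] <- "indirect"
  cat[w == "ambiguous"] <- "ambiguous"
  cat[w == "unknown"] <- "unknown"
  miss <- is.na(cat)
  cat[miss] <- categoryFromDirection(direction[miss])
  cat
}

categoryFromDirection <- function(direction) {
  ifelse(direction == 1L, "activation",
         ifelse(direction == -1L, "inhibition", "unknown"))
}

# Validate an evidence record table (drug, protein, doc_id, direction,
# category); returns the table with canonical column types.
checkEvidence <- function(records) {
  need <- c("drug", "protein", "doc_id", "direction", "category")
  if (!all(need %in% names(records)))
    stop("evidence table must have columns ",
         paste(need, collapse = ", "))
  records$direction <- as.integer(records$direction)
  if (nrow(records) > 0) {
    if (!all(records$direction %in% c(-1L, 0L, 1L)))
      stop("directions must be -1, 0 or +1")
    if (!all(records$category %in% EVIDENCE_CATEGORIES))
      stop("unknown evidence category")
    ok <- (records$direction == 1L) == (records$category == "activation") &
      (records$direction == -1L) == (records$category == "inhibition")
    if (!all(ok))
      stop("direction/category mismatch in evidence records")
  }
  records
}

emptyEvidence <- function() {
  data.frame(drug = character(), protein = character(),
             doc_id = character(), direction = integer(),
             category = character(), stringsAsFactors = FALSE)
}
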