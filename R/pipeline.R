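#' Pipeline run configuration
#'
#' Builds and validates the configuration for [runPipeline()].  All
#' numeric parameters are checked before any stage runs; defaults
#' mirror the published analysis (k = 2, one-hop expansion,
#' significance cut-off 0.05, neutrality band 0).
#'
#' @param network,seeds paths for the network-mining stage (optional).
#' @param retrieved,background,vocab paths for the literature-mining
#'   stage (optional).
#' @param evidence path to a per-abstract evidence TSV (optional).
#' @param annotations path to a pre-aggregated annotation TSV with
#'   columns drug/protein/direction and optionally r_p (optional;
#'   ignored when `evidence` is given).
#' @param expression path to an expression-status TSV (optional).
#' @param scores path to a protein/r_p TSV used when no ranking stage
#'   runs (optional).
#' @param drugs character vector of drugs to assess (optional).
#' @param out_dir output directory (created if missing).
#' @param k,depth,min_conf,n_samples,sample_size,alpha,tau,n_pairs,
#'   logfc_threshold numeric stage parameters.
#' @param seed integer seed for all stochastic stages.
#' @return a validated config list of class `netpharm_config`.
#' @export
runConfig <- function(network = NULL, seeds = NULL, retrieved = NULL,
                      background = NULL, vocab = NULL, evidence = NULL,
                      annotations = NULL, expression = NULL,
                      scores = NULL, drugs = NULL,
                      out_dir = tempfile("netpharm_run_"),
                      k = 2, depth = 1, min_conf = 0, n_samples = 100,
                      sample_size = NULL, alpha = 0.05, tau = 0,
                      n_pairs = 500, logfc_threshold = NULL,
                      seed = NULL) {
  cfg <- list(network = network, seeds = seeds, retrieved = retrieved,
              background = background, vocab = vocab,
              evidence = evidence, annotations = annotations,
              expression = expression, scores = scores, drugs = drugs,
              out_dir = out_dir, k = k, depth = depth,
              min_conf = min_conf, n_samples = n_samples,
              sample_size = sample_size, alpha = alpha, tau = tau,
              n_pairs = n_pairs, logfc_threshold = logfc_threshold,
              seed = seed)
  num <- c("k", "depth", "min_conf", "n_samples", "alpha", "tau",
           "n_pairs")
  for (nm in num)
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 ||
        !is.finite(cfg[[nm]]))
      stop("config parameter '", nm, "' must be a single number")
  if (cfg$depth < 0 || cfg$min_conf < 0 || cfg$tau < 0 ||
      cfg$alpha <= 0 || cfg$alpha >= 1 || cfg$n_samples < 2)
    stop("config parameter out of range")
  paths <- c("network", "seeds", "retrieved", "background", "vocab",
             "evidence", "annotations", "expression", "scores")
  for (nm in paths)
    if (!is.null(cfg[[nm]]) && !file.exists(cfg[[nm]]))
      stop("input file for '", nm, "' not found: ", cfg[[nm]])
  class(cfg) <- "netpharm_config"
  cfg
}

readAnnotationTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  need <- c("drug", "protein", "direction")
  if (!all(need %in% names(df)))
    stop("annotation TSV must have columns drug, protein, direction")
  df$direction <- as.integer(df$direction)
  if (!all(df$direction %in% c(-1L, 0L, 1L)))
    stop("annotation directions must be -1, 0 or +1")
  df
}

readScoresTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  if (!all(c("protein", "r_p") %in% names(df)))
    stop("scores TSV must have columns protein, r_p")
  out <- as.numeric(df$r_p)
  names(out) <- df$protein
  out
}

writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the end-to-end connectivity-map pipeline
#'
#' Executes whichever stages the configuration provides inputs for:
#' network mining (seed expansion + relevance ranking), literature
#' mining (drug enrichment), top-pair selection (when both rankings
#' exist and pair co-mention counts can be derived from the retrieved
#' corpus), directionality aggregation, and per-drug effect assessment
#' against an expression profile.  Every artifact is written to
#' `config$out_dir` and listed in `manifest.json` with its MD5
#' checksum, the package version, the seed and all parameters, so a
#' run is fully reproducible and auditable.
#'
#' @param config a `netpharm_config` from [runConfig()].
#' @return invisibly, a list with the in-memory results
#'   (`ranked`, `enrichment`, `pairs`, `annotations`, `assessments`)
#'   and the manifest.
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "netpharm_config"))
    config <- do.call(runConfig, config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  res <- list()
  emit <- function(name, path) {
    artifacts[[name]] <<- list(path = basename(path),
                               md5 = unname(tools::md5sum(path)))
  }

  if (!is.null(config$network)) {
    res$ranked <- stage("network-mining", {
      net <- readNetwork(config$network, min_conf = config$min_conf)
      sub <- if (!is.null(config$seeds)) {
        sl <- readSeedList(config$seeds)
        expandSubnetwork(sl, net, depth = config$depth)
      } else net
      suppressWarnings(rankProteins(sub, k = config$k,
                                    seeds = if (!is.null(config$seeds))
                                      readSeedList(config$seeds)))
    })
    p <- file.path(config$out_dir, "ranked_proteins.tsv")
    writeTSV(res$ranked, p); emit("ranked_proteins", p)
  }

  if (!is.null(config$retrieved) && !is.null(config$background) &&
      !is.null(config$vocab)) {
    res$enrichment <- stage("literature-mining", {
      vocab <- readLines(config$vocab)
      vocab <- vocab[nzchar(trimws(vocab))]
      enrichDrugs(readCorpus(config$retrieved, "retrieved"),
                  readCorpus(config$background, "background"),
                  vocab, n_samples = config$n_samples,
                  sample_size = config$sample_size,
                  seed = config$seed)
    })
    p <- file.path(config$out_dir, "drug_enrichment.tsv")
    writeTSV(res$enrichment, p); emit("drug_enrichment", p)
  }

  if (!is.null(res$ranked) && !is.null(res$enrichment)) {
    res$pairs <- stage("pair-selection", {
      co <- corpusPairCounts(readCorpus(config$retrieved, "retrieved"))
      selectTopPairs(res$ranked, res$enrichment, co, config$n_pairs)
    })
    p <- file.path(config$out_dir, "top_pairs.tsv")
    writeTSV(res$pairs, p); emit("top_pairs", p)
  }

  if (!is.null(config$evidence)) {
    res$annotations <- stage("directionality", {
      aggregateAll(readEvidence(config$evidence))
    })
    p <- file.path(config$out_dir, "annotations.tsv")
    writeTSV(res$annotations, p); emit("annotations", p)
  } else if (!is.null(config$annotations)) {
    res$annotations <- stage("directionality", {
      readAnnotationTable(config$annotations)
    })
  }

  if (!is.null(config$expression) && !is.null(config$drugs) &&
      !is.null(res$annotations)) {
    profile <- stage("drug-effect", {
      readExpression(config$expression,
                     logfc_threshold = config$logfc_threshold)
    })
    scores <- if (!is.null(config$scores))
      readScoresTable(config$scores)
    else if (!is.null(res$ranked)) {
      s <- res$ranked$r_p; names(s) <- res$ranked$protein; s
    } else if ("r_p" %in% names(res$annotations)) {
      s <- res$annotations$r_p; names(s) <- res$annotations$protein; s
    } else stop("[drug-effect] no relevance scores available")
    res$assessments <- lapply(config$drugs, function(d)
      stage("drug-effect",
            assessDrug(d, res$annotations, profile, scores,
                       tau = config$tau)))
    names(res$assessments) <- config$drugs
    for (d in config$drugs) {
      a <- res$assessments[[d]]
      p <- file.path(config$out_dir,
                     paste0("assessment_", gsub("\\W", "_", d), ".json"))
      jsonlite::write_json(list(drug = d,
                                counts = as.list(effectCounts(a)),
                                net_score = netScore(a),
                                overall = overallEffect(a),
                                pairs = effectPairs(a)),
                           p, auto_unbox = TRUE, digits = NA)
      emit(paste0("assessment_", d), p)
      g <- file.path(config$out_dir,
                     paste0("subnetwork_", gsub("\\W", "_", d),
                            ".graphml"))
      writeSubnetwork(a, g); emit(paste0("subnetwork_", d), g)
    }
  }

  manifest <- list(
    package = "netpharm",
    version = as.character(utils::packageVersion("netpharm")),
    seed = config$seed,
    parameters = config[c("k", "depth", "min_conf", "n_samples",
                          "sample_size", "alpha", "tau", "n_pairs")],
    artifacts = artifacts)
  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  res$manifest <- manifest
  invisible(res)
}

#' Drug-protein co-mention counts in a corpus
#'
#' Counts, for every (drug term, protein id) pair, the number of
#' documents annotated with both — the evidence base required of a
#' candidate pair before it can enter [selectTopPairs()].
#'
#' @param corpus a [Corpus-class].
#' @return data.frame with columns `drug`, `protein`, `n_docs`.
#' @export
corpusPairCounts <- function(corpus) {
  stopifnot(is(corpus, "Corpus"))
  dl <- drugTerms(corpus)
  pl <- proteinTerms(corpus)
  rows <- lapply(seq_along(dl), function(i) {
    if (length(dl[[i]]) == 0 || length(pl[[i]]) == 0) return(NULL)
    expand.grid(drug = dl[[i]], protein = pl[[i]],
                stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(data.frame(drug = character(), protein = character(),
                      n_docs = integer()))
  agg <- stats::aggregate(list(n_docs = rep(1L, nrow(rows))),
                          by = rows[c("drug", "protein")], FUN = sum)
  agg[order(agg$drug, agg$protein), , drop = FALSE]
}
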