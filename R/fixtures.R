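#' Load a packaged case-study fixture
#'
#' The package ships small plain-text transcriptions of the published
#' breast-cancer case-study inputs, typed on load:
#' \describe{
#'   \item{`table3_tamoxifen_esr1`}{nine per-abstract evidence records
#'     for the Tamoxifen-ESR1 pair (7 inhibitory, 2 stimulatory), as an
#'     evidence data.frame.}
#'   \item{`table5_directionality`}{the 17 curated drug-protein rows
#'     (15 Tamoxifen partners, 2 Plicamycin partners) with published
#'     relevance scores, as a data.frame with columns `drug`,
#'     `protein`, `r_p`, `direction`.  The scores are fixture inputs
#'     from the source interaction database, not recomputable here.}
#'   \item{`luminalA_status`}{expression status of the fixture proteins
#'     in the luminal A subtype (over: ESR1, ERBB2; under: JUN, MYC;
#'     rest unchanged), as an [ExpressionProfile-class].}
#'   \item{`basal_status`}{expression status in the basal-like subtype
#'     (over: E2F1; under: JUN, IRS1; rest unchanged).}
#'   \item{`table4_performance`}{published benchmark metrics (percent)
#'     for nine cancers, as a data.frame.}
#' }
#'
#' @param name one of the fixture names above.
#' @return see the per-fixture descriptions.
#' @examples
#' nrow(loadFixture("table5_directionality"))  # 17
#' @export
loadFixture <- function(name = c("table3_tamoxifen_esr1",
                                 "table5_directionality",
                                 "luminalA_status", "basal_status",
                                 "table4_performance")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"),
                      package = "netpharm", mustWork = TRUE)
  switch(name,
    table3_tamoxifen_esr1 = readEvidence(path),
    table5_directionality = {
      df <- utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
      data.frame(drug = df$drug, protein = df$protein,
                 r_p = as.numeric(df$rp_score),
                 direction = as.integer(df$direction),
                 stringsAsFactors = FALSE)
    },
    luminalA_status = readExpression(path),
    basal_status = readExpression(path),
    table4_performance = utils::read.table(path, header = TRUE,
                                           sep = "\t",
                                           stringsAsFactors = FALSE))
}
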