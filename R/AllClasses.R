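#' SecretomeTable: a differential secretome protein table
#'
#' One row per mass-spectrometry protein ID, with an optional gene symbol and,
#' per experimental condition, a log2 fold change (case vs control) and a
#' -log10 FDR-corrected p-value. Columns follow the schema
#' \code{protein_id}, \code{gene_symbol}, then \code{log2fc_<cond>} and
#' \code{neglog10p_<cond>} for each condition.
#'
#' @slot records data.frame with the schema above.
#' @slot conditions character vector of condition names.
#' @exportClass SecretomeTable
setClass("SecretomeTable",
  representation(records = "data.frame", conditions = "character"))

setValidity("SecretomeTable", function(object) {
  rec <- object@records
  msgs <- character()
  if (!"protein_id" %in% names(rec)) msgs <- c(msgs, "missing column protein_id")
  if (!"gene_symbol" %in% names(rec)) msgs <- c(msgs, "missing column gene_symbol")
  if (length(object@conditions) < 1) msgs <- c(msgs, "at least one condition required")
  if ("protein_id" %in% names(rec)) {
    ids <- as.character(rec$protein_id)
    if (any(is.na(ids) | ids == ""))
      msgs <- c(msgs, "empty protein_id")
    dup <- ids[duplicated(ids)]
    if (length(dup))
      msgs <- c(msgs, paste0("duplicate protein_id: ",
                             paste(unique(dup), collapse = ", ")))
  }
  for (cond in object@conditions) {
    for (col in c(fcCol(cond), pCol(cond))) {
      if (!col %in% names(rec)) {
        msgs <- c(msgs, paste0("missing column ", col))
      } else {
        v <- rec[[col]]
        if (!is.numeric(v)) msgs <- c(msgs, paste0("non-numeric column ", col))
        else if (any(!is.na(v) & !is.finite(v)))
          msgs <- c(msgs, paste0("non-finite values in ", col))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SecretomeTable
#'
#' @param records data.frame with columns \code{protein_id},
#'   \code{gene_symbol} and per-condition \code{log2fc_<cond>},
#'   \code{neglog10p_<cond>}.
#' @param conditions character vector of condition names; if \code{NULL},
#'   inferred from the \code{log2fc_*} column names.
#' @return A \linkS4class{SecretomeTable}.
#' @examples
#' df <- data.frame(protein_id = c("P1", "P2"), gene_symbol = c("A", "B"),
#'                  log2fc_c1 = c(2, -2), neglog10p_c1 = c(0.5, 0.5))
#' SecretomeTable(df)
#' @export
SecretomeTable <- function(records, conditions = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (is.null(conditions)) {
    conditions <- sub("^log2fc_", "", grep("^log2fc_", names(records), value = TRUE))
    if (!length(conditions)) stop("no log2fc_<condition> columns found")
  }
  records$protein_id <- as.character(records$protein_id)
  records$gene_symbol <- normGene(records$gene_symbol)
  new("SecretomeTable", records = records, conditions = conditions)
}

#' CandidateSet: threshold-passing, direction-called candidate genes
#'
#' Result of combining per-condition threshold passes: the passing protein IDs
#' per condition, the union gene table with a per-gene direction call
#' (\code{up}, \code{down} or \code{discordant}), the protein-to-gene map of
#' the passers, and a provenance log.
#'
#' @slot passing named list, condition -> character vector of protein IDs.
#' @slot genes data.frame: \code{gene_symbol}, \code{direction},
#'   per-condition \code{mean_log2fc_<cond>}, \code{n_protein_ids}.
#' @slot proteinGenes data.frame mapping passing \code{protein_id} to
#'   \code{gene_symbol}.
#' @slot log character provenance messages.
#' @exportClass CandidateSet
setClass("CandidateSet",
  representation(passing = "list", genes = "data.frame",
                 proteinGenes = "data.frame", log = "character"))

setValidity("CandidateSet", function(object) {
  msgs <- character()
  need <- c("gene_symbol", "direction")
  if (!all(need %in% names(object@genes)))
    msgs <- c(msgs, "genes table needs gene_symbol and direction")
  else {
    if (!all(object@genes$direction %in% c("up", "down", "discordant")))
      msgs <- c(msgs, "direction must be up/down/discordant")
    mapped <- unique(object@proteinGenes$gene_symbol)
    orphan <- setdiff(object@genes$gene_symbol, mapped)
    if (length(orphan))
      msgs <- c(msgs, paste0("union gene without passing protein: ",
                             paste(orphan, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' SimBundle: a complete synthetic input bundle with planted ground truth
#'
#' Everything the pipeline consumes, generated from one \code{\link{simConfig}}:
#' the differential secretome table, the secretion annotation table, the
#' tissue-specific (BSP) membership vector, the per-miRNA predicted-target
#' sets, the marker transcription-factor table, and the emitted ground truth.
#'
#' @slot secretome \linkS4class{SecretomeTable}.
#' @slot annotations data.frame of per-gene secretion evidence.
#' @slot bsp character vector of BSP member genes.
#' @slot targets named list, miRNA id -> character vector of predicted targets.
#' @slot tfs data.frame: \code{marker}, \code{tf_symbol}, \code{sign}.
#' @slot truth list of planted signals (see \code{\link{simTruth}}).
#' @slot config the \code{\link{simConfig}} used.
#' @exportClass SimBundle
setClass("SimBundle",
  representation(secretome = "SecretomeTable", annotations = "data.frame",
                 bsp = "character", targets = "list", tfs = "data.frame",
                 truth = "list", config = "list"))

setValidity("SimBundle", function(object) {
  msgs <- character()
  tr <- object@truth
  if (!all(c("markers", "decoys") %in% names(tr)))
    msgs <- c(msgs, "truth must carry markers and decoys")
  genes <- geneSymbols(object@secretome)
  if (length(tr$markers$gene) && !all(tr$markers$gene %in% genes))
    msgs <- c(msgs, "planted marker missing from generated genes")
  if (length(msgs)) msgs else TRUE
})
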