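CLASSICAL_METHODS <- c("HPA", "MDSEC", "PHOBIUS", "SIGNALP", "SPOCTOPUS")

#' Read a secretion annotation table
#'
#' TSV schema: \code{gene_symbol}, \code{bsp_member} (0/1), one 0/1 column
#' per classical signal-peptide method (\code{hpa}, \code{mdsec},
#' \code{phobius}, \code{signalp}, \code{spoctopus}), and SecretomeP's
#' \code{secretomep_nn} and \code{secretomep_odds} (empty when absent).
#'
#' @param path path to the TSV.
#' @return data.frame with normalised gene symbols, logical method flags and
#'   numeric SecretomeP scores (NA when absent).
#' @export
readSecretionAnnotations <- function(path) {
  ann <- readTsv(path)
  need <- c("gene_symbol", "bsp_member", tolower(CLASSICAL_METHODS),
            "secretomep_nn", "secretomep_odds")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation table missing columns: ",
                         paste(miss, collapse = ", "))
  ann$gene_symbol <- normGene(ann$gene_symbol)
  for (col in c("bsp_member", tolower(CLASSICAL_METHODS)))
    ann[[col]] <- as.logical(as.integer(ann[[col]]))
  for (col in c("secretomep_nn", "secretomep_odds"))
    ann[[col]] <- suppressWarnings(as.numeric(ann[[col]]))
  ann
}

#' Filter candidate genes to a tissue-specific proteome
#'
#' Keeps the genes present in the supplied membership set (e.g. the
#' breast-specific proteome of a tissue expression atlas); the rest are
#' returned with an explicit removal reason.
#'
#' @param genes character vector of gene symbols.
#' @param bsp character vector of member gene symbols.
#' @return list: \code{retained} (character), \code{removed} (data.frame
#'   \code{gene_symbol}, \code{reason}).
#' @export
filterBSP <- function(genes, bsp) {
  genes <- normGene(genes)
  bsp <- normGene(bsp)
  if (!length(bsp))
    warning("empty tissue-proteome membership set; all genes removed")
  keep <- genes %in% bsp
  list(retained = genes[keep],
       removed = data.frame(gene_symbol = genes[!keep],
                            reason = rep("not in breast-specific proteome",
                                         sum(!keep)),
                            stringsAsFactors = FALSE))
}

#' SecretomeP non-classical secretion test
#'
#' Passes when the neural-network score strictly exceeds 0.6 and the odds
#' ratio strictly exceeds 3. Absent scores fail the test (with no error):
#' no data is treated as no non-classical evidence.
#'
#' @param nn neural-network score in [0, 1] (may be NA).
#' @param odds odds ratio >= 0 (may be NA).
#' @param nn_cut,odds_cut the strict cutoffs (defaults 0.6 and 3).
#' @return logical, vectorised over its inputs.
#' @examples
#' secretomePPass(0.8, 4)  # TRUE
#' secretomePPass(0.6, 4)  # FALSE: boundary excluded
#' @export
secretomePPass <- function(nn, odds, nn_cut = 0.6, odds_cut = 3) {
  ok <- !is.na(nn) & !is.na(odds) & is.finite(nn) & is.finite(odds)
  out <- logical(length(ok))
  out[ok] <- nn[ok] > nn_cut & odds[ok] > odds_cut
  out
}

#' Classify secretion evidence into classical / non-classical / none
#'
#' Classical evidence dominates: any hit among the five signal-peptide
#' methods makes the gene \code{classical}, even when SecretomeP also passes
#' (a protein found by both kinds of method is still a classically secreted
#' protein). \code{non_classical} is reserved for genes with no classical hit
#' but a SecretomeP pass; \code{none} means no evidence at all.
#'
#' @param ann data.frame as returned by
#'   \code{\link{readSecretionAnnotations}} (the \code{bsp_member} column is
#'   not consulted here).
#' @return data.frame: \code{gene_symbol}, \code{secretion_class},
#'   \code{classical_hits} (semicolon-joined method names),
#'   \code{secretomep_pass}.
#' @export
classifySecretion <- function(ann) {
  flagCols <- tolower(CLASSICAL_METHODS)
  miss <- setdiff(c("gene_symbol", flagCols, "secretomep_nn", "secretomep_odds"),
                  names(ann))
  if (length(miss)) stop("annotation table missing columns: ",
                         paste(miss, collapse = ", "))
  flags <- as.matrix(as.data.frame(lapply(ann[flagCols], function(v)
    !is.na(v) & as.logical(v))))
  nHits <- rowSums(flags)
  spPass <- secretomePPass(ann$secretomep_nn, ann$secretomep_odds)
  cls <- ifelse(nHits >= 1, "classical",
                ifelse(spPass, "non_classical", "none"))
  hits <- apply(flags, 1, function(f)
    paste(CLASSICAL_METHODS[f], collapse = ";"))
  data.frame(gene_symbol = normGene(ann$gene_symbol),
             secretion_class = cls,
             classical_hits = hits,
             secretomep_pass = spPass,
             stringsAsFactors = FALSE)
}

#' Call the final secretome markers
#'
#' A marker is a BSP-retained candidate gene with a concordant direction
#' (\code{up} or \code{down}) and a secretion class other than \code{none}.
#' Genes failing either requirement are returned in an audit table with the
#' stage at which they were eliminated.
#'
#' @param candidates a \linkS4class{CandidateSet} (direction calls).
#' @param retained character vector of BSP-retained gene symbols (from
#'   \code{\link{filterBSP}}).
#' @param calls secretion-class table from \code{\link{classifySecretion}}.
#' @return list: \code{markers} (data.frame \code{gene_symbol},
#'   \code{direction}, \code{secretion_class}, per-condition mean log2 FC),
#'   \code{audit} (every candidate gene with its \code{fate}).
#' @export
callMarkers <- function(candidates, retained, calls) {
  stopifnot(is(candidates, "CandidateSet"))
  genes <- candidateGenes(candidates)
  retained <- normGene(retained)
  cls <- calls$secretion_class[match(genes$gene_symbol, calls$gene_symbol)]
  cls[is.na(cls)] <- "none"
  fate <- ifelse(genes$direction == "discordant", "discordant_direction",
          ifelse(!genes$gene_symbol %in% retained, "not_in_bsp",
          ifelse(cls == "none", "no_secretion_evidence", "marker")))
  audit <- data.frame(gene_symbol = genes$gene_symbol,
                      direction = genes$direction,
                      secretion_class = cls,
                      fate = fate, stringsAsFactors = FALSE)
  markers <- genes[fate == "marker", , drop = FALSE]
  markers$secretion_class <- cls[fate == "marker"]
  rownames(markers) <- NULL
  list(markers = markers, audit = audit)
}
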