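#' RunReport: the result of one pipeline run
#'
#' Carries the stage-by-stage funnel, the final marker table, the per-gene
#' elimination audit, the candidate set and any downstream results.
#'
#' @slot funnel data.frame: \code{stage}, \code{n_in}, \code{n_out},
#'   \code{n_eliminated}, \code{detail}.
#' @slot markers data.frame of final marker calls.
#' @slot audit data.frame: every union gene with its \code{fate}.
#' @slot candidates \linkS4class{CandidateSet}.
#' @slot extras list of optional downstream results (e.g. regulatory
#'   explanations).
#' @slot config list echoing the run parameters.
#' @exportClass RunReport
setClass("RunReport",
  representation(funnel = "data.frame", markers = "data.frame",
                 audit = "data.frame", candidates = "CandidateSet",
                 extras = "list", config = "list"))

setMethod("show", "RunReport", function(object) {
  cat("RunReport:", nrow(object@markers), "markers\n")
  f <- object@funnel
  for (i in seq_len(nrow(f)))
    cat(sprintf("  %-22s %5d -> %5d  (%s)\n", f$stage[i], f$n_in[i],
                f$n_out[i], f$detail[i]))
})

#' @rdname accessors
#' @param x a \code{RunReport}.
#' @export
setGeneric("markerCalls", function(x) standardGeneric("markerCalls"))
#' @rdname accessors
setMethod("markerCalls", "RunReport", function(x) x@markers)

#' Run the secretome marker-discovery pipeline
#'
#' Executes the full curation funnel on a simulated bundle (or explicit
#' inputs): threshold curation per condition, union with direction
#' concordance, restriction to the tissue-specific proteome, secretion
#' consensus classification and the final marker call. When miRNA target
#' sets and a TF table are available, regulatory-consistency explanations
#' for the called markers are appended to the report. The run is fully
#' deterministic given its inputs.
#'
#' @param x a \linkS4class{SimBundle}, or a \linkS4class{SecretomeTable}
#'   (then \code{annotations} and \code{bsp} must be supplied).
#' @param spec a \code{\link{thresholdSpec}}.
#' @param level threshold filter level, \code{"protein"} or \code{"gene"}.
#' @param annotations secretion annotation data.frame (ignored for bundles).
#' @param bsp BSP membership vector (ignored for bundles).
#' @param targets optional named list of miRNA target sets.
#' @param tfs optional TF regulation table.
#' @return A \linkS4class{RunReport}.
#' @export
runPipeline <- function(x, spec = thresholdSpec(),
                        level = c("protein", "gene"),
                        annotations = NULL, bsp = NULL,
                        targets = NULL, tfs = NULL) {
  level <- match.arg(level)
  if (is(x, "SimBundle")) {
    annotations <- x@annotations
    bsp <- x@bsp
    if (is.null(targets) && length(x@targets)) targets <- x@targets
    if (is.null(tfs) && nrow(x@tfs)) tfs <- x@tfs
    sec <- x@secretome
  } else {
    stopifnot(is(x, "SecretomeTable"))
    if (is.null(annotations) || is.null(bsp))
      stop("annotations and bsp are required when not running from a bundle")
    sec <- x
  }

  nIn <- nProteins(sec)
  cur <- curateSecretome(sec, spec, level)
  cand <- cur$candidates
  genes <- candidateGenes(cand)

  funnel <- data.frame(stage = "input", n_in = nIn, n_out = nIn,
                       n_eliminated = 0L,
                       detail = sprintf("%d protein IDs, %d mapped genes",
                                        nIn, length(geneSymbols(sec))),
                       stringsAsFactors = FALSE)
  nKept <- nIn - nrow(cur$excluded)
  funnel <- rbind(funnel, data.frame(
    stage = "unmapped_exclusion", n_in = nIn, n_out = nKept,
    n_eliminated = nrow(cur$excluded),
    detail = sprintf("%d protein IDs without gene symbol removed",
                     nrow(cur$excluded)), stringsAsFactors = FALSE))
  for (cond in names(cur$passes)) {
    np <- length(cur$passes[[cond]]$protein_ids)
    ng <- length(cur$passes[[cond]]$genes)
    funnel <- rbind(funnel, data.frame(
      stage = paste0("threshold_", cond), n_in = nKept, n_out = np,
      n_eliminated = nKept - np,
      detail = sprintf("%d proteins / %d genes pass in %s", np, ng, cond),
      stringsAsFactors = FALSE))
  }
  nUnionP <- length(unique(unlist(passingProteins(cand))))
  funnel <- rbind(funnel, data.frame(
    stage = "union", n_in = nKept, n_out = nUnionP,
    n_eliminated = nKept - nUnionP,
    detail = sprintf("union: %d proteins / %d genes", nUnionP, nrow(genes)),
    stringsAsFactors = FALSE))
  nConc <- sum(genes$direction != "discordant")
  funnel <- rbind(funnel, data.frame(
    stage = "concordance", n_in = nrow(genes), n_out = nConc,
    n_eliminated = nrow(genes) - nConc,
    detail = sprintf("%d up, %d down, %d discordant",
                     sum(genes$direction == "up"),
                     sum(genes$direction == "down"),
                     sum(genes$direction == "discordant")),
    stringsAsFactors = FALSE))

  bspRes <- filterBSP(genes$gene_symbol, bsp)
  funnel <- rbind(funnel, data.frame(
    stage = "bsp", n_in = nrow(genes), n_out = length(bspRes$retained),
    n_eliminated = nrow(bspRes$removed),
    detail = sprintf("%d genes in the tissue-specific proteome",
                     length(bspRes$retained)), stringsAsFactors = FALSE))

  calls <- classifySecretion(annotations)
  mk <- callMarkers(cand, bspRes$retained, calls)
  funnel <- rbind(funnel, data.frame(
    stage = "secretion", n_in = length(bspRes$retained),
    n_out = nrow(mk$markers),
    n_eliminated = length(bspRes$retained) - nrow(mk$markers),
    detail = sprintf("%d markers (%d classical, %d non-classical)",
                     nrow(mk$markers),
                     sum(mk$markers$secretion_class == "classical"),
                     sum(mk$markers$secretion_class == "non_classical")),
    stringsAsFactors = FALSE))

  extras <- list()
  if (!is.null(targets) && !is.null(tfs) && nrow(mk$markers))
    extras$regulatory <- explainMarkers(mk$markers, tfs, targets)

  new("RunReport", funnel = funnel, markers = mk$markers,
      audit = mk$audit, candidates = cand, extras = extras,
      config = list(threshold = unclass(spec), level = level))
}

#' Stage-by-stage funnel summary of a pipeline run
#'
#' @param report a \linkS4class{RunReport}.
#' @return data.frame: \code{stage}, \code{n_in}, \code{n_out},
#'   \code{n_eliminated}, \code{detail}.
#' @export
summarizeFunnel <- function(report) {
  stopifnot(is(report, "RunReport"))
  report@funnel
}
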