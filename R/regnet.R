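#' Read per-miRNA predicted target sets
#'
#' TSV schema: \code{mirna_id}, \code{gene_symbol}; one row per predicted
#' target. Gene symbols are case-normalised.
#'
#' @param path path to the TSV.
#' @return Named list: miRNA id -> character vector of target genes.
#' @export
readTargetSets <- function(path) {
  df <- readTsv(path)
  if (!all(c("mirna_id", "gene_symbol") %in% names(df)))
    stop("target-set table needs columns mirna_id and gene_symbol")
  lapply(split(normGene(df$gene_symbol), df$mirna_id), function(g)
    unique(g[!is.na(g)]))
}

#' Read a marker transcription-factor regulation table
#'
#' TSV schema: \code{marker}, \code{tf_symbol}, \code{sign} with sign in
#' \code{positive}/\code{negative}/\code{dual}. \code{dual} records a TF
#' reported with both activating and repressing roles.
#'
#' @param path path to the TSV.
#' @return data.frame with one row per (marker, tf) pair.
#' @export
readTFTable <- function(path) {
  df <- readTsv(path)
  need <- c("marker", "tf_symbol", "sign")
  if (!all(need %in% names(df)))
    stop("TF table needs columns ", paste(need, collapse = ", "))
  df$marker <- normGene(df$marker)
  df$tf_symbol <- normGene(df$tf_symbol)
  df$sign <- tolower(df$sign)
  if (!all(df$sign %in% c("positive", "negative", "dual")))
    stop("sign must be positive, negative or dual")
  if (anyDuplicated(df[c("marker", "tf_symbol")]))
    stop("duplicate (marker, tf) rows")
  df
}

#' Intersect two miRNA predicted-target sets
#'
#' @param a,b character vectors of predicted target genes.
#' @return list: \code{n_a}, \code{n_b}, \code{common} (sorted character
#'   vector), \code{n_common}.
#' @export
commonTargets <- function(a, b) {
  a <- unique(normGene(a)); a <- a[!is.na(a)]
  b <- unique(normGene(b)); b <- b[!is.na(b)]
  common <- sort(intersect(a, b))
  list(n_a = length(a), n_b = length(b),
       common = common, n_common = length(common))
}

#' Cross-reference a marker's transcription factors with a miRNA target set
#'
#' Returns the marker's TFs that are themselves predicted targets of the
#' miRNA(s), preserving the sign annotation. A marker absent from the TF
#' table yields an empty result with a warning.
#'
#' @param marker gene symbol of the marker.
#' @param tfTable TF regulation table (see \code{\link{readTFTable}}).
#' @param targets character vector of predicted target genes.
#' @return data.frame: \code{tf_symbol}, \code{sign} for the targeted TFs.
#' @export
xrefTFs <- function(marker, tfTable, targets) {
  marker <- normGene(marker)
  rows <- tfTable[tfTable$marker %in% marker, , drop = FALSE]
  if (!nrow(rows)) {
    warning("marker ", marker, " absent from TF table")
    return(data.frame(tf_symbol = character(0), sign = character(0),
                      stringsAsFactors = FALSE))
  }
  targets <- normGene(targets)
  hit <- rows$tf_symbol %in% targets
  out <- rows[hit, c("tf_symbol", "sign"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Explain a marker's direction from its miRNA-targeted transcription factors
#'
#' A miRNA suppresses its targets. If a marker's negative-regulator TF is a
#' miRNA target, losing that repressor explains marker upregulation;
#' conversely a targeted positive regulator explains downregulation. TFs
#' annotated \code{dual} can explain either direction and are kept flagged
#' so they are never mistaken for unambiguous evidence.
#'
#' @param marker marker gene symbol.
#' @param direction \code{"up"} or \code{"down"} (the marker's concordant
#'   direction call; discordant markers are rejected).
#' @param targetedTFs data.frame \code{tf_symbol}, \code{sign} from
#'   \code{\link{xrefTFs}}.
#' @param mirna label of the target set used (e.g. an miRNA id or
#'   \code{"common"}); recorded in the result.
#' @return list of class \code{RegulatoryExplanation}: \code{marker},
#'   \code{direction}, \code{mirna}, \code{targeted_tfs} (data.frame),
#'   \code{explaining_tfs} (data.frame subset), \code{consistent} (logical).
#' @export
explainDirection <- function(marker, direction, targetedTFs,
                             mirna = "common") {
  if (!direction %in% c("up", "down"))
    stop("direction must be 'up' or 'down' (got ", direction, ")")
  want <- if (direction == "up") c("negative", "dual") else c("positive", "dual")
  expl <- targetedTFs[targetedTFs$sign %in% want, , drop = FALSE]
  rownames(expl) <- NULL
  structure(list(marker = normGene(marker), direction = direction,
                 mirna = mirna, targeted_tfs = targetedTFs,
                 explaining_tfs = expl, consistent = nrow(expl) > 0),
            class = "RegulatoryExplanation")
}

#' @export
print.RegulatoryExplanation <- function(x, ...) {
  cat("RegulatoryExplanation:", x$marker, "(", x$direction, ") vs",
      x$mirna, "targets\n")
  cat("  targeted TFs:",
      if (nrow(x$targeted_tfs))
        paste0(x$targeted_tfs$tf_symbol, "[", x$targeted_tfs$sign, "]",
               collapse = " ") else "(none)", "\n")
  cat("  explaining:",
      if (nrow(x$explaining_tfs))
        paste(x$explaining_tfs$tf_symbol, collapse = ", ") else "(none)",
      "->", if (x$consistent) "consistent" else "not consistent", "\n")
  invisible(x)
}

#' Flag a marker as a predicted direct miRNA target
#'
#' Membership test of the marker in each miRNA's predicted-target set. A
#' direct target that is nonetheless upregulated is flagged as a
#' post-transcriptional anomaly: suppression by the miRNA would predict the
#' opposite, so the observed direction must arise downstream of transcript
#' targeting.
#'
#' @param marker marker gene symbol.
#' @param targetSets named list, miRNA id -> target gene vector.
#' @param direction the marker's direction (\code{"up"}/\code{"down"}), used
#'   for the anomaly flag; \code{NULL} skips it.
#' @return list: \code{direct} (named logical per miRNA), \code{anomaly}
#'   (named logical; direct target yet upregulated).
#' @export
flagDirectTarget <- function(marker, targetSets, direction = NULL) {
  marker <- normGene(marker)
  direct <- vapply(targetSets, function(tg) marker %in% normGene(tg),
                   logical(1))
  anomaly <- if (!is.null(direction)) direct & direction == "up"
             else setNames(rep(FALSE, length(direct)), names(direct))
  list(direct = direct, anomaly = anomaly)
}

#' Regulatory-consistency report for a marker table
#'
#' Runs \code{\link{xrefTFs}}, \code{\link{explainDirection}} and
#' \code{\link{flagDirectTarget}} for every marker, both against the common
#' target set of all miRNAs and against each miRNA's own target set.
#'
#' @param markers data.frame with \code{gene_symbol} and \code{direction}
#'   (\code{up}/\code{down}).
#' @param tfTable TF regulation table.
#' @param targetSets named list of per-miRNA target gene vectors (>= 1).
#' @return data.frame, one row per marker x target-set mode: \code{marker},
#'   \code{direction}, \code{mirna}, \code{targeted_tfs},
#'   \code{explaining_tfs} (semicolon-joined), \code{consistent},
#'   \code{direct_target}, \code{anomaly}.
#' @export
explainMarkers <- function(markers, tfTable, targetSets) {
  modes <- targetSets
  if (length(targetSets) > 1)
    modes <- c(list(common = Reduce(intersect, lapply(targetSets, normGene))),
               targetSets)
  rows <- list()
  for (i in seq_len(nrow(markers))) {
    m <- markers$gene_symbol[i]
    dir <- markers$direction[i]
    for (mode in names(modes)) {
      targeted <- suppressWarnings(xrefTFs(m, tfTable, modes[[mode]]))
      ex <- explainDirection(m, dir, targeted, mirna = mode)
      flags <- flagDirectTarget(m, modes[mode], dir)
      direct <- unname(flags$direct[1])
      anom <- unname(flags$anomaly[1])
      rows[[length(rows) + 1L]] <- data.frame(
        marker = m, direction = dir, mirna = mode,
        targeted_tfs = paste(targeted$tf_symbol, collapse = ";"),
        explaining_tfs = paste(ex$explaining_tfs$tf_symbol, collapse = ";"),
        consistent = ex$consistent,
        direct_target = direct, anomaly = anom,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(marker = character(0), direction = character(0),
                      mirna = character(0), targeted_tfs = character(0),
                      explaining_tfs = character(0), consistent = logical(0),
                      direct_target = logical(0), anomaly = logical(0)))
  do.call(rbind, rows)
}
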