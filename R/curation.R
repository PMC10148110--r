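#' Read a differential secretome table
#'
#' Reads a TSV with columns \code{protein_id}, \code{gene_symbol} and, per
#' condition, \code{log2fc_<cond>} and \code{neglog10p_<cond>}. Numeric
#' columns must parse; rows with unparseable numerics are reported by row
#' index in the error.
#'
#' @param path path to a TSV file.
#' @param conditions condition names; \code{NULL} infers them from the
#'   \code{log2fc_*} columns.
#' @return A \linkS4class{SecretomeTable}.
#' @export
readDifferentialTable <- function(path, conditions = NULL) {
  raw <- readTsv(path, colClasses = "character")
  if (!all(c("protein_id", "gene_symbol") %in% names(raw)))
    stop("required columns protein_id and gene_symbol not found in ", path)
  if (is.null(conditions)) {
    conditions <- sub("^log2fc_", "", grep("^log2fc_", names(raw), value = TRUE))
    if (!length(conditions)) stop("no log2fc_<condition> columns in ", path)
  }
  for (cond in conditions) {
    for (col in c(fcCol(cond), pCol(cond))) {
      if (!col %in% names(raw)) stop("missing required column ", col)
      v <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- which(is.na(v) & !is.na(raw[[col]]) &
                   !raw[[col]] %in% c("", "NA"))
      if (length(bad))
        stop("unparseable numeric in column ", col, " at row(s) ",
             paste(bad, collapse = ", "))
      raw[[col]] <- v
    }
  }
  dup <- unique(raw$protein_id[duplicated(raw$protein_id)])
  if (length(dup))
    stop("duplicate protein_id: ", paste(dup, collapse = ", "))
  SecretomeTable(raw, conditions)
}

#' Write a differential secretome table to TSV
#'
#' Inverse of \code{\link{readDifferentialTable}}; round-trips losslessly up
#' to numeric printing precision (15 significant digits are written).
#'
#' @param x a \linkS4class{SecretomeTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDifferentialTable <- function(x, path) {
  stopifnot(is(x, "SecretomeTable"))
  rec <- x@records
  num <- vapply(rec, is.numeric, logical(1))
  rec[num] <- lapply(rec[num], function(v) format(v, digits = 15, trim = TRUE,
                                                  scientific = FALSE))
  writeTsv(rec, path)
}

#' Exclude protein IDs without a gene symbol
#'
#' Protein IDs that could not be mapped to a gene symbol carry no gene-level
#' information and are removed before aggregation, mirroring the standard
#' practice of dropping identifier-less hits from curation.
#'
#' @param x a \linkS4class{SecretomeTable}.
#' @return A list with \code{kept} (a \linkS4class{SecretomeTable}),
#'   \code{excluded} (data.frame of removed records) and \code{log}
#'   (counts as a character message).
#' @export
excludeUnmapped <- function(x) {
  stopifnot(is(x, "SecretomeTable"))
  rec <- x@records
  miss <- isMissingGene(rec$gene_symbol)
  kept <- rec[!miss, , drop = FALSE]
  excluded <- rec[miss, , drop = FALSE]
  rownames(kept) <- rownames(excluded) <- NULL
  list(kept = SecretomeTable(kept, x@conditions),
       excluded = excluded,
       log = sprintf("excluded %d of %d protein IDs with no gene symbol",
                     nrow(excluded), nrow(rec)))
}

#' Aggregate protein-level records to gene level
#'
#' Several protein IDs can map to the same gene; their per-condition log2
#' fold changes and -log10 p-values are combined by the unweighted arithmetic
#' mean. Gene symbols are case-normalised before grouping. Values missing for
#' some IDs of a gene are averaged over the available IDs, with the count of
#' such genes reported in the \code{log} attribute.
#'
#' @param x a \linkS4class{SecretomeTable} with all records mapped (run
#'   \code{\link{excludeUnmapped}} first).
#' @return data.frame with one row per gene: \code{gene_symbol},
#'   per-condition \code{mean_log2fc_<cond>} and \code{mean_neglog10p_<cond>},
#'   \code{n_protein_ids}, \code{protein_ids} (semicolon-joined).
#' @export
aggregateByGene <- function(x) {
  stopifnot(is(x, "SecretomeTable"))
  rec <- x@records
  if (any(isMissingGene(rec$gene_symbol)))
    stop("records with missing gene symbols present; run excludeUnmapped first")
  gene <- normGene(rec$gene_symbol)
  idx <- split(seq_len(nrow(rec)), gene)
  genes <- names(idx)
  out <- data.frame(gene_symbol = genes, stringsAsFactors = FALSE)
  n_partial <- 0L
  for (cond in x@conditions) {
    for (col in c(fcCol(cond), pCol(cond))) {
      v <- rec[[col]]
      m <- vapply(idx, function(i) mean(v[i], na.rm = TRUE), numeric(1))
      m[is.nan(m)] <- NA_real_
      n_partial <- n_partial +
        sum(vapply(idx, function(i) any(is.na(v[i])) && !all(is.na(v[i])),
                   logical(1)))
      out[[sub("^(log2fc|neglog10p)_", "mean_\\1_", col)]] <- m
    }
  }
  out$n_protein_ids <- lengths(idx)
  out$protein_ids <- vapply(idx, function(i)
    paste(rec$protein_id[i], collapse = ";"), character(1))
  rownames(out) <- NULL
  attr(out, "log") <- sprintf(
    "aggregated %d protein IDs into %d genes (%d gene/condition cells averaged over partial data)",
    nrow(rec), nrow(out), n_partial)
  out
}

#' Derive a p-value cutoff from a percentile of the data
#'
#' Returns the value below which \code{percentile} percent of the supplied
#' -log10 p-values lie, using the linear-interpolation quantile (type 7).
#' Used to translate an empirical percentile (e.g. the top 8 percent of the
#' evidence distribution) into a reusable -log10 p cutoff.
#'
#' @param values numeric vector of -log10 p-values.
#' @param percentile percentage in (0, 100); default 92.
#' @return The cutoff, a single number.
#' @examples
#' derivePCutoff(seq(0, 1, by = 0.01), 92)  # 0.92
#' @export
derivePCutoff <- function(values, percentile = 92) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values to take a percentile of")
  if (!is.numeric(percentile) || percentile <= 0 || percentile >= 100)
    stop("percentile must lie in (0, 100)")
  unname(quantile(values, probs = percentile / 100, type = 7))
}

#' Threshold specification for differential filtering
#'
#' A protein (or gene) passes when \code{log2fc > log2_fc_cut} or
#' \code{log2fc < -log2_fc_cut}, and \code{neglog10p > neg_log10_p_cut};
#' both inequalities are strict, so boundary rows are excluded.
#'
#' @param log2_fc_cut positive fold-change cut (default 1.5).
#' @param neg_log10_p_cut positive -log10 p cut (default 0.3).
#' @return An object of class \code{ThresholdSpec}.
#' @export
thresholdSpec <- function(log2_fc_cut = 1.5, neg_log10_p_cut = 0.3) {
  if (!is.numeric(log2_fc_cut) || log2_fc_cut <= 0 ||
      !is.numeric(neg_log10_p_cut) || neg_log10_p_cut <= 0)
    stop("threshold cuts must be positive")
  structure(list(log2_fc_cut = log2_fc_cut,
                 neg_log10_p_cut = neg_log10_p_cut),
            class = "ThresholdSpec")
}

#' Apply the fold-change / p-value threshold in one condition
#'
#' A row passes iff its absolute log2 fold change strictly exceeds the cut
#' and its -log10 p strictly exceeds the p cut. At \code{level = "protein"}
#' the filter runs on protein rows and induces the gene set from the passing
#' rows; at \code{level = "gene"} it runs on gene-level means (the table from
#' \code{\link{aggregateByGene}}).
#'
#' @param x a \linkS4class{SecretomeTable} (protein level) or a gene table
#'   from \code{\link{aggregateByGene}} (gene level).
#' @param condition condition name.
#' @param spec a \code{\link{thresholdSpec}}.
#' @param level \code{"protein"} (default) or \code{"gene"}.
#' @return list: \code{protein_ids} (character; empty at gene level),
#'   \code{genes} (character), \code{n_boundary} (rows exactly at a cut).
#' @export
applyThreshold <- function(x, condition, spec = thresholdSpec(),
                           level = c("protein", "gene")) {
  level <- match.arg(level)
  stopifnot(inherits(spec, "ThresholdSpec"))
  if (level == "protein") {
    stopifnot(is(x, "SecretomeTable"))
    if (!condition %in% x@conditions)
      stop("unknown condition: ", condition)
    rec <- x@records
    fc <- rec[[fcCol(condition)]]
    p <- rec[[pCol(condition)]]
    pass <- !is.na(fc) & !is.na(p) &
      (fc > spec$log2_fc_cut | fc < -spec$log2_fc_cut) &
      p > spec$neg_log10_p_cut
    boundary <- sum(abs(fc) == spec$log2_fc_cut | p == spec$neg_log10_p_cut,
                    na.rm = TRUE)
    genes <- normGene(rec$gene_symbol[pass])
    list(protein_ids = rec$protein_id[pass],
         genes = unique(genes[!is.na(genes)]),
         n_boundary = boundary)
  } else {
    fccol <- paste0("mean_", fcCol(condition))
    pcol <- paste0("mean_", pCol(condition))
    if (!all(c(fccol, pcol) %in% names(x)))
      stop("unknown condition: ", condition)
    fc <- x[[fccol]]
    p <- x[[pcol]]
    pass <- !is.na(fc) & !is.na(p) &
      (fc > spec$log2_fc_cut | fc < -spec$log2_fc_cut) &
      p > spec$neg_log10_p_cut
    boundary <- sum(abs(fc) == spec$log2_fc_cut | p == spec$neg_log10_p_cut,
                    na.rm = TRUE)
    list(protein_ids = character(0),
         genes = x$gene_symbol[pass],
         n_boundary = boundary)
  }
}

#' Combine per-condition threshold passes into a candidate set
#'
#' Takes the union of passing proteins/genes across conditions and calls a
#' per-gene direction from the sign of the gene-level mean log2 fold change
#' in every condition: all positive means give \code{up}, all negative give
#' \code{down}, anything else \code{discordant}. Discordant genes stay in the
#' set, flagged, but are barred from marker candidacy downstream.
#'
#' @param passes named list (condition -> result of
#'   \code{\link{applyThreshold}}) covering at least one condition.
#' @param geneTable gene-level table from \code{\link{aggregateByGene}}.
#' @param proteinGenes data.frame mapping \code{protein_id} to
#'   \code{gene_symbol} (the records of the filtered table); used for
#'   provenance. May be \code{NULL} at gene-level filtering.
#' @return A \linkS4class{CandidateSet}.
#' @export
combineSecretomes <- function(passes, geneTable, proteinGenes = NULL) {
  if (!length(passes)) stop("no conditions processed")
  conds <- names(passes)
  unionGenes <- sort(unique(as.character(unlist(lapply(passes, `[[`, "genes")))))
  gt <- geneTable[match(unionGenes, geneTable$gene_symbol), , drop = FALSE]
  fcCols <- paste0("mean_", vapply(conds, fcCol, character(1)))
  signs <- as.matrix(gt[, fcCols, drop = FALSE])
  direction <- apply(signs, 1, function(s) {
    if (all(!is.na(s)) && all(s > 0)) "up"
    else if (all(!is.na(s)) && all(s < 0)) "down"
    else "discordant"
  })
  genes <- data.frame(gene_symbol = unionGenes,
                      direction = as.character(direction),
                      stringsAsFactors = FALSE)
  for (i in seq_along(conds))
    genes[[fcCols[i]]] <- signs[, i]
  genes$n_protein_ids <- gt$n_protein_ids
  passing <- lapply(passes, `[[`, "protein_ids")
  if (is.null(proteinGenes)) {
    # gene-level filtering: map every union gene to a pseudo-entry so the
    # validity invariant (each gene backed by a passer) still holds
    proteinGenes <- data.frame(protein_id = if (length(unionGenes))
                                 paste0("gene:", unionGenes) else character(0),
                               gene_symbol = unionGenes,
                               stringsAsFactors = FALSE)
  } else {
    allPass <- unique(unlist(passing))
    proteinGenes <- proteinGenes[proteinGenes$protein_id %in% allPass,
                                 c("protein_id", "gene_symbol"), drop = FALSE]
    proteinGenes$gene_symbol <- normGene(proteinGenes$gene_symbol)
  }
  log <- c(sprintf("union: %d proteins, %d genes",
                   length(unique(unlist(passing))), length(unionGenes)),
           sprintf("directions: %d up, %d down, %d discordant",
                   sum(direction == "up"), sum(direction == "down"),
                   sum(direction == "discordant")))
  new("CandidateSet", passing = passing, genes = genes,
      proteinGenes = proteinGenes, log = log)
}

#' Run the full threshold curation over all conditions
#'
#' Convenience wrapper: excludes unmapped protein IDs, aggregates to gene
#' level, applies the threshold in every condition and combines the results
#' into a \linkS4class{CandidateSet}.
#'
#' @param x a \linkS4class{SecretomeTable}.
#' @param spec a \code{\link{thresholdSpec}}.
#' @param level filter level, \code{"protein"} or \code{"gene"}.
#' @return list: \code{candidates} (\linkS4class{CandidateSet}),
#'   \code{geneTable}, \code{excluded} (unmapped records), \code{passes}.
#' @export
curateSecretome <- function(x, spec = thresholdSpec(),
                            level = c("protein", "gene")) {
  level <- match.arg(level)
  ex <- excludeUnmapped(x)
  geneTable <- aggregateByGene(ex$kept)
  target <- if (level == "protein") ex$kept else geneTable
  passes <- lapply(setNames(x@conditions, x@conditions), function(cond)
    applyThreshold(target, cond, spec, level))
  pg <- if (level == "protein") records(ex$kept) else NULL
  cand <- combineSecretomes(passes, geneTable, pg)
  list(candidates = cand, geneTable = geneTable,
       excluded = ex$excluded, passes = passes)
}
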