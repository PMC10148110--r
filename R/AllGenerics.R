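#' Accessors for secretoMiner classes
#'
#' \code{conditions} returns the condition names of a table or bundle;
#' \code{nProteins} the number of protein rows; \code{geneSymbols} the
#' distinct mapped gene symbols; \code{records} the underlying data.frame;
#' \code{candidateGenes} the union gene table of a \linkS4class{CandidateSet};
#' \code{simTruth} the planted ground truth of a \linkS4class{SimBundle}.
#'
#' @param x a \linkS4class{SecretomeTable}, \linkS4class{CandidateSet} or
#'   \linkS4class{SimBundle}.
#' @return See details above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("conditions", function(x) standardGeneric("conditions"))
#' @rdname accessors
#' @export
setGeneric("nProteins", function(x) standardGeneric("nProteins"))
#' @rdname accessors
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))
#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("candidateGenes", function(x) standardGeneric("candidateGenes"))
#' @rdname accessors
#' @export
setGeneric("passingProteins", function(x) standardGeneric("passingProteins"))
#' @rdname accessors
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))

#' @rdname accessors
setMethod("conditions", "SecretomeTable", function(x) x@conditions)
#' @rdname accessors
setMethod("nProteins", "SecretomeTable", function(x) nrow(x@records))
#' @rdname accessors
setMethod("geneSymbols", "SecretomeTable", function(x) {
  g <- normGene(x@records$gene_symbol)
  unique(g[!is.na(g)])
})
#' @rdname accessors
setMethod("records", "SecretomeTable", function(x) x@records)
#' @rdname accessors
setMethod("candidateGenes", "CandidateSet", function(x) x@genes)
#' @rdname accessors
setMethod("passingProteins", "CandidateSet", function(x) x@passing)
#' @rdname accessors
setMethod("simTruth", "SimBundle", function(x) x@truth)
#' @rdname accessors
setMethod("conditions", "SimBundle", function(x) x@secretome@conditions)

setMethod("show", "SecretomeTable", function(object) {
  cat("SecretomeTable with", nrow(object@records), "protein IDs,",
      length(geneSymbols(object)), "mapped genes\n")
  cat("conditions:", paste(object@conditions, collapse = ", "), "\n")
})

setMethod("show", "CandidateSet", function(object) {
  dirs <- table(factor(object@genes$direction,
                       levels = c("up", "down", "discordant")))
  cat("CandidateSet:", nrow(object@genes), "union genes (",
      dirs[["up"]], "up,", dirs[["down"]], "down,",
      dirs[["discordant"]], "discordant )\n")
  for (cond in names(object@passing))
    cat("  ", cond, ": ", length(object@passing[[cond]]),
        " passing proteins\n", sep = "")
})

setMethod("show", "SimBundle", function(object) {
  cat("SimBundle:", nProteins(object@secretome), "protein IDs,",
      length(geneSymbols(object@secretome)), "genes,",
      nrow(object@truth$markers), "planted markers\n")
})
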