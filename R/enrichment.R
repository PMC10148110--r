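#' Read a GMT-format term collection
#'
#' Standard GMT: one term per line, tab-separated as
#' \code{term_id <TAB> description <TAB> gene1 <TAB> gene2 ...}.
#'
#' @param path path to the GMT file.
#' @param category one of \code{"cellular_component"},
#'   \code{"biological_process"}, \code{"molecular_function"},
#'   \code{"pathway"}; recorded on every term.
#' @return data.frame: \code{term_id}, \code{term_name}, \code{category},
#'   and a list column \code{genes} of case-normalised gene sets.
#' @export
readGmt <- function(path, category = c("pathway", "cellular_component",
                                       "biological_process",
                                       "molecular_function")) {
  category <- match.arg(category)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) stop("GMT line(s) with fewer than 3 fields: ",
                        paste(bad, collapse = ", "))
  out <- data.frame(term_id = vapply(parts, `[[`, character(1), 1),
                    term_name = vapply(parts, `[[`, character(1), 2),
                    category = category, stringsAsFactors = FALSE)
  out$genes <- lapply(parts, function(p) unique(normGene(p[-(1:2)])))
  out
}

#' Hypergeometric over-representation analysis
#'
#' For each term, tests whether the query gene set overlaps the term's gene
#' set more than expected by chance against the supplied universe, with the
#' one-sided (upper-tail) hypergeometric probability
#' \eqn{p = \sum_{i=k}^{\min(K,n)} {K \choose i}{N-K \choose n-i}/{N \choose n}}
#' where \eqn{k} is the overlap, \eqn{K} the term size within the universe,
#' \eqn{n} the query size and \eqn{N} the universe size. Term gene sets are
#' intersected with the universe before testing; p-values are BH-adjusted
#' across the tested terms.
#'
#' @param query character vector of gene symbols (must lie in the universe).
#' @param terms term collection from \code{\link{readGmt}} (or any data.frame
#'   with \code{term_id}, \code{term_name} and a \code{genes} list column).
#' @param universe character vector of background gene symbols.
#' @return data.frame sorted by p then term_id: \code{term_id},
#'   \code{term_name}, \code{k}, \code{K}, \code{n}, \code{N}, \code{p},
#'   \code{fdr}.
#' @export
enrich <- function(query, terms, universe) {
  query <- unique(normGene(query))
  query <- query[!is.na(query)]
  universe <- unique(normGene(universe))
  universe <- universe[!is.na(universe)]
  if (!length(query)) stop("empty query gene set")
  if (!length(universe)) stop("empty universe")
  extra <- setdiff(query, universe)
  if (length(extra))
    stop("query genes outside universe: ", paste(head(extra, 5), collapse = ", "))
  N <- length(universe)
  n <- length(query)
  res <- do.call(rbind, lapply(seq_len(nrow(terms)), function(i) {
    tg <- intersect(terms$genes[[i]], universe)
    K <- length(tg)
    k <- length(intersect(tg, query))
    # upper tail including k itself
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = terms$term_id[i], term_name = terms$term_name[i],
               k = k, K = K, n = n, N = N, p = min(p, 1),
               stringsAsFactors = FALSE)
  }))
  res$fdr <- bhFdr(res$p)
  res[order(res$p, res$term_id), , drop = FALSE]
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjustment with monotonicity enforcement, preserving the input
#' order. A thin wrapper over \code{stats::p.adjust(method = "BH")} that
#' additionally validates its input range.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted values, same length and order as \code{p}.
#' @export
bhFdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
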