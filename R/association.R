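#' Read an expression matrix with stratum labels
#'
#' TSV schema: samples in rows, one \code{sample_id} column, one
#' \code{stratum} column (subtype or group label) and one numeric column per
#' feature (markers, miRNAs). Values are expected on a log scale, typically
#' log2(TPM+1) or microarray intensity; the scale is recorded as an
#' attribute, never re-transformed.
#'
#' @param path path to the TSV.
#' @param scale label recorded on the result (default \code{"log2"}).
#' @return data.frame with \code{sample_id}, \code{stratum} and numeric
#'   feature columns; attribute \code{scale}.
#' @export
readExpressionMatrix <- function(path, scale = "log2") {
  df <- readTsv(path)
  if (!all(c("sample_id", "stratum") %in% names(df)))
    stop("expression table needs sample_id and stratum columns")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids")
  feat <- setdiff(names(df), c("sample_id", "stratum"))
  for (col in feat) df[[col]] <- as.numeric(df[[col]])
  attr(df, "scale") <- scale
  df
}

#' Score a miRNA cluster as the mean of its member expressions
#'
#' Genomically co-located miRNAs are transcribed together; a cluster's
#' expression is summarised as the unweighted arithmetic mean of its member
#' miRNA columns, per sample. Samples missing some member values are
#' averaged over the available members.
#'
#' @param mat expression data.frame (samples in rows, features in columns).
#' @param members character vector of member feature names (>= 1 present).
#' @return numeric vector, one score per sample.
#' @export
clusterScore <- function(mat, members) {
  present <- intersect(members, names(mat))
  if (!length(present))
    stop("no cluster member present in the matrix: ",
         paste(members, collapse = ", "))
  unname(rowMeans(as.matrix(mat[, present, drop = FALSE]), na.rm = TRUE))
}

#' Pearson correlation with a t-distribution p-value
#'
#' Sample Pearson r between paired vectors, with the two-sided p-value from
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom
#' (via \code{stats::cor.test}). Pairs with a missing value in either vector
#' are dropped (pairwise-complete), and the n actually used is reported.
#'
#' @param x,y numeric vectors of equal length.
#' @return list: \code{r}, \code{p}, \code{n}.
#' @export
pearsonCor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs (got ", n, ")")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant vector")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Subtype-stratified marker x miRNA-cluster correlations
#'
#' For every marker x cluster x stratum combination, computes the Pearson
#' correlation between the marker's expression and the cluster's mean score
#' within the stratum's samples. The plan maps stratum names to label values;
#' \code{NULL} means all samples (non-stratified). Raw p-values carry the
#' conventional star tiers (* <0.05, ** <0.01, *** <0.001); BH-adjusted
#' values over the whole table are appended as an extra column.
#'
#' @param mat expression data.frame with a \code{stratum} column.
#' @param markers character vector of marker feature names.
#' @param clusters named list: cluster id -> member feature names.
#' @param strataPlan named list: stratum name -> label values
#'   (\code{NULL} = all samples). Default: one non-stratified stratum.
#' @return data.frame: \code{marker}, \code{cluster}, \code{stratum},
#'   \code{n}, \code{r}, \code{p}, \code{tier}, \code{fdr}, \code{note}.
#'   Strata with fewer than 3 samples (or a constant vector) yield an NA row
#'   with the reason in \code{note}.
#' @export
stratifiedCorrelations <- function(mat, markers, clusters,
                                   strataPlan = list(`non-stratified` = NULL)) {
  scores <- lapply(clusters, function(mem) clusterScore(mat, mem))
  rows <- list()
  for (st in names(strataPlan)) {
    labels <- strataPlan[[st]]
    sel <- if (is.null(labels)) rep(TRUE, nrow(mat)) else mat$stratum %in% labels
    for (mk in markers) {
      for (cl in names(clusters)) {
        x <- mat[[mk]][sel]
        y <- scores[[cl]][sel]
        res <- tryCatch(pearsonCor(x, y), error = function(e)
          list(r = NA_real_, p = NA_real_, n = sum(is.finite(x) & is.finite(y)),
               note = conditionMessage(e)))
        rows[[length(rows) + 1L]] <- data.frame(
          marker = mk, cluster = cl, stratum = st,
          n = res$n, r = res$r, p = res$p,
          note = if (is.null(res$note)) "" else res$note,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$tier <- starTier(out$p)
  out$fdr <- bhFdr(out$p)
  out[c("marker", "cluster", "stratum", "n", "r", "p", "tier", "fdr", "note")]
}

#' Two-group t-test on expression values
#'
#' Unpaired two-tailed comparison of two groups, Welch's variant by default
#' (no equal-variance assumption); \code{variant = "student"} gives the
#' pooled-variance test.
#'
#' @param a,b numeric vectors (each n >= 2 finite values).
#' @param variant \code{"welch"} (default) or \code{"student"}.
#' @return list: \code{t}, \code{p}, \code{df}, \code{mean_a}, \code{mean_b}.
#' @export
twoGroupT <- function(a, b, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 finite values")
  tt <- t.test(a, b, var.equal = variant == "student",
               alternative = "two.sided", paired = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_a = mean(a), mean_b = mean(b))
}

#' Log2 fold-change summary between two groups
#'
#' On an already-log2 scale the summary is the difference of group means; on
#' a linear scale it is \code{log2((mean(case)+pc)/(mean(control)+pc))} with
#' pseudocount \code{pc}. The scale is declared, never guessed.
#'
#' @param case,control numeric vectors.
#' @param scale \code{"log2"} (default) or \code{"linear"}.
#' @param pseudocount added to both linear means (default 0).
#' @return Single numeric log2 fold change.
#' @examples
#' groupLog2FC(c(3, 3), c(1, 1))                    # 2 (log2 scale)
#' groupLog2FC(8, 2, scale = "linear")              # 2 = log2(4)
#' @export
groupLog2FC <- function(case, control, scale = c("log2", "linear"),
                        pseudocount = 0) {
  scale <- match.arg(scale)
  case <- case[is.finite(case)]; control <- control[is.finite(control)]
  if (!length(case) || !length(control)) stop("empty group")
  if (scale == "log2") {
    mean(case) - mean(control)
  } else {
    mc <- mean(case) + pseudocount
    m0 <- mean(control) + pseudocount
    if (mc <= 0 || m0 <= 0)
      stop("non-positive linear mean; supply a pseudocount")
    log2(mc / m0)
  }
}
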