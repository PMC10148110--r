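# independent brute-force oracles used across the suite; each is written
# directly from the defining formula and never calls package internals

# exhaustive row scan of the fold-change / p-value threshold
scanOracle <- function(records, cond, fc_cut = 1.5, p_cut = 0.3) {
  out <- character(0)
  for (i in seq_len(nrow(records))) {
    fc <- records[[paste0("log2fc_", cond)]][i]
    p <- records[[paste0("neglog10p_", cond)]][i]
    if (!is.na(fc) && !is.na(p) && (fc > fc_cut || fc < -fc_cut) && p > p_cut)
      out <- c(out, records$protein_id[i])
  }
  out
}

# hypergeometric upper tail by enumerating all query-sized subsets
hyperOracle <- function(k, K, n, N) {
  universe <- seq_len(N)
  term <- seq_len(K)
  subsets <- utils::combn(universe, n)
  hits <- apply(subsets, 2, function(s) length(intersect(s, term)) >= k)
  mean(hits)
}

# Pearson r from the raw covariance / variance-ratio formula, p from the
# t transform
pearsonOracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# product-limit estimator coded independently: loop over distinct event
# times, multiplying (1 - d/n)
kmOracle <- function(time, event) {
  ts <- sort(unique(time[event]))
  s <- 1
  out <- data.frame(time = numeric(0), surv = numeric(0))
  for (t in ts) {
    n <- sum(time >= t)
    d <- sum(time == t & event)
    s <- s * (1 - d / n)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}

# log-rank O/E computation with the hypergeometric variance at each
# distinct event time
logrankOracle <- function(t1, e1, t2, e2) {
  times <- sort(unique(c(t1[e1], t2[e2])))
  O1 <- E1 <- V <- 0
  for (t in times) {
    n1 <- sum(t1 >= t); n2 <- sum(t2 >= t); n <- n1 + n2
    d1 <- sum(t1 == t & e1); d <- d1 + sum(t2 == t & e2)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chi2 <- (O1 - E1)^2 / V
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

# small random protein table builder for property tests
randomTable <- function(n = 40, conds = c("c1", "c2"), seed = 1) {
  set.seed(seed)
  df <- data.frame(protein_id = sprintf("P%03d", seq_len(n)),
                   gene_symbol = sample(sprintf("G%02d", seq_len(max(2, n %/% 3))),
                                        n, replace = TRUE),
                   stringsAsFactors = FALSE)
  for (cond in conds) {
    df[[paste0("log2fc_", cond)]] <- round(rnorm(n, 0, 2), 3)
    df[[paste0("neglog10p_", cond)]] <- round(rexp(n, 3), 3)
  }
  df
}

fixturePath <- function(name) {
  system.file("extdata", name, package = "secretoMiner", mustWork = TRUE)
}
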