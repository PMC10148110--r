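# internal helpers shared across modules

# Run `expr` under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Gene symbols are compared case-insensitively throughout; "" and NA both
# mean "no symbol".
normGene <- function(x) {
  x <- as.character(x)
  x[!is.na(x)] <- toupper(trimws(x[!is.na(x)]))
  x[x %in% ""] <- NA_character_
  x
}

isMissingGene <- function(x) is.na(normGene(x))

fcCol <- function(cond) paste0("log2fc_", cond)
pCol  <- function(cond) paste0("neglog10p_", cond)

readTsv <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# star tiers used in correlation reports: * <0.05, ** <0.01, *** <0.001
starTier <- function(p) {
  ifelse(is.na(p), "",
  ifelse(p < 0.001, "***",
  ifelse(p < 0.01, "**",
  ifelse(p < 0.05, "*", ""))))
}
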