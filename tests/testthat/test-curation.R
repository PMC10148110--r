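test_that("differential tables round-trip through TSV and reject bad input", {
  df <- randomTable(12, seed = 3)
  tab <- SecretomeTable(df)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeDifferentialTable(tab, path)
  back <- readDifferentialTable(path)
  expect_equal(records(back)$protein_id, records(tab)$protein_id)
  for (col in grep("log2fc|neglog10p", names(df), value = TRUE))
    expect_equal(records(back)[[col]], records(tab)[[col]], tolerance = 1e-12)

  dup <- df
  dup$protein_id[2] <- dup$protein_id[1]
  expect_error(SecretomeTable(dup), "duplicate protein_id.*P001")

  bad <- df
  bad$log2fc_c1 <- as.character(bad$log2fc_c1)
  bad$log2fc_c1[5] <- "oops"
  badpath <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, badpath, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readDifferentialTable(badpath), "row\\(s\\) 5")
})

test_that("unmapped protein IDs are excluded and the partition is exact", {
  df <- randomTable(10, seed = 4)
  df$gene_symbol[c(2, 7)] <- c("", NA)
  res <- excludeUnmapped(SecretomeTable(df))
  expect_equal(nProteins(res$kept), 8)
  expect_equal(nrow(res$excluded), 2)
  expect_setequal(c(records(res$kept)$protein_id, res$excluded$protein_id),
                  df$protein_id)
  allMapped <- excludeUnmapped(SecretomeTable(randomTable(6, seed = 5)))
  expect_equal(nrow(allMapped$excluded), 0)
})

test_that("gene aggregation takes arithmetic means and is order-invariant", {
  df <- data.frame(protein_id = c("A", "B", "C"),
                   gene_symbol = c("g1", "G1", "G2"),
                   log2fc_c1 = c(1, 2, 5), neglog10p_c1 = c(0.2, 0.4, 0.9))
  agg <- aggregateByGene(SecretomeTable(df))
  expect_equal(nrow(agg), 2)  # case-normalised grouping
  g1 <- agg[agg$gene_symbol == "G1", ]
  expect_equal(g1$mean_log2fc_c1, 1.5)
  expect_equal(g1$mean_neglog10p_c1, 0.3)
  expect_equal(g1$n_protein_ids, 2L)
  g2 <- agg[agg$gene_symbol == "G2", ]
  expect_equal(g2$mean_log2fc_c1, 5)   # single-ID gene unchanged

  big <- randomTable(60, seed = 6)
  a <- aggregateByGene(SecretomeTable(big))
  b <- aggregateByGene(SecretomeTable(big[sample(nrow(big)), ]))
  b <- b[match(a$gene_symbol, b$gene_symbol), ]
  expect_equal(a$mean_log2fc_c1, b$mean_log2fc_c1, tolerance = 1e-12)
  expect_equal(a$mean_neglog10p_c2, b$mean_neglog10p_c2, tolerance = 1e-12)
  expect_true(nrow(a) <= nrow(big))
})

test_that("percentile-derived p cutoff follows the interpolation quantile", {
  expect_equal(derivePCutoff(rep(0.5, 20), 92), 0.5)
  expect_equal(derivePCutoff(rep(0.5, 20), 10), 0.5)
  expect_equal(derivePCutoff(seq(0, 1, by = 0.01), 92), 0.92)
  # monotone in the percentile
  v <- rexp(200)
  expect_true(derivePCutoff(v, 50) <= derivePCutoff(v, 92))
  expect_error(derivePCutoff(numeric(0)), "no finite values")
  expect_error(derivePCutoff(1:5, 0), "percentile")
})

test_that("null p-value calibration puts the 92nd percentile near 0.3", {
  cfg <- simConfig(seed = 11)
  tab <- genSecretomeTable(cfg)$table
  rec <- records(tab)
  nullGenes <- genSecretomeTable(cfg)$truth$decoys
  nullGenes <- nullGenes$gene[nullGenes$fate == "threshold_fail"]
  p <- rec$neglog10p_miR526b[rec$gene_symbol %in% nullGenes]
  expect_equal(derivePCutoff(p, 92), 0.3, tolerance = 0.05)
})

test_that("threshold filtering is strict at both cuts and matches the scan oracle", {
  df <- data.frame(protein_id = c("P1", "P2", "P3", "P4"),
                   gene_symbol = c("A", "B", "C", "D"),
                   log2fc_c1 = c(1.5, 1.6, -1.6, -1.6),
                   neglog10p_c1 = c(0.5, 0.3, 0.31, 0.29))
  res <- applyThreshold(SecretomeTable(df), "c1")
  expect_setequal(res$protein_ids, "P3")  # boundary rows P1, P2 excluded
  expect_equal(res$n_boundary, 2)
  expect_error(applyThreshold(SecretomeTable(df), "nope"), "unknown condition")

  for (seed in 1:25) {
    tabdf <- randomTable(50, seed = seed)
    got <- applyThreshold(SecretomeTable(tabdf), "c1")
    expect_setequal(got$protein_ids, scanOracle(tabdf, "c1"))
  }
})

test_that("union combination applies inclusion-exclusion and calls directions", {
  # two conditions sharing 55 of 96 + 95 passing proteins -> union of 136
  idsA <- 1:96
  idsB <- c(42:96, 97:136)          # 55 shared with A
  expect_equal(length(idsB), 95)
  df <- data.frame(protein_id = sprintf("P%03d", 1:136),
                   gene_symbol = sprintf("G%03d", 1:136),
                   log2fc_c1 = 2, neglog10p_c1 = 0.5,
                   log2fc_c2 = 2, neglog10p_c2 = 0.5)
  tab <- SecretomeTable(df)
  gt <- aggregateByGene(tab)
  passes <- list(c1 = list(protein_ids = df$protein_id[idsA],
                           genes = df$gene_symbol[idsA]),
                 c2 = list(protein_ids = df$protein_id[idsB],
                           genes = df$gene_symbol[idsB]))
  cand <- combineSecretomes(passes, gt, records(tab))
  expect_equal(length(unique(unlist(passingProteins(cand)))), 136)

  # identical sets: union equals either input
  cand2 <- combineSecretomes(passes[c(1, 1)], gt, records(tab))
  expect_equal(length(unique(unlist(passingProteins(cand2)))), 96)

  # direction calls: concordant signs in ALL conditions, otherwise discordant
  df2 <- data.frame(protein_id = c("U", "D", "X"),
                    gene_symbol = c("UP", "DOWN", "MIX"),
                    log2fc_c1 = c(2, -2, 2), neglog10p_c1 = 0.5,
                    log2fc_c2 = c(1.8, -1.8, -2), neglog10p_c2 = 0.5)
  cur <- curateSecretome(SecretomeTable(df2))
  g <- candidateGenes(cur$candidates)
  expect_equal(g$direction[match(c("UP", "DOWN", "MIX"), g$gene_symbol)],
               c("up", "down", "discordant"))

  # antisymmetry: negating every fold change flips up and down
  df3 <- df2
  df3$log2fc_c1 <- -df3$log2fc_c1
  df3$log2fc_c2 <- -df3$log2fc_c2
  g3 <- candidateGenes(curateSecretome(SecretomeTable(df3))$candidates)
  expect_equal(g3$direction[match(c("UP", "DOWN", "MIX"), g3$gene_symbol)],
               c("down", "up", "discordant"))
})

test_that("gene-level filtering mode thresholds the gene means", {
  # two IDs averaging below the cut pass at protein level but not gene level
  df <- data.frame(protein_id = c("P1", "P2"), gene_symbol = c("G", "G"),
                   log2fc_c1 = c(2.5, 0), neglog10p_c1 = c(0.5, 0.5))
  tab <- SecretomeTable(df)
  prot <- curateSecretome(tab, level = "protein")
  gene <- curateSecretome(tab, level = "gene")
  expect_equal(candidateGenes(prot$candidates)$gene_symbol, "G")
  expect_equal(nrow(candidateGenes(gene$candidates)), 0)
})
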