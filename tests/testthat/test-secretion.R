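annRow <- function(gene = "G", flags = rep(FALSE, 5), nn = NA, odds = NA,
                   bsp = TRUE) {
  out <- data.frame(gene_symbol = gene, bsp_member = bsp,
                    stringsAsFactors = FALSE)
  for (i in seq_along(flags))
    out[[c("hpa", "mdsec", "phobius", "signalp", "spoctopus")[i]]] <- flags[i]
  out$secretomep_nn <- nn
  out$secretomep_odds <- odds
  out
}

test_that("SecretomeP pass rule uses strict cutoffs and tolerates absent scores", {
  expect_true(secretomePPass(0.8, 4))
  expect_false(secretomePPass(0.6, 4))
  expect_false(secretomePPass(0.9, 3))
  expect_false(secretomePPass(NA, 4))
  expect_false(secretomePPass(0.8, NA))
  expect_equal(secretomePPass(c(0.8, 0.5), c(4, 4)), c(TRUE, FALSE))
})

test_that("secretion classification is total, exhaustive and classical-dominant", {
  combos <- expand.grid(replicate(5, c(FALSE, TRUE), simplify = FALSE))
  spStates <- list(pass = c(0.8, 4), fail = c(0.2, 1), absent = c(NA, NA))
  for (sp in names(spStates)) {
    ann <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i)
      annRow(sprintf("G%02d", i), unlist(combos[i, ]),
             spStates[[sp]][1], spStates[[sp]][2])))
    cls <- classifySecretion(ann)
    expect_true(all(cls$secretion_class %in%
                    c("classical", "non_classical", "none")))
    nHits <- rowSums(combos)
    expect_equal(cls$secretion_class[nHits >= 1],
                 rep("classical", sum(nHits >= 1)))
    expected0 <- if (sp == "pass") "non_classical" else "none"
    expect_equal(cls$secretion_class[nHits == 0], expected0)
  }
  # SecretomeP pass never demotes a classical hit
  both <- classifySecretion(annRow(flags = c(TRUE, rep(FALSE, 4)),
                                   nn = 0.9, odds = 5))
  expect_equal(both$secretion_class, "classical")
})

test_that("the marker annotation fixture reproduces the 6 classical / 2 non-classical split", {
  ann <- readSecretionAnnotations(fixturePath("synthetic_marker_annotations.tsv"))
  cls <- classifySecretion(ann)
  expect_equal(sum(cls$secretion_class == "classical"), 6)
  expect_setequal(cls$gene_symbol[cls$secretion_class == "non_classical"],
                  c("YWHAB", "PEA15"))
  expect_setequal(cls$gene_symbol[cls$secretion_class == "classical"],
                  c("SFN", "TXNDC12", "MYL6B", "FN1", "PSMB6", "PRDX4"))
})

test_that("tissue-proteome filtering removes exactly the absent genes", {
  study <- c("YWHAB", "SFN", "H2AC1", "H2AC12", "H2AC14", "H2AC18",
             "OBSCN", "SEPT14", "FN1")
  absentees <- c("H2AC1", "H2AC12", "H2AC14", "H2AC18", "OBSCN", "SEPT14")
  bsp <- setdiff(study, absentees)
  res <- filterBSP(study, bsp)
  expect_setequal(res$removed$gene_symbol, absentees)
  expect_setequal(res$retained, bsp)
  expect_equal(unique(res$removed$reason), "not in breast-specific proteome")

  all_in <- filterBSP(study, study)
  expect_equal(nrow(all_in$removed), 0)
  expect_warning(filterBSP(study, character(0)), "empty")
})

test_that("synthetic BSP dropouts match the emitted truth", {
  cfg <- simConfig(seed = 21)
  b <- simulateBundle(cfg)
  tr <- simTruth(b)
  res <- filterBSP(geneSymbols(b@secretome), b@bsp)
  expect_setequal(res$removed$gene_symbol, tr$bsp_excluded)
  expect_true(all(tr$markers$gene %in% res$retained))
})

test_that("marker calling keeps only concordant, BSP-retained, evidenced genes", {
  cfg <- simConfig(seed = 22)
  b <- simulateBundle(cfg)
  cur <- curateSecretome(b@secretome)
  retained <- filterBSP(candidateGenes(cur$candidates)$gene_symbol, b@bsp)$retained
  calls <- classifySecretion(b@annotations)
  mk <- callMarkers(cur$candidates, retained, calls)
  tr <- simTruth(b)
  expect_setequal(mk$markers$gene_symbol, tr$markers$gene)
  got <- mk$markers[match(tr$markers$gene, mk$markers$gene_symbol), ]
  expect_equal(got$direction, tr$markers$direction)
  expect_equal(got$secretion_class, tr$markers$secretion_class)

  # monotone shrinkage: markers within BSP-retained within union candidates
  expect_true(all(mk$markers$gene_symbol %in% retained))
  expect_true(all(retained %in% candidateGenes(cur$candidates)$gene_symbol))
  expect_true(all(candidateGenes(cur$candidates)$gene_symbol %in%
                  geneSymbols(b@secretome)))

  # sensitivity: stripping a marker's only evidence removes it
  victim <- tr$markers$gene[1]
  ann2 <- b@annotations
  i <- ann2$gene_symbol == victim
  ann2[i, c("hpa", "mdsec", "phobius", "signalp", "spoctopus")] <- FALSE
  ann2[i, c("secretomep_nn", "secretomep_odds")] <- c(0.1, 0.5)
  mk2 <- callMarkers(cur$candidates, retained, classifySecretion(ann2))
  expect_false(victim %in% mk2$markers$gene_symbol)
  expect_equal(mk2$audit$fate[mk2$audit$gene_symbol == victim],
               "no_secretion_evidence")

  # all evidence stripped: empty marker table
  ann3 <- b@annotations
  ann3[, c("hpa", "mdsec", "phobius", "signalp", "spoctopus")] <- FALSE
  ann3[, c("secretomep_nn", "secretomep_odds")] <- NA
  mk3 <- callMarkers(cur$candidates, retained, classifySecretion(ann3))
  expect_equal(nrow(mk3$markers), 0)
})
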