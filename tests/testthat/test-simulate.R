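test_that("configuration validation rejects impossible designs", {
  expect_error(simConfig(n_proteins = 0), "positive")
  expect_error(simConfig(n_genes = 2000, n_proteins = 100), "budget")
  expect_error(simConfig(planted_markers = data.frame(
    gene = "G", direction = "sideways", secretion_class = "classical")),
    "direction")
  expect_error(simConfig(multi_id_rate = 1.5), "rates")
  mk <- defaultMarkers()
  expect_equal(nrow(mk), 8)
  expect_equal(sum(mk$direction == "up"), 4)
  expect_equal(sum(mk$secretion_class == "classical"), 6)
})

test_that("the same seed reproduces byte-identical bundles", {
  cfg <- simConfig(seed = 71, n_proteins = 400, n_genes = 120)
  b1 <- simulateBundle(cfg)
  b2 <- simulateBundle(cfg)
  expect_identical(records(b1@secretome), records(b2@secretome))
  expect_identical(b1@annotations, b2@annotations)
  expect_identical(b1@targets, b2@targets)
  expect_identical(simTruth(b1), simTruth(b2))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeBundle(b1, d1); writeBundle(b2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # and a different seed gives different data
  b3 <- simulateBundle(simConfig(seed = 72, n_proteins = 400, n_genes = 120))
  expect_false(identical(records(b1@secretome), records(b3@secretome)))
})

test_that("planted markers pass the threshold in every condition with their sign", {
  cfg <- simConfig(seed = 73)
  g <- genSecretomeTable(cfg)
  rec <- records(g$table)
  agg <- aggregateByGene(excludeUnmapped(g$table)$kept)
  for (i in seq_len(nrow(g$truth$markers))) {
    m <- g$truth$markers[i, ]
    row <- agg[agg$gene_symbol == m$gene, ]
    for (cond in cfg$conditions) {
      fc <- row[[paste0("mean_log2fc_", cond)]]
      expect_gt(abs(fc), 1.5)
      expect_equal(sign(fc), if (m$direction == "up") 1 else -1)
      expect_gt(row[[paste0("mean_neglog10p_", cond)]], 0.3)
    }
  }
  # multi-ID genes exist and scatter around the gene mean
  expect_gt(sum(agg$n_protein_ids > 1), 0)
  expect_true(all(agg$n_protein_ids >= 1))
  expect_equal(sum(agg$n_protein_ids), nProteins(g$table) - cfg$n_unmapped)
})

test_that("decoys exercise every elimination branch of the funnel", {
  cfg <- simConfig(seed = 74)
  b <- simulateBundle(cfg)
  tr <- simTruth(b)
  expect_setequal(unique(tr$decoys$fate),
                  c("threshold_fail", "discordant", "bsp_fail", "no_evidence"))
  rep <- runPipeline(b)
  audit <- rep@audit
  disc <- tr$decoys$gene[tr$decoys$fate == "discordant"]
  expect_true(all(audit$fate[audit$gene_symbol %in% disc] ==
                  "discordant_direction"))
  bspf <- tr$decoys$gene[tr$decoys$fate == "bsp_fail"]
  expect_true(all(audit$fate[audit$gene_symbol %in% bspf] == "not_in_bsp"))
  noev <- tr$decoys$gene[tr$decoys$fate == "no_evidence"]
  expect_true(all(audit$fate[audit$gene_symbol %in% noev] ==
                  "no_secretion_evidence"))
  expect_equal(length(tr$unmapped_ids), cfg$n_unmapped)
})

test_that("zero planted markers yield an empty marker list downstream", {
  cfg <- simConfig(seed = 75, n_proteins = 300, n_genes = 100,
                   planted_markers = defaultMarkers()[0, ],
                   n_discordant = 2L, n_bsp_fail = 2L, n_no_evidence = 0L)
  rep <- runPipeline(simulateBundle(cfg))
  expect_equal(nrow(markerCalls(rep)), 0)
})

test_that("planted secretion evidence obeys the consensus contract", {
  cfg <- simConfig(seed = 76)
  b <- simulateBundle(cfg)
  ann <- b@annotations
  tr <- simTruth(b)
  flagCols <- c("hpa", "mdsec", "phobius", "signalp", "spoctopus")
  for (i in seq_len(nrow(tr$markers))) {
    row <- ann[ann$gene_symbol == tr$markers$gene[i], ]
    if (tr$markers$secretion_class[i] == "classical") {
      expect_gte(sum(unlist(row[flagCols])), 1)
    } else {
      expect_equal(sum(unlist(row[flagCols])), 0)
      expect_gt(row$secretomep_nn, 0.6)
      expect_gt(row$secretomep_odds, 3)
    }
  }
})

test_that("expression generator plants the correlation in the right stratum", {
  cfg <- simConfig(seed = 77)
  tr <- genSecretomeTable(cfg)$truth
  ge <- genExpression(tr, n_samples = 400, cfg = cfg, rho = 0.6)
  expect_true(all(c("sample_id", "stratum") %in% names(ge$matrix)))
  expect_equal(nrow(ge$matrix), 400)
  ct <- ge$truth$correlation
  expect_setequal(unique(ct$rho[ct$stratum == "Other"]), 0)
  expect_setequal(abs(unique(ct$rho[ct$stratum == "LumA"])), c(0.6))
  # cluster members carry the signal through their mean
  luma <- ge$matrix[ge$matrix$stratum == "LumA", ]
  cl <- names(ge$clusters)[1]
  score <- clusterScore(luma, ge$clusters[[cl]])
  up <- tr$markers$gene[tr$markers$direction == "up"][1]
  expect_gt(pearsonCor(luma[[up]], score)$r, 0.4)
  expect_error(genExpression(tr, n_samples = 4, cfg = cfg),
               "3 per stratum")
  expect_error(genExpression(tr, n_samples = 100,
                             strata = c(a = 0.6, b = 0.6), cfg = cfg),
               "sum to 1")
})

test_that("survival generator honours censoring and hazard settings", {
  all_events <- genSurvival(n = 50, hr = 1, censor_rate = 0, seed = 78)
  expect_true(all(all_events$event))
  expect_error(genSurvival(n = 5), "at least 10")
  expect_error(genSurvival(hr = -1), "positive")
  expect_error(genSurvival(censor_rate = 1), "censor_rate")
  cens <- genSurvival(n = 2000, hr = 1, censor_rate = 0.3, seed = 79)
  expect_equal(mean(!cens$event), 0.3, tolerance = 0.06)
  # planted hazard ratio shortens high-group survival
  hr3 <- genSurvival(n = 1000, hr = 3, censor_rate = 0, seed = 80)
  sp <- dichotomize(hr3, 100)
  expect_lt(median(sp$high$time_years), median(sp$low$time_years))
})
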