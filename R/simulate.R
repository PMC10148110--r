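#' Default planted markers for simulation
#'
#' Eight markers mirroring the study design the generator emulates: four
#' upregulated and four downregulated secreted proteins, six following the
#' classical (signal-peptide) pathway and two the non-classical one.
#'
#' @return data.frame: \code{gene}, \code{direction}, \code{secretion_class}.
#' @export
defaultMarkers <- function() {
  data.frame(
    gene = c("YWHAB", "SFN", "TXNDC12", "MYL6B",
             "FN1", "PSMB6", "PRDX4", "PEA15"),
    direction = c(rep("up", 4), rep("down", 4)),
    secretion_class = c("non_classical", "classical", "classical", "classical",
                        "classical", "classical", "classical", "non_classical"),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' All knobs of the synthetic input generator. Defaults emulate the study
#' conditions: 1535 protein IDs over 442 genes, two miRNA-secretome
#' conditions, eight planted markers at |log2 FC| = 2.5, and a null
#' -log10 p distribution whose 92nd percentile sits at 0.3 (so the empirical
#' percentile-to-cutoff calibration of \code{\link{derivePCutoff}} is
#' reproduced).
#'
#' @param seed integer; the single source of randomness for the bundle.
#' @param n_proteins total protein IDs (including unmapped ones).
#' @param n_genes distinct mapped genes (<= n_proteins - n_unmapped).
#' @param conditions condition names (>= 1).
#' @param planted_markers data.frame \code{gene}, \code{direction},
#'   \code{secretion_class}; see \code{\link{defaultMarkers}}.
#' @param effect_log2fc planted |log2 FC| magnitude.
#' @param null_log2fc_sd per-ID log2 FC scatter (0 = noiseless).
#' @param multi_id_rate fraction of genes carrying more than one protein ID.
#' @param n_unmapped protein IDs emitted without a gene symbol.
#' @param n_discordant decoy genes passing with opposite signs per condition.
#' @param n_bsp_fail decoy genes passing threshold but absent from the BSP.
#' @param n_no_evidence decoy genes passing all filters but with no
#'   secretion evidence.
#' @param bsp_dropout fraction of plain (threshold-failing) decoys excluded
#'   from the BSP membership set.
#' @param evidence_rate fraction of plain decoys given some secretion
#'   evidence anyway.
#' @param p_model list: \code{null_rate} (exponential rate of null -log10 p;
#'   default calibrated so the 92nd percentile is 0.3),
#'   \code{planted_offset} and \code{planted_rate} (planted -log10 p =
#'   offset + Exp(rate), guaranteed above the 0.3 cutoff).
#' @return list of class \code{SimConfig}.
#' @export
simConfig <- function(seed = 1L,
                      n_proteins = 1535L,
                      n_genes = 442L,
                      conditions = c("miR526b", "miR655"),
                      planted_markers = defaultMarkers(),
                      effect_log2fc = 2.5,
                      null_log2fc_sd = 0.5,
                      multi_id_rate = 0.5,
                      n_unmapped = 14L,
                      n_discordant = 6L,
                      n_bsp_fail = 6L,
                      n_no_evidence = 6L,
                      bsp_dropout = 0.1,
                      evidence_rate = 0.3,
                      p_model = list(null_rate = -log(1 - 0.92) / 0.3,
                                     planted_offset = 0.35,
                                     planted_rate = 2)) {
  if (n_proteins <= 0 || n_genes <= 0) stop("counts must be positive")
  if (n_genes > n_proteins - n_unmapped)
    stop("n_genes exceeds the mapped protein budget")
  if (length(conditions) < 1) stop("at least one condition required")
  if (nrow(planted_markers) > n_genes)
    stop("planted gene count exceeds n_genes")
  if (!all(planted_markers$direction %in% c("up", "down")))
    stop("marker direction must be up or down")
  if (!all(planted_markers$secretion_class %in% c("classical", "non_classical")))
    stop("marker secretion_class must be classical or non_classical")
  if (anyDuplicated(planted_markers$gene)) stop("duplicate planted genes")
  for (r in c(multi_id_rate, bsp_dropout, evidence_rate))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  nSpecial <- nrow(planted_markers) + n_discordant + n_bsp_fail + n_no_evidence
  if (nSpecial > n_genes)
    stop("planted + decoy-branch genes exceed n_genes")
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 n_genes = as.integer(n_genes), conditions = conditions,
                 planted_markers = planted_markers,
                 effect_log2fc = effect_log2fc,
                 null_log2fc_sd = null_log2fc_sd,
                 multi_id_rate = multi_id_rate,
                 n_unmapped = as.integer(n_unmapped),
                 n_discordant = as.integer(n_discordant),
                 n_bsp_fail = as.integer(n_bsp_fail),
                 n_no_evidence = as.integer(n_no_evidence),
                 bsp_dropout = bsp_dropout, evidence_rate = evidence_rate,
                 p_model = p_model),
            class = "SimConfig")
}

# planted -log10 p draws, always strictly above the default 0.3 cutoff
plantedP <- function(n, pm) pm$planted_offset + rexp(n, rate = pm$planted_rate)

#' Generate a differential secretome table with planted markers
#'
#' Builds a protein-level table in which the planted markers exceed the
#' |log2 FC| > effect and -log10 p > 0.3 thresholds in every condition with
#' the planted sign, while decoy genes exercise each elimination branch of
#' the curation funnel: plain nulls failing the threshold, genes passing
#' with discordant signs across conditions, genes destined to fail the BSP
#' filter, genes destined to lack secretion evidence, and protein IDs with
#' no gene symbol. Genes selected by \code{multi_id_rate} carry several
#' protein IDs whose per-ID values scatter around the gene effect.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list: \code{table} (\linkS4class{SecretomeTable}), \code{truth}
#'   (list: \code{markers}, \code{decoys} with per-gene \code{fate},
#'   \code{unmapped_ids}).
#' @export
genSecretomeTable <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  with_seed(cfg$seed, {
    markers <- cfg$planted_markers
    nDecoys <- cfg$n_genes - nrow(markers)
    decoyGenes <- sprintf("DECOY%04d", seq_len(nDecoys))
    fate <- rep("threshold_fail", nDecoys)
    idx <- 0L
    for (f in c("discordant", "bsp_fail", "no_evidence")) {
      k <- switch(f, discordant = cfg$n_discordant,
                  bsp_fail = cfg$n_bsp_fail,
                  no_evidence = cfg$n_no_evidence)
      if (k > 0) fate[idx + seq_len(k)] <- f
      idx <- idx + k
    }
    decoys <- data.frame(gene = decoyGenes, fate = fate,
                         stringsAsFactors = FALSE)
    genes <- c(markers$gene, decoyGenes)

    # per-gene, per-condition effect sizes
    nc <- length(cfg$conditions)
    eff <- matrix(0, nrow = length(genes), ncol = nc,
                  dimnames = list(genes, cfg$conditions))
    mSign <- ifelse(markers$direction == "up", 1, -1)
    eff[seq_len(nrow(markers)), ] <- mSign * cfg$effect_log2fc
    dSign <- sample(c(-1, 1), nDecoys, replace = TRUE)
    for (j in seq_len(nc)) {
      s <- ifelse(fate == "discordant" & j > 1, -dSign, dSign)
      plant <- fate != "threshold_fail"
      eff[nrow(markers) + which(plant), j] <-
        (s * cfg$effect_log2fc)[plant]
    }
    # a single condition cannot express discordance; such decoys then behave
    # like concordant passers and are re-labelled
    if (nc == 1 && any(fate == "discordant"))
      decoys$fate[decoys$fate == "discordant"] <- "no_evidence"

    # protein IDs per gene: every gene has one, multi-ID genes share the rest
    budget <- cfg$n_proteins - cfg$n_unmapped
    nIds <- rep(1L, length(genes))
    nMulti <- round(cfg$multi_id_rate * length(genes))
    extra <- budget - length(genes)
    if (nMulti > 0 && extra > 0) {
      multi <- sample(seq_along(genes), nMulti)
      base <- pmin(3L, extra %/% nMulti)
      nIds[multi] <- nIds[multi] + base
      rem <- extra - base * nMulti
      if (rem > 0) {
        bump <- sample(multi, rem, replace = rem > length(multi))
        add <- table(bump)
        nIds[as.integer(names(add))] <- nIds[as.integer(names(add))] +
          as.integer(add)
      }
    } else if (extra > 0) {
      bump <- sample(seq_along(genes), extra, replace = TRUE)
      add <- table(bump)
      nIds[as.integer(names(add))] <- nIds[as.integer(names(add))] +
        as.integer(add)
    }

    geneOfId <- rep(genes, times = nIds)
    plantOfId <- rep(c(rep(TRUE, nrow(markers)),
                       fate != "threshold_fail"), times = nIds)
    nMapped <- length(geneOfId)
    rec <- data.frame(protein_id = sprintf("PID%05d", seq_len(nMapped)),
                      gene_symbol = geneOfId, stringsAsFactors = FALSE)
    for (j in seq_len(nc)) {
      cond <- cfg$conditions[j]
      rec[[fcCol(cond)]] <- eff[geneOfId, j] +
        rnorm(nMapped, 0, cfg$null_log2fc_sd)
      p <- rexp(nMapped, rate = cfg$p_model$null_rate)
      p[plantOfId] <- plantedP(sum(plantOfId), cfg$p_model)
      rec[[pCol(cond)]] <- p
    }

    # unmapped protein IDs: no gene symbol; half would pass the threshold if
    # they were not excluded first
    if (cfg$n_unmapped > 0) {
      un <- data.frame(protein_id = sprintf("UNMAPPED%03d",
                                            seq_len(cfg$n_unmapped)),
                       gene_symbol = NA_character_, stringsAsFactors = FALSE)
      pass <- seq_len(cfg$n_unmapped) <= cfg$n_unmapped / 2
      for (j in seq_len(nc)) {
        cond <- cfg$conditions[j]
        fc <- rnorm(cfg$n_unmapped, 0, cfg$null_log2fc_sd)
        fc[pass] <- fc[pass] + cfg$effect_log2fc
        un[[fcCol(cond)]] <- fc
        p <- rexp(cfg$n_unmapped, rate = cfg$p_model$null_rate)
        p[pass] <- plantedP(sum(pass), cfg$p_model)
        un[[pCol(cond)]] <- p
      }
      rec <- rbind(rec, un)
    }
    rownames(rec) <- NULL
    truth <- list(markers = markers, decoys = decoys,
                  unmapped_ids = rec$protein_id[isMissingGene(rec$gene_symbol)])
    list(table = SecretomeTable(rec, cfg$conditions), truth = truth)
  })
}

#' Generate secretion annotations and BSP membership with planted evidence
#'
#' Planted classical markers receive at least one hit among the five
#' signal-peptide methods; planted non-classical markers receive a
#' SecretomeP neural-network score > 0.6 and odds > 3 with no classical
#' flag. Decoys destined for the no-evidence branch get none; a
#' \code{evidence_rate} fraction of the remaining decoys gets random
#' evidence. BSP membership covers every gene except the \code{bsp_fail}
#' decoys and a \code{bsp_dropout} fraction of plain decoys.
#'
#' @param truth truth list from \code{\link{genSecretomeTable}}.
#' @param universe character vector of all generated gene symbols.
#' @param cfg the \code{\link{simConfig}}.
#' @return list: \code{annotations} (data.frame in the
#'   \code{\link{readSecretionAnnotations}} schema), \code{bsp} (character),
#'   \code{truth} (updated with \code{bsp_excluded}).
#' @export
genAnnotations <- function(truth, universe, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  universe <- normGene(universe)
  missing <- setdiff(truth$markers$gene, universe)
  if (length(missing))
    stop("planted gene missing from universe: ",
         paste(missing, collapse = ", "))
  with_seed(cfg$seed + 1L, {
    n <- length(universe)
    ann <- data.frame(gene_symbol = universe, stringsAsFactors = FALSE)
    flags <- matrix(FALSE, n, 5,
                    dimnames = list(universe, tolower(CLASSICAL_METHODS)))
    nn <- runif(n, 0, 0.55)
    odds <- runif(n, 0, 2.5)
    nn[runif(n) < 0.2] <- NA
    odds[is.na(nn)] <- NA

    mk <- truth$markers
    for (i in seq_len(nrow(mk))) {
      g <- mk$gene[i]
      if (mk$secretion_class[i] == "classical") {
        hit <- sample(5, sample(1:3, 1))
        flags[g, hit] <- TRUE
        # classical markers may also score with SecretomeP; priority keeps
        # them classical either way
        nn[universe == g] <- runif(1, 0.3, 0.9)
        odds[universe == g] <- runif(1, 1, 5)
      } else {
        flags[g, ] <- FALSE
        nn[universe == g] <- runif(1, 0.65, 0.95)
        odds[universe == g] <- runif(1, 3.5, 6)
      }
    }
    dec <- truth$decoys
    noEv <- dec$gene[dec$fate == "no_evidence"]
    plain <- dec$gene[dec$fate %in% c("threshold_fail", "discordant",
                                      "bsp_fail")]
    withEv <- plain[runif(length(plain)) < cfg$evidence_rate]
    for (g in withEv) {
      if (runif(1) < 0.5) flags[g, sample(5, 1)] <- TRUE
      else { nn[universe == g] <- runif(1, 0.65, 0.95)
             odds[universe == g] <- runif(1, 3.5, 6) }
    }
    flags[noEv, ] <- FALSE
    nn[universe %in% noEv] <- runif(length(noEv), 0, 0.55)
    odds[universe %in% noEv] <- runif(length(noEv), 0, 2.5)

    bspOut <- dec$gene[dec$fate == "bsp_fail"]
    plainNull <- dec$gene[dec$fate == "threshold_fail"]
    dropped <- plainNull[runif(length(plainNull)) < cfg$bsp_dropout]
    bspOut <- c(bspOut, dropped)
    ann <- cbind(ann, as.data.frame(flags, row.names = NULL))
    ann$bsp_member <- !universe %in% bspOut
    ann$secretomep_nn <- nn
    ann$secretomep_odds <- odds
    ann <- ann[c("gene_symbol", "bsp_member", tolower(CLASSICAL_METHODS),
                 "secretomep_nn", "secretomep_odds")]
    truth$bsp_excluded <- bspOut
    list(annotations = ann, bsp = universe[ann$bsp_member], truth = truth)
  })
}

#' Generate miRNA target sets and marker TF tables with planted explanations
#'
#' For every planted marker, emits explaining transcription factors whose
#' sign makes the marker's direction consistent with miRNA suppression
#' (upregulated marker: a negative-regulator TF inside every miRNA target
#' set; downregulated: a positive regulator), plus two kinds of distractor:
#' a consistently signed TF absent from the target sets, and an oppositely
#' signed TF inside them. The first downregulated marker is additionally
#' planted as a direct target of every miRNA, and the first upregulated
#' marker as a direct target of the last miRNA only (a post-transcriptional
#' anomaly).
#'
#' @param truth truth list (needs \code{markers}, \code{decoys}).
#' @param cfg the \code{\link{simConfig}}; condition names double as miRNA
#'   ids.
#' @return list: \code{targets} (named list of gene vectors), \code{tfs}
#'   (data.frame \code{marker}, \code{tf_symbol}, \code{sign}),
#'   \code{truth} (updated with \code{explaining} and \code{direct}).
#' @export
genRegulatoryTables <- function(truth, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  with_seed(cfg$seed + 2L, {
    mirnas <- cfg$conditions
    mk <- truth$markers
    targets <- setNames(vector("list", length(mirnas)), mirnas)
    # filler targets: random decoy genes, partially shared across miRNAs
    filler <- truth$decoys$gene
    shared <- sample(filler, min(30, length(filler)))
    for (m in mirnas)
      targets[[m]] <- unique(c(shared,
                               sample(filler, min(30, length(filler)))))
    tfs <- list()
    explaining <- list()
    for (i in seq_len(nrow(mk))) {
      g <- mk$gene[i]
      consSign <- if (mk$direction[i] == "up") "negative" else "positive"
      oppSign <- if (mk$direction[i] == "up") "positive" else "negative"
      expl <- paste0("TF_", g, "_E", 1:2)
      offTarget <- paste0("TF_", g, "_OFF")
      oppOn <- paste0("TF_", g, "_OPP")
      tfs[[g]] <- data.frame(
        marker = g,
        tf_symbol = c(expl, offTarget, oppOn),
        sign = c(consSign, consSign, consSign, oppSign),
        stringsAsFactors = FALSE)
      for (m in mirnas)
        targets[[m]] <- c(targets[[m]], expl, oppOn)
      explaining[[g]] <- expl
    }
    direct <- data.frame(marker = character(0), mirna = character(0),
                         stringsAsFactors = FALSE)
    downs <- mk$gene[mk$direction == "down"]
    ups <- mk$gene[mk$direction == "up"]
    if (length(downs)) {
      for (m in mirnas) targets[[m]] <- c(targets[[m]], downs[1])
      direct <- rbind(direct, data.frame(marker = downs[1], mirna = mirnas,
                                         stringsAsFactors = FALSE))
    }
    if (length(ups)) {
      last <- mirnas[length(mirnas)]
      targets[[last]] <- c(targets[[last]], ups[1])
      direct <- rbind(direct, data.frame(marker = ups[1], mirna = last,
                                         stringsAsFactors = FALSE))
    }
    targets <- lapply(targets, function(g) sort(unique(normGene(g))))
    tfTable <- if (length(tfs)) do.call(rbind, tfs) else
      data.frame(marker = character(0), tf_symbol = character(0),
                 sign = character(0), stringsAsFactors = FALSE)
    rownames(tfTable) <- NULL
    tfTable$tf_symbol <- normGene(tfTable$tf_symbol)
    truth$explaining <- lapply(explaining, normGene)
    truth$direct <- direct
    list(targets = targets, tfs = tfTable, truth = truth)
  })
}

#' Generate an expression matrix with planted stratified correlations
#'
#' Within the designated stratum each marker is drawn jointly with the
#' latent cluster scores so that its population correlation with cluster
#' \eqn{c} equals the planted \eqn{\rho_c} (positive for upregulated
#' markers, negative for downregulated ones); all other strata are drawn
#' with \eqn{\rho = 0}. Member miRNA columns are built as the latent score
#' plus per-sample centred noise, so the cluster mean reproduces the latent
#' score exactly and carries the planted signal.
#'
#' @param truth truth list (needs \code{markers}).
#' @param n_samples total samples (default 283, the emulated cohort size).
#' @param strata named numeric vector of stratum proportions summing to 1.
#' @param cfg the \code{\link{simConfig}}.
#' @param rho planted correlation magnitude in the signal stratum.
#' @param signal_stratum name of the stratum carrying the signal.
#' @param clusters named list of member miRNA ids; default two clusters of
#'   2 and 16 members (the emulated miRNA cluster sizes).
#' @param member_sd standard deviation of member scatter around the latent
#'   cluster score.
#' @return list: \code{matrix} (data.frame \code{sample_id}, \code{stratum},
#'   features), \code{clusters}, \code{truth} (updated with
#'   \code{correlation}: marker x cluster x stratum planted rho).
#' @export
genExpression <- function(truth, n_samples = 283,
                          strata = c(LumA = 0.5, Other = 0.5),
                          cfg = simConfig(), rho = 0.6,
                          signal_stratum = names(strata)[1],
                          clusters = NULL, member_sd = 0.5) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (abs(sum(strata) - 1) > 1e-8) stop("stratum proportions must sum to 1")
  counts <- round(n_samples * strata)
  counts[length(counts)] <- n_samples - sum(counts[-length(counts)])
  if (any(counts < 3)) stop("n_samples < 3 per stratum")
  if (is.null(clusters)) {
    cs <- unique(cfg$conditions)
    sizes <- c(2L, 16L)
    clusters <- list()
    for (i in seq_len(min(2L, length(cs))))
      clusters[[paste0(cs[i], "_cluster")]] <-
        paste0(cs[i], ".m", seq_len(sizes[i]))
  }
  mk <- truth$markers
  nCl <- length(clusters)
  if (nCl * rho^2 >= 1)
    stop("rho too large for ", nCl, " independent clusters")
  with_seed(cfg$seed + 3L, {
    rows <- list()
    corTruth <- list()
    for (si in seq_along(counts)) {
      st <- names(counts)[si]
      ns <- counts[si]
      z <- matrix(rnorm(ns * nCl), ns, nCl,
                  dimnames = list(NULL, names(clusters)))
      dat <- data.frame(sample_id = sprintf("S_%s_%03d", st, seq_len(ns)),
                        stratum = st, stringsAsFactors = FALSE)
      for (i in seq_len(nrow(mk))) {
        sgn <- if (mk$direction[i] == "up") 1 else -1
        r <- if (st == signal_stratum) sgn * rho else 0
        resid <- sqrt(max(0, 1 - nCl * r^2))
        val <- as.vector(z %*% rep(r, nCl)) + resid * rnorm(ns)
        dat[[mk$gene[i]]] <- 6 + 1.5 * val
        for (cl in names(clusters))
          corTruth[[length(corTruth) + 1L]] <- data.frame(
            marker = mk$gene[i], cluster = cl, stratum = st, rho = r,
            stringsAsFactors = FALSE)
      }
      for (cl in names(clusters)) {
        mem <- clusters[[cl]]
        e <- matrix(rnorm(ns * length(mem), 0, member_sd), ns, length(mem))
        if (length(mem) > 1) e <- e - rowMeans(e) else e[] <- 0
        for (j in seq_along(mem))
          dat[[mem[j]]] <- 4 + z[, cl] + e[, j]
      }
      rows[[si]] <- dat
    }
    mat <- do.call(rbind, rows)
    rownames(mat) <- NULL
    attr(mat, "scale") <- "log2"
    truth$correlation <- unique(do.call(rbind, corTruth))
    list(matrix = mat, clusters = clusters, truth = truth)
  })
}

#' Generate a survival cohort with a planted hazard ratio
#'
#' Event times are exponential; samples whose expression exceeds the planted
#' cutoff have their hazard multiplied by \code{hr}. Censoring is an
#' independent exponential clock whose rate is tuned to the requested
#' marginal censoring fraction; \code{censor_rate = 0} observes every event.
#'
#' @param n cohort size (>= 10).
#' @param hr hazard ratio of the expression-high group (> 0).
#' @param censor_rate target censoring fraction in [0, 1).
#' @param seed integer seed.
#' @param base_hazard baseline hazard per year for the low group.
#' @param cutoff expression cutoff defining the high group.
#' @return data.frame: \code{sample_id}, \code{time_years}, \code{event},
#'   \code{expression}, \code{stage}; attribute \code{truth} with the
#'   planted \code{hr} and \code{cutoff}.
#' @export
genSurvival <- function(n = 500, hr = 1, censor_rate = 0.2, seed = 1,
                        base_hazard = 0.1, cutoff = 100) {
  if (n < 10) stop("n must be at least 10")
  if (hr <= 0) stop("hr must be positive")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must lie in [0, 1)")
  with_seed(seed, {
    expression <- rnorm(n, 100, 20)
    high <- expression > cutoff
    rate <- base_hazard * ifelse(high, hr, 1)
    t_event <- rexp(n, rate)
    if (censor_rate > 0) {
      cRate <- mean(rate) * censor_rate / (1 - censor_rate)
      t_cens <- rexp(n, cRate)
      event <- t_event <= t_cens
      time <- pmin(t_event, t_cens)
    } else {
      event <- rep(TRUE, n)
      time <- t_event
    }
    out <- data.frame(sample_id = sprintf("P%04d", seq_len(n)),
                      time_years = time, event = event,
                      expression = expression,
                      stage = sample(c("early", "late"), n, replace = TRUE),
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- list(hr = hr, cutoff = cutoff)
    out
  })
}

#' Generate the complete synthetic input bundle
#'
#' Chains \code{\link{genSecretomeTable}}, \code{\link{genAnnotations}} and
#' \code{\link{genRegulatoryTables}} into a \linkS4class{SimBundle} carrying
#' every pipeline input plus the planted truth. The same configuration
#' (including its seed) always yields an identical bundle.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return A \linkS4class{SimBundle}.
#' @export
simulateBundle <- function(cfg = simConfig()) {
  sec <- genSecretomeTable(cfg)
  universe <- geneSymbols(sec$table)
  ann <- genAnnotations(sec$truth, universe, cfg)
  reg <- genRegulatoryTables(ann$truth, cfg)
  new("SimBundle", secretome = sec$table, annotations = ann$annotations,
      bsp = ann$bsp, targets = reg$targets, tfs = reg$tfs,
      truth = reg$truth, config = unclass(cfg))
}

#' Write a simulated bundle to TSV files plus a JSON truth file
#'
#' Emits \code{secretome.tsv}, \code{annotations.tsv}, \code{bsp.tsv},
#' \code{targets.tsv}, \code{tf_regulation.tsv}, \code{truth.json} and
#' \code{config.json} into \code{dir}.
#'
#' @param bundle a \linkS4class{SimBundle}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
  stopifnot(is(bundle, "SimBundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeDifferentialTable(bundle@secretome, file.path(dir, "secretome.tsv"))
  ann <- bundle@annotations
  for (col in c("bsp_member", tolower(CLASSICAL_METHODS)))
    ann[[col]] <- as.integer(ann[[col]])
  writeTsv(ann, file.path(dir, "annotations.tsv"))
  writeTsv(data.frame(gene_symbol = bundle@bsp), file.path(dir, "bsp.tsv"))
  tg <- do.call(rbind, lapply(names(bundle@targets), function(m)
    data.frame(mirna_id = m, gene_symbol = bundle@targets[[m]],
               stringsAsFactors = FALSE)))
  writeTsv(tg, file.path(dir, "targets.tsv"))
  writeTsv(bundle@tfs, file.path(dir, "tf_regulation.tsv"))
  truth <- bundle@truth
  truth$explaining <- lapply(truth$explaining, as.list)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(bundle@config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
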