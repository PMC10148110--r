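---
title: "Secretome marker curation: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Secretome marker curation: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secretoMiner)
```

# The curation model

secretoMiner treats secretome biomarker discovery as a sequence of
explicit filters over a protein-level differential table, each of which
can be audited:

1. **Evidence threshold.** A protein passes in condition $c$ iff
   $|\mathrm{log_2FC}_c| > f$ and $-\log_{10} p_c > q$, with defaults
   $f = 1.5$ and $q = 0.3$. Both inequalities are strict: a row sitting
   exactly at a cut is excluded and counted in `n_boundary`, so the
   decision at the boundary is visible rather than silent. The p cut can
   be derived from the data: `derivePCutoff(values, 92)` returns the
   92nd-percentile of the observed $-\log_{10} p$ distribution using the
   linear-interpolation quantile (R type 7). That definition is stated
   because the percentile-to-cutoff translation is only reproducible if
   the quantile estimator is pinned.

2. **Identifier handling.** Protein IDs with no gene symbol carry no
   gene-level information and are excluded up front, with counts logged.
   Multiple protein IDs mapping to one (case-normalised) gene are
   combined by the unweighted arithmetic mean per condition. The mean —
   rather than the extreme or a weighted combination — is used because
   multiple IDs of one gene are typically isoforms or fragmentary
   identifications of the same secreted product, with no principled
   weight available from the table alone.

3. **Union and concordance.** Candidates are genes passing in at least
   one condition. A direction is called from the gene-level mean
   log2 FC in *every* condition: all positive → `up`, all negative →
   `down`, anything else → `discordant`. Discordant genes stay in the
   candidate table, flagged, and are barred from marker candidacy; they
   are never silently dropped.

4. **Tissue specificity.** Candidates must belong to a tissue-specific
   proteome membership list (here called BSP), supplied as data. The
   package never queries an atlas; membership is a pinned input.

5. **Secretion consensus.** Five classical signal-peptide predictors
   (HPA, MDSEC, Phobius, SignalP, SPOCTOPUS) are consumed as boolean
   flags, and SecretomeP as a neural-network score and odds ratio. The
   class is `classical` if any classical flag fired, otherwise
   `non_classical` if NN $> 0.6$ and odds $> 3$ (strict), otherwise
   `none`. Classical evidence dominates: a protein detected by both
   kinds of method is still classically secreted, since possession of a
   signal peptide is a stronger, sequence-level statement than the
   ab-initio SecretomeP score. Absent SecretomeP scores fail the
   non-classical test quietly — no data is treated as no evidence, not
   as an error.

A marker is a candidate that survives all five stages. `runPipeline`
emits the funnel (counts in/out per stage) and a per-gene audit of where
every non-marker died.

## Threshold level: protein or gene

Published secretome funnels are ambiguous about whether the evidence
threshold is applied to protein rows (with genes induced by any passing
protein) or to gene-averaged values. Both readings are implemented
(`level = "protein"`, the default, or `"gene"` in `curateSecretome` /
`runPipeline`); they differ whenever a gene's IDs straddle the cut. The
protein-level default matches the convention of reporting counts as "N
proteins coded by M genes". Neither is asserted to be the only correct
reading.

## Direction rule

The default requires sign concordance in **all** conditions before
calling `up`/`down`. A laxer either-condition rule would admit genes
driven by a single condition; concordance is the stricter and more
reproducible choice, and the discordant flag preserves the information
the laxer rule would use.

# Downstream statistics

* **Over-representation** uses the one-sided hypergeometric upper tail
  (`stats::phyper`) with BH adjustment (`stats::p.adjust`). Term gene
  sets are intersected with the declared universe before testing; the
  default universe is all genes of the differential table. GO-style
  graph propagation is out of scope — term collections are flat inputs
  in GMT format.
* **Regulatory consistency**: a miRNA suppresses its predicted targets,
  so an upregulated marker is *explained* by a targeted
  negative-regulator TF and a downregulated one by a targeted positive
  regulator. TFs annotated `dual` (reported with both roles) can explain
  either direction but keep their annotation in every report, so they
  are never mistaken for unambiguous evidence. Both the common-target
  mode (intersection of all miRNA target sets) and per-miRNA modes are
  computed, because a marker can lack common-target TFs yet be explained
  within each miRNA separately. A marker that is itself a predicted
  target yet upregulated is flagged as a post-transcriptional anomaly.
* **Stratified correlation**: cluster expression is the unweighted mean
  of member miRNAs; Pearson r with the $t$-transform p-value
  (`stats::cor.test`) is computed per marker × cluster × stratum with
  pairwise-complete deletion and the n used reported per cell. Raw
  p-values carry the conventional star tiers (\*, \*\*, \*\*\* at 0.05,
  0.01, 0.001); a BH column over the whole table is appended rather than
  substituted, since heatmap-style reports conventionally show raw
  tiers.
* **Two-group comparison** defaults to Welch's t (no equal-variance
  assumption); `variant = "student"` gives the pooled test. Log2
  fold-change summaries require the scale to be declared (`log2`: mean
  difference; `linear`: log ratio of means with an explicit
  pseudocount) — nothing is ever re-transformed silently.
* **Survival**: expression is dichotomized at a supplied cutoff with
  ties to the low group by default (`high_inclusive = TRUE` flips the
  convention; either way the convention used is recorded in the output).
  Kaplan-Meier curves come from `survival::survfit` and the unweighted
  log-rank test from `survival::survdiff`; both are cross-checked in the
  test suite against independently coded product-limit and O/E oracles.
  An empty group at the cutoff skips the test with a reason instead of
  erroring.

# The synthetic-data generator

`simConfig()` defaults describe the emulated study design: 1535 protein
IDs over 442 genes, two miRNA-secretome conditions, eight planted
markers (4 up, 4 down; 6 classical, 2 non-classical) at
$|\mathrm{log_2FC}| = 2.5$, 14 unmapped protein IDs, and a null
$-\log_{10} p$ distribution drawn Exponential with rate
$-\ln(0.08)/0.3$ so that its 92nd percentile sits at 0.3 — reproducing
the percentile-derived cutoff relation. Planted rows draw
$-\log_{10} p$ as $0.35 + \mathrm{Exp}(2)$, guaranteeing threshold
passage. Per-ID log2 FC scatters Normal(0, `null_log2fc_sd` = 0.5)
around the gene effect; the replicate dispersion of real FC estimates is
not published, so 0.5 is a choice — small enough that a 2.5-magnitude
effect essentially always survives gene averaging, large enough that
per-ID values visibly disagree. Setting it to 0 gives the noiseless
regime used for exact-recovery checks.

Decoys exercise every elimination branch: plain nulls (threshold), genes
planted with opposite signs per condition (concordance), genes removed
from the BSP list (tissue filter), genes with no secretion evidence
(consensus), and unmapped protein IDs (identifier handling). A
`bsp_dropout` fraction (default 0.1) of plain decoys is also removed
from the BSP list, and an `evidence_rate` fraction (default 0.3) of
decoys receives secretion evidence anyway, so annotation content is not
a giveaway for the planted markers.

The expression generator plants correlations by drawing each marker
jointly with independent latent cluster scores: within the signal
stratum the marker is $\sum_c \rho\, z_c + \sqrt{1 - k\rho^2}\,
\varepsilon$, giving population correlation exactly $\rho$ with each of
the $k$ clusters ($+\rho$ for up markers, $-\rho$ for down); other
strata use $\rho = 0$. Member miRNA columns equal the latent score plus
per-sample *centred* noise, so the cluster mean reproduces the latent
score exactly and the planted correlation survives averaging
unattenuated. The survival generator uses exponential event times with
the hazard multiplied by the planted ratio in the expression-high group
and an independent exponential censoring clock tuned to the requested
marginal censoring fraction.

All randomness flows from the single `seed` in `simConfig`; the
generator functions save and restore the caller's RNG state, and the
same configuration is byte-identical across runs.

**What the generator does not emulate:** correlated protein families
(real secretomes contain blocks of histones, septins and 14-3-3
proteins whose fold changes co-move), heavy-tailed or
intensity-dependent MS noise, missingness that depends on abundance,
batch structure, and real miRNA target networks. Passing tests on
synthetic data therefore demonstrate that the *logic* of every stage is
correct and calibrated, not that the thresholds are optimal for any
particular instrument or cell system.

# Problem sizes and numerical choices

The test suite runs study-scale bundles (1535 × 442) where recovery is
asserted, and smaller tables (hundreds of rows) for property loops; null
calibrations use 2,000 replicates for the Kolmogorov-Smirnov uniformity
checks and 1,000 cells for the star-tier rate. These sizes keep the
whole suite under a minute while leaving the Monte-Carlo assertions
comfortably inside their tolerances. Quantiles are type 7 everywhere;
correlation requires $n \ge 3$ and non-constant vectors and otherwise
reports an annotated NA row rather than failing a whole table; the
log-rank variance uses the hypergeometric form with ties pooled.

# Known limitations

* The secretion consensus consumes predictor outputs; it cannot rescue
  a gene the upstream predictors never scored, and the MDSEC majority
  rule is opaque to the package (a boolean input).
* Direction calls use gene-level means; a gene with strongly opposed
  isoform-specific secretion would be called discordant rather than
  resolved.
* The BH column in correlation tables adjusts across whatever table was
  computed — changing the strata plan changes the adjustment family.
* The funnel's counts depend on the strict-inequality convention at the
  cuts; data with values exactly at a cut (common after rounding) will
  differ from pipelines using non-strict comparisons, which is why
  boundary rows are counted and reported.
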