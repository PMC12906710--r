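# putscore

Putrescine-metabolism scoring for single-cell and bulk transcriptomes, and
its link to CXCR6+CD8+ T-cell function and patient survival in colorectal
cancer.

## What it does

Putrescine — the entry polyamine, made by ODC1/AGMAT, consumed by SRM and the
antizymes OAZ1/2/3, moved by the SLC22A1–3/SLC7A1 carriers, ATP13A2/3 and
GPC1 — shapes anti-tumour immunity. `putscore` implements the scoring
framework that quantifies this at three levels:

* **Per unit (cell or bulk sample).** A rank-based single-sample enrichment
  walk scores the three putrescine programmes,
  `S_In` (biosynthesis), `S_Loss` (loss) and `S_Trans` (transport):
  with genes ranked `rho_g` (1 = lowest) and walked by decreasing expression,
  `ES = sum_k [ P_in(k) - P_out(k) ]` where `P_in` is the rank-weighted
  (`rho^0.25`) in-set ECDF and `P_out` the uniform out-of-set ECDF. Derived
  indices: `S_extracellular = S_Trans / S_In`,
  `S_accumulation = S_In - S_Loss`.
* **Per cell / per sample.** `Exp_in` and `Exp_loss` (sums of log-normalized
  biosynthesis and loss gene expression), the accumulation score
  `S_PA = Exp_in / Exp_loss`, and the pericellular putrescine index of a
  sample, `Pi = S_1 / N` — the sum of `S_PA` over all non-CXCR6+CD8+ cells
  divided by the number of CXCR6+CD8+ T cells. The association of `Pi` with
  the per-sample median functional state of CXCR6+CD8+ cells (cytotoxicity,
  exhaustion, …) is estimated jointly by a cross-validated LASSO.
* **Cohort level.** ROC-AUC one-vs-rest marker selection (AUC > 0.85 and
  detection difference > 0.55), tumour-vs-normal responsiveness
  (`D_median`), per-cell QC with the two published threshold profiles,
  median-split Kaplan–Meier / log-rank survival contrasts, and canonical
  correlation attribution of pathway activity to the putrescine scores.

A synthetic cohort generator (`simulateScCohort`, `simulateBulkCohort`)
plants known effects in negative-binomial counts — never in the scores — and
records a ground-truth ledger, so every stage's recovery is testable.

## Worked example

```r
library(putscore)
library(SummarizedExperiment)

# a synthetic 80-sample cohort with a planted negative coupling between the
# sample-level putrescine burden and CXCR6+CD8+ cytotoxicity
cfg <- simConfig(coupling_beta = -0.8, seed = 1)
sce <- simulateScCohort(cfg)

counts  <- assay(sce, "counts")
ann     <- as.data.frame(colData(sce))
lognorm <- logNormalize(counts)
ann     <- labelCxcr6Cd8(counts, ann)

spa    <- spaScore(expScores(lognorm))
pi_rec <- piPerSample(spa, ann)
head(pi_rec, 3)
#>   sample_id       s1  n        pi valid
#> 1      S001  47.1165 11  4.283318  TRUE
#> 2      S002 292.7378  6 48.789639  TRUE
#> 3      S003 107.1596 15  7.143973  TRUE

target <- ann$cxcr6_status == "pos"
fun    <- ssgseaScore(lognorm[, target], builtinTFunctionalGenesets())
med    <- functionalMedians(fun, ann[target, ])
assoc  <- lassoAssociation(pi_rec, med, seed = 1)
round(assoc$coefficients["cytotoxicity"], 3)
#> cytotoxicity
#>       -0.149
round(assoc$spearman["cytotoxicity"], 3)
#> cytotoxicity
#>       -0.417
```

`Pi` here is the per-sample pericellular putrescine load around CXCR6+CD8+
T cells (`s1` sums the per-cell accumulation scores of the surrounding
cells, `n` counts the target cells). Both the descriptive Spearman
correlation between `Pi` and the per-sample cytotoxicity medians and the
CV-selected LASSO coefficient are negative, recovering the planted
suppression. The truth ledger in `metadata(sce)$truth` records the realized
planted correlation (`realized_spearman`, -0.499 at this seed) that the
measured value tracks.

## Layout

* `R/` — gene-set containers and GMT I/O; QC and downsampling; the
  enrichment walk; labelling, markers, DEG screen and `D_median`;
  `S_PA`/`Pi`/LASSO; survival; CCA; the synthetic generators; the pipeline
  orchestrator (`runPipeline`).
* `inst/extdata/` — the built-in putrescine sets as GMT, plus synthetic
  placeholder T-cell functional sets (substitute curated lists via
  `parseGMT`).
* `inst/scripts/putscore-cli.R` — thin command-line front end
  (`simulate`, `run-all`).
* `vignettes/putrescine-scoring-methods.Rmd` — the model, its assumptions,
  parameter choices and limitations.
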