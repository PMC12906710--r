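# small cohorts keep the unit tests fast; the full-size recovery runs live
# in test-acceptance.R
small_cfg <- function(...) simConfig(n_samples = 6L, cells_per_sample = 120L,
                                     n_noise_genes = 40L, ...)

test_that("identical (config, seed) reproduces the cohort bit for bit", {
  a <- simulateScCohort(small_cfg(seed = 9))
  b <- simulateScCohort(small_cfg(seed = 9))
  expect_identical(SummarizedExperiment::assay(a, "counts"),
                   SummarizedExperiment::assay(b, "counts"))
  expect_identical(S4Vectors::metadata(a)$truth,
                   S4Vectors::metadata(b)$truth)
  c <- simulateScCohort(small_cfg(seed = 10))
  expect_false(identical(SummarizedExperiment::assay(a, "counts"),
                         SummarizedExperiment::assay(c, "counts")))
})

test_that("counts are overdispersed relative to Poisson", {
  sce <- simulateScCohort(simConfig(n_samples = 2L,
                                    cells_per_sample = 400L,
                                    n_noise_genes = 40L, seed = 5))
  counts <- SummarizedExperiment::assay(sce, "counts")
  ann <- SummarizedExperiment::colData(sce)
  # within one (sample, broad type) stratum cells are i.i.d.
  idx <- which(ann$sample_id == "S001" & ann$broad_type == "Epithelial" &
                 !ann$cxcr6_true)
  m <- counts[, idx]
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  hi <- mu > 5
  expect_gt(mean(v[hi] / mu[hi]), 1.2)
})

test_that("annotation structure and target-cell guarantees hold", {
  cfg <- small_cfg(seed = 3)
  sce <- simulateScCohort(cfg)
  ann <- as.data.frame(SummarizedExperiment::colData(sce))
  expect_setequal(unique(ann$tissue), c("Tumor", "Normal"))
  expect_true(all(table(ann$sample_id) == 120L))
  # each sample has at least one true CXCR6+CD8+ cell
  by_sample <- tapply(ann$cxcr6_true, ann$sample_id, sum)
  expect_true(all(by_sample >= 1))
  # CXCR6+ cells are CD8 T cells
  expect_true(all(ann$t_subset[ann$cxcr6_true] == "CD8T"))
})

test_that("the planted CXCR6+ enrichment in tumors is realized", {
  cfg <- simConfig(n_samples = 10L, cells_per_sample = 500L,
                   n_noise_genes = 40L, seed = 21)
  sce <- simulateScCohort(cfg)
  ann <- as.data.frame(SummarizedExperiment::colData(sce))
  cd8 <- !is.na(ann$t_subset) & ann$t_subset == "CD8T"
  frac <- function(tiss)
    sum(ann$cxcr6_true[cd8 & ann$tissue == tiss]) /
      sum(cd8 & ann$tissue == tiss)
  expect_gt(frac("Tumor"), frac("Normal"))
})

test_that("marker genes are detected mostly in their defining populations", {
  sce <- simulateScCohort(simConfig(n_samples = 4L,
                                    cells_per_sample = 500L,
                                    n_noise_genes = 40L, seed = 6))
  counts <- SummarizedExperiment::assay(sce, "counts")
  ann <- as.data.frame(SummarizedExperiment::colData(sce))
  cd8 <- !is.na(ann$t_subset) & ann$t_subset == "CD8T"
  expect_gt(mean(counts["CD8A", cd8] > 0), 0.8)
  expect_lt(mean(counts["CD8A", !cd8] > 0), 0.12)
  expect_gt(mean(counts["CXCR6", ann$cxcr6_true] > 0), 0.8)
  expect_lt(mean(counts["CXCR6", !ann$cxcr6_true] > 0), 0.12)
})

test_that("infeasible single-cell configs are rejected", {
  expect_error(simulateScCohort(simConfig(cells_per_sample = 3L)),
               "at least the number of broad types")
  expect_error(simConfig(cell_type_proportions = c(A = 0.5, B = 0.6)),
               "sum to 1")
  expect_error(simConfig(cxcr6_frac_tumor = 1.4), "0, 1")
  expect_error(simConfig(baseline_hazard = 0), "positive")
})

test_that("bulk cohort reproduces and obeys the censoring contract", {
  cfg <- simConfig(n_samples = 30L, cells_per_sample = 120L,
                   n_noise_genes = 40L, seed = 12)
  a <- simulateBulkCohort(cfg)
  b <- simulateBulkCohort(cfg)
  expect_identical(SummarizedExperiment::assay(a, "counts"),
                   SummarizedExperiment::assay(b, "counts"))
  cd <- SummarizedExperiment::colData(a)
  expect_true(all(cd$event == 1))  # censoring rate 0: every event observed
  cens <- simulateBulkCohort(simConfig(n_samples = 50L,
                                       cells_per_sample = 120L,
                                       n_noise_genes = 40L,
                                       censoring_rate = 0.2, seed = 12))
  expect_true(any(SummarizedExperiment::colData(cens)$event == 0))
})

test_that("a planted transport hazard separates the measured score strata", {
  cfg <- simConfig(n_samples = 100L, cells_per_sample = 100L,
                   n_noise_genes = 40L, hazard_log_hr = log(2), seed = 33)
  se <- simulateBulkCohort(cfg)
  z <- bulkNormalize(SummarizedExperiment::assay(se, "counts"))
  sc <- ssgseaScore(z, builtinPutGenesets(), normalize = TRUE)
  tr <- S4Vectors::metadata(se)$truth
  expect_gt(cor(sc["put_transport", ], tr$transport_burden), 0.8)
  cd <- SummarizedExperiment::colData(se)
  ms <- medianSplitSurvival(
    data.frame(time = cd$time, event = cd$event,
               feature = sc["put_transport", ]), "feature")
  expect_lt(ms$logrank$p_value, 0.05)
})
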