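test_that("QC metrics compute the documented count fractions", {
  counts <- matrix(0, 6, 3,
                   dimnames = list(c("MT-CO1", "RPL3", "RPS4X", "HBB",
                                     "ACTB", "CXCR6"),
                                   c("c1", "c2", "c3")))
  counts[, 1] <- c(16, 0, 0, 0, 84, 0)
  counts[, 2] <- c(0, 30, 30, 0, 40, 0)
  counts[, 3] <- 0
  m <- computeQCMetrics(counts)
  expect_equal(m$mito_ratio[1], 0.16)
  expect_equal(m$ribo_ratio[2], 0.60)
  expect_equal(m$n_count[3], 0)
  expect_true(m$zero_total[3])
  expect_equal(m$mito_ratio[3], 0)
  # fractions of disjoint gene families cannot exceed 1 jointly
  expect_true(all(m$mito_ratio + m$ribo_ratio + m$hb_ratio <= 1 + 1e-12))
  expect_error(computeQCMetrics(counts[0, , drop = FALSE]), "zero genes")
})

test_that("the two threshold profiles carry the published cutoffs", {
  ti <- qcThresholds("integrated")
  expect_equal(ti[c("mito_max", "ribo_max", "hb_max")],
               list(mito_max = 0.15, ribo_max = 0.50, hb_max = 0.01))
  expect_equal(ti$n_count_max, 10000L)
  expect_equal(c(ti$n_feature_min, ti$n_feature_max), c(400L, 6000L))
  tm <- qcThresholds("mmr")
  expect_equal(tm$mito_max, 0.30)
  expect_equal(tm$n_feature_max, 7000L)
  expect_error(qcThresholds("bogus"), "unknown")
})

test_that("filtering applies strict-exclusion boundaries per profile", {
  mk <- function(mito = 0, ribo = 0, hb = 0, n_count = 2000,
                 n_feature = 1000)
    S4Vectors::DataFrame(n_count = n_count, n_feature = n_feature,
                         mito_ratio = mito, ribo_ratio = ribo,
                         hb_ratio = hb)
  keep1 <- function(m, p) filterCells(m, qcThresholds(p))$keep
  expect_false(keep1(mk(mito = 0.16), "integrated"))
  expect_true(keep1(mk(mito = 0.16), "mmr"))
  expect_true(keep1(mk(mito = 0.15), "integrated"))  # boundary kept
  expect_true(keep1(mk(n_feature = 400), "integrated"))
  expect_false(keep1(mk(n_feature = 399), "integrated"))
  expect_true(keep1(mk(n_feature = 6000), "integrated"))
  expect_false(keep1(mk(n_feature = 6500), "integrated"))
  expect_true(keep1(mk(n_feature = 6500), "mmr"))
  expect_true(keep1(mk(n_count = 10000), "integrated"))
  expect_false(keep1(mk(n_count = 10001), "integrated"))
})

test_that("filtering equals brute-force rule evaluation on random metrics", {
  set.seed(11)
  n <- 200
  m <- S4Vectors::DataFrame(
    n_count = sample(c(500, 9000, 10001, 15000), n, TRUE),
    n_feature = sample(c(399, 400, 3000, 6000, 6001, 7100), n, TRUE),
    mito_ratio = sample(c(0, 0.1, 0.15, 0.2, 0.31), n, TRUE),
    ribo_ratio = sample(c(0, 0.4, 0.5, 0.55), n, TRUE),
    hb_ratio = sample(c(0, 0.005, 0.02), n, TRUE))
  for (p in c("integrated", "mmr")) {
    thr <- qcThresholds(p)
    brute <- vapply(seq_len(n), function(i)
      !(m$mito_ratio[i] > thr$mito_max || m$ribo_ratio[i] > thr$ribo_max ||
        m$hb_ratio[i] > thr$hb_max || m$n_count[i] > thr$n_count_max ||
        m$n_feature[i] < thr$n_feature_min ||
        m$n_feature[i] > thr$n_feature_max), logical(1))
    res <- filterCells(m, thr)
    expect_identical(res$keep, brute)
    expect_equal(unname(res$summary["kept"]), sum(brute))
  }
})

test_that("noise-gene stripping removes MT-/RPL/RPS prefixes only", {
  counts <- make_count_fixture(c("MT-CO1", "RPL3", "RPS4X", "ACTB",
                                 "CXCR6"), 4)
  out <- stripNoiseGenes(counts)
  expect_identical(rownames(out), c("ACTB", "CXCR6"))
  expect_identical(out["ACTB", ], counts["ACTB", ])
  expect_identical(stripNoiseGenes(counts[4:5, ]), counts[4:5, ])
  expect_error(stripNoiseGenes(counts[1:2, ]), "every gene")
  # metrics computed after stripping would lose the mito signal entirely
  expect_equal(computeQCMetrics(out)$mito_ratio, rep(0, 4))
})

test_that("per-group downsampling caps deterministically", {
  ann <- data.frame(ct = rep(c("A", "B"), c(30, 120)))
  keep <- downsamplePerGroup(ann, "ct", cap = 50L, seed = 7)
  expect_equal(sum(keep[ann$ct == "A"]), 30)   # under cap: all kept
  expect_equal(sum(keep[ann$ct == "B"]), 50)   # capped exactly
  expect_identical(keep, downsamplePerGroup(ann, "ct", cap = 50L, seed = 7))
  expect_false(identical(keep,
                         downsamplePerGroup(ann, "ct", cap = 50L,
                                            seed = 8)))
  expect_error(downsamplePerGroup(ann, "nope", 10L, 1), "unknown group_key")
})
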