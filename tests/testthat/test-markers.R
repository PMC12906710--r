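make_label_fixture <- function() {
  counts <- rbind(CXCR6 = c(3, 0, 5, 1, 0),
                  CD8A = c(9, 8, 0, 7, 2),
                  ACTB = c(5, 5, 5, 5, 5))
  colnames(counts) <- paste0("c", 1:5)
  ann <- data.frame(cell_id = colnames(counts),
                    sample_id = "S1", subject_id = "P1", tissue = "Tumor",
                    broad_type = "TNKILC",
                    t_subset = c("CD8T", "CD8T", "CD4T", "CD8T", "CD8T"))
  list(counts = counts, ann = ann)
}

test_that("CXCR6+CD8+ labelling follows the detection rule and subset guard", {
  fx <- make_label_fixture()
  ann <- labelCxcr6Cd8(fx$counts, fx$ann)
  expect_equal(as.character(ann$cxcr6_status),
               c("pos", "neg", "na", "pos", "neg"))
  expect_error(labelCxcr6Cd8(fx$counts[-1, , drop = FALSE], fx$ann),
               "CXCR6")
})

test_that("expression percentage counts detected cells", {
  counts <- rbind(G = c(0, 0, 5, 1))
  colnames(counts) <- paste0("c", 1:4)
  expect_equal(pctExpressed(counts, rep(TRUE, 4), "G"), 0.5)
  expect_equal(pctExpressed(counts * 0, rep(TRUE, 4), "G"), 0)
  expect_equal(pctExpressed(counts + 1, rep(TRUE, 4), "G"), 1)
  expect_error(pctExpressed(counts, rep(FALSE, 4), "G"), "empty")
})

test_that("AUC matches the exhaustive pair-counting oracle", {
  set.seed(21)
  for (rep in 1:20) {
    n_t <- sample(3:25, 1); n_r <- sample(3:25, 1)
    vals <- matrix(sample(0:5, 2 * (n_t + n_r), TRUE), 2)
    colnames(vals) <- paste0("c", seq_len(ncol(vals)))
    rownames(vals) <- c("g1", "g2")
    mask <- c(rep(TRUE, n_t), rep(FALSE, n_r))
    res <- aucMarkerScan(vals, mask, forced = character())
    for (g in c("g1", "g2"))
      expect_equal(res$auc[res$gene == g],
                   oracle_auc(vals[g, mask], vals[g, !mask]))
  }
})

test_that("AUC hand cases: separation, ties, scale invariance", {
  m <- rbind(perfect = c(2, 3, 4, 0, 0, 1),
             tied = rep(1, 6),
             mixed = c(0, 2, 0, 1, 3, 0))
  colnames(m) <- paste0("c", 1:6)
  mask <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  res <- aucMarkerScan(m, mask, forced = character())
  expect_equal(res$auc[res$gene == "perfect"], 1.0)
  expect_equal(res$auc[res$gene == "tied"], 0.5)
  expect_equal(res$auc[res$gene == "mixed"],
               oracle_auc(m["mixed", mask], m["mixed", !mask]))
  scaled <- aucMarkerScan(m * 17, mask, forced = character())
  expect_equal(scaled$auc, res$auc)
  expect_equal(scaled$pct_diff, res$pct_diff)
})

test_that("marker selection applies both thresholds plus the forced list", {
  set.seed(4)
  n <- 60
  mask <- rep(c(TRUE, FALSE), c(20, 40))
  m <- rbind(planted = ifelse(mask, rpois(n, 6), rbinom(n, 1, 0.05)),
             null1 = rpois(n, 2),
             CD8A = rpois(n, 2))  # forced despite no signal
  colnames(m) <- paste0("c", 1:n)
  res <- aucMarkerScan(m, mask)
  expect_true(res$selected[res$gene == "planted"])
  expect_false(res$selected[res$gene == "null1"])
  expect_true(res$selected[res$gene == "CD8A"])
  expect_equal(res$gene[1], "planted")  # sorted by AUC descending
})

test_that("DEG screen filters on detection and adjusts p-values", {
  set.seed(9)
  n <- 40
  mask_a <- rep(c(TRUE, FALSE), each = n / 2)
  expr <- rbind(rare = rbinom(n, 1, 0.1) * 0.5,
                shifted = c(rnorm(n / 2, 3), rnorm(n / 2, 0)),
                flat = rnorm(n, 1))
  expr[expr < 0] <- 0
  colnames(expr) <- paste0("c", 1:n)
  res <- degScreen(expr, mask_a, !mask_a, min_pct = 0.3)
  expect_false("rare" %in% res$gene)      # <30% detection in both groups
  expect_equal(res$gene[1], "shifted")
  expect_true(all(res$p_adj >= res$p - 1e-12))
  # identical group distributions: no significance
  same <- rbind(g = rep(c(1, 2, 3, 4), 10))
  colnames(same) <- paste0("c", 1:40)
  grp1 <- rep(c(TRUE, FALSE), each = 20)
  res0 <- degScreen(same, grp1, !grp1)
  expect_true(all(res0$p_adj > 0.9))
  expect_warning(degScreen(same * 0, mask_a, !mask_a), "min_pct")
})

test_that("proportion table computes fractions and tissue contrasts", {
  ann <- data.frame(
    cell_id = sprintf("c%02d", 1:40),
    sample_id = rep(c("T1", "N1", "T2", "N2"), each = 10),
    subject_id = rep(c("P1", "P1", "P2", "P2"), each = 10),
    tissue = rep(c("Tumor", "Normal", "Tumor", "Normal"), each = 10),
    broad_type = "TNKILC",
    t_subset = rep(c("CD8T", "CD4T"), 20),
    cxcr6_status = "na", stringsAsFactors = FALSE)
  # per sample: 5 CD8T; tumor samples get 2 positives, normal 1
  ann$cxcr6_status[ann$t_subset == "CD8T"] <- "neg"
  for (s in c("T1", "T2"))
    ann$cxcr6_status[which(ann$sample_id == s &
                             ann$t_subset == "CD8T")[1:2]] <- "pos"
  for (s in c("N1", "N2"))
    ann$cxcr6_status[which(ann$sample_id == s &
                             ann$t_subset == "CD8T")[1]] <- "pos"
  pt <- proportionTable(ann)
  t1 <- pt$per_sample[pt$per_sample$sample_id == "T1", ]
  expect_equal(t1$frac_all, 0.2)
  expect_equal(t1$frac_cd8, 0.4)
  expect_equal(pt$n_pairs, 2L)
  expect_true(is.finite(pt$unpaired_p))
  # identical fractions across tissues within subject -> paired p = 1
  ann2 <- ann
  ann2$cxcr6_status[ann2$t_subset == "CD8T"] <- "neg"
  for (s in c("T1", "T2", "N1", "N2"))
    ann2$cxcr6_status[which(ann2$sample_id == s &
                              ann2$t_subset == "CD8T")[1]] <- "pos"
  expect_equal(proportionTable(ann2)$paired_p, 1)
})

test_that("fractions handle samples without CD8 T cells", {
  ann <- data.frame(cell_id = c("a", "b"), sample_id = "S1",
                    subject_id = "P1", tissue = "Tumor",
                    broad_type = "B", t_subset = NA_character_,
                    cxcr6_status = "na")
  pt <- suppressWarnings(proportionTable(ann))
  expect_true(is.na(pt$per_sample$frac_cd8))
})

test_that("d_median is the median difference, antisymmetric, pair-filterable", {
  scores <- matrix(c(0.2, 0.4, 0.6, 0.1, 0.2, 0.3), 1,
                   dimnames = list("cytotoxicity", sprintf("c%d", 1:6)))
  ann <- data.frame(
    sample_id = rep(c("T1", "N1"), each = 3),
    subject_id = c("P1", "P1", "P2", "P1", "P1", "P3"),
    tissue = rep(c("Tumor", "Normal"), each = 3))
  grp <- rep(TRUE, 6)
  r <- dMedian(scores, ann, grp, "cytotoxicity")
  expect_equal(r$d_median, 0.4 - 0.2)
  # swap tissue labels -> sign flips
  ann_sw <- ann
  ann_sw$tissue <- rev(ann$tissue)
  r_sw <- dMedian(scores, ann_sw, grp, "cytotoxicity")
  expect_equal(r_sw$d_median, -r$d_median)
  # paired-only excludes subjects lacking both tissues (P2, P3)
  rp <- dMedian(scores, ann, grp, "cytotoxicity", paired_only = TRUE)
  expect_equal(rp$d_median,
               median(c(0.2, 0.4)) - median(c(0.1, 0.2)))
  expect_equal(rp$n_tumor, 2L)
  # identical distributions -> 0
  sc0 <- matrix(rep(c(0.1, 0.2, 0.3), 2), 1,
                dimnames = list("s", sprintf("c%d", 1:6)))
  expect_equal(dMedian(sc0, ann, grp, "s")$d_median, 0)
  expect_error(dMedian(scores, ann, c(TRUE, TRUE, TRUE, FALSE, FALSE,
                                      FALSE), "cytotoxicity"),
               "non-empty")
})
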