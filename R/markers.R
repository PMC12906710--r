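.check_annotation <- function(ann, n_cells = NULL) {
  req <- c("cell_id", "sample_id", "subject_id", "tissue", "broad_type")
  if (!all(req %in% colnames(ann)))
    stop("annotation must contain columns: ", paste(req, collapse = ", "))
  if (!is.null(n_cells) && nrow(ann) != n_cells)
    stop("annotation rows (", nrow(ann), ") do not match cells (",
         n_cells, ")")
  invisible(ann)
}

#' Label CXCR6+ CD8+ T cells from expression
#'
#' CD8 T cells with at least one CXCR6 count are labelled \code{pos}, CD8 T
#' cells without detectable CXCR6 \code{neg}, and every other cell \code{na}.
#' The positivity rule (count > 0) is the standard single-cell detection
#' convention; the threshold is configurable.
#'
#' @param counts Raw count matrix containing a \code{CXCR6} row.
#' @param ann Per-cell annotation with a \code{t_subset} column (CD8 T cells
#'   coded \code{"CD8T"}).
#' @param min_count Minimum CXCR6 count to call a cell positive (default 1).
#' @return \code{ann} with a \code{cxcr6_status} factor column
#'   (\code{pos}/\code{neg}/\code{na}).
#' @export
labelCxcr6Cd8 <- function(counts, ann, min_count = 1L) {
  counts <- .as_counts_matrix(counts)
  sym <- toupper(rownames(counts))
  if (!"CXCR6" %in% sym) stop("CXCR6 is absent from the gene symbols")
  if (!"t_subset" %in% colnames(ann))
    stop("annotation lacks a 't_subset' column")
  cx <- as.numeric(counts[match("CXCR6", sym), ])
  is_cd8 <- !is.na(ann$t_subset) & ann$t_subset == "CD8T"
  status <- rep("na", nrow(ann))
  status[is_cd8] <- ifelse(cx[is_cd8] >= min_count, "pos", "neg")
  ann$cxcr6_status <- factor(status, levels = c("pos", "neg", "na"))
  ann
}

#' Fraction of cells expressing a gene
#'
#' @param counts Count (or log-normalized) matrix.
#' @param mask Logical or integer cell subset; must be non-empty.
#' @param gene Gene symbol.
#' @return Fraction of masked cells with value > 0.
#' @export
pctExpressed <- function(counts, mask, gene) {
  counts <- .as_counts_matrix(counts)
  idx <- if (is.logical(mask)) which(mask) else as.integer(mask)
  if (length(idx) == 0L) stop("empty cell mask")
  g <- match(toupper(gene), toupper(rownames(counts)))
  if (is.na(g)) stop("gene not found: ", gene)
  mean(counts[g, idx] > 0)
}

# Midrank (Mann-Whitney) AUC of values for target vs rest, one gene at a
# time, vectorized over genes: AUC = (R_target - n_t(n_t+1)/2) / (n_t * n_r).
.auc_rowwise <- function(expr, target) {
  n_t <- sum(target); n_r <- sum(!target)
  apply(expr, 1L, function(x) {
    r <- rank(x, ties.method = "average")
    (sum(r[target]) - n_t * (n_t + 1) / 2) / (n_t * n_r)
  })
}

#' ROC-AUC one-vs-rest marker scan
#'
#' For every gene, the AUC of a rank-sum (Mann-Whitney) classifier separating
#' the target cells from all others is computed with midrank tie handling,
#' together with the detection percentage in each group. A gene is selected
#' iff \code{auc > auc_min} and the signed detection difference
#' \code{pct_target - pct_rest > diff_min}, or it belongs to the
#' \code{forced} list (canonical lineage markers retained regardless of
#' thresholds). Records are sorted by AUC, descending.
#'
#' @param expr Expression matrix (log-normalized; AUC and detection fractions
#'   are invariant to positive rescaling).
#' @param target_mask Logical mask of target cells (e.g. CXCR6+CD8+); target
#'   and rest must each contain at least 2 cells.
#' @param auc_min AUC threshold (default 0.85).
#' @param diff_min Detection-difference threshold (default 0.55).
#' @param forced Genes always marked selected when present (default the
#'   CXCR6+CD8+ lineage panel CD3D, CD3E, CD8A, CD8B, CXCR6).
#' @return data.frame: gene, auc, pct_target, pct_rest, pct_diff, selected.
#' @export
aucMarkerScan <- function(expr, target_mask, auc_min = 0.85,
                          diff_min = 0.55,
                          forced = c("CD3D", "CD3E", "CD8A", "CD8B",
                                     "CXCR6")) {
  expr <- as.matrix(.as_counts_matrix(expr))
  target_mask <- as.logical(target_mask)
  if (length(target_mask) != ncol(expr))
    stop("target mask length does not match cell count")
  if (sum(target_mask) < 2L || sum(!target_mask) < 2L)
    stop("target and rest must each contain at least 2 cells")
  auc <- .auc_rowwise(expr, target_mask)
  pct_t <- rowMeans(expr[, target_mask, drop = FALSE] > 0)
  pct_r <- rowMeans(expr[, !target_mask, drop = FALSE] > 0)
  out <- data.frame(gene = rownames(expr), auc = auc,
                    pct_target = pct_t, pct_rest = pct_r,
                    pct_diff = pct_t - pct_r, row.names = NULL)
  out$selected <- (out$auc > auc_min & out$pct_diff > diff_min) |
    toupper(out$gene) %in% toupper(forced)
  out[order(-out$auc, out$gene), , drop = FALSE]
}

#' Differential-expression screen between two cell groups
#'
#' Genes detected in at least \code{min_pct} of cells in either group are
#' tested with a two-sided rank-sum (Wilcoxon) test on log-normalized
#' expression; p-values are Benjamini-Hochberg adjusted; the log fold change
#' is the difference of group means on the log scale.
#'
#' @param expr Log-normalized expression matrix.
#' @param mask_a,mask_b Logical masks of the two groups (>= 3 cells each).
#' @param min_pct Minimum detection fraction in at least one group
#'   (default 0.3).
#' @return data.frame: gene, lfc, p, p_adj, pct_a, pct_b; empty (with a
#'   warning) when no gene passes the detection filter.
#' @export
degScreen <- function(expr, mask_a, mask_b, min_pct = 0.3) {
  expr <- as.matrix(.as_counts_matrix(expr))
  mask_a <- as.logical(mask_a); mask_b <- as.logical(mask_b)
  if (sum(mask_a) < 3L || sum(mask_b) < 3L)
    stop("each group must contain at least 3 cells")
  pct_a <- rowMeans(expr[, mask_a, drop = FALSE] > 0)
  pct_b <- rowMeans(expr[, mask_b, drop = FALSE] > 0)
  testable <- pct_a >= min_pct | pct_b >= min_pct
  if (!any(testable)) {
    warning("no genes pass the min_pct detection filter")
    return(data.frame(gene = character(), lfc = numeric(), p = numeric(),
                      p_adj = numeric(), pct_a = numeric(),
                      pct_b = numeric()))
  }
  genes <- which(testable)
  p <- vapply(genes, function(g)
    suppressWarnings(wilcox.test(expr[g, mask_a], expr[g, mask_b],
                                 exact = FALSE)$p.value), numeric(1))
  p[is.na(p)] <- 1  # fully tied gene: no evidence of difference
  lfc <- rowMeans(expr[genes, mask_a, drop = FALSE]) -
    rowMeans(expr[genes, mask_b, drop = FALSE])
  out <- data.frame(gene = rownames(expr)[genes], lfc = lfc, p = p,
                    p_adj = p.adjust(p, "BH"),
                    pct_a = pct_a[genes], pct_b = pct_b[genes],
                    row.names = NULL)
  out[order(out$p_adj, out$p, out$gene), , drop = FALSE]
}

#' Per-sample CXCR6+CD8+ proportions with tissue contrasts
#'
#' Computes, per sample, the fraction of CXCR6+CD8+ cells among all cells
#' and among CD8 T cells, then compares Tumor against Normal samples: a
#' paired Wilcoxon signed-rank test across subjects contributing both
#' tissues, and an unpaired rank-sum test over all samples. Border-tissue
#' samples are excluded from the contrasts. Samples without CD8 T cells get
#' a missing among-CD8 fraction.
#'
#' @param ann Per-cell annotation with \code{cxcr6_status} labels.
#' @return list: \code{per_sample} data.frame (sample_id, subject_id, tissue,
#'   n_cells, n_cd8, n_pos, frac_all, frac_cd8), \code{paired_p},
#'   \code{unpaired_p} (each NA, with a warning, when inapplicable), and
#'   \code{n_pairs}.
#' @export
proportionTable <- function(ann) {
  .check_annotation(ann)
  if (!"cxcr6_status" %in% colnames(ann))
    stop("annotation lacks 'cxcr6_status'; run labelCxcr6Cd8 first")
  ann <- as.data.frame(ann)
  sp <- split(ann, ann$sample_id)
  per <- do.call(rbind, lapply(sp, function(d) {
    n_cd8 <- sum(d$t_subset == "CD8T", na.rm = TRUE)
    n_pos <- sum(d$cxcr6_status == "pos")
    data.frame(sample_id = d$sample_id[1], subject_id = d$subject_id[1],
               tissue = as.character(d$tissue[1]), n_cells = nrow(d),
               n_cd8 = n_cd8, n_pos = n_pos,
               frac_all = n_pos / nrow(d),
               frac_cd8 = if (n_cd8 > 0) n_pos / n_cd8 else NA_real_)
  }))
  rownames(per) <- NULL
  tn <- per[per$tissue %in% c("Tumor", "Normal"), ]
  unpaired_p <- paired_p <- NA_real_
  n_pairs <- 0L
  if (all(c("Tumor", "Normal") %in% tn$tissue)) {
    unpaired_p <- suppressWarnings(
      wilcox.test(frac_cd8 ~ tissue, data = tn[!is.na(tn$frac_cd8), ],
                  exact = FALSE)$p.value)
    # subject-level pairing: mean fraction per (subject, tissue)
    agg <- stats::aggregate(frac_cd8 ~ subject_id + tissue, data = tn,
                            FUN = mean, na.rm = TRUE)
    wide <- merge(agg[agg$tissue == "Tumor", c("subject_id", "frac_cd8")],
                  agg[agg$tissue == "Normal", c("subject_id", "frac_cd8")],
                  by = "subject_id", suffixes = c("_tumor", "_normal"))
    wide <- wide[complete.cases(wide), ]
    n_pairs <- nrow(wide)
    if (n_pairs >= 1L) {
      paired_p <- suppressWarnings(
        wilcox.test(wide$frac_cd8_tumor, wide$frac_cd8_normal,
                    paired = TRUE, exact = FALSE)$p.value)
      if (is.na(paired_p)) paired_p <- 1  # all differences zero
    } else {
      warning("no subjects with both tissues; paired test omitted")
    }
  } else {
    warning("need both Tumor and Normal samples for tissue contrasts")
  }
  list(per_sample = per, paired_p = paired_p, unpaired_p = unpaired_p,
       n_pairs = n_pairs)
}

#' Tumor-versus-normal median score difference (D_median)
#'
#' For a gene set and cell group, the responsiveness statistic
#' \code{D_median = median(score | tumor cells) - median(score | normal
#' cells)}. Optionally restricted to subjects contributing both tissues so
#' the contrast is within-subject. Swapping the tissue labels flips the sign.
#'
#' @param scores Score matrix (sets x cells) from \code{\link{ssgseaScore}}.
#' @param ann Per-cell annotation aligned with the score columns.
#' @param cell_group Logical mask of the cells to consider (e.g. CXCR6+CD8+).
#' @param gene_set Row name of the set to contrast.
#' @param paired_only Restrict to subjects with both tissues (default FALSE).
#' @return list: \code{d_median}, \code{n_tumor}, \code{n_normal},
#'   \code{gene_set}.
#' @export
dMedian <- function(scores, ann, cell_group, gene_set,
                    paired_only = FALSE) {
  if (!gene_set %in% rownames(scores))
    stop("gene set not present in score matrix: ", gene_set)
  cell_group <- as.logical(cell_group)
  keep <- cell_group & ann$tissue %in% c("Tumor", "Normal")
  if (paired_only) {
    tiss_by_subj <- split(as.character(ann$tissue[keep]),
                          as.character(ann$subject_id[keep]))
    both <- names(tiss_by_subj)[vapply(tiss_by_subj, function(t)
      all(c("Tumor", "Normal") %in% t), logical(1))]
    keep <- keep & as.character(ann$subject_id) %in% both
  }
  s <- scores[gene_set, ]
  tum <- s[keep & ann$tissue == "Tumor"]
  nor <- s[keep & ann$tissue == "Normal"]
  if (length(tum) == 0L || length(nor) == 0L)
    stop("both tissue groups must be non-empty within the cell group")
  list(d_median = median(tum) - median(nor),
       n_tumor = length(tum), n_normal = length(nor), gene_set = gene_set)
}
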