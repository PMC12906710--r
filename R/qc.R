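.HEMOGLOBIN_GENES <- c("HBA1", "HBA2", "HBB", "HBD", "HBE1",
                       "HBG1", "HBG2", "HBM", "HBQ1", "HBZ")

.as_counts_matrix <- function(counts) {
  if (is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  if (is.null(rownames(counts)))
    stop("expression matrix must carry gene symbols as rownames")
  counts
}

#' Per-cell quality-control metrics
#'
#' Computes total counts, detected features and the mitochondrial, ribosomal
#' and hemoglobin count fractions per cell. Mitochondrial genes are those
#' with symbol prefix \code{MT-}; ribosomal genes have prefix \code{RPL} or
#' \code{RPS}; hemoglobin genes are the fixed list HBA1/HBA2/HBB/HBD/HBE1/
#' HBG1/HBG2/HBM/HBQ1/HBZ (a prefix rule would also catch HBEGF). Cells with
#' zero total counts receive all-zero ratios and are flagged. Metrics must be
#' computed \emph{before} \code{\link{stripNoiseGenes}} — afterwards the
#' mitochondrial and ribosomal fractions are identically zero.
#'
#' @param counts Raw integer count matrix (genes x cells, symbols as
#'   rownames), dense or \code{dgCMatrix}, or a SummarizedExperiment with a
#'   \code{counts} assay.
#' @return A \code{DataFrame} with one row per cell: \code{n_count},
#'   \code{n_feature}, \code{mito_ratio}, \code{ribo_ratio}, \code{hb_ratio},
#'   \code{zero_total} flag.
#' @export
computeQCMetrics <- function(counts) {
  if (nrow(counts) == 0L) stop("count matrix has zero genes")
  counts <- .as_counts_matrix(counts)
  sym <- toupper(rownames(counts))
  mito <- startsWith(sym, "MT-")
  ribo <- startsWith(sym, "RPL") | startsWith(sym, "RPS")
  hb <- sym %in% .HEMOGLOBIN_GENES
  tot <- unname(Matrix::colSums(counts))
  nfeat <- unname(Matrix::colSums(counts > 0))
  safe_tot <- ifelse(tot > 0, tot, 1)
  ratio <- function(mask) {
    if (!any(mask)) return(numeric(ncol(counts)))
    as.numeric(Matrix::colSums(counts[mask, , drop = FALSE])) / safe_tot
  }
  S4Vectors::DataFrame(
    n_count = as.numeric(tot),
    n_feature = as.integer(nfeat),
    mito_ratio = ratio(mito),
    ribo_ratio = ratio(ribo),
    hb_ratio = ratio(hb),
    zero_total = tot == 0,
    row.names = colnames(counts))
}

#' Named QC threshold profiles
#'
#' Two profiles mirror the two filtering regimes used for, respectively, the
#' merged multi-dataset object ("integrated") and the mismatch-repair cohort
#' ("mmr", which tolerates a higher mitochondrial fraction and feature
#' count): \describe{
#'   \item{integrated}{mito > 15\%, ribo > 50\%, hb > 1\%, total counts >
#'     10,000, features < 400 or > 6,000 excluded.}
#'   \item{mmr}{as above but mito > 30\% and features > 7,000.}
#' }
#' Exclusions are strict inequalities, so boundary cells (e.g. exactly 400
#' features, exactly 15\% mitochondrial) are kept.
#'
#' @param profile \code{"integrated"} or \code{"mmr"}, or a list overriding
#'   individual fields of the integrated profile.
#' @return A named list: \code{mito_max}, \code{ribo_max}, \code{hb_max},
#'   \code{n_count_max}, \code{n_feature_min}, \code{n_feature_max},
#'   \code{profile}.
#' @export
qcThresholds <- function(profile = "integrated") {
  base <- list(mito_max = 0.15, ribo_max = 0.50, hb_max = 0.01,
               n_count_max = 10000L, n_feature_min = 400L,
               n_feature_max = 6000L, profile = "integrated")
  if (is.list(profile)) {
    out <- utils::modifyList(base, profile)
    out$profile <- if (is.null(profile$profile)) "custom" else profile$profile
  } else if (identical(profile, "integrated")) {
    out <- base
  } else if (identical(profile, "mmr")) {
    out <- utils::modifyList(base, list(mito_max = 0.30,
                                        n_feature_max = 7000L,
                                        profile = "mmr"))
  } else stop("unknown QC profile: ", profile)
  if (out$n_feature_min >= out$n_feature_max)
    stop("n_feature_min must be below n_feature_max")
  out
}

#' Filter cells on QC metrics
#'
#' A cell is kept iff \code{mito_ratio <= mito_max} and
#' \code{ribo_ratio <= ribo_max} and \code{hb_ratio <= hb_max} and
#' \code{n_count <= n_count_max} and
#' \code{n_feature_min <= n_feature <= n_feature_max}. Because the exclusion
#' rules are written as strict inequalities (">15\%", "<400"), boundary
#' values survive.
#'
#' @param metrics Output of \code{\link{computeQCMetrics}}.
#' @param thresholds Output of \code{\link{qcThresholds}}.
#' @return A list: \code{keep} (logical mask over cells) and \code{summary}
#'   (named counts of cells failing each criterion, plus kept/total).
#' @export
filterCells <- function(metrics, thresholds = qcThresholds()) {
  req <- c("n_count", "n_feature", "mito_ratio", "ribo_ratio", "hb_ratio")
  if (!all(req %in% colnames(metrics)))
    stop("metrics must contain columns: ", paste(req, collapse = ", "))
  fail_mito <- metrics$mito_ratio > thresholds$mito_max
  fail_ribo <- metrics$ribo_ratio > thresholds$ribo_max
  fail_hb   <- metrics$hb_ratio > thresholds$hb_max
  fail_cnt  <- metrics$n_count > thresholds$n_count_max
  fail_lo   <- metrics$n_feature < thresholds$n_feature_min
  fail_hi   <- metrics$n_feature > thresholds$n_feature_max
  keep <- !(fail_mito | fail_ribo | fail_hb | fail_cnt | fail_lo | fail_hi)
  list(keep = as.logical(keep),
       summary = c(total = nrow(metrics), kept = sum(keep),
                   fail_mito = sum(fail_mito), fail_ribo = sum(fail_ribo),
                   fail_hb = sum(fail_hb), fail_count = sum(fail_cnt),
                   fail_feature_low = sum(fail_lo),
                   fail_feature_high = sum(fail_hi)))
}

#' Remove mitochondrial and ribosomal genes
#'
#' Strips genes with symbol prefix \code{MT-}, \code{RPL} or \code{RPS} from
#' the matrix; remaining counts are untouched. Apply only after
#' \code{\link{computeQCMetrics}}: the mitochondrial/ribosomal fractions are
#' meaningless on the stripped matrix.
#'
#' @param counts Count matrix with gene symbols as rownames.
#' @return The matrix without noise genes.
#' @export
stripNoiseGenes <- function(counts) {
  counts <- .as_counts_matrix(counts)
  sym <- toupper(rownames(counts))
  drop <- startsWith(sym, "MT-") | startsWith(sym, "RPL") |
    startsWith(sym, "RPS")
  if (all(drop)) stop("stripping noise genes would remove every gene")
  counts[!drop, , drop = FALSE]
}

#' Downsample cells per group to a cap
#'
#' Within each level of \code{ann[[group_key]]}: groups at or below
#' \code{cap} are kept in full; larger groups are reduced to exactly
#' \code{cap} cells by uniform sampling without replacement. Deterministic
#' for a fixed seed.
#'
#' @param ann A data.frame/DataFrame of per-cell annotation.
#' @param group_key Column name to group by (e.g. broad cell type).
#' @param cap Maximum cells per group (default 10000).
#' @param seed Integer seed.
#' @return Logical keep-mask over rows of \code{ann}.
#' @export
downsamplePerGroup <- function(ann, group_key, cap = 10000L, seed = 1L) {
  if (!group_key %in% colnames(ann))
    stop("unknown group_key: ", group_key)
  stopifnot(cap >= 1L)
  groups <- as.character(ann[[group_key]])
  keep <- logical(nrow(ann))
  .with_seed(seed, {
    for (g in sort(unique(groups))) {
      idx <- which(groups == g)
      if (length(idx) <= cap) keep[idx] <- TRUE
      else keep[sample(idx, cap)] <- TRUE
    }
  })
  keep
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  eval.parent(substitute(expr))
}
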