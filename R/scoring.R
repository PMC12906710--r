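#' Library-size log-normalization
#'
#' Per unit (cell or sample): \code{x -> ln(1 + scale * x / total)}. Units
#' with zero total counts get all-zero output with a warning. Doubling every
#' count of a unit leaves its normalized values unchanged (only proportions
#' enter).
#'
#' @param counts Non-negative count matrix (genes x units), dense or sparse.
#' @param scale Scale factor (default 1e4).
#' @return A dense numeric matrix of the same shape.
#' @export
logNormalize <- function(counts, scale = 1e4) {
  counts <- .as_counts_matrix(counts)
  if (any(counts < 0)) stop("negative counts are not allowed")
  tot <- Matrix::colSums(counts)
  if (any(tot == 0))
    warning(sum(tot == 0), " unit(s) with zero total counts; output zeroed")
  denom <- ifelse(tot > 0, tot, 1)
  out <- sweep(as.matrix(counts), 2L, denom, "/")
  dimnames(out) <- dimnames(counts)
  log1p(scale * out)
}

#' Bulk normalization: log2 then per-gene z-score
#'
#' For bulk profiles on the TPM scale: per gene, \code{log2(x + 1)} followed
#' by a z-score across units. Genes with zero variance get z = 0.
#'
#' @param expr Non-negative matrix (genes x samples), TPM or similar.
#' @return Matrix of per-gene z-scores.
#' @export
bulkNormalize <- function(expr) {
  expr <- .as_counts_matrix(expr)
  if (ncol(expr) < 2L)
    stop("z-scoring requires at least two samples")
  if (any(expr < 0)) stop("negative expression values are not allowed")
  lg <- log2(as.matrix(expr) + 1)
  mu <- rowMeans(lg)
  sdv <- apply(lg, 1L, sd)
  z <- (lg - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  z
}

# Single-unit enrichment walk. ranks: average ranks of expression (1 =
# lowest); ord: gene indices by decreasing expression (ties broken by gene
# name for permutation invariance); inset: logical vector.
.es_walk <- function(ranks, ord, inset, alpha) {
  n <- length(ranks)
  nset <- sum(inset)
  w <- ranks^alpha * inset
  denom_in <- sum(w)
  p_in <- cumsum(w[ord]) / denom_in
  p_out <- cumsum(!inset[ord]) / (n - nset)
  sum(p_in - p_out)
}

#' Single-sample gene-set enrichment scores (rank-walk statistic)
#'
#' For each unit and gene set: genes receive rank values (1 = lowest
#' expression, ties by average rank) and are walked in order of decreasing
#' expression. At list position k the in-set weighted ECDF
#' \eqn{P_{in}(k) = \sum_{j \le k, g_j \in S} \rho_{g_j}^\alpha /
#' \sum_{g \in S} \rho_g^\alpha} is compared with the uniform out-of-set ECDF
#' \eqn{P_{out}(k) = \#\{j \le k, g_j \notin S\} / (G - |S|)}; the enrichment
#' score is the sum of differences over all G positions. Scores depend on
#' expression only through ranks, so any strictly increasing per-unit
#' transform leaves them unchanged. Ties in the walk order are broken by gene
#' symbol so the result is invariant to permuting the input's gene order; a
#' unit whose expression is completely tied is degenerate and scores 0 for
#' every set.
#'
#' @param expr Expression matrix (genes x units); any monotone scale
#'   (log-normalized counts, z-scores).
#' @param coll A \linkS4class{GeneSetCollection}; sets are restricted to the
#'   matrix genes first (see \code{\link{restrictToUniverse}}).
#' @param alpha Rank-weight exponent (default 0.25).
#' @param normalize If TRUE, divide the whole score matrix by
#'   \code{max(ES) - min(ES)} over all entries (the usual choice for bulk
#'   cohorts; leave FALSE for per-cell scoring).
#' @return Numeric matrix, sets x units.
#' @export
ssgseaScore <- function(expr, coll, alpha = 0.25, normalize = FALSE) {
  expr <- .as_counts_matrix(expr)
  stopifnot(is(coll, "GeneSetCollection"), alpha >= 0)
  if (nrow(expr) < 2L) stop("need at least two genes to score")
  expr <- as.matrix(expr)
  rownames(expr) <- toupper(rownames(expr))
  coll <- restrictToUniverse(coll, rownames(expr))
  sets <- geneSets(coll)
  n <- nrow(expr)
  insets <- lapply(sets, function(g) rownames(expr) %in% g)
  for (i in seq_along(insets))
    if (all(insets[[i]]))
      stop("gene set '", names(sets)[i],
           "' covers every gene in the matrix; out-of-set ECDF undefined")
  nm_order <- order(rownames(expr))  # tie-break key
  es <- matrix(0, length(sets), ncol(expr),
               dimnames = list(names(sets), colnames(expr)))
  for (u in seq_len(ncol(expr))) {
    x <- expr[, u]
    if (length(unique(x)) == 1L) next  # fully tied: degenerate walk, ES 0
    ranks <- rank(x, ties.method = "average")
    ord <- order(-x, rownames(expr), method = "radix")
    for (i in seq_along(sets))
      es[i, u] <- .es_walk(ranks, ord, insets[[i]], alpha)
  }
  if (normalize) {
    rng <- max(es) - min(es)
    if (rng > 0) es <- es / rng
  }
  es
}

#' Derived putrescine indices
#'
#' Appends two per-unit rows to a score matrix containing the rows
#' \code{put_biosynthesis} (S_In), \code{put_loss} (S_Loss) and
#' \code{put_transport} (S_Trans): \describe{
#'   \item{S_extracellular}{S_Trans / S_In — an index of extracellular
#'     putrescine availability; set to NA (flagged invalid) where
#'     S_In <= 0, since the ratio is meaningless at a non-positive
#'     denominator.}
#'   \item{S_accumulation}{S_In - S_Loss — intracellular accumulation as the
#'     difference of the two scores.}
#' }
#'
#' @param scores Score matrix from \code{\link{ssgseaScore}} containing the
#'   three putrescine rows.
#' @return The matrix with rows \code{S_extracellular} and
#'   \code{S_accumulation} appended; an attribute \code{invalid_extracellular}
#'   holds the logical per-unit invalidity mask.
#' @export
derivePutIndices <- function(scores) {
  req <- c("put_biosynthesis", "put_loss", "put_transport")
  if (!all(req %in% rownames(scores)))
    stop("score matrix must contain rows: ", paste(req, collapse = ", "))
  s_in <- scores["put_biosynthesis", ]
  s_loss <- scores["put_loss", ]
  s_trans <- scores["put_transport", ]
  invalid <- s_in <= 0
  s_extra <- ifelse(invalid, NA_real_, s_trans / s_in)
  s_acc <- s_in - s_loss
  out <- rbind(scores,
               S_extracellular = s_extra,
               S_accumulation = s_acc)
  attr(out, "invalid_extracellular") <- invalid
  out
}
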