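#' Per-cell biosynthesis and loss expression scores
#'
#' \code{Exp_in} is the per-cell sum of log-normalized expression over the
#' biosynthesis genes (ODC1, AGMAT, PAOX); \code{Exp_loss} the sum over the
#' loss genes (SRM, OAZ1, OAZ2, OAZ3, NQO1). Genes absent from the matrix
#' contribute 0 with a warning.
#'
#' @param expr Log-normalized expression matrix (genes x cells).
#' @param coll Gene-set collection containing \code{put_biosynthesis} and
#'   \code{put_loss} (default \code{\link{builtinPutGenesets}}).
#' @return data.frame with columns \code{exp_in}, \code{exp_loss}, one row
#'   per cell.
#' @export
expScores <- function(expr, coll = builtinPutGenesets()) {
  expr <- .as_counts_matrix(expr)
  sets <- geneSets(coll)
  req <- c("put_biosynthesis", "put_loss")
  if (!all(req %in% names(sets)))
    stop("collection must contain sets: ", paste(req, collapse = ", "))
  sym <- toupper(rownames(expr))
  sum_over <- function(genes) {
    present <- genes[genes %in% sym]
    if (length(present) < length(genes))
      warning("genes missing from matrix (contribute 0): ",
              paste(setdiff(genes, present), collapse = ", "))
    if (length(present) == 0L) return(numeric(ncol(expr)))
    as.numeric(Matrix::colSums(expr[match(present, sym), , drop = FALSE]))
  }
  data.frame(exp_in = sum_over(sets$put_biosynthesis),
             exp_loss = sum_over(sets$put_loss),
             row.names = colnames(expr))
}

#' Per-cell putrescine accumulation score S_PA
#'
#' \code{S_PA = Exp_in / Exp_loss}, with two guards: cells with
#' \code{Exp_in = 0} score exactly 0 (the dominant case in CXCR6+CD8+ T
#' cells, where biosynthesis genes are rarely detected), and cells with
#' positive \code{Exp_in} but zero \code{Exp_loss} are computed against
#' \code{Exp_loss + eps} and flagged. Scaling both inputs by the same
#' positive constant leaves S_PA unchanged (up to the eps guard).
#'
#' @param exp_in,exp_loss Non-negative per-cell scores from
#'   \code{\link{expScores}} (or a data.frame from it as the first argument).
#' @param eps Denominator guard (default 1e-8).
#' @return Numeric vector of S_PA values, with attribute
#'   \code{denominator_guarded} marking cells where the eps guard fired.
#' @export
spaScore <- function(exp_in, exp_loss = NULL, eps = 1e-8) {
  if (is.data.frame(exp_in) && is.null(exp_loss)) {
    exp_loss <- exp_in$exp_loss
    exp_in <- exp_in$exp_in
  }
  if (any(exp_in < 0) || any(exp_loss < 0))
    stop("expression scores must be non-negative")
  guarded <- exp_in > 0 & exp_loss == 0
  spa <- ifelse(exp_in == 0, 0, exp_in / (exp_loss + eps))
  attr(spa, "denominator_guarded") <- guarded
  spa
}

#' Per-sample pericellular putrescine index Pi
#'
#' For each sample: \code{S_1} is the sum of S_PA over every cell that is
#' \emph{not} CXCR6+CD8+ (all broad types included), \code{N} is the number
#' of CXCR6+CD8+ T cells, and \code{Pi = S_1 / N}. Samples without target
#' cells (N = 0) are flagged invalid and should be excluded downstream.
#'
#' @param spa Per-cell S_PA vector.
#' @param ann Per-cell annotation with \code{sample_id} and
#'   \code{cxcr6_status}.
#' @return data.frame: sample_id, s1, n, pi, valid.
#' @export
piPerSample <- function(spa, ann) {
  if (length(spa) != nrow(ann))
    stop("S_PA vector and annotation have different lengths")
  if (!"cxcr6_status" %in% colnames(ann))
    stop("annotation lacks 'cxcr6_status'; run labelCxcr6Cd8 first")
  ids <- as.character(ann$sample_id)
  out <- do.call(rbind, lapply(split(seq_along(spa), ids), function(idx) {
    if (length(idx) == 0L) stop("sample with zero cells")
    pos <- ann$cxcr6_status[idx] == "pos"
    s1 <- sum(spa[idx][!pos])
    n <- sum(pos)
    data.frame(sample_id = ids[idx[1]], s1 = s1, n = n,
               pi = if (n > 0) s1 / n else NA_real_, valid = n > 0)
  }))
  rownames(out) <- NULL
  out
}

#' Per-sample median functional scores in CXCR6+CD8+ cells
#'
#' For every functional gene set (row of \code{scores}) and sample, the
#' median per-cell score over the sample's CXCR6+CD8+ T cells. Samples with
#' no target cells yield a missing row.
#'
#' @param scores Score matrix (sets x cells).
#' @param ann Per-cell annotation aligned with the columns.
#' @return data.frame: one row per sample (sample_id plus one column per
#'   set); NA entries where the sample has no target cells.
#' @export
functionalMedians <- function(scores, ann) {
  if (ncol(scores) != nrow(ann))
    stop("score columns and annotation rows differ")
  if (!"cxcr6_status" %in% colnames(ann))
    stop("annotation lacks 'cxcr6_status'")
  ids <- as.character(ann$sample_id)
  pos <- ann$cxcr6_status == "pos"
  samples <- sort(unique(ids))
  med <- t(vapply(samples, function(s) {
    idx <- which(ids == s & pos)
    if (length(idx) == 0L) return(rep(NA_real_, nrow(scores)))
    apply(scores[, idx, drop = FALSE], 1L, median)
  }, numeric(nrow(scores))))
  out <- data.frame(sample_id = samples, med, row.names = NULL,
                    check.names = FALSE)
  colnames(out) <- c("sample_id", rownames(scores))
  out
}

#' LASSO coefficients at fixed penalties
#'
#' Thin deterministic wrapper around the coordinate-descent L1 solver used
#' by \code{\link{lassoAssociation}}, exposed so the penalized fit can be
#' examined at chosen penalty values: minimizes
#' \eqn{\frac{1}{2n}\|y - X\beta\|^2 + \lambda \|\beta\|_1} (no intercept,
#' no internal standardization).
#'
#' @param x Predictor matrix (n x p).
#' @param y Response vector.
#' @param lambda Penalty values (decreasing order recommended).
#' @return Coefficient matrix, p x length(lambda).
#' @export
lassoCoefficients <- function(x, y, lambda) {
  # glmnet wants a decreasing path of >= 2 penalties; pad with a larger one
  path <- sort(unique(c(lambda, max(lambda) + 1)), decreasing = TRUE)
  fit <- glmnet::glmnet(x, y, alpha = 1, lambda = path,
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-14, maxit = 1e6)
  out <- as.matrix(coef(fit, s = lambda, exact = TRUE, x = x, y = y))[-1, ,
                                                                     drop = FALSE]
  colnames(out) <- as.character(lambda)
  out
}

#' Association of Pi with functional-state medians (LASSO)
#'
#' The per-sample pericellular putrescine index is regressed on the
#' per-sample median functional scores of CXCR6+CD8+ T cells: both sides are
#' standardized, an L1 path is fit by coordinate descent, and the penalty is
#' chosen by k-fold cross-validated mean squared error with a fixed fold
#' assignment derived from \code{seed} (the CV-optimal \code{lambda.min} rule
#' by default; \code{lambda.1se} gives a sparser fit). Pi is a ratio
#' statistic with a heavy right tail (a handful of samples with few target
#' cells and strong biosynthesis dominate its variance), so by default the
#' response is \code{log1p(Pi)} before standardization — the usual
#' variance stabilization for a Gaussian-model fit; set
#' \code{log_pi = FALSE} for the raw scale. Descriptive Pearson and Spearman
#' correlations between the (transformed) response and each median are
#' reported alongside.
#'
#' @param pi_records Output of \code{\link{piPerSample}}; only valid samples
#'   are used.
#' @param medians Output of \code{\link{functionalMedians}}.
#' @param cv_folds Number of CV folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param lambda_rule \code{"lambda.min"} (default) or \code{"lambda.1se"}.
#' @param log_pi Stabilize the response as \code{log1p(Pi)} (default TRUE).
#' @return list: \code{coefficients} (named, standardized scale),
#'   \code{lambda} (selected penalty), \code{lambda_path}, \code{pearson},
#'   \code{spearman}, \code{n} (samples used).
#' @export
lassoAssociation <- function(pi_records, medians, cv_folds = 5L, seed = 1L,
                             lambda_rule = c("lambda.min", "lambda.1se"),
                             log_pi = TRUE) {
  lambda_rule <- match.arg(lambda_rule)
  d <- merge(pi_records[pi_records$valid, c("sample_id", "pi")], medians,
             by = "sample_id")
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < cv_folds)
    stop("fewer complete valid samples (", nrow(d), ") than CV folds (",
         cv_folds, ")")
  if (log_pi && any(d$pi < 0)) {
    warning("negative Pi values; log1p stabilization skipped")
    log_pi <- FALSE
  }
  y <- as.numeric(scale(if (log_pi) log1p(d$pi) else d$pi))
  x <- scale(as.matrix(d[, setdiff(colnames(d), c("sample_id", "pi")),
                         drop = FALSE]))
  x[is.nan(x)] <- 0  # constant medians carry no information
  pear <- apply(x, 2L, function(col)
    suppressWarnings(cor(col, y)))
  spear <- apply(x, 2L, function(col)
    suppressWarnings(cor(col, y, method = "spearman")))
  foldid <- .with_seed(seed,
                       sample(rep_len(seq_len(cv_folds), nrow(d))))
  cvfit <- glmnet::cv.glmnet(x, y, alpha = 1, nfolds = cv_folds,
                             foldid = foldid, standardize = FALSE)
  lam <- cvfit[[lambda_rule]]
  beta <- as.numeric(coef(cvfit, s = lam))[-1]
  names(beta) <- colnames(x)
  list(coefficients = beta, lambda = lam,
       lambda_path = cvfit$lambda, pearson = pear, spearman = spear,
       n = nrow(d))
}
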