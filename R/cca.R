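#' CCAResult: canonical correlation analysis output
#'
#' @slot correlations Canonical correlations, descending, clipped to [0, 1].
#' @slot xweights Canonical coefficients for the X block (p x k).
#' @slot yweights Canonical coefficients for the Y block (q x k).
#' @slot xloadings,yloadings Structure correlations between the original
#'   (standardized) columns and the canonical variates.
#' @slot ridge Ridge regularizer added to both covariance blocks before
#'   whitening.
#'
#' @export
setClass("CCAResult",
  representation(correlations = "numeric", xweights = "matrix",
                 yweights = "matrix", xloadings = "matrix",
                 yloadings = "matrix", ridge = "numeric"))

setValidity("CCAResult", function(object) {
  msg <- character()
  if (is.unsorted(rev(object@correlations)))
    msg <- c(msg, "correlations must be sorted descending")
  if (any(object@correlations < 0 | object@correlations > 1))
    msg <- c(msg, "correlations must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CCAResult", function(object) {
  cat("CCAResult:", length(object@correlations), "canonical variates\n")
  cat("  correlations:",
      paste(signif(object@correlations, 4), collapse = ", "), "\n")
  cat("  ridge:", object@ridge, "\n")
})

#' @rdname CCAResult-accessors
#' @export
setGeneric("canonicalCorrelations",
           function(x) standardGeneric("canonicalCorrelations"))
#' @rdname CCAResult-accessors
#' @export
setGeneric("yWeights", function(x) standardGeneric("yWeights"))
#' @rdname CCAResult-accessors
#' @export
setGeneric("xWeights", function(x) standardGeneric("xWeights"))

#' Accessors for CCAResult
#'
#' @param x A \linkS4class{CCAResult}.
#' @name CCAResult-accessors
NULL

#' @rdname CCAResult-accessors
#' @export
setMethod("canonicalCorrelations", "CCAResult",
          function(x) x@correlations)
#' @rdname CCAResult-accessors
#' @export
setMethod("xWeights", "CCAResult", function(x) x@xweights)
#' @rdname CCAResult-accessors
#' @export
setMethod("yWeights", "CCAResult", function(x) x@yweights)

.inv_sqrt <- function(S, ridge) {
  S <- S + diag(ridge, nrow(S))
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
}

#' Canonical correlation analysis (Hotelling, ridge-stabilized)
#'
#' Columns of both blocks are standardized; the canonical directions come
#' from the SVD of the whitened cross-covariance
#' \eqn{K = \Sigma_{xx}^{-1/2} \Sigma_{xy} \Sigma_{yy}^{-1/2}}, with a ridge
#' term added to both covariance blocks before inversion to stabilize the
#' whitening when the panel width approaches the number of units. Canonical
#' correlations are the singular values of K, clipped to [0, 1].
#'
#' @param x Units x p matrix (e.g. the five putrescine scores per cell).
#' @param y Units x q matrix (e.g. pathway scores for the same cells).
#' @param ridge Ridge regularizer (default 1e-6).
#' @return A \linkS4class{CCAResult}.
#' @export
ccaScores <- function(x, y, ridge = 1e-6) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y must share their units (rows)")
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  if (is.null(colnames(y))) colnames(y) <- paste0("Y", seq_len(ncol(y)))
  if (nrow(x) < ncol(x) + ncol(y) + 2L)
    warning("fewer units than p + q + 2; canonical correlations may be ",
            "unstable despite the ridge")
  const_x <- apply(x, 2L, sd) == 0
  const_y <- apply(y, 2L, sd) == 0
  if (any(const_x))
    stop("constant column(s) in x: ",
         paste(colnames(x)[const_x], collapse = ", "))
  if (any(const_y))
    stop("constant column(s) in y: ",
         paste(colnames(y)[const_y], collapse = ", "))
  xs <- scale(x); ys <- scale(y)
  sxx <- cov(xs); syy <- cov(ys); sxy <- cov(xs, ys)
  wx <- .inv_sqrt(sxx, ridge)
  wy <- .inv_sqrt(syy, ridge)
  k <- min(ncol(x), ncol(y))
  sv <- svd(wx %*% sxy %*% wy, nu = k, nv = k)
  a <- wx %*% sv$u[, seq_len(k), drop = FALSE]
  b <- wy %*% sv$v[, seq_len(k), drop = FALSE]
  rownames(a) <- colnames(x); rownames(b) <- colnames(y)
  u_var <- xs %*% a
  v_var <- ys %*% b
  new("CCAResult",
      correlations = pmin(pmax(sv$d[seq_len(k)], 0), 1),
      xweights = a, yweights = b,
      xloadings = cor(xs, u_var), yloadings = cor(ys, v_var),
      ridge = ridge)
}

#' Top-weighted pathways on the first canonical variate
#'
#' Pathways ranked by the absolute Y-side canonical coefficient of the first
#' variate; ties are broken alphabetically for determinism.
#'
#' @param result A \linkS4class{CCAResult}.
#' @param k Number of pathways to return (default 20; must not exceed q).
#' @return Character vector of pathway names, ordered.
#' @export
topWeighted <- function(result, k = 20L) {
  stopifnot(is(result, "CCAResult"))
  q <- nrow(result@yweights)
  if (k > q) stop("k (", k, ") exceeds the number of pathways (", q, ")")
  if (k == 0L) return(character())
  w <- abs(result@yweights[, 1L])
  ord <- order(-w, names(w))
  names(w)[ord][seq_len(k)]
}

#' Pearson correlation panel
#'
#' Pairwise Pearson correlations between the putrescine-score columns and the
#' selected pathway columns; zero-variance columns produce NA entries.
#'
#' @param x Units x p matrix of putrescine scores.
#' @param y_selected Units x k matrix of selected pathway scores.
#' @return p x k correlation matrix.
#' @export
pearsonPanel <- function(x, y_selected) {
  x <- as.matrix(x); y_selected <- as.matrix(y_selected)
  if (nrow(x) != nrow(y_selected)) stop("row mismatch between x and y")
  if (nrow(x) < 3L) stop("need at least 3 units")
  suppressWarnings(cor(x, y_selected))
}
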