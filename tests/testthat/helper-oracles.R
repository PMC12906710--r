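# Independent oracles used across the suite. Each is a deliberately naive,
# literal implementation kept separate from the package's code paths.

# Brute-force enrichment walk: explicit position-by-position ECDF difference.
oracle_ssgsea_unit <- function(x, set_genes, alpha = 0.25) {
  genes <- names(x)
  rho <- rank(x, ties.method = "average")
  ord <- order(-x, genes, method = "radix")
  inset <- genes %in% set_genes
  G <- length(x)
  denom_in <- sum(rho[inset]^alpha)
  es <- 0
  p_in <- 0
  p_out <- 0
  for (k in seq_len(G)) {
    g <- ord[k]
    if (inset[g]) p_in <- p_in + rho[g]^alpha / denom_in
    else p_out <- p_out + 1 / (G - sum(inset))
    es <- es + (p_in - p_out)
  }
  es
}

# Exhaustive pairwise win/tie counting AUC.
oracle_auc <- function(target_vals, rest_vals) {
  wins <- 0
  for (t in target_vals) for (r in rest_vals)
    wins <- wins + (t > r) + 0.5 * (t == r)
  wins / (length(target_vals) * length(rest_vals))
}

# Textbook two-group log-rank from explicit risk tables.
oracle_logrank <- function(ta, ea, tb, eb) {
  time <- c(ta, tb); event <- c(ea, eb)
  arm_a <- c(rep(TRUE, length(ta)), rep(FALSE, length(tb)))
  o_minus_e <- 0; v <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & arm_a)
    d <- sum(event == 1 & time == tt)
    d1 <- sum(event == 1 & time == tt & arm_a)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chi_square = chisq,
       p_value = pchisq(chisq, df = 1, lower.tail = FALSE))
}

# Classical CCA by eigen-decomposition of Sxx^-1 Sxy Syy^-1 Syx (no ridge).
oracle_cca_correlations <- function(x, y) {
  xs <- scale(x); ys <- scale(y)
  sxx <- cov(xs); syy <- cov(ys); sxy <- cov(xs, ys)
  m <- solve(sxx) %*% sxy %*% solve(syy) %*% t(sxy)
  ev <- eigen(m, only.values = TRUE)$values
  sqrt(pmin(pmax(Re(ev), 0), 1))
}

# Soft-threshold closed form for the lasso with X'X = n I.
oracle_soft_threshold <- function(b_ols, lambda) {
  sign(b_ols) * pmax(abs(b_ols) - lambda, 0)
}

# Small deterministic count fixture: genes x cells with named symbols.
make_count_fixture <- function(genes, cells, seed = 42, max_count = 20) {
  set.seed(seed)
  m <- matrix(rpois(length(genes) * cells, lambda = 3), length(genes), cells,
              dimnames = list(genes, paste0("cell", seq_len(cells))))
  m
}
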