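#' PutSimConfig: synthetic-cohort study conditions
#'
#' Bundles every parameter of the synthetic single-cell and bulk cohort
#' generators. The defaults define the study conditions the recovery tests
#' run under; see \code{\link{simConfig}}.
#'
#' @slot n_samples,cells_per_sample Cohort dimensions.
#' @slot tissue_labels Per-sample tissue (\code{Tumor}/\code{Normal});
#'   alternating when empty.
#' @slot cell_type_proportions Named simplex over broad cell types.
#' @slot t_subset_proportions Named simplex over T/NK/ILC subsets.
#' @slot cxcr6_frac_tumor,cxcr6_frac_normal CXCR6+ fraction of CD8 T cells.
#' @slot put_burden_sd SD of the per-sample latent putrescine burden P_s.
#' @slot coupling_beta Slope of the cytotoxic-gene log-mean on P_s in
#'   CXCR6+CD8+ cells (negative plants the suppression effect).
#' @slot cyto_resid_sd SD of the sample-level cytotoxicity residual, the
#'   burden-independent variation that keeps the planted correlation away
#'   from plus/minus 1.
#' @slot cyto_cell_sd SD of the per-cell cytotoxicity random effect within a
#'   sample's CXCR6+CD8+ compartment.
#' @slot nb_dispersion Negative-binomial size parameter (shared).
#' @slot library_size_mean Expected counts per cell.
#' @slot n_noise_genes Unstructured filler genes appended to the panel.
#' @slot hazard_log_hr Log hazard ratio per SD of the latent transport
#'   burden (bulk arm).
#' @slot baseline_hazard,censoring_rate Exponential event and censoring
#'   rates (bulk arm).
#' @slot seed Integer seed; identical (config, seed) gives identical output.
#'
#' @export
setClass("PutSimConfig",
  representation(n_samples = "integer", cells_per_sample = "integer",
                 tissue_labels = "character",
                 cell_type_proportions = "numeric",
                 t_subset_proportions = "numeric",
                 cxcr6_frac_tumor = "numeric", cxcr6_frac_normal = "numeric",
                 put_burden_sd = "numeric", coupling_beta = "numeric",
                 cyto_resid_sd = "numeric", cyto_cell_sd = "numeric",
                 nb_dispersion = "numeric",
                 library_size_mean = "numeric", n_noise_genes = "integer",
                 hazard_log_hr = "numeric", baseline_hazard = "numeric",
                 censoring_rate = "numeric", seed = "integer"))

setValidity("PutSimConfig", function(object) {
  msg <- character()
  if (object@n_samples < 1L || object@cells_per_sample < 1L)
    msg <- c(msg, "cohort dimensions must be positive")
  if (abs(sum(object@cell_type_proportions) - 1) > 1e-9)
    msg <- c(msg, "cell_type_proportions must sum to 1")
  if (abs(sum(object@t_subset_proportions) - 1) > 1e-9)
    msg <- c(msg, "t_subset_proportions must sum to 1")
  fr <- c(object@cxcr6_frac_tumor, object@cxcr6_frac_normal)
  if (any(fr < 0 | fr > 1))
    msg <- c(msg, "CXCR6 fractions must lie in [0, 1]")
  if (object@put_burden_sd < 0 || object@nb_dispersion <= 0 ||
      object@library_size_mean <= 0)
    msg <- c(msg, "put_burden_sd >= 0, nb_dispersion > 0 and ",
             "library_size_mean > 0 required")
  if (object@baseline_hazard <= 0)
    msg <- c(msg, "baseline_hazard must be positive")
  if (object@censoring_rate < 0)
    msg <- c(msg, "censoring_rate must be non-negative")
  if (length(object@tissue_labels) &&
      (length(object@tissue_labels) != object@n_samples ||
       !all(object@tissue_labels %in% c("Tumor", "Normal"))))
    msg <- c(msg, "tissue_labels must be one Tumor/Normal label per sample")
  if (length(msg)) msg else TRUE
})

.BROAD_TYPES <- c(Epithelial = 0.30, TNKILC = 0.25, Myeloid = 0.12,
                  B = 0.10, Plasma = 0.08, FibroGlial = 0.08,
                  Endothelial = 0.05, Mast = 0.02)
.T_SUBSETS <- c(CD4T = 0.40, CD8T = 0.35, gdT = 0.10, NK = 0.10,
                ILC = 0.05)

#' Construct a simulation configuration
#'
#' Defaults describe a desk-scale colorectal-cancer-like cohort: 80 samples
#' (alternating tumor/normal) of 400 cells over 8 broad cell types, a T/NK
#' compartment in which 35\% of T cells are CD8, a CXCR6+ fraction of CD8 T
#' cells of 40\% in tumor versus 15\% in normal tissue, negative-binomial
#' counts with shared dispersion 2 at ~2,000 counts per cell, a unit-SD
#' latent putrescine burden per sample, and no planted burden-cytotoxicity
#' coupling (\code{coupling_beta = 0}) unless requested.
#'
#' @param n_samples,cells_per_sample Cohort dimensions.
#' @param tissue_labels Optional per-sample tissue labels.
#' @param cell_type_proportions,t_subset_proportions Named simplexes.
#' @param cxcr6_frac_tumor,cxcr6_frac_normal CXCR6+ fractions of CD8 T cells.
#' @param put_burden_sd,coupling_beta,cyto_resid_sd,cyto_cell_sd
#'   Latent-effect parameters.
#' @param nb_dispersion,library_size_mean,n_noise_genes Count model.
#' @param hazard_log_hr,baseline_hazard,censoring_rate Bulk survival arm.
#' @param seed Integer seed.
#' @return A \linkS4class{PutSimConfig}.
#' @export
simConfig <- function(n_samples = 80L, cells_per_sample = 400L,
                      tissue_labels = character(),
                      cell_type_proportions = .BROAD_TYPES,
                      t_subset_proportions = .T_SUBSETS,
                      cxcr6_frac_tumor = 0.40, cxcr6_frac_normal = 0.15,
                      put_burden_sd = 1, coupling_beta = 0,
                      cyto_resid_sd = 0.75, cyto_cell_sd = 0.5,
                      nb_dispersion = 2,
                      library_size_mean = 2000, n_noise_genes = 200L,
                      hazard_log_hr = 0, baseline_hazard = 0.1,
                      censoring_rate = 0, seed = 1L) {
  new("PutSimConfig",
      n_samples = as.integer(n_samples),
      cells_per_sample = as.integer(cells_per_sample),
      tissue_labels = as.character(tissue_labels),
      cell_type_proportions = cell_type_proportions,
      t_subset_proportions = t_subset_proportions,
      cxcr6_frac_tumor = cxcr6_frac_tumor,
      cxcr6_frac_normal = cxcr6_frac_normal,
      put_burden_sd = put_burden_sd, coupling_beta = coupling_beta,
      cyto_resid_sd = cyto_resid_sd, cyto_cell_sd = cyto_cell_sd,
      nb_dispersion = nb_dispersion,
      library_size_mean = library_size_mean,
      n_noise_genes = as.integer(n_noise_genes),
      hazard_log_hr = hazard_log_hr, baseline_hazard = baseline_hazard,
      censoring_rate = censoring_rate, seed = as.integer(seed))
}

.MARKER_GENES <- c("CD3D", "CD3E", "CD8A", "CD8B", "CXCR6")
# NB means giving ~90% / ~5% detection at dispersion size 2
.MU_MARKER_HIGH <- 4.3
.MU_MARKER_LOW <- 0.05

.sim_gene_panel <- function(n_noise) {
  put <- unlist(geneSets(builtinPutGenesets()), use.names = FALSE)
  fun <- unlist(geneSets(builtinTFunctionalGenesets()), use.names = FALSE)
  noise <- sprintf("NOISE%03d", seq_len(n_noise))
  unique(c(.MARKER_GENES, put, fun, noise))
}

.sim_tissues <- function(config) {
  if (length(config@tissue_labels)) return(config@tissue_labels)
  rep_len(c("Tumor", "Normal"), config@n_samples)
}

# Baseline log-means per gene x broad type, scaled so the expected library
# size matches config@library_size_mean for every type.
.sim_base_logmu <- function(genes, config) {
  types <- names(config@cell_type_proportions)
  base <- rnorm(length(genes), mean = log(0.3), sd = 0.7)
  logmu <- matrix(base, length(genes), length(types),
                  dimnames = list(genes, types))
  logmu <- logmu + matrix(rnorm(length(logmu), 0, 0.5), nrow(logmu))
  # the random baseline is rescaled per type so the expected library size
  # roughly matches library_size_mean; the genes below are then pinned at
  # absolute means calibrated for their detection rates, so they must be
  # assigned after the scaling
  for (ty in types) {
    tot <- sum(exp(logmu[, ty]))
    logmu[, ty] <- logmu[, ty] + log(config@library_size_mean / tot)
  }
  # lineage markers: high only in defining populations (refined per subset
  # at the cell level), low elsewhere
  logmu[.MARKER_GENES, ] <- log(.MU_MARKER_LOW)
  # putrescine genes: the loss genes (antizymes, SRM) are housekeeping-level
  # in all lineages so the S_PA denominator is essentially never zero;
  # biosynthesis is appreciable in epithelial and B cells but rare in the
  # T/NK compartment, reproducing the preponderance of zero S_PA among
  # T cells
  sets <- geneSets(builtinPutGenesets())
  logmu[sets$put_loss, ] <- log(8)
  logmu[sets$put_biosynthesis, ] <- log(0.5)
  hi <- intersect(c("Epithelial", "B"), types)
  if (length(hi)) logmu[sets$put_biosynthesis, hi] <- log(1.5)
  if ("TNKILC" %in% types)
    logmu[sets$put_biosynthesis, "TNKILC"] <- log(0.15)
  # T-cell functional programmes are abundantly expressed in the T/NK
  # compartment (effector molecules, checkpoint receptors), keeping per-cell
  # enrichment ranks informative there
  fun <- unlist(geneSets(builtinTFunctionalGenesets()), use.names = FALSE)
  if ("TNKILC" %in% types) logmu[fun, "TNKILC"] <- log(1.5)
  logmu
}

# Library-normalized expected expression (linear scale): the latent,
# noise-free quantity the pericellular index responds to. The log1p used for
# the measured path saturates; the linear scale keeps the latent ledger
# monotone in the planted shifts without compression.
.latent_linear <- function(mu_mat, scale = 1e4) {
  tot <- colSums(mu_mat)
  scale * sweep(mu_mat, 2L, ifelse(tot > 0, tot, 1), "/")
}

#' Simulate a multi-sample single-cell cohort
#'
#' Draws negative-binomial counts for a gene panel of lineage markers, the
#' putrescine-metabolism genes, ten functional programmes and unstructured
#' filler genes, over a cohort with per-sample latent putrescine burden
#' \code{P_s ~ N(0, put_burden_sd)}: \itemize{
#'   \item in non-CXCR6+CD8+ cells, biosynthesis-gene log-means shift by
#'     \code{+P_s} and loss-gene log-means by \code{-P_s/2}, so the
#'     pericellular S_PA signal tracks the burden;
#'   \item in CXCR6+CD8+ cells, cytotoxicity-gene log-means shift by
#'     \code{coupling_beta * P_s + e_s + u_c} with the burden-independent
#'     sample residual \code{e_s ~ N(0, cyto_resid_sd)} and per-cell effect
#'     \code{u_c ~ N(0, cyto_cell_sd)};
#'   \item lineage markers are expressed at high rate only in their defining
#'     populations (CD3D/CD3E in T cells, CD8A/CD8B in CD8 T cells, CXCR6 in
#'     the planted CXCR6+ fraction);
#'   \item every sample contains at least one CD8 T cell and, when the
#'     CXCR6 fractions are positive, at least one CXCR6+CD8+ cell.
#' }
#' The ground truth (latent burdens, true labels, and the realized planted
#' Spearman correlation between the noise-free pericellular index and the
#' noise-free cytotoxicity medians) is stored in
#' \code{metadata(sce)$truth}.
#'
#' @param config A \linkS4class{PutSimConfig}.
#' @return A \code{SingleCellExperiment} with a \code{counts} assay, per-cell
#'   \code{colData} (cell_id, sample_id, subject_id, tissue, broad_type,
#'   t_subset, true cxcr6 label), and the truth ledger in \code{metadata}.
#' @export
simulateScCohort <- function(config = simConfig()) {
  stopifnot(is(config, "PutSimConfig"))
  validObject(config)
  n_types <- length(config@cell_type_proportions)
  if (config@cells_per_sample < n_types)
    stop("cells_per_sample must be at least the number of broad types")
  genes <- .sim_gene_panel(config@n_noise_genes)
  sets <- geneSets(builtinPutGenesets())
  fun_sets <- geneSets(builtinTFunctionalGenesets())
  tissues <- .sim_tissues(config)
  .with_seed(config@seed, {
    logmu_base <- .sim_base_logmu(genes, config)
    p_s <- rnorm(config@n_samples, 0, config@put_burden_sd)
    e_s <- rnorm(config@n_samples, 0, config@cyto_resid_sd)
    ann_list <- vector("list", config@n_samples)
    mu_list <- vector("list", config@n_samples)
    cyto_shift <- vector("list", config@n_samples)
    for (s in seq_len(config@n_samples)) {
      nc <- config@cells_per_sample
      broad <- sample(names(config@cell_type_proportions), nc,
                      replace = TRUE, prob = config@cell_type_proportions)
      t_subset <- rep(NA_character_, nc)
      tn <- broad == "TNKILC"
      t_subset[tn] <- sample(names(config@t_subset_proportions), sum(tn),
                             replace = TRUE,
                             prob = config@t_subset_proportions)
      if (!any(t_subset == "CD8T", na.rm = TRUE)) {
        k <- if (any(tn)) which(tn)[1] else 1L
        broad[k] <- "TNKILC"; t_subset[k] <- "CD8T"
      }
      frac <- if (tissues[s] == "Tumor") config@cxcr6_frac_tumor
              else config@cxcr6_frac_normal
      cd8 <- which(!is.na(t_subset) & t_subset == "CD8T")
      cx <- rep(FALSE, nc)
      cx[cd8] <- runif(length(cd8)) < frac
      if (frac > 0 && !any(cx)) cx[cd8[1]] <- TRUE
      ann_list[[s]] <- data.frame(
        sample_id = sprintf("S%03d", s),
        subject_id = sprintf("P%03d", (s + 1L) %/% 2L),
        tissue = tissues[s], broad_type = broad, t_subset = t_subset,
        cxcr6_true = cx, stringsAsFactors = FALSE)
      # per-cell log-mean matrix for this sample
      lm <- logmu_base[, broad, drop = FALSE]
      is_t <- !is.na(t_subset)
      lm[c("CD3D", "CD3E"), is_t & t_subset %in% c("CD4T", "CD8T", "gdT")] <-
        log(.MU_MARKER_HIGH)
      lm[c("CD8A", "CD8B"), is_t & t_subset == "CD8T"] <-
        log(.MU_MARKER_HIGH)
      lm["CXCR6", cx] <- log(.MU_MARKER_HIGH)
      target <- cx
      lm[sets$put_biosynthesis, !target] <-
        lm[sets$put_biosynthesis, !target] + p_s[s]
      lm[sets$put_loss, !target] <- lm[sets$put_loss, !target] - p_s[s] / 2
      if (any(target)) {
        u_c <- rnorm(sum(target), 0, config@cyto_cell_sd)
        shift <- config@coupling_beta * p_s[s] + e_s[s] + u_c
        lm[fun_sets$cytotoxicity, target] <-
          sweep(lm[fun_sets$cytotoxicity, target, drop = FALSE], 2L,
                shift, "+")
        cyto_shift[[s]] <- setNames(shift, which(target))
      }
      mu_list[[s]] <- exp(lm)
    }
    ann <- do.call(rbind, ann_list)
    ann$cell_id <- sprintf("C%06d", seq_len(nrow(ann)))
    mu <- do.call(cbind, mu_list)
    colnames(mu) <- ann$cell_id
    sf <- rlnorm(ncol(mu), 0, 0.3)
    mu_obs <- sweep(mu, 2L, sf, "*")
    counts <- matrix(rnbinom(length(mu_obs), mu = as.numeric(mu_obs),
                             size = config@nb_dispersion),
                     nrow(mu_obs), ncol(mu_obs), dimnames = dimnames(mu_obs))
    # ground truth: noise-free pericellular index (linear expected
    # expression, true labels) and the planted per-sample cytotoxicity level
    # (median per-cell log-mean shift)
    latent <- .latent_linear(mu)
    lat_in <- colSums(latent[sets$put_biosynthesis, , drop = FALSE])
    lat_loss <- colSums(latent[sets$put_loss, , drop = FALSE])
    lat_spa <- ifelse(lat_in == 0, 0, lat_in / (lat_loss + 1e-8))
    ids <- ann$sample_id
    lat_pi <- vapply(split(seq_len(nrow(ann)), ids), function(idx) {
      n_pos <- sum(ann$cxcr6_true[idx])
      if (n_pos == 0) return(NA_real_)
      sum(lat_spa[idx][!ann$cxcr6_true[idx]]) / n_pos
    }, numeric(1))
    lat_med <- vapply(seq_len(config@n_samples), function(s)
      if (is.null(cyto_shift[[s]])) NA_real_ else median(cyto_shift[[s]]),
      numeric(1))
    names(lat_med) <- sprintf("S%03d", seq_len(config@n_samples))
    lat_pi <- lat_pi[names(lat_med)]
    ok <- is.finite(lat_pi) & is.finite(lat_med)
    realized <- if (sum(ok) >= 3)
      suppressWarnings(cor(lat_pi[ok], lat_med[ok], method = "spearman"))
    else NA_real_
    truth <- list(
      p_s = setNames(p_s, sprintf("S%03d", seq_len(config@n_samples))),
      cyto_resid = e_s, tissue = tissues,
      cxcr6_true = setNames(ann$cxcr6_true, ann$cell_id),
      latent_pi = lat_pi, latent_cyto_median = lat_med,
      realized_spearman = realized,
      coupling_beta = config@coupling_beta, seed = config@seed)
    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = counts),
      colData = S4Vectors::DataFrame(ann, row.names = ann$cell_id))
    S4Vectors::metadata(sce)$truth <- truth
    S4Vectors::metadata(sce)$config <- config
    sce
  })
}

#' Simulate a bulk expression cohort with survival endpoints
#'
#' Bulk profiles are pseudobulk sums over the cohort's cells: within each
#' (sample, broad type) stratum the summed count of independent
#' NB(\code{mu}, \code{size}) cells is drawn in closed form as
#' NB(\code{n * mu}, \code{n * size}), which is distributionally identical to
#' simulating and summing the individual cells. A per-sample latent transport
#' burden \code{T_s ~ N(0, put_burden_sd)} shifts transport-gene log-means in
#' all cells; survival times are exponential with log-hazard
#' \code{log(baseline_hazard) + hazard_log_hr * standardize(T_s)}, with
#' independent exponential censoring at \code{censoring_rate} (0 = none).
#'
#' @param config A \linkS4class{PutSimConfig}.
#' @return A \code{SummarizedExperiment}: \code{counts} assay (genes x
#'   samples), \code{colData} columns time/event/tissue, truth ledger
#'   (latent transport burden, true hazard ratio) in \code{metadata}.
#' @export
simulateBulkCohort <- function(config = simConfig()) {
  stopifnot(is(config, "PutSimConfig"))
  validObject(config)
  genes <- .sim_gene_panel(config@n_noise_genes)
  trans <- geneSets(builtinPutGenesets())$put_transport
  tissues <- .sim_tissues(config)
  .with_seed(config@seed, {
    logmu_base <- .sim_base_logmu(genes, config)
    t_s <- rnorm(config@n_samples, 0, config@put_burden_sd)
    n_type <- setNames(pmax(1L, round(config@cell_type_proportions *
                                        config@cells_per_sample)),
                       names(config@cell_type_proportions))
    counts <- matrix(0, length(genes), config@n_samples,
                     dimnames = list(genes,
                                     sprintf("B%03d",
                                             seq_len(config@n_samples))))
    for (s in seq_len(config@n_samples)) {
      lm <- logmu_base
      lm[trans, ] <- lm[trans, ] + t_s[s]
      mu <- exp(lm)
      for (ty in names(n_type)) {
        n <- n_type[[ty]]
        counts[, s] <- counts[, s] +
          rnbinom(length(genes), mu = n * mu[, ty],
                  size = n * config@nb_dispersion)
      }
    }
    z <- if (sd(t_s) > 0) (t_s - mean(t_s)) / sd(t_s) else t_s * 0
    rate <- config@baseline_hazard * exp(config@hazard_log_hr * z)
    t_event <- rexp(config@n_samples, rate)
    if (config@censoring_rate > 0) {
      t_cens <- rexp(config@n_samples, config@censoring_rate)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1L, config@n_samples)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts),
      colData = S4Vectors::DataFrame(
        sample_id = colnames(counts), tissue = tissues,
        time = time, event = event, row.names = colnames(counts)))
    S4Vectors::metadata(se)$truth <- list(
      transport_burden = setNames(t_s, colnames(counts)),
      true_hr = exp(config@hazard_log_hr), seed = config@seed)
    S4Vectors::metadata(se)$config <- config
    se
  })
}
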