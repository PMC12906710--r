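#' Assemble a pipeline configuration
#'
#' The pipeline consumes in-memory cohort objects (a
#' \code{SingleCellExperiment} for the single-cell stages and optionally a
#' \code{SummarizedExperiment} with time/event columns for the survival
#' stage) plus a gene-set collection, and writes one artifact per stage under
#' \code{out_dir}, each carrying a commented JSON provenance header.
#'
#' @param sce SingleCellExperiment with a \code{counts} assay and annotation
#'   columns (sample_id, subject_id, tissue, broad_type, t_subset).
#' @param bulk Optional SummarizedExperiment with \code{counts} and
#'   colData time/event for the survival stage.
#' @param genesets GeneSetCollection of functional/pathway sets scored
#'   alongside the built-in putrescine sets.
#' @param out_dir Output directory.
#' @param qc_profile QC profile name (see \code{\link{qcThresholds}}).
#' @param alpha,normalize Scoring parameters (see \code{\link{ssgseaScore}}).
#' @param auc_min,diff_min Marker-selection thresholds.
#' @param eps,cv_folds Pericellular-index parameters.
#' @param survival_feature Score row used for the median-split survival
#'   contrast (default the transport score).
#' @param cca_population Broad type whose cells enter the CCA stage.
#' @param cca_k Pathways retained by \code{\link{topWeighted}} (capped at the
#'   panel width).
#' @param ridge CCA ridge.
#' @param seed Global seed; stage s uses seed + s so stages can be re-run
#'   independently and reproducibly.
#' @return A named list (class \code{putscore_config}).
#' @export
pipelineConfig <- function(sce, bulk = NULL,
                           genesets = builtinTFunctionalGenesets(),
                           out_dir = tempfile("putscore_"),
                           qc_profile = "integrated", alpha = 0.25,
                           normalize = FALSE, auc_min = 0.85,
                           diff_min = 0.55, eps = 1e-8, cv_folds = 5L,
                           survival_feature = "put_transport",
                           cca_population = "Epithelial", cca_k = 20L,
                           ridge = 1e-6, seed = 1L) {
  structure(list(sce = sce, bulk = bulk, genesets = genesets,
                 out_dir = out_dir, qc_profile = qc_profile, alpha = alpha,
                 normalize = normalize, auc_min = auc_min,
                 diff_min = diff_min, eps = eps, cv_folds = cv_folds,
                 survival_feature = survival_feature,
                 cca_population = cca_population, cca_k = cca_k,
                 ridge = ridge, seed = as.integer(seed)),
            class = "putscore_config")
}

.provenance_header <- function(stage, params, seed) {
  rec <- list(stage = stage, params = params, seed = seed,
              package = "putscore",
              version = as.character(packageVersion("putscore")))
  paste0("# provenance: ",
         jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
}

.write_artifact <- function(df, path, stage, params, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_header(stage, params, seed), con)
  write.csv(df, con, row.names = FALSE)
  path
}

#' Read a pipeline artifact CSV (skipping the provenance header)
#'
#' @param path Artifact path.
#' @return data.frame.
#' @export
readArtifact <- function(path) {
  read.csv(path, comment.char = "#", check.names = FALSE)
}

#' Validate pipeline inputs
#'
#' Checks cell-id agreement between matrix and annotation, gene-set overlap
#' with the measured universe, and (when survival data are supplied)
#' time/event sanity. Report-only: never throws.
#'
#' @param config A \code{putscore_config}.
#' @return data.frame with columns \code{level} (\code{error}/\code{warning})
#'   and \code{message}; zero rows when everything is consistent.
#' @export
validateInputs <- function(config) {
  entries <- list()
  add <- function(level, message)
    entries[[length(entries) + 1L]] <<- data.frame(level = level,
                                                   message = message)
  sce <- config$sce
  counts <- SummarizedExperiment::assay(sce, "counts")
  ann <- SummarizedExperiment::colData(sce)
  if (!identical(colnames(counts), rownames(ann)))
    add("error", "matrix columns and annotation rows disagree")
  req <- c("sample_id", "subject_id", "tissue", "broad_type")
  miss <- setdiff(req, colnames(ann))
  if (length(miss))
    add("error", paste("annotation lacks columns:",
                       paste(miss, collapse = ", ")))
  sym <- toupper(rownames(counts))
  for (nm in names(geneSets(config$genesets))) {
    ov <- sum(geneSets(config$genesets)[[nm]] %in% sym)
    if (ov == 0L)
      add("error", paste0("gene set '", nm, "' has zero overlap with the ",
                          "measured genes"))
  }
  put_ov <- vapply(geneSets(builtinPutGenesets()),
                   function(g) sum(g %in% sym), integer(1))
  if (any(put_ov == 0L))
    add("error", paste("putrescine set(s) with zero overlap:",
                       paste(names(put_ov)[put_ov == 0], collapse = ", ")))
  if (!is.null(config$bulk)) {
    cd <- SummarizedExperiment::colData(config$bulk)
    if (!all(c("time", "event") %in% colnames(cd)))
      add("error", "bulk colData lacks time/event columns")
    else if (any(cd$time < 0) || !all(cd$event %in% c(0, 1)))
      add("error", "invalid survival times or event codes")
  }
  if (length(entries)) do.call(rbind, entries)
  else data.frame(level = character(), message = character())
}

#' Run the full scoring pipeline
#'
#' Executes, in order: cell QC -> noise-gene stripping -> log-normalization
#' -> gene-set scoring (putrescine sets with derived indices, plus the
#' functional sets) -> CXCR6+CD8+ labelling -> marker scan -> pericellular
#' putrescine index -> LASSO association -> median-split survival (when bulk
#' data are supplied) -> CCA pathway attribution. Each stage writes a CSV
#' artifact with a provenance header; a failure at stage k leaves the
#' artifacts of stages < k in place. Reruns with identical inputs, config and
#' seed are byte-identical.
#'
#' @param config Output of \code{\link{pipelineConfig}}.
#' @return Manifest data.frame (stage, artifact path), invisibly; results are
#'   also returned in the \code{results} attribute.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "putscore_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  rep <- validateInputs(config)
  if (any(rep$level == "error"))
    stop("input validation failed:\n  ",
         paste(rep$message[rep$level == "error"], collapse = "\n  "))
  manifest <- list()
  results <- list()
  emit <- function(stage, df, params) {
    path <- file.path(config$out_dir, paste0(stage, ".csv"))
    .write_artifact(df, path, stage, params, config$seed)
    manifest[[length(manifest) + 1L]] <<- data.frame(stage = stage,
                                                     artifact = path)
  }
  counts <- SummarizedExperiment::assay(config$sce, "counts")
  ann <- as.data.frame(SummarizedExperiment::colData(config$sce))

  ## 1: QC
  thr <- qcThresholds(config$qc_profile)
  qcm <- computeQCMetrics(counts)
  flt <- filterCells(qcm, thr)
  emit("qc", data.frame(cell_id = rownames(qcm), as.data.frame(qcm),
                        keep = flt$keep),
       list(profile = thr$profile))
  counts <- counts[, flt$keep, drop = FALSE]
  ann <- ann[flt$keep, , drop = FALSE]

  ## 2: strip noise genes + log-normalize
  counts_str <- stripNoiseGenes(counts)
  lognorm <- logNormalize(counts_str)
  emit("normalize", data.frame(gene = rownames(lognorm)),
       list(n_genes = nrow(lognorm), n_cells = ncol(lognorm)))

  ## 3: labelling (before scoring so Pi and medians can use the labels)
  ann <- labelCxcr6Cd8(counts_str, ann)
  results$annotation <- ann
  emit("labels", data.frame(cell_id = rownames(ann),
                            ann[, c("sample_id", "tissue", "broad_type",
                                    "t_subset", "cxcr6_status")]),
       list(rule = "CXCR6 count > 0 in CD8T"))

  ## 4: scoring
  put_scores <- derivePutIndices(
    ssgseaScore(lognorm, builtinPutGenesets(), alpha = config$alpha,
                normalize = config$normalize))
  target <- ann$cxcr6_status == "pos"
  fun_scores <- ssgseaScore(lognorm[, target, drop = FALSE],
                            config$genesets, alpha = config$alpha,
                            normalize = config$normalize)
  results$put_scores <- put_scores
  results$fun_scores <- fun_scores
  emit("scores", data.frame(set = rownames(put_scores),
                            round(put_scores, 10), check.names = FALSE),
       list(alpha = config$alpha, normalize = config$normalize))

  ## 5: marker scan
  markers <- aucMarkerScan(lognorm, target, auc_min = config$auc_min,
                           diff_min = config$diff_min)
  results$markers <- markers
  emit("markers", markers,
       list(auc_min = config$auc_min, diff_min = config$diff_min))

  ## 6: pericellular index
  spa <- spaScore(expScores(lognorm), eps = config$eps)
  pi_rec <- piPerSample(spa, ann)
  results$pi <- pi_rec
  emit("pi", pi_rec, list(eps = config$eps))

  ## 7: association
  med <- functionalMedians(fun_scores, ann[target, , drop = FALSE])
  assoc <- lassoAssociation(pi_rec, med, cv_folds = config$cv_folds,
                            seed = config$seed + 7L)
  results$association <- assoc
  emit("association",
       data.frame(set = names(assoc$coefficients),
                  coefficient = assoc$coefficients,
                  pearson = assoc$pearson, spearman = assoc$spearman),
       list(cv_folds = config$cv_folds, lambda = assoc$lambda))

  ## 8: survival (optional)
  if (!is.null(config$bulk)) {
    bn <- bulkNormalize(SummarizedExperiment::assay(config$bulk, "counts"))
    bscore <- ssgseaScore(bn, builtinPutGenesets(), alpha = config$alpha,
                          normalize = TRUE)
    cd <- as.data.frame(SummarizedExperiment::colData(config$bulk))
    surv <- data.frame(sample_id = colnames(bn), time = cd$time,
                       event = cd$event,
                       feature = bscore[config$survival_feature, ])
    ms <- medianSplitSurvival(surv, "feature")
    results$survival <- ms
    emit("survival",
         data.frame(sample_id = surv$sample_id, group = ms$group,
                    time = surv$time, event = surv$event),
         list(feature = config$survival_feature,
              chi_square = ms$logrank$chi_square,
              p_value = ms$logrank$p_value))
  }

  ## 9: CCA over the chosen population
  pop <- ann$broad_type == config$cca_population
  if (sum(pop) >= 10L) {
    xmat <- t(put_scores[, pop, drop = FALSE])
    keepx <- apply(xmat, 2L, function(v) all(is.finite(v)) && sd(v) > 0)
    pw_scores <- ssgseaScore(lognorm[, pop, drop = FALSE], config$genesets,
                             alpha = config$alpha)
    ymat <- t(pw_scores)
    keepy <- apply(ymat, 2L, sd) > 0
    cca <- ccaScores(xmat[, keepx, drop = FALSE],
                     ymat[, keepy, drop = FALSE], ridge = config$ridge)
    k <- min(config$cca_k, sum(keepy))
    results$cca <- cca
    results$cca_top <- topWeighted(cca, k)
    results$cca_panel <- pearsonPanel(xmat[, keepx, drop = FALSE],
                                      ymat[, results$cca_top, drop = FALSE])
    emit("cca",
         data.frame(pathway = rownames(yWeights(cca)),
                    weight = yWeights(cca)[, 1],
                    loading = cca@yloadings[, 1]),
         list(ridge = config$ridge, k = k,
              first_correlation = canonicalCorrelations(cca)[1]))
  } else {
    warning("fewer than 10 cells in the CCA population; stage skipped")
  }

  manifest <- do.call(rbind, manifest)
  attr(manifest, "results") <- results
  invisible(manifest)
}
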