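#' Run the full analysis on a cohort
#'
#' Executes every stage on a [TumorCohort-class]: response labeling (if
#' not already present), the Table-1 descriptive comparison, differential
#' expression, signature Z-scoring with Mann-Whitney testing and AUROC,
#' two-class GSEA and ssGSEA on the cohort's gene sets, alpha diversity
#' with Welch group tests, differential abundance with the enrichment
#' filter, microbe-signature Spearman correlation with display ordering,
#' the five feature-set random-forest cross-validation reports and their
#' pairwise comparison. When `outdir` is given, all result tables are
#' written as CSV/TSV, the report as JSON, and a resolved copy of the
#' configuration plus a run log (including every seed used) are placed
#' next to the outputs for provenance.
#'
#' @param cohort a [TumorCohort-class] object.
#' @param config a `PipelineConfig` list (default
#'   [defaultPipelineConfig()]).
#' @param outdir optional output directory.
#' @param gseaSeed seed for the GSEA permutation draws (default the first
#'   configured seed).
#' @return named list with components `table1`, `deg`, `scores`,
#'   `signatureTests`, `signatureAUROC`, `gsea`, `ssgsea`, `diversity`,
#'   `diversityTests`, `diffAbundance`, `enrichedTaxa`, `correlation`,
#'   `cvReports`, `modelComparison`.
#' @export
runPipeline <- function(cohort, config = defaultPipelineConfig(),
                        outdir = NULL, gseaSeed = config$seed_list[1]) {
  .validatePipelineConfig(config)
  md <- sampleData(cohort)
  if (!"response" %in% names(md)) {
    md <- labelResponse(md, config$responder_cutoff_months)
    sampleData(cohort) <- md
  }
  labels <- as.character(md$response)
  logexpr <- logTransform(expressionMatrix(cohort))
  sets <- geneSets(cohort)
  if (!length(sets)) stop("cohort carries no gene sets")

  table1 <- makeTable1(md)
  deg <- differentialExpression(logexpr, labels,
                                lfcThreshold = config$deg_lfc_threshold,
                                fdrThreshold = config$deg_fdr_threshold)
  scores <- scoreSignatures(logexpr, sets)
  sigTests <- stratifyAndTest(scores, labels,
                              fdrThreshold = config$signature_fdr_threshold)
  sigAUC <- signatureAUROC(scores, labels)
  gsea <- gseaTwoClass(logexpr, labels, sets,
                       nPerm = config$gsea_n_perm, seed = gseaSeed)
  ssgsea <- ssgseaScores(logexpr, sets, alpha = config$ssgsea_alpha)
  div <- alphaDiversity(microbeCounts(cohort))
  divTests <- diversityTest(div, labels)
  da <- differentialAbundance(microbeCounts(cohort), labels,
                              pThreshold = config$microbe_p_threshold,
                              lfcThreshold = config$microbe_lfc_threshold)
  enriched <- da$taxon[da$enriched]
  relab <- relativeAbundance(microbeCounts(cohort), humanReads(cohort))
  correlation <- NULL
  if (length(enriched) >= 1) {
    corr <- correlateTaxaSignatures(relab[enriched, , drop = FALSE],
                                    scores)
    es <- stats::setNames(da$effectSize, da$taxon)[enriched]
    correlation <- clusterOrder(corr, es)
  }
  immuneSig <- sigTests$signature[sigTests$significant]
  cvReports <- NULL; comparison <- NULL
  if (length(enriched) >= 1 && length(immuneSig) >= 1) {
    fs <- buildFeatureSets(scores, relab, enriched, div, immuneSig)
    cvReports <- lapply(names(fs), function(nm)
      cvEvaluate(fs[[nm]], labels, nTrees = config$n_trees,
                 nFolds = config$n_folds, seeds = config$seed_list,
                 featureSet = nm))
    names(cvReports) <- names(fs)
    comparison <- compareModels(cvReports)
  }

  result <- list(table1 = table1, deg = deg, scores = scores,
                 signatureTests = sigTests, signatureAUROC = sigAUC,
                 gsea = gsea, ssgsea = ssgsea, diversity = div,
                 diversityTests = divTests, diffAbundance = da,
                 enrichedTaxa = enriched, correlation = correlation,
                 cvReports = cvReports, modelComparison = comparison)
  if (!is.null(outdir)) .writePipelineOutputs(result, config, outdir)
  result
}

.writePipelineOutputs <- function(result, config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  w(result$table1, "table1.csv")
  w(result$deg, "differential_expression.csv")
  w(result$signatureTests, "signature_tests.csv")
  w(data.frame(signature = names(result$signatureAUROC),
               auroc = unname(result$signatureAUROC)),
    "signature_auroc.csv")
  w(result$gsea, "gsea.csv")
  writeExpression(result$scores, file.path(outdir, "signature_scores.tsv"),
                  idColumn = "signature")
  writeExpression(result$ssgsea, file.path(outdir, "ssgsea_scores.tsv"),
                  idColumn = "gene_set")
  w(result$diversity, "diversity.csv")
  w(result$diversityTests, "diversity_tests.csv")
  w(result$diffAbundance, "differential_abundance.csv")
  if (!is.null(result$correlation)) {
    for (comp in c("rho", "p", "padj"))
      utils::write.csv(result$correlation[[comp]],
                       file.path(outdir, paste0("correlation_", comp, ".csv")))
  }
  if (!is.null(result$cvReports)) {
    cv <- do.call(rbind, lapply(result$cvReports, function(r)
      cbind(featureSet = r@featureSet, r@perModel)))
    w(cv, "cv_per_model.csv")
    w(data.frame(featureSet = names(result$cvReports),
                 meanAUROC = vapply(result$cvReports, meanAUROC,
                                    numeric(1))),
      "cv_mean_auroc.csv")
    w(result$modelComparison, "model_comparison.csv")
    jsonlite::write_json(
      lapply(result$cvReports, function(r)
        list(featureSet = r@featureSet, meanAUROC = r@meanAUROC,
             perModel = r@perModel)),
      file.path(outdir, "cv_report.json"), auto_unbox = TRUE, digits = NA)
  }
  writePipelineConfig(config, file.path(outdir, "config_resolved.yaml"))
  log <- c(
    paste("run at:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste("seeds:", paste(config$seed_list, collapse = ", ")),
    paste("trees:", config$n_trees, "folds:", config$n_folds),
    paste("thresholds: deg |lfc| >", config$deg_lfc_threshold,
          "padj <=", config$deg_fdr_threshold,
          "; microbe p <", config$microbe_p_threshold,
          "|lfc| >", config$microbe_lfc_threshold,
          "; signature FDR <", config$signature_fdr_threshold),
    paste("responder cutoff (months):", config$responder_cutoff_months),
    paste("enriched taxa:", length(result$enrichedTaxa)),
    paste("significant signatures:",
          sum(result$signatureTests$significant)))
  writeLines(log, file.path(outdir, "run.log"))
  invisible(outdir)
}
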