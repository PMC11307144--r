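#' TumorCohort: matched expression, microbe and clinical data for one cohort
#'
#' The central data container of the package. It holds a gene-level TPM
#' expression matrix (genes x samples), a taxon-level raw count matrix
#' (taxa x samples) with the per-sample number of human-aligned reads used
#' as the denominator for relative abundance, per-sample clinical metadata,
#' an optional gene-set collection (named lists of gene identifiers), and,
#' for simulated cohorts, a `truth` record of the planted effects.
#'
#' Sample identifiers are the single source of alignment: the metadata row
#' names are canonical and both matrices must carry exactly the same sample
#' columns in the same order.
#'
#' @slot expression numeric matrix, genes x samples, TPM scale (values >= 0).
#' @slot microbes numeric matrix, taxa x samples, raw non-negative integer
#'   counts.
#' @slot humanReads named numeric vector of positive per-sample
#'   human-aligned read counts.
#' @slot metadata data.frame of per-sample clinical variables, row names are
#'   sample identifiers. Expected columns include `os_months`,
#'   `vital_status`, `ici_class`, `age`, `sex` and (possibly derived)
#'   `response`.
#' @slot geneSets named list of character vectors of gene identifiers
#'   (may be empty).
#' @slot truth list describing planted effects of a simulated cohort
#'   (empty for real data).
#'
#' @seealso [generateCohort()], [readCohort()], [expressionMatrix()],
#'   [microbeCounts()], [humanReads()], [sampleData()]
#' @export
setClass("TumorCohort",
  representation(
    expression = "matrix",
    microbes   = "matrix",
    humanReads = "numeric",
    metadata   = "data.frame",
    geneSets   = "list",
    truth      = "list"
  )
)

setValidity("TumorCohort", function(object) {
  msgs <- character()
  sm <- rownames(object@metadata)
  if (is.null(sm) || anyDuplicated(sm))
    msgs <- c(msgs, "metadata row names must be unique sample identifiers")
  if (!identical(colnames(object@expression), sm))
    msgs <- c(msgs, "expression columns must match metadata sample ids (same order)")
  if (!identical(colnames(object@microbes), sm))
    msgs <- c(msgs, "microbe columns must match metadata sample ids (same order)")
  if (!identical(names(object@humanReads), sm))
    msgs <- c(msgs, "humanReads names must match metadata sample ids (same order)")
  if (length(object@expression) && any(object@expression < 0))
    msgs <- c(msgs, "expression values must be non-negative")
  if (length(object@microbes)) {
    if (any(object@microbes < 0))
      msgs <- c(msgs, "microbe counts must be non-negative")
    if (any(object@microbes != round(object@microbes)))
      msgs <- c(msgs, "microbe counts must be integral")
  }
  if (length(object@humanReads) && any(object@humanReads <= 0))
    msgs <- c(msgs, "humanReads must be positive")
  if (anyDuplicated(rownames(object@expression)))
    msgs <- c(msgs, "duplicate gene identifiers in expression matrix")
  if (anyDuplicated(rownames(object@microbes)))
    msgs <- c(msgs, "duplicate taxon identifiers in microbe matrix")
  if (length(msgs)) msgs else TRUE
})

#' CVReport: cross-validated random-forest performance for one feature set
#'
#' Produced by [cvEvaluate()]. Each of the `length(seeds) x nFolds`
#' (seed, fold) pairs corresponds to one trained forest scored on its
#' held-out fold; `meanAUROC` is the arithmetic mean of the per-model
#' AUROC values.
#'
#' @slot featureSet name of the evaluated feature set.
#' @slot perModel data.frame with columns `seed`, `fold`, `auroc`.
#' @slot meanAUROC mean AUROC over all trained models.
#' @slot nTrees number of trees per forest.
#' @slot nFolds number of cross-validation folds.
#' @slot seeds integer vector of random seeds used.
#'
#' @seealso [cvEvaluate()], [compareModels()]
#' @export
setClass("CVReport",
  representation(
    featureSet = "character",
    perModel   = "data.frame",
    meanAUROC  = "numeric",
    nTrees     = "numeric",
    nFolds     = "numeric",
    seeds      = "numeric"
  )
)

setValidity("CVReport", function(object) {
  msgs <- character()
  need <- c("seed", "fold", "auroc")
  if (!all(need %in% names(object@perModel)))
    msgs <- c(msgs, "perModel must have columns seed, fold, auroc")
  else {
    a <- object@perModel$auroc
    if (any(a < 0 | a > 1)) msgs <- c(msgs, "AUROC values must lie in [0, 1]")
    if (abs(object@meanAUROC - mean(a)) > 1e-12)
      msgs <- c(msgs, "meanAUROC must equal the mean of per-model AUROCs")
  }
  if (length(msgs)) msgs else TRUE
})

#' ValidationReport: external-cohort performance of a trained classifier
#'
#' Produced by [trainAndValidate()]. Balanced accuracy is the arithmetic
#' mean of sensitivity and specificity, with responders as the positive
#' class.
#'
#' @slot cohort name of the external cohort.
#' @slot sensitivity true-positive rate on external responders.
#' @slot specificity true-negative rate on external nonresponders.
#' @slot balancedAccuracy (sensitivity + specificity) / 2.
#' @slot threshold responder-probability classification threshold.
#'
#' @export
setClass("ValidationReport",
  representation(
    cohort           = "character",
    sensitivity      = "numeric",
    specificity      = "numeric",
    balancedAccuracy = "numeric",
    threshold        = "numeric"
  )
)

setValidity("ValidationReport", function(object) {
  msgs <- character()
  ba <- (object@sensitivity + object@specificity) / 2
  if (abs(object@balancedAccuracy - ba) > 1e-12)
    msgs <- c(msgs, "balancedAccuracy must equal mean(sensitivity, specificity)")
  if (object@balancedAccuracy < 0 || object@balancedAccuracy > 1)
    msgs <- c(msgs, "balancedAccuracy must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})
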