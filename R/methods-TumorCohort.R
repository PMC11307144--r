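#' Construct a TumorCohort
#'
#' Assembles the matched expression, microbe and clinical tables into a
#' validated [TumorCohort-class] object. The metadata sample order is
#' canonical: the expression matrix, microbe matrix and human-read vector
#' are re-indexed to it. Absent samples in any component are an error —
#' inputs must be dense.
#'
#' @param expression numeric matrix, genes x samples, TPM.
#' @param microbes numeric matrix, taxa x samples, raw counts.
#' @param humanReads named numeric vector of per-sample human-aligned
#'   read counts.
#' @param metadata data.frame with sample identifiers as row names (or a
#'   `sample_id` column, which is promoted to row names).
#' @param geneSets optional named list of gene identifier vectors.
#' @param truth optional list of planted effects (simulated cohorts).
#'
#' @return A [TumorCohort-class] object.
#' @export
TumorCohort <- function(expression, microbes, humanReads, metadata,
                        geneSets = list(), truth = list()) {
  if (!is.null(metadata$sample_id) && is.null(rownames(metadata))) {
    rownames(metadata) <- metadata$sample_id
  } else if (!is.null(metadata$sample_id)) {
    rownames(metadata) <- as.character(metadata$sample_id)
  }
  sm <- rownames(metadata)
  if (is.null(sm)) stop("metadata must carry sample identifiers as row names")
  for (what in list(list(colnames(expression), "expression"),
                    list(colnames(microbes), "microbe count"),
                    list(names(humanReads), "human read"))) {
    missing <- setdiff(sm, what[[1]])
    if (length(missing))
      stop("samples absent from the ", what[[2]], " table: ",
           paste(missing, collapse = ", "))
  }
  expression <- expression[, sm, drop = FALSE]
  microbes <- microbes[, sm, drop = FALSE]
  humanReads <- humanReads[sm]
  methods::new("TumorCohort",
    expression = expression, microbes = microbes, humanReads = humanReads,
    metadata = metadata, geneSets = geneSets, truth = truth)
}

#' Accessors for TumorCohort components
#'
#' @param x a [TumorCohort-class] object.
#' @param value replacement metadata data.frame (same samples).
#' @return The corresponding component: expression matrix, microbe count
#'   matrix, named human-read vector, metadata data.frame, gene-set list,
#'   or truth list.
#' @name TumorCohort-accessors
NULL

#' @rdname TumorCohort-accessors
#' @export
setMethod("expressionMatrix", "TumorCohort", function(x) x@expression)

#' @rdname TumorCohort-accessors
#' @export
setMethod("microbeCounts", "TumorCohort", function(x) x@microbes)

#' @rdname TumorCohort-accessors
#' @export
setMethod("humanReads", "TumorCohort", function(x) x@humanReads)

#' @rdname TumorCohort-accessors
#' @export
setMethod("sampleData", "TumorCohort", function(x) x@metadata)

#' @rdname TumorCohort-accessors
#' @export
setMethod("sampleData<-", "TumorCohort", function(x, value) {
  if (!identical(rownames(value), rownames(x@metadata)))
    stop("replacement metadata must keep the same samples in the same order")
  x@metadata <- value
  methods::validObject(x)
  x
})

#' @rdname TumorCohort-accessors
#' @export
setMethod("geneSets", "TumorCohort", function(x) x@geneSets)

#' @rdname TumorCohort-accessors
#' @export
setMethod("cohortTruth", "TumorCohort", function(x) x@truth)

#' Subset a TumorCohort by sample
#'
#' `cohort[, j]` keeps the selected samples in all components.
#'
#' @param x a [TumorCohort-class] object.
#' @param i unused (row subsetting is not defined for a cohort).
#' @param j sample selector: character ids, integer or logical index.
#' @param ... ignored.
#' @param drop ignored.
#' @export
setMethod("[", "TumorCohort", function(x, i, j, ..., drop = FALSE) {
  if (!missing(i)) stop("row subsetting is not defined for a TumorCohort")
  sm <- rownames(x@metadata)[seq_along(rownames(x@metadata))]
  sel <- if (is.character(j)) j else sm[j]
  methods::new("TumorCohort",
    expression = x@expression[, sel, drop = FALSE],
    microbes   = x@microbes[, sel, drop = FALSE],
    humanReads = x@humanReads[sel],
    metadata   = x@metadata[sel, , drop = FALSE],
    geneSets   = x@geneSets,
    truth      = x@truth)
})

setMethod("show", "TumorCohort", function(object) {
  cat("TumorCohort with", ncol(object@expression), "samples\n")
  cat("  expression:", nrow(object@expression), "genes (TPM)\n")
  cat("  microbes  :", nrow(object@microbes), "taxa (raw counts)\n")
  cat("  gene sets :", length(object@geneSets), "\n")
  if ("response" %in% names(object@metadata)) {
    tab <- table(object@metadata$response)
    cat("  response  :", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  if (length(object@truth)) cat("  simulated cohort with planted truth\n")
})

#' @rdname CVReport-accessors
#' @param x a [CVReport-class] object.
#' @name CVReport-accessors
#' @export
setMethod("meanAUROC", "CVReport", function(x) x@meanAUROC)

#' @rdname CVReport-accessors
#' @export
setMethod("perModelAUROC", "CVReport", function(x) x@perModel)

setMethod("show", "CVReport", function(object) {
  cat(sprintf("CVReport '%s': mean AUROC %.3f over %d models (%d trees, %d-fold CV, seeds %s)\n",
              object@featureSet, object@meanAUROC, nrow(object@perModel),
              object@nTrees, object@nFolds,
              paste(object@seeds, collapse = ",")))
})

#' @rdname ValidationReport-class
#' @param x a [ValidationReport-class] object.
#' @export
setMethod("balancedAccuracyOf", "ValidationReport", function(x) x@balancedAccuracy)

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport '%s': balanced accuracy %.3f (sens %.3f, spec %.3f, threshold %.2f)\n",
              object@cohort, object@balancedAccuracy, object@sensitivity,
              object@specificity, object@threshold))
})
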