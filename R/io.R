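#' Read a gene-level TPM expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene identifiers
#' and whose header row holds sample identifiers; the body must be dense,
#' numeric and non-negative.
#'
#' @param path path to the TSV file.
#' @return numeric matrix, genes x samples, with the file's labels.
#' @export
readExpression <- function(path) {
  .readLabeledMatrix(path, what = "gene")
}

#' Read a taxon-level microbe count matrix from TSV
#'
#' Same layout as [readExpression()] with taxa in rows; values must be
#' non-negative integers. An optional `lineage` column (if present as the
#' second column and non-numeric) is attached as the `"lineage"` attribute.
#'
#' @param path path to the TSV file.
#' @return numeric matrix, taxa x samples.
#' @export
readMicrobeCounts <- function(path) {
  m <- .readLabeledMatrix(path, what = "taxon", allowLineage = TRUE)
  if (any(m != round(m)))
    stop("microbe counts must be integral")
  m
}

.readLabeledMatrix <- function(path, what, allowLineage = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected at least one ", what,
                         " column and one sample column in ", path)
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate ", what, " identifiers: ", paste(dup, collapse = ", "))
  sampleNames <- names(df)[-1]  # before [.data.frame repairs duplicates
  body <- df[, -1, drop = FALSE]
  names(body) <- sampleNames
  lineage <- NULL
  if (allowLineage && ncol(body) >= 1 && !is.numeric(body[[1]]) &&
      identical(tolower(names(body)[1]), "lineage")) {
    lineage <- stats::setNames(as.character(body[[1]]), ids)
    body <- body[, -1, drop = FALSE]
  }
  if (anyDuplicated(names(body)))
    stop("duplicate sample identifiers in ", path)
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(col)))) |
                     !grepl("^\\s*-?[0-9.eE+-]+\\s*$", as.character(col)))
      bad <- if (length(bad)) bad[1] else 1L
      stop(sprintf("non-numeric value at %s '%s', sample '%s'",
                   what, ids[bad], names(body)[j]))
    }
    if (anyNA(col)) {
      bad <- which(is.na(col))[1]
      stop(sprintf("missing value at %s '%s', sample '%s' (inputs must be dense)",
                   what, ids[bad], names(body)[j]))
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative value at %s '%s', sample '%s'",
                 what, rownames(m)[neg[1, 1]], colnames(m)[neg[1, 2]]))
  if (!is.null(lineage)) attr(m, "lineage") <- lineage
  m
}

#' Write an expression or count matrix as TSV
#'
#' Inverse of [readExpression()] / [readMicrobeCounts()]: first column
#' carries the row identifiers under `idColumn`, remaining columns are the
#' samples. Values are written with full precision so that a read
#' round-trip reproduces them to at least six significant digits.
#'
#' @param x numeric matrix with row and column names.
#' @param path output path.
#' @param idColumn header of the identifier column.
#' @export
writeExpression <- function(x, path, idColumn = "gene_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- idColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeExpression
#' @export
writeMicrobeCounts <- function(x, path, idColumn = "taxon_id") {
  writeExpression(x, path, idColumn = idColumn)
}

#' Read a gene-set collection from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate genes within a set are collapsed with a warning; a line with
#' fewer than three fields is an error reported with its line number.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors; descriptions in the
#'   `"description"` attribute.
#' @export
readGeneSets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description and at least one gene",
                   i, length(fields)))
    name <- fields[1]
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop(sprintf("GMT line %d (%s) defines an empty set", i, name))
    if (anyDuplicated(genes)) {
      warning(sprintf("set '%s': %d duplicated gene(s) collapsed",
                      name, sum(duplicated(genes))))
      genes <- unique(genes)
    }
    if (name %in% names(sets))
      stop(sprintf("duplicate set name '%s' at GMT line %d", name, i))
    sets[[name]] <- genes
    desc[name] <- fields[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named character vector of set descriptions
#'   (defaults to `"na"`).
#' @export
writeGeneSets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "description")
    if (is.null(descriptions))
      descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write per-sample clinical metadata (CSV)
#'
#' The CSV must contain a `sample_id` column; remaining columns are kept
#' as is. Row names are set to the sample identifiers.
#'
#' @param path path to the CSV file.
#' @return data.frame with sample identifiers as row names.
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df))
    stop("metadata must contain a 'sample_id' column")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample identifiers in metadata")
  rownames(df) <- df$sample_id
  df
}

#' @rdname readSampleMetadata
#' @param metadata data.frame of per-sample variables.
#' @export
writeSampleMetadata <- function(metadata, path) {
  df <- metadata
  if (!"sample_id" %in% names(df))
    df <- cbind(sample_id = rownames(df), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-sample human-aligned read counts (CSV)
#'
#' Expects columns `sample_id` and `human_reads`.
#'
#' @param path path to the CSV file.
#' @return named numeric vector.
#' @export
readHumanReads <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "human_reads") %in% names(df)))
    stop("expected columns 'sample_id' and 'human_reads'")
  stats::setNames(as.numeric(df$human_reads), df$sample_id)
}

#' @rdname readHumanReads
#' @param humanReads named numeric vector.
#' @export
writeHumanReads <- function(humanReads, path) {
  utils::write.csv(data.frame(sample_id = names(humanReads),
                              human_reads = unname(humanReads)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Derive the durable-clinical-benefit response label
#'
#' Patients with overall survival of at least `cutoffMonths` months after
#' the start of ICI treatment are labeled `responder`. Patients who died
#' before the cutoff are `nonresponder`. Patients still alive with
#' follow-up shorter than the cutoff cannot be classified either way and
#' are labeled `indeterminate`; downstream two-group analyses exclude
#' them, and their count is reported via `message()`.
#'
#' @param metadata data.frame with `os_months` and `vital_status`
#'   (`"dead"`/`"alive"`) columns; row names are sample ids.
#' @param cutoffMonths response cutoff in months (default 24).
#' @return `metadata` with a `response` factor column with levels
#'   `nonresponder`, `responder`, `indeterminate`.
#' @export
labelResponse <- function(metadata, cutoffMonths = 24) {
  if (cutoffMonths <= 0) stop("cutoffMonths must be positive")
  if (!"os_months" %in% names(metadata))
    stop("metadata lacks an 'os_months' column")
  if (!"vital_status" %in% names(metadata))
    stop("metadata lacks a 'vital_status' column")
  os <- metadata$os_months
  if (anyNA(os)) {
    bad <- rownames(metadata)[is.na(os)]
    stop("missing os_months for sample(s): ", paste(bad, collapse = ", "))
  }
  vs <- tolower(as.character(metadata$vital_status))
  if (!all(vs %in% c("dead", "alive")))
    stop("vital_status must be 'dead' or 'alive'")
  response <- ifelse(os >= cutoffMonths, "responder",
                     ifelse(vs == "dead", "nonresponder", "indeterminate"))
  nInd <- sum(response == "indeterminate")
  if (nInd > 0)
    message(nInd, " sample(s) censored before the ", cutoffMonths,
            "-month cutoff labeled indeterminate and excluded from two-group analyses")
  metadata$response <- factor(response,
                              levels = c("nonresponder", "responder",
                                         "indeterminate"))
  metadata
}

#' Default analysis configuration
#'
#' Houses the pipeline constants: 500 trees, fivefold cross-validation and
#' 5 seeds for the random-forest protocol; |log2FC| > 1 with BH-adjusted
#' p <= 0.1 for differential expression; raw p < 0.05 with fold difference
#' > 1.00 (log2 units) for microbe enrichment; FDR < 0.05 for signature
#' significance; the 24-month overall-survival response cutoff; ssGSEA
#' exponent 0.25; and 1000 gene-set permutations for two-class GSEA.
#'
#' @return a named list of configuration values (class `PipelineConfig`).
#' @export
defaultPipelineConfig <- function() {
  structure(list(
    seed_list = 1:5,
    n_trees = 500L,
    n_folds = 5L,
    deg_lfc_threshold = 1,
    deg_fdr_threshold = 0.1,
    microbe_p_threshold = 0.05,
    microbe_lfc_threshold = 1,
    signature_fdr_threshold = 0.05,
    responder_cutoff_months = 24,
    ssgsea_alpha = 0.25,
    gsea_n_perm = 1000L,
    paths = list()
  ), class = "PipelineConfig")
}

.validatePipelineConfig <- function(config) {
  stopifnot(
    "n_trees must be >= 1" = config$n_trees >= 1,
    "n_folds must be >= 2" = config$n_folds >= 2,
    "seed_list must be non-empty" = length(config$seed_list) >= 1,
    "responder_cutoff_months must be > 0" = config$responder_cutoff_months > 0,
    "deg_fdr_threshold must lie in (0,1]" =
      config$deg_fdr_threshold > 0 && config$deg_fdr_threshold <= 1,
    "microbe_p_threshold must lie in (0,1]" =
      config$microbe_p_threshold > 0 && config$microbe_p_threshold <= 1,
    "signature_fdr_threshold must lie in (0,1]" =
      config$signature_fdr_threshold > 0 && config$signature_fdr_threshold <= 1,
    "ssgsea_alpha must be >= 0" = config$ssgsea_alpha >= 0,
    "gsea_n_perm must be >= 100" = config$gsea_n_perm >= 100
  )
  invisible(config)
}

#' Read / write the pipeline configuration (YAML)
#'
#' Unknown keys are an error; missing keys fall back to
#' [defaultPipelineConfig()]. Every pipeline run writes a resolved copy of
#' its configuration next to its outputs for provenance.
#'
#' @param path path to the YAML file.
#' @return a validated `PipelineConfig` list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  config <- defaultPipelineConfig()
  unknown <- setdiff(names(user), names(config))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  config[names(user)] <- user
  .validatePipelineConfig(config)
  config
}

#' @rdname readPipelineConfig
#' @param config a `PipelineConfig` list.
#' @export
writePipelineConfig <- function(config, path) {
  .validatePipelineConfig(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
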