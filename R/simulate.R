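#' Configuration of the synthetic-cohort generator
#'
#' The defaults emulate the structure of a 71-patient metastatic-melanoma
#' ICI cohort: 32 nonresponders and 39 responders; overall survival drawn
#' per group from truncated normals with mean (SD) 10.82 (6.23) months
#' below the 24-month cutoff for nonresponders and 49.58 (19.24) months
#' above it for responders; 31 gene signatures of which 16 are
#' immune-activation programs elevated in responders; and nine
#' differentially abundant taxa (one responder-enriched, eight
#' nonresponder-enriched), with the responder-enriched taxon additionally
#' coupled to the per-sample immune-activation level.
#'
#' Expression model: each gene g has a baseline log2-TPM drawn once from
#' `N(baselineExprMean, baselineExprSd)`; sample s adds iid noise
#' `N(0, noiseSd)`. Genes belonging to immune signatures additionally
#' receive a shared per-sample immune-infiltration factor
#' `N(0, immuneLatentSd)` plus `immuneEffect` (log2 units) in responders.
#' The latent factor models the biological heterogeneity of bulk-tumor
#' immune infiltration; without it, multi-gene signature scores would
#' separate the groups almost perfectly, which real ICI cohorts do not
#' show. Values are back-transformed to TPM and columns rescaled to sum
#' to 1e6.
#'
#' Microbe model: taxon t has baseline natural-log abundance per million
#' human reads drawn from `N(baselineTaxonLogMean, baselineTaxonLogSd)`;
#' enriched taxa are shifted by `+/- taxonLog2Fold` (log2, responder vs
#' nonresponder); the responder-enriched taxon adds
#' `microbeImmuneCoupling` log2 units per standard deviation of the
#' sample's immune-activation level. Counts are negative binomial with
#' mean `exp(log abundance) * human_reads / 1e6` and the shared
#' `dispersion`; human reads are log-normal.
#'
#' @param nResponders,nNonresponders group sizes.
#' @param nGenes,nTaxa numbers of genes and taxa.
#' @param nSignatures,nImmuneSignatures total and immune-activated
#'   signature counts (immune signatures are the first
#'   `nImmuneSignatures`).
#' @param signatureSizeRange integer pair, genes per signature (uniform).
#' @param immuneEffect responder shift of immune-signature genes,
#'   log2-expression units.
#' @param noiseSd iid per-gene per-sample expression noise SD (log2).
#' @param immuneLatentSd SD of the shared per-sample immune-infiltration
#'   factor (log2).
#' @param nEnrichedTaxaResp,nEnrichedTaxaNonresp planted enriched taxon
#'   counts.
#' @param taxonLog2Fold planted |log2 fold| of enriched taxa (responder
#'   vs nonresponder).
#' @param microbeImmuneCoupling slope (log2 abundance per SD of immune
#'   score) coupling the responder-enriched taxon to immune activation.
#' @param librarySizeLogmean,librarySizeLogsd log-normal parameters of
#'   per-sample human-aligned read counts.
#' @param dispersion shared negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param microbialLoadSd SD (log2 units) of a shared per-sample
#'   microbial-load factor applied to every taxon's abundance. Total
#'   microbial load varies widely between tumors and the relative
#'   abundances are normalized against host reads, not microbial totals,
#'   so this load variation survives normalization and correlates taxa
#'   within a sample.
#' @param taxonCommunitySd SD (log2 units) of per-sample community
#'   factors shared within blocks of the nonresponder-enriched taxa.
#'   Enriched taxa in tumor microbiomes tend to be taxonomically
#'   related, co-occurring organisms (family-level blocks), so their
#'   abundances fluctuate together rather than independently.
#' @param nCommunities number of independent co-occurrence blocks among
#'   the nonresponder-enriched taxa (round-robin assignment).
#' @param baselineExprMean,baselineExprSd baseline log2-TPM distribution.
#' @param immuneBaselineMean,immuneBaselineSd baseline log2-TPM
#'   distribution of immune-signature genes. Kept moderate so the immune
#'   program is a realistically small share of library mass; otherwise
#'   the TPM renormalization would depress every other gene in
#'   responders and turn the whole transcriptome differential.
#' @param baselineTaxonLogMean,baselineTaxonLogSd baseline ln abundance
#'   (per million human reads) distribution.
#' @param osParams list with `responder` and `nonresponder` components,
#'   each `c(mean=, sd=)` months, for truncated-normal survival draws.
#' @param cutoffMonths response cutoff (months).
#' @param seed integer random seed; the generated cohort is a
#'   deterministic function of the configuration including the seed.
#'
#' @return a validated `SimConfig` list.
#' @seealso [generateCohort()]
#' @export
simConfig <- function(nResponders = 39, nNonresponders = 32,
                      nGenes = 2000, nTaxa = 150,
                      nSignatures = 31, nImmuneSignatures = 16,
                      signatureSizeRange = c(10, 40),
                      immuneEffect = 2, noiseSd = 1,
                      immuneLatentSd = 1.5,
                      nEnrichedTaxaResp = 1, nEnrichedTaxaNonresp = 8,
                      taxonLog2Fold = 1.6, microbeImmuneCoupling = 1,
                      librarySizeLogmean = log(5e7),
                      librarySizeLogsd = 0.4,
                      dispersion = 1,
                      microbialLoadSd = 0.75,
                      taxonCommunitySd = 2.25,
                      nCommunities = 3,
                      baselineExprMean = 4, baselineExprSd = 2,
                      immuneBaselineMean = 2, immuneBaselineSd = 1,
                      baselineTaxonLogMean = 0, baselineTaxonLogSd = 2,
                      osParams = list(
                        responder = c(mean = 49.58, sd = 19.24),
                        nonresponder = c(mean = 10.82, sd = 6.23)),
                      cutoffMonths = 24, seed = 1) {
  config <- as.list(environment())
  stopifnot(
    "group sizes must be >= 1" = nResponders >= 1 && nNonresponders >= 1,
    "nGenes/nTaxa must be >= 1" = nGenes >= 1 && nTaxa >= 1,
    "nSignatures must be >= 1" = nSignatures >= 1,
    "nImmuneSignatures must lie in [1, nSignatures]" =
      nImmuneSignatures >= 1 && nImmuneSignatures <= nSignatures,
    "signature sizes must be >= 2" = signatureSizeRange[1] >= 2,
    "signatureSizeRange must be non-decreasing" =
      signatureSizeRange[2] >= signatureSizeRange[1],
    "enriched taxon counts must be >= 0" =
      nEnrichedTaxaResp >= 0 && nEnrichedTaxaNonresp >= 0,
    "dispersion must be > 0" = dispersion > 0,
    "noiseSd must be > 0" = noiseSd > 0,
    "cutoffMonths must be > 0" = cutoffMonths > 0
  )
  if (nEnrichedTaxaResp + nEnrichedTaxaNonresp > nTaxa)
    stop("planted enriched taxa exceed nTaxa")
  class(config) <- "SimConfig"
  config
}

# truncated-normal draw by rejection; degenerate configurations surface
# loudly after maxTries draws
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf,
                        maxTries = 1000L) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (k in seq_len(maxTries)) {
      x <- stats::rnorm(1, mean, sd)
      if (x >= lower && x < upper) { out[i] <- x; ok <- TRUE; break }
    }
    if (!ok)
      stop(sprintf("truncated-normal rejection failed after %d draws (mean %.2f, sd %.2f, bounds [%.2f, %.2f))",
                   maxTries, mean, sd, lower, upper))
  }
  out
}

#' Generate a synthetic ICI cohort
#'
#' Draws a [TumorCohort-class] with the statistical structure described in
#' [simConfig()]. The result is a deterministic function of the
#' configuration (including its seed). The `truth` slot records the
#' planted differentially expressed genes, the planted enriched taxa with
#' their signed log2 folds, the immune signature names and the coupled
#' taxon, so recovery can be scored without external data.
#'
#' @param config a `SimConfig` list from [simConfig()].
#' @return a [TumorCohort-class] object with labeled `response` metadata.
#' @export
generateCohort <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  nR <- config$nResponders; nN <- config$nNonresponders
  n <- nR + nN
  samples <- sprintf("S%03d", seq_len(n))
  response <- c(rep("nonresponder", nN), rep("responder", nR))
  isResp <- response == "responder"

  genes <- sprintf("G%04d", seq_len(config$nGenes))
  taxa <- sprintf("T%03d", seq_len(config$nTaxa))
  sigs <- sprintf("sig%02d", seq_len(config$nSignatures))

  # disjoint signature memberships keep the planted truth unambiguous
  sizes <- sample(seq(config$signatureSizeRange[1],
                      config$signatureSizeRange[2]),
                  config$nSignatures, replace = TRUE)
  if (sum(sizes) > config$nGenes)
    stop("signature memberships exceed nGenes; increase nGenes or shrink signatures")
  pool <- sample(genes, sum(sizes))
  geneSets <- split(pool, rep(seq_len(config$nSignatures), times = sizes))
  names(geneSets) <- sigs
  immuneSigs <- sigs[seq_len(config$nImmuneSignatures)]
  immuneGenes <- sort(unlist(geneSets[immuneSigs], use.names = FALSE))

  # expression: baseline + iid noise (+ latent infiltration and group
  # shift on immune genes), then back-transform and rescale to TPM
  baseline <- stats::rnorm(config$nGenes, config$baselineExprMean,
                           config$baselineExprSd)
  baseline[match(immuneGenes, genes)] <-
    stats::rnorm(length(immuneGenes), config$immuneBaselineMean,
                 config$immuneBaselineSd)
  latent <- stats::rnorm(n, 0, config$immuneLatentSd)
  logexpr <- matrix(baseline, config$nGenes, n) +
    matrix(stats::rnorm(config$nGenes * n, 0, config$noiseSd),
           config$nGenes, n)
  immuneIdx <- match(immuneGenes, genes)
  shift <- latent + config$immuneEffect * isResp
  logexpr[immuneIdx, ] <- logexpr[immuneIdx, ] +
    matrix(shift, length(immuneIdx), n, byrow = TRUE)
  tpm <- pmax(2^logexpr - 1, 0)
  tpm <- sweep(tpm, 2, colSums(tpm), "/") * 1e6
  dimnames(tpm) <- list(genes, samples)

  # immune-activation level of each sample, standardized; drives the
  # coupled taxon
  immScore <- as.numeric(scale(shift))

  # microbes
  humanReads <- round(stats::rlnorm(n, config$librarySizeLogmean,
                                    config$librarySizeLogsd))
  enriched <- character(0); signedFold <- numeric(0)
  if (config$nEnrichedTaxaResp + config$nEnrichedTaxaNonresp > 0) {
    enriched <- taxa[seq_len(config$nEnrichedTaxaResp +
                               config$nEnrichedTaxaNonresp)]
    signedFold <- c(rep(config$taxonLog2Fold, config$nEnrichedTaxaResp),
                    rep(-config$taxonLog2Fold, config$nEnrichedTaxaNonresp))
    names(signedFold) <- enriched
  }
  coupledTaxon <- if (config$nEnrichedTaxaResp > 0) enriched[1] else NA_character_
  baseLog <- stats::rnorm(config$nTaxa, config$baselineTaxonLogMean,
                          config$baselineTaxonLogSd)
  load <- stats::rnorm(n, 0, config$microbialLoadSd * log(2))
  logAbund <- matrix(baseLog, config$nTaxa, n) +
    matrix(load, config$nTaxa, n, byrow = TRUE)  # ln per-million scale
  if (length(enriched)) {
    idx <- match(enriched, taxa)
    # planted fold applied symmetrically about the baseline
    half <- outer(signedFold / 2, ifelse(isResp, 1, -1)) * log(2)
    logAbund[idx, ] <- logAbund[idx, ] + half
    # ecological co-occurrence: responder-enriched taxa fluctuate
    # individually, nonresponder-enriched taxa in family-like blocks
    nrIdx <- idx[signedFold < 0]
    rIdx <- idx[signedFold > 0]
    block <- c(seq_along(rIdx),
               length(rIdx) + rep_len(seq_len(max(1, config$nCommunities)),
                                      length(nrIdx)))
    members <- split(c(rIdx, nrIdx), block)
    for (bi in members) {
      comm <- stats::rnorm(n, 0, config$taxonCommunitySd * log(2))
      logAbund[bi, ] <- logAbund[bi, ] +
        matrix(comm, length(bi), n, byrow = TRUE)
    }
  }
  if (!is.na(coupledTaxon)) {
    ci <- match(coupledTaxon, taxa)
    logAbund[ci, ] <- logAbund[ci, ] +
      config$microbeImmuneCoupling * log(2) * immScore
  }
  mu <- sweep(exp(logAbund), 2, humanReads / 1e6, "*")
  counts <- matrix(stats::rnbinom(config$nTaxa * n, mu = as.numeric(mu),
                                  size = 1 / config$dispersion),
                   config$nTaxa, n)
  dimnames(counts) <- list(taxa, samples)

  # survival consistent with the response label by construction
  os <- numeric(n)
  os[isResp] <- .rtruncnorm(nR, config$osParams$responder["mean"],
                            config$osParams$responder["sd"],
                            lower = config$cutoffMonths)
  os[!isResp] <- .rtruncnorm(nN, config$osParams$nonresponder["mean"],
                             config$osParams$nonresponder["sd"],
                             lower = 0, upper = config$cutoffMonths)
  vital <- ifelse(isResp, "alive", "dead")
  age <- round(.rtruncnorm(n, 58, 15, lower = 24, upper = 84))
  sex <- sample(c("male", "female"), n, replace = TRUE,
                prob = c(0.59, 0.41))
  ici <- character(n)
  ici[!isResp] <- sample(c("anti-CTLA4", "anti-PD1/PDL1", "combination"),
                         nN, replace = TRUE, prob = c(6, 20, 6) / 32)
  ici[isResp] <- sample(c("anti-CTLA4", "anti-PD1/PDL1", "combination"),
                        nR, replace = TRUE, prob = c(16, 22, 1) / 39)

  metadata <- data.frame(
    sample_id = samples, os_months = os, vital_status = vital,
    ici_class = ici, age = age, sex = sex,
    response = factor(response,
                      levels = c("nonresponder", "responder",
                                 "indeterminate")),
    row.names = samples, stringsAsFactors = FALSE)

  truth <- list(
    degGenes = immuneGenes,
    enrichedTaxa = data.frame(taxon = enriched,
                              log2fold = unname(signedFold),
                              stringsAsFactors = FALSE),
    immuneSignatures = immuneSigs,
    coupledTaxon = coupledTaxon,
    immuneScore = stats::setNames(immScore, samples),
    config = config)

  TumorCohort(expression = tpm, microbes = counts,
              humanReads = stats::setNames(as.numeric(humanReads), samples),
              metadata = metadata, geneSets = geneSets, truth = truth)
}

#' Write a cohort to a directory of plain-text files
#'
#' Emits `expression.tsv`, `microbes.tsv`, `human_reads.csv`,
#' `metadata.csv`, `signatures.gmt` and `truth.json`, all re-readable
#' with [readCohort()].
#'
#' @param cohort a [TumorCohort-class] object.
#' @param outdir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return `outdir`, invisibly.
#' @export
writeCohort <- function(cohort, outdir, overwrite = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) && !overwrite)
    stop("directory ", outdir, " is non-empty; use overwrite = TRUE")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  writeExpression(expressionMatrix(cohort),
                  file.path(outdir, "expression.tsv"))
  writeMicrobeCounts(microbeCounts(cohort),
                     file.path(outdir, "microbes.tsv"))
  writeHumanReads(humanReads(cohort), file.path(outdir, "human_reads.csv"))
  writeSampleMetadata(sampleData(cohort), file.path(outdir, "metadata.csv"))
  if (length(geneSets(cohort)))
    writeGeneSets(geneSets(cohort), file.path(outdir, "signatures.gmt"))
  truth <- cohortTruth(cohort)
  if (length(truth)) {
    truth$config <- unclass(truth$config)
    jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(outdir)
}

#' Read a cohort directory written by [writeCohort()]
#'
#' @param dir directory containing the cohort files.
#' @return a [TumorCohort-class] object.
#' @export
readCohort <- function(dir) {
  expr <- readExpression(file.path(dir, "expression.tsv"))
  microbes <- readMicrobeCounts(file.path(dir, "microbes.tsv"))
  hr <- readHumanReads(file.path(dir, "human_reads.csv"))
  metadata <- readSampleMetadata(file.path(dir, "metadata.csv"))
  if ("response" %in% names(metadata))
    metadata$response <- factor(metadata$response,
                                levels = c("nonresponder", "responder",
                                           "indeterminate"))
  gmt <- file.path(dir, "signatures.gmt")
  sets <- if (file.exists(gmt)) readGeneSets(gmt) else list()
  truthPath <- file.path(dir, "truth.json")
  truth <- if (file.exists(truthPath))
    jsonlite::read_json(truthPath, simplifyVector = TRUE) else list()
  TumorCohort(expression = expr, microbes = microbes, humanReads = hr,
              metadata = metadata, geneSets = sets, truth = truth)
}
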