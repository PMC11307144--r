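test_that("cohort generation is deterministic and honors the configuration", {
  cfg <- smallSimConfig(seed = 11)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(expressionMatrix(a), expressionMatrix(b))
  expect_identical(microbeCounts(a), microbeCounts(b))
  expect_identical(sampleData(a), sampleData(b))

  md <- sampleData(a)
  expect_equal(sum(md$response == "responder"), cfg$nResponders)
  expect_equal(sum(md$response == "nonresponder"), cfg$nNonresponders)
  # survival consistent with the label by construction
  expect_true(all(md$os_months[md$response == "responder"] >=
                    cfg$cutoffMonths))
  expect_true(all(md$os_months[md$response == "nonresponder"] <
                    cfg$cutoffMonths))
  expect_true(all(md$vital_status[md$response == "nonresponder"] == "dead"))
  # labeling rule reproduces the constructed labels
  relab <- labelResponse(md[, setdiff(names(md), "response")],
                         cfg$cutoffMonths)
  expect_identical(as.character(relab$response), as.character(md$response))
  # TPM columns sum to one million
  expect_equal(unname(colSums(expressionMatrix(a))),
               rep(1e6, ncol(expressionMatrix(a))))
  # truth describes planted features drawn from the row labels
  truth <- cohortTruth(a)
  expect_true(all(truth$degGenes %in% rownames(expressionMatrix(a))))
  expect_identical(nrow(truth$enrichedTaxa), 9L)
  expect_identical(sum(truth$enrichedTaxa$log2fold > 0), 1L)

  expect_error(generateCohort(simConfig(nTaxa = 5)), "exceed nTaxa")
})

test_that("written cohorts re-read identically", {
  co <- generateCohort(smallSimConfig(seed = 3))
  dir <- withr::local_tempdir()
  writeCohort(co, dir, overwrite = TRUE)
  expect_error(writeCohort(co, dir), "non-empty")
  gmt <- readLines(file.path(dir, "signatures.gmt"))
  expect_length(gmt, length(geneSets(co)))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$enrichedTaxa$taxon,
                  cohortTruth(co)$enrichedTaxa$taxon)
  back <- readCohort(dir)
  expect_equal(expressionMatrix(back), expressionMatrix(co),
               tolerance = 1e-6)
  expect_equal(microbeCounts(back), microbeCounts(co),
               ignore_attr = FALSE)
  expect_identical(as.character(sampleData(back)$response),
                   as.character(sampleData(co)$response))
  expect_identical(geneSets(back)[names(geneSets(co))], geneSets(co))
})

test_that("stronger immune effects widen the responder score separation", {
  sep <- vapply(c(0, 1, 2), function(eff) {
    co <- generateCohort(smallSimConfig(seed = 5, immuneEffect = eff))
    lx <- logTransform(expressionMatrix(co))
    sc <- suppressWarnings(suppressMessages(
      scoreSignatures(lx, geneSets(co))))
    imm <- cohortTruth(co)$immuneSignatures
    isResp <- sampleData(co)$response == "responder"
    mean(sc[imm, isResp]) - mean(sc[imm, !isResp])
  }, numeric(1))
  expect_true(all(diff(sep) > 0))
})

test_that("the coupled taxon tracks immune activation across seeds", {
  hits <- vapply(1:20, function(s) {
    co <- generateCohort(smallSimConfig(seed = s))
    truth <- cohortTruth(co)
    relab <- relativeAbundance(microbeCounts(co), humanReads(co))
    stats::cor(relab[truth$coupledTaxon, ], truth$immuneScore,
               method = "spearman") > 0
  }, logical(1))
  expect_gte(sum(hits), 19L)
})

test_that("degenerate truncated-normal settings fail loudly", {
  cfg <- smallSimConfig(seed = 1)
  cfg$osParams$responder <- c(mean = -500, sd = 1)
  expect_error(generateCohort(cfg), "rejection failed")
})
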