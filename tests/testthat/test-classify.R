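makeFeatureInputs <- function(seed = 1) {
  co <- generateCohort(smallSimConfig(seed = seed))
  labels <- as.character(sampleData(co)$response)
  lx <- logTransform(expressionMatrix(co))
  scores <- suppressWarnings(suppressMessages(
    scoreSignatures(lx, geneSets(co))))
  relab <- relativeAbundance(microbeCounts(co), humanReads(co))
  div <- alphaDiversity(microbeCounts(co))
  list(co = co, labels = labels, scores = scores, relab = relab,
       div = div)
}

test_that("feature sets are exact concatenations with canonical columns", {
  f <- makeFeatureInputs()
  enr <- cohortTruth(f$co)$enrichedTaxa$taxon
  imm <- cohortTruth(f$co)$immuneSignatures
  fs <- buildFeatureSets(f$scores, f$relab, enr, f$div, imm)
  expect_named(fs, c("microbe", "GeneSig_Z_score", "Imm_Act_Z_score",
                     "GS_Z_microbe", "Imm_Act_Z_microbe", "diversity"))
  expect_identical(ncol(fs$microbe), length(enr))
  expect_identical(ncol(fs$GS_Z_microbe),
                   ncol(fs$GeneSig_Z_score) + ncol(fs$microbe))
  expect_identical(ncol(fs$Imm_Act_Z_microbe),
                   length(imm) + length(enr))
  expect_identical(ncol(fs$diversity), 5L)
  # combined sets hold exactly the parts' columns
  expect_setequal(colnames(fs$Imm_Act_Z_microbe),
                  c(colnames(fs$Imm_Act_Z_score), colnames(fs$microbe)))
  expect_equal(fs$Imm_Act_Z_microbe[, colnames(fs$microbe)], fs$microbe)
  # canonical (sorted) column order everywhere
  for (m in fs) expect_identical(colnames(m), sort(colnames(m)))
  expect_error(buildFeatureSets(f$scores, f$relab, character(0), f$div,
                                imm), "empty")
  expect_error(buildFeatureSets(f$scores, f$relab, enr, f$div,
                                character(0)), "review")
})

test_that("cross-validated forests are reproducible and sane", {
  f <- makeFeatureInputs(seed = 4)
  isResp <- f$labels == "responder"
  # leak-by-construction: the label itself as a feature
  leak <- matrix(as.numeric(isResp) + rnorm(length(isResp), 0, 0.01),
                 ncol = 1,
                 dimnames = list(colnames(f$scores), "leak"))
  rep1 <- cvEvaluate(leak, f$labels, nTrees = 100, seeds = 1:2)
  expect_gte(meanAUROC(rep1), 0.99)
  expect_identical(nrow(perModelAUROC(rep1)), 10L)  # 2 seeds x 5 folds
  # identical configuration reproduces the report exactly
  rep2 <- cvEvaluate(leak, f$labels, nTrees = 100, seeds = 1:2)
  expect_identical(perModelAUROC(rep1), perModelAUROC(rep2))
  # shuffled feature columns are canonicalized before fitting
  enr <- cohortTruth(f$co)$enrichedTaxa$taxon
  fs <- buildFeatureSets(f$scores, f$relab, enr, f$div,
                         cohortTruth(f$co)$immuneSignatures)
  x <- fs$Imm_Act_Z_microbe
  shuffled <- x[, rev(seq_len(ncol(x)))]
  a <- cvEvaluate(x, f$labels, nTrees = 100, seeds = 1)
  b <- cvEvaluate(shuffled, f$labels, nTrees = 100, seeds = 1)
  expect_identical(perModelAUROC(a), perModelAUROC(b))
})

test_that("model comparison reuses the Mann-Whitney machinery", {
  pm <- function(a) methods::new("CVReport", featureSet = "x",
    perModel = data.frame(seed = 1, fold = seq_along(a), auroc = a),
    meanAUROC = mean(a), nTrees = 10, nFolds = length(a), seeds = 1)
  same <- pm(c(0.6, 0.7, 0.8, 0.75, 0.64))
  res <- compareModels(list(same, same))
  expect_equal(res$p.value, 1)
  lo <- pm(c(0.51, 0.52, 0.53, 0.54, 0.55))
  hi <- pm(c(0.91, 0.92, 0.93, 0.94, 0.95))
  res2 <- compareModels(list(lo, hi))
  expect_equal(res2$U, 0)  # perfect separation, minimal U
  ref <- suppressWarnings(stats::wilcox.test(lo@perModel$auroc,
                                             hi@perModel$auroc,
                                             exact = FALSE, correct = TRUE))
  expect_equal(res2$p.value, ref$p.value, tolerance = 1e-12)
})

test_that("balanced accuracy is the mean of sensitivity and specificity", {
  pred <- c(rep("responder", 3), "nonresponder",      # TP=3, FN=1
            rep("nonresponder", 2), rep("responder", 2))  # TN=2, FP=2
  truth <- c(rep("responder", 4), rep("nonresponder", 4))
  ba <- balancedAccuracy(pred, truth)
  expect_equal(ba$sensitivity, 0.75)
  expect_equal(ba$specificity, 0.5)
  expect_equal(ba$balancedAccuracy, 0.625)
  expect_equal(balancedAccuracy(truth, truth)$balancedAccuracy, 1)
  flip <- ifelse(truth == "responder", "nonresponder", "responder")
  expect_equal(balancedAccuracy(flip, truth)$balancedAccuracy, 0)
  # flipping both predictions and truth swaps sens/spec, keeps the mean
  flipPred <- ifelse(pred == "responder", "nonresponder", "responder")
  ba2 <- balancedAccuracy(flipPred, flip)
  expect_equal(ba2$sensitivity, ba$specificity)
  expect_equal(ba2$specificity, ba$sensitivity)
  expect_equal(ba2$balancedAccuracy, ba$balancedAccuracy)
  expect_error(balancedAccuracy(pred, rep("responder", 8)), "single class")
})

test_that("external validation aligns features and scores sanely", {
  f <- makeFeatureInputs(seed = 6)
  enr <- cohortTruth(f$co)$enrichedTaxa$taxon
  fs <- buildFeatureSets(f$scores, f$relab, enr, f$div,
                         cohortTruth(f$co)$immuneSignatures)
  x <- fs$Imm_Act_Z_microbe
  # resubstitution sanity bound
  rep <- trainAndValidate(x, f$labels, x, f$labels, nTrees = 100,
                          seeds = 1:3)
  expect_gte(balancedAccuracyOf(rep), 0.95)
  expect_s4_class(rep, "ValidationReport")
  # missing external columns are zero-filled with a message
  expect_message(
    rep2 <- trainAndValidate(x, f$labels, x[, -1], f$labels,
                             nTrees = 50, seeds = 1),
    "filled with 0")
  expect_error(trainAndValidate(x, f$labels,
                                matrix(0, nrow(x), 1,
                                       dimnames = list(rownames(x), "zz")),
                                f$labels, nTrees = 50, seeds = 1),
               "no overlapping")
})
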