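#' Build the five classifier feature sets
#'
#' Assembles the samples x features tables fed to the random-forest
#' harness: `microbe` (relative abundances of the selected taxa),
#' `GeneSig_Z_score` (all signature Z-scores), `Imm_Act_Z_score` (the
#' significant immune-activated subset), the two concatenations
#' `GS_Z_microbe` and `Imm_Act_Z_microbe`, and `diversity` (the five
#' alpha-diversity indices). Feature columns are sorted lexicographically
#' so fits are order-independent; combined sets are exact column
#' concatenations of their parts.
#'
#' @param scores signatures x samples Z-score matrix.
#' @param relabund taxa x samples relative-abundance matrix.
#' @param enrichedTaxa character vector of selected taxa (non-empty).
#' @param diversity data.frame from [alphaDiversity()].
#' @param immuneSignatureNames significant immune-activated signature
#'   names (e.g. from [stratifyAndTest()] at FDR < 0.05).
#' @return named list of samples x features numeric matrices.
#' @export
buildFeatureSets <- function(scores, relabund, enrichedTaxa, diversity,
                             immuneSignatureNames) {
  samples <- colnames(scores)
  if (!identical(sort(samples), sort(colnames(relabund))))
    stop("scores and relabund must share the same samples")
  if (!identical(sort(samples), sort(diversity$sample)))
    stop("diversity table must cover the same samples")
  if (!length(enrichedTaxa)) stop("enrichedTaxa is empty")
  missingTaxa <- setdiff(enrichedTaxa, rownames(relabund))
  if (length(missingTaxa))
    stop("enriched taxa absent from relabund: ",
         paste(missingTaxa, collapse = ", "))
  if (!length(immuneSignatureNames))
    stop("no significant immune-activated signatures; review the FDR threshold")
  missingSig <- setdiff(immuneSignatureNames, rownames(scores))
  if (length(missingSig))
    stop("immune signatures absent from scores: ",
         paste(missingSig, collapse = ", "))

  canon <- function(m) {
    m <- m[, order(colnames(m)), drop = FALSE]
    if (anyNA(m)) stop("feature table contains missing values")
    m
  }
  microbe <- canon(t(relabund[enrichedTaxa, samples, drop = FALSE]))
  geneSig <- canon(t(scores[, samples, drop = FALSE]))
  immAct <- canon(t(scores[immuneSignatureNames, samples, drop = FALSE]))
  divIdx <- c("shannon", "simpson", "invSimpson", "chao1", "ACE")
  div <- as.matrix(diversity[match(samples, diversity$sample), divIdx])
  rownames(div) <- samples
  list(
    microbe = microbe,
    GeneSig_Z_score = geneSig,
    Imm_Act_Z_score = immAct,
    GS_Z_microbe = canon(cbind(geneSig, microbe)),
    Imm_Act_Z_microbe = canon(cbind(immAct, microbe)),
    diversity = canon(div)
  )
}

# fit one forest and return held-out responder probabilities
.forestProb <- function(xTrain, yTrain, xTest, nTrees) {
  fit <- randomForest::randomForest(x = xTrain, y = yTrain,
                                    ntree = nTrees)
  stats::predict(fit, xTest, type = "prob")[, "responder"]
}

#' Cross-validated random-forest evaluation of one feature set
#'
#' For each seed, samples are split into `nFolds` stratified folds; each
#' fold is held out once while a bootstrap-aggregated decision-tree
#' ensemble (`nTrees` trees, square-root feature subsampling — the
#' randomForest classification default) is trained on the rest and scores
#' the held-out fold with responder class probabilities. Each (seed, fold)
#' pair is one trained model with its held-out AUROC; with 5 seeds and 5
#' folds this yields 25 trained models, and the headline number is the
#' arithmetic mean of the 25 per-model AUROCs. Identical inputs and seeds
#' reproduce the report exactly.
#'
#' @param features samples x features numeric matrix (one element of
#'   [buildFeatureSets()]).
#' @param labels per-sample response labels aligned with the rows.
#' @param nTrees trees per forest (default 500).
#' @param nFolds cross-validation folds (default 5).
#' @param seeds integer seeds, one cross-validation round each
#'   (default 1:5).
#' @param featureSet name recorded in the report.
#' @return a [CVReport-class] object.
#' @export
cvEvaluate <- function(features, labels, nTrees = 500, nFolds = 5,
                       seeds = 1:5, featureSet = "features") {
  g <- .responseGroups(labels, minPer = nFolds)
  x <- features[g$keep, , drop = FALSE]
  x <- x[, order(colnames(x)), drop = FALSE]  # canonical column order
  isResp <- g$isResp
  if (nrow(x) < 2 * nFolds)
    stop("need at least 2 x nFolds samples")
  y <- factor(ifelse(isResp, "responder", "nonresponder"),
              levels = c("nonresponder", "responder"))
  rows <- list()
  for (seed in seeds) {
    set.seed(seed)
    fold <- .stratifiedFolds(isResp, nFolds)
    for (f in seq_len(nFolds)) {
      test <- fold == f
      prob <- .forestProb(x[!test, , drop = FALSE], y[!test],
                          x[test, , drop = FALSE], nTrees)
      rows[[length(rows) + 1]] <- data.frame(
        seed = seed, fold = f,
        auroc = .aurocVec(prob, isResp[test]))
    }
  }
  perModel <- do.call(rbind, rows)
  methods::new("CVReport", featureSet = featureSet, perModel = perModel,
               meanAUROC = mean(perModel$auroc), nTrees = nTrees,
               nFolds = nFolds, seeds = as.numeric(seeds))
}

#' Pairwise Mann-Whitney comparison of model AUROC distributions
#'
#' Compares the per-model AUROC vectors of every report pair with a
#' two-sided Mann-Whitney U test (same machinery as the signature tests)
#' and BH-adjusts over the pairs. Reports with different model counts are
#' compared anyway, with the sizes recorded.
#'
#' @param reports list of [CVReport-class] objects (>= 2).
#' @return data.frame with columns `model1`, `model2`, `n1`, `n2`, `U`,
#'   `p.value`, `padj`.
#' @export
compareModels <- function(reports) {
  if (length(reports) < 2) stop("need at least 2 reports")
  nm <- vapply(reports, function(r) r@featureSet, character(1))
  pairs <- utils::combn(length(reports), 2)
  out <- apply(pairs, 2, function(ij) {
    a <- reports[[ij[1]]]@perModel$auroc
    b <- reports[[ij[2]]]@perModel$auroc
    mw <- .mannWhitney(a, b)
    data.frame(model1 = nm[ij[1]], model2 = nm[ij[2]],
               n1 = length(a), n2 = length(b),
               U = mw$U, p.value = mw$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$padj <- stats::p.adjust(out$p.value, method = "BH")
  out
}

#' Balanced accuracy of predicted against true labels
#'
#' (sensitivity + specificity) / 2 with responders as the positive class:
#' sensitivity = TP / (TP + FN), specificity = TN / (TN + FP).
#'
#' @param predicted predicted labels (`responder` / `nonresponder`).
#' @param truth true labels; both classes must be present.
#' @return list with `sensitivity`, `specificity`, `balancedAccuracy`.
#' @export
balancedAccuracy <- function(predicted, truth) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (length(unique(truth)) < 2)
    stop("truth labels contain a single class")
  posT <- truth == "responder"; posP <- predicted == "responder"
  sens <- sum(posP & posT) / sum(posT)
  spec <- sum(!posP & !posT) / sum(!posT)
  list(sensitivity = sens, specificity = spec,
       balancedAccuracy = (sens + spec) / 2)
}

#' Train on a full cohort and validate on an external cohort
#'
#' Fits one forest per seed on the complete training cohort, classifies
#' each external sample at responder-probability threshold `threshold`
#' per seed, and takes the majority vote across seeds (ties resolved by
#' the mean probability against the threshold). External feature columns
#' are aligned to the training columns; taxa or signatures absent from
#' the external cohort are filled with zeros (reported via `message()`),
#' and an empty overlap is an error.
#'
#' @param trainFeatures,trainLabels training cohort (samples x features
#'   matrix, aligned labels).
#' @param extFeatures,extLabels external cohort in the same feature
#'   space.
#' @param nTrees trees per forest (default 500).
#' @param seeds integer seeds (default 1:5).
#' @param threshold responder-probability threshold (default 0.5).
#' @param cohort external cohort name recorded in the report.
#' @return a [ValidationReport-class] object.
#' @export
trainAndValidate <- function(trainFeatures, trainLabels, extFeatures,
                             extLabels, nTrees = 500, seeds = 1:5,
                             threshold = 0.5, cohort = "external") {
  g <- .responseGroups(trainLabels, minPer = 2)
  xTrain <- trainFeatures[g$keep, , drop = FALSE]
  xTrain <- xTrain[, order(colnames(xTrain)), drop = FALSE]
  y <- factor(ifelse(g$isResp, "responder", "nonresponder"),
              levels = c("nonresponder", "responder"))
  ge <- .responseGroups(extLabels, minPer = 1)
  xExt <- extFeatures[ge$keep, , drop = FALSE]
  common <- intersect(colnames(xTrain), colnames(xExt))
  if (!length(common)) stop("no overlapping feature columns")
  absent <- setdiff(colnames(xTrain), colnames(xExt))
  if (length(absent)) {
    message(length(absent),
            " training feature(s) absent from the external cohort filled with 0")
    fill <- matrix(0, nrow(xExt), length(absent),
                   dimnames = list(rownames(xExt), absent))
    xExt <- cbind(xExt, fill)
  }
  xExt <- xExt[, colnames(xTrain), drop = FALSE]
  probs <- vapply(seeds, function(seed) {
    set.seed(seed)
    .forestProb(xTrain, y, xExt, nTrees)
  }, numeric(nrow(xExt)))
  probs <- matrix(probs, nrow = nrow(xExt))
  votes <- rowSums(probs >= threshold)
  meanProb <- rowMeans(probs)
  predResp <- votes > length(seeds) / 2 |
    (votes == length(seeds) / 2 & meanProb >= threshold)
  pred <- ifelse(predResp, "responder", "nonresponder")
  truth <- ifelse(ge$isResp, "responder", "nonresponder")
  ba <- balancedAccuracy(pred, truth)
  methods::new("ValidationReport", cohort = cohort,
               sensitivity = ba$sensitivity, specificity = ba$specificity,
               balancedAccuracy = ba$balancedAccuracy,
               threshold = threshold)
}
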