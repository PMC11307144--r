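#' log2(TPM + 1) transform
#'
#' @param tpm numeric matrix of non-negative TPM values.
#' @return matrix of the same shape, elementwise log2(x + 1).
#' @export
logTransform <- function(tpm) {
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  log2(tpm + 1)
}

#' Differential expression between responders and nonresponders
#'
#' Per gene, the log2 fold change is the difference of group means of the
#' log2(TPM + 1) values (responder minus nonresponder) and the p-value
#' comes from a two-sided Welch t-test; p-values are Benjamini-Hochberg
#' adjusted across all genes. A gene is flagged significant when
#' |log2FC| > `lfcThreshold` and adjusted p <= `fdrThreshold`.
#'
#' This is a plainly defined test on the log-transformed matrix, not the
#' moderated linear-model machinery of limma/edgeR; the thresholds are the
#' same, the per-gene variance is not shrunk. A gene with zero variance in
#' both groups and equal means gets p = 1.
#'
#' @param logexpr genes x samples log2(TPM + 1) matrix.
#' @param labels per-sample response labels (`responder` /
#'   `nonresponder`; others are excluded).
#' @param lfcThreshold absolute log2-fold-change cutoff (default 1).
#' @param fdrThreshold BH-adjusted p cutoff (default 0.1).
#' @return data.frame with columns `gene`, `log2FC`, `p.value`, `padj`,
#'   `significant`.
#' @export
differentialExpression <- function(logexpr, labels, lfcThreshold = 1,
                                   fdrThreshold = 0.1) {
  g <- .responseGroups(labels, minPer = 3)
  x <- logexpr[, g$keep, drop = FALSE]
  isResp <- g$isResp
  xr <- x[, isResp, drop = FALSE]; xn <- x[, !isResp, drop = FALSE]
  n1 <- ncol(xr); n2 <- ncol(xn)
  m1 <- rowMeans(xr); m2 <- rowMeans(xn)
  v1 <- .rowVars(xr); v2 <- .rowVars(xn)
  lfc <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  t <- ifelse(se2 == 0, ifelse(lfc == 0, 0, Inf * sign(lfc)),
              lfc / sqrt(se2))
  df <- ifelse(se2 == 0, n1 + n2 - 2,
               se2^2 / (pmax(v1 / n1, 0)^2 / (n1 - 1) +
                          pmax(v2 / n2, 0)^2 / (n2 - 1)))
  p <- ifelse(is.infinite(t), 0,
              ifelse(se2 == 0, 1, 2 * stats::pt(-abs(t), df)))
  padj <- stats::p.adjust(p, method = "BH")
  data.frame(gene = rownames(logexpr), log2FC = lfc, p.value = p,
             padj = padj,
             significant = abs(lfc) > lfcThreshold & padj <= fdrThreshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Signature Z-scores per sample
#'
#' Each gene row is standardized across samples (sample SD, n - 1); the
#' signature score of a sample is the mean of the standardized values over
#' the signature's genes present in the matrix. Zero-variance genes are
#' dropped from the mean (their count is reported via `message()`); a
#' signature with no overlapping genes scores NA with a warning; coverage
#' below 50% of the signature draws a warning.
#'
#' @param logexpr genes x samples log2(TPM + 1) matrix with >= 2 samples.
#' @param geneSets named list of gene identifier vectors.
#' @return signatures x samples score matrix with attributes `genesUsed`
#'   and `genesMissing` (named integer vectors).
#' @export
scoreSignatures <- function(logexpr, geneSets) {
  if (ncol(logexpr) < 2) stop("need at least 2 samples to standardize")
  sds <- sqrt(.rowVars(logexpr))
  zero <- sds == 0
  if (any(zero))
    message(sum(zero), " zero-variance gene(s) dropped from signature scoring")
  z <- (logexpr - rowMeans(logexpr)) / sds
  scores <- matrix(NA_real_, length(geneSets), ncol(logexpr),
                   dimnames = list(names(geneSets), colnames(logexpr)))
  used <- missing <- stats::setNames(integer(length(geneSets)),
                                     names(geneSets))
  for (k in seq_along(geneSets)) {
    sig <- geneSets[[k]]
    present <- intersect(sig, rownames(logexpr))
    present <- present[!zero[match(present, rownames(logexpr))]]
    used[k] <- length(present)
    missing[k] <- length(sig) - length(present)
    if (!length(present)) {
      warning("signature '", names(geneSets)[k],
              "' shares no usable genes with the matrix; score NA")
      next
    }
    if (length(present) < length(sig) / 2)
      warning("signature '", names(geneSets)[k], "' has coverage below 50% (",
              length(present), "/", length(sig), ")")
    scores[k, ] <- colMeans(z[present, , drop = FALSE])
  }
  attr(scores, "genesUsed") <- used
  attr(scores, "genesMissing") <- missing
  scores
}

#' Stratify signatures and test responder vs nonresponder scores
#'
#' Per signature, samples are split into "high"/"low" at the cohort mean
#' score (group sizes reported), and responder scores are compared with
#' nonresponder scores by a two-sided Mann-Whitney U test (normal
#' approximation with tie and continuity correction). P-values are BH
#' adjusted across signatures; significance means adjusted p <
#' `fdrThreshold`.
#'
#' @param scores signatures x samples matrix from [scoreSignatures()].
#' @param labels per-sample response labels aligned with the columns.
#' @param fdrThreshold BH-adjusted p cutoff (default 0.05).
#' @return data.frame with columns `signature`, `U`, `p.value`, `padj`,
#'   `nHigh`, `nLow`, `significant`.
#' @export
stratifyAndTest <- function(scores, labels, fdrThreshold = 0.05) {
  g <- .responseGroups(labels, minPer = 2)
  s <- scores[, g$keep, drop = FALSE]
  isResp <- g$isResp
  out <- lapply(seq_len(nrow(s)), function(k) {
    v <- s[k, ]
    high <- sum(v >= mean(v)); low <- length(v) - high
    mw <- .mannWhitney(v[isResp], v[!isResp])
    data.frame(signature = rownames(s)[k], U = mw$U, p.value = mw$p.value,
               nHigh = high, nLow = low, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$padj <- stats::p.adjust(out$p.value, method = "BH")
  out$significant <- out$padj < fdrThreshold
  out[, c("signature", "U", "p.value", "padj", "nHigh", "nLow",
          "significant")]
}

#' Per-signature AUROC for responder vs nonresponder
#'
#' AUROC = (concordant pairs + 0.5 tied pairs) / (n_resp * n_nonresp),
#' with responders as the positive class, computed through the rank
#' identity with midranks.
#'
#' @param scores signatures x samples matrix (or a numeric vector for a
#'   single score).
#' @param labels per-sample response labels aligned with the columns.
#' @return named numeric vector of AUROC values.
#' @export
signatureAUROC <- function(scores, labels) {
  if (is.null(dim(scores)))
    scores <- matrix(scores, 1, length(scores),
                     dimnames = list("score", names(scores)))
  g <- .responseGroups(labels, minPer = 1)
  s <- scores[, g$keep, drop = FALSE]
  apply(s, 1, .aurocVec, positive = g$isResp)
}
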