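# shared internal helpers

# normalize a response label vector: drops indeterminate entries (with a
# message), errors unless both remaining groups are present with >= minPer
# samples. Returns a list(keep = logical index, isResp = logical over kept).
.responseGroups <- function(labels, minPer = 2) {
  labels <- as.character(labels)
  keep <- labels %in% c("responder", "nonresponder")
  nDropped <- sum(!keep & !is.na(labels))
  if (nDropped > 0)
    message(nDropped, " sample(s) excluded from two-group analysis")
  isResp <- labels[keep] == "responder"
  if (sum(isResp) < minPer || sum(!isResp) < minPer)
    stop("need at least ", minPer,
         " samples per response group (responder/nonresponder)")
  list(keep = keep, isResp = isResp)
}

# row means / variances (sample variance, n - 1) without extra deps
.rowVars <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1)
}

# AUROC of a score for a binary label by the rank (Mann-Whitney) identity;
# ties receive half credit through midranks
.aurocVec <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("AUROC needs both classes present")
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Mann-Whitney U (first sample) and two-sided p by the normal
# approximation with tie and continuity correction; all-tied input gives
# p = 1 by convention
.mannWhitney <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (length(unique(c(x, y))) == 1)
    return(list(U = nx * ny / 2, p.value = 1))
  res <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE))
  p <- res$p.value
  if (is.nan(p)) p <- 1
  list(U = unname(res$statistic), p.value = p)
}

# deterministic stratified fold assignment: per class, samples are
# shuffled (under the caller's RNG state) and dealt round-robin
.stratifiedFolds <- function(isResp, nFolds) {
  fold <- integer(length(isResp))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(isResp == cls)
    if (length(idx) < nFolds)
      stop("class with ", length(idx),
           " samples cannot be stratified into ", nFolds, " folds")
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  fold
}
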