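# running-sum enrichment machinery shared by ssGSEA and two-class GSEA

# signed extreme deviation of the weighted Kolmogorov-Smirnov running sum;
# isHit: logical over the ranked list; weight: non-negative per-position
# weights applied to hits (uniform step for misses)
.runningES <- function(isHit, weight) {
  denomHit <- sum(weight[isHit])
  nMiss <- sum(!isHit)
  if (denomHit == 0 || nMiss == 0) return(0)
  dev <- cumsum(ifelse(isHit, weight, 0)) / denomHit -
    cumsum(!isHit) / nMiss
  dev[which.max(abs(dev))]
}

#' Single-sample gene-set enrichment (ssGSEA) scores
#'
#' Per sample, genes are ranked by expression in decreasing order (ties
#' broken by gene label so reruns are deterministic) and assigned rank
#' weights `(N - position + 1)^alpha`. The set score is the sum over list
#' positions of the difference between the cumulative weighted in-set
#' fraction and the cumulative uniform out-of-set fraction (the running
#' sum's integral). With `normalize = TRUE` (default) all scores are
#' finally divided by the range (max - min) over the whole matrix.
#'
#' Scores depend on the data only through within-sample ranks, so any
#' strictly increasing within-sample transform leaves them unchanged.
#'
#' @param logexpr genes x samples log2(TPM + 1) matrix.
#' @param geneSets named list of gene identifier vectors.
#' @param alpha rank-weighting exponent, >= 0 (default 0.25).
#' @param normalize divide all scores by the matrix-wide score range.
#' @return gene-set x sample score matrix (NA for sets with no overlap).
#' @export
ssgseaScores <- function(logexpr, geneSets, alpha = 0.25,
                         normalize = TRUE) {
  stopifnot(alpha >= 0)
  N <- nrow(logexpr)
  genes <- rownames(logexpr)
  scores <- matrix(NA_real_, length(geneSets), ncol(logexpr),
                   dimnames = list(names(geneSets), colnames(logexpr)))
  overlap <- lapply(geneSets, intersect, y = genes)
  empty <- lengths(overlap) == 0
  if (any(empty))
    warning("gene set(s) with no overlap score NA: ",
            paste(names(geneSets)[empty], collapse = ", "))
  posWeight <- (N - seq_len(N) + 1)^alpha
  for (s in seq_len(ncol(logexpr))) {
    ord <- order(-logexpr[, s], genes)
    ranked <- genes[ord]
    for (k in which(!empty)) {
      isHit <- ranked %in% overlap[[k]]
      nIn <- sum(isHit)
      cumIn <- cumsum(ifelse(isHit, posWeight, 0)) /
        sum(posWeight[isHit])
      cumOut <- cumsum(!isHit) / (N - nIn)
      scores[k, s] <- sum(cumIn - cumOut)
    }
  }
  if (normalize) {
    rng <- range(scores, na.rm = TRUE)
    if (diff(rng) > 0) scores <- scores / diff(rng)
  }
  scores
}

#' Two-class GSEA with gene-set permutation
#'
#' Genes are ranked by the signal-to-noise ratio
#' `(mean_R - mean_NR) / (sd_R + sd_NR)`, with each group SD floored at
#' `max(0.2 |mean|, 0.2)`; ties are broken by gene label. The enrichment
#' score (ES) is the signed extreme deviation of the weight-1 (absolute
#' ranking-statistic weighted) running sum. The null distribution per set
#' comes from `nPerm` random gene sets of equal size drawn from the ranked
#' genes (gene-set permutation, not phenotype permutation). NES divides
#' the ES by the mean |null ES| of matching sign; the p-value is
#' `(1 + # same-sign null ES at least as extreme) / (1 + # same-sign
#' nulls)`; the FDR q-value is the ratio of the pooled-null and observed
#' NES tail fractions, capped at 1. Sets with fewer than 2 genes after
#' intersection are skipped with a warning.
#'
#' @param logexpr genes x samples log2(TPM + 1) matrix.
#' @param labels per-sample response labels (two classes, each n >= 3).
#' @param geneSets named list of gene identifier vectors.
#' @param nPerm number of random gene sets per set size (>= 100).
#' @param fdrThreshold significance cutoff on q (default 0.1).
#' @param seed optional integer seed for the permutation draws.
#' @return data.frame with columns `set`, `size`, `ES`, `NES`, `p.value`,
#'   `qvalue`, `significant`.
#' @export
gseaTwoClass <- function(logexpr, labels, geneSets, nPerm = 1000,
                         fdrThreshold = 0.1, seed = NULL) {
  stopifnot(nPerm >= 100)
  if (!is.null(seed)) set.seed(seed)
  g <- .responseGroups(labels, minPer = 3)
  x <- logexpr[, g$keep, drop = FALSE]
  isResp <- g$isResp
  xr <- x[, isResp, drop = FALSE]; xn <- x[, !isResp, drop = FALSE]
  m1 <- rowMeans(xr); m2 <- rowMeans(xn)
  s1 <- sqrt(.rowVars(xr)); s2 <- sqrt(.rowVars(xn))
  s1 <- pmax(s1, pmax(0.2 * abs(m1), 0.2))
  s2 <- pmax(s2, pmax(0.2 * abs(m2), 0.2))
  s2n <- (m1 - m2) / (s1 + s2)
  ord <- order(-s2n, rownames(logexpr))
  ranked <- rownames(logexpr)[ord]
  absStat <- abs(s2n[ord])
  N <- length(ranked)

  overlap <- lapply(geneSets, intersect, y = ranked)
  small <- lengths(overlap) < 2
  if (any(small))
    warning("set(s) skipped with < 2 genes after intersection: ",
            paste(names(geneSets)[small], collapse = ", "))
  overlap <- overlap[!small]
  if (!length(overlap))
    stop("no gene set overlaps the expression matrix with >= 2 genes")

  sizes <- lengths(overlap)
  es <- vapply(overlap, function(set)
    .runningES(ranked %in% set, absStat), numeric(1))

  # one null ensemble per distinct set size
  nullES <- list()
  for (m in unique(sizes)) {
    nullES[[as.character(m)]] <- vapply(seq_len(nPerm), function(i) {
      isHit <- logical(N)
      isHit[sample.int(N, m)] <- TRUE
      .runningES(isHit, absStat)
    }, numeric(1))
  }

  nes <- p <- numeric(length(es))
  nullNESpool <- numeric(0)
  nesOf <- function(v, posMean, negMean)
    ifelse(v >= 0, v / posMean, v / negMean)
  norms <- lapply(nullES, function(nv) {
    list(pos = mean(abs(nv[nv >= 0])), neg = mean(abs(nv[nv < 0])))
  })
  for (k in seq_along(es)) {
    nv <- nullES[[as.character(sizes[k])]]
    nk <- norms[[as.character(sizes[k])]]
    if (es[k] >= 0) {
      same <- nv[nv >= 0]
      p[k] <- (1 + sum(same >= es[k])) / (1 + length(same))
      nes[k] <- es[k] / nk$pos
    } else {
      same <- nv[nv < 0]
      p[k] <- (1 + sum(same <= es[k])) / (1 + length(same))
      nes[k] <- es[k] / abs(nk$neg)
    }
  }
  for (m in unique(sizes)) {
    nv <- nullES[[as.character(m)]]
    nk <- norms[[as.character(m)]]
    nullNESpool <- c(nullNESpool, nesOf(nv, nk$pos, abs(nk$neg)))
  }
  q <- vapply(nes, function(v) {
    if (is.na(v)) return(NA_real_)
    if (v >= 0) {
      num <- mean(nullNESpool >= v)
      den <- mean(nes >= v)
    } else {
      num <- mean(nullNESpool <= v)
      den <- mean(nes <= v)
    }
    min(1, if (den > 0) num / den else 1)
  }, numeric(1))

  data.frame(set = names(overlap), size = unname(sizes), ES = unname(es),
             NES = unname(nes), p.value = unname(p), qvalue = unname(q),
             significant = unname(q) < fdrThreshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
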