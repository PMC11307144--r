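#' Relative abundance of taxa against human-aligned reads
#'
#' Divides each taxon's raw count by the sample's human-aligned read
#' count, the convention used for intratumoral microbe abundances derived
#' from tumor RNA-seq (the denominator is host sequencing depth, not the
#' microbial total).
#'
#' @param counts taxa x samples raw count matrix.
#' @param humanReads named numeric vector of positive per-sample human
#'   read counts (names must cover the count columns).
#' @return taxa x samples matrix of unitless ratios.
#' @export
relativeAbundance <- function(counts, humanReads) {
  hr <- humanReads[colnames(counts)]
  if (anyNA(hr))
    stop("human read counts missing for sample(s): ",
         paste(colnames(counts)[is.na(hr)], collapse = ", "))
  bad <- names(hr)[hr <= 0]
  if (length(bad))
    stop("non-positive human read count for sample(s): ",
         paste(bad, collapse = ", "))
  sweep(counts, 2, hr, "/")
}

#' Alpha diversity of raw microbe counts
#'
#' Per sample: observed richness; Shannon H = -sum p_i ln p_i (natural
#' log); Simpson D = 1 - sum p_i^2; inverse Simpson 1 / sum p_i^2;
#' bias-corrected Chao1 = S_obs + F1 (F1 - 1) / (2 (F2 + 1)) with F1/F2
#' the singleton/doubleton counts; and ACE with the conventional rare
#' cutoff of 10. Shannon, Simpson and inverse Simpson come from
#' `vegan::diversity()`, Chao1 and ACE from `vegan::estimateR()`.
#' Diversity is computed on raw counts without rarefaction. A sample with
#' zero total count gets an NA row with a warning.
#'
#' @param counts taxa x samples raw integer count matrix.
#' @return data.frame with one row per sample: `sample`, `observed`,
#'   `shannon`, `simpson`, `invSimpson`, `chao1`, `ACE`.
#' @export
alphaDiversity <- function(counts) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  comm <- t(counts)  # vegan expects samples in rows
  total <- rowSums(comm)
  out <- data.frame(
    sample = rownames(comm),
    observed = rowSums(comm > 0),
    shannon = NA_real_, simpson = NA_real_, invSimpson = NA_real_,
    chao1 = NA_real_, ACE = NA_real_,
    row.names = NULL, stringsAsFactors = FALSE)
  ok <- total > 0
  if (any(!ok)) {
    warning("sample(s) with zero total count get NA diversity: ",
            paste(rownames(comm)[!ok], collapse = ", "))
    out$observed[!ok] <- NA_integer_
  }
  if (any(ok)) {
    sub <- comm[ok, , drop = FALSE]
    out$shannon[ok] <- vegan::diversity(sub, index = "shannon")
    out$simpson[ok] <- vegan::diversity(sub, index = "simpson")
    out$invSimpson[ok] <- vegan::diversity(sub, index = "invsimpson")
    est <- suppressWarnings(vegan::estimateR(sub))
    out$chao1[ok] <- est["S.chao1", ]
    ace <- est["S.ACE", ]
    ace[is.nan(ace)] <- NA_real_  # undefined for degenerate rare classes
    out$ACE[ok] <- ace
  }
  out
}

#' Welch t-tests on alpha-diversity indices between response groups
#'
#' Applies a two-sided Welch two-sample t-test per diversity index.
#' Samples with NA diversity are dropped per index with a reported count.
#'
#' @param diversity data.frame from [alphaDiversity()].
#' @param labels per-sample response labels aligned with the rows.
#' @return data.frame with columns `index`, `t`, `df`, `p.value`.
#' @export
diversityTest <- function(diversity, labels) {
  g <- .responseGroups(labels, minPer = 2)
  idx <- c("observed", "shannon", "simpson", "invSimpson", "chao1", "ACE")
  out <- lapply(idx, function(v) {
    x <- diversity[[v]][g$keep]
    na <- is.na(x)
    if (any(na))
      message(sum(na), " NA value(s) dropped for index ", v)
    xr <- x[g$isResp & !na]; xn <- x[!g$isResp & !na]
    if (length(xr) < 2 || length(xn) < 2 ||
        (stats::sd(xr) == 0 && stats::sd(xn) == 0)) {
      tt <- tTestFromSummary(mean(xr), max(stats::sd(xr), 0), max(length(xr), 2),
                             mean(xn), max(stats::sd(xn), 0), max(length(xn), 2),
                             equalVariance = FALSE)
    } else {
      ht <- stats::t.test(xr, xn)
      tt <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p.value = ht$p.value)
    }
    data.frame(index = v, t = tt$t, df = tt$df, p.value = tt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# median-of-ratios size factors with a total-count fallback when no taxon
# is observed in every sample
.sizeFactors <- function(counts) {
  allNonzero <- rowSums(counts == 0) == 0
  if (any(allNonzero)) {
    sub <- counts[allNonzero, , drop = FALSE]
    logGeo <- rowMeans(log(sub))
    sf <- apply(sub, 2,
                function(col) exp(stats::median(log(col) - logGeo)))
  } else {
    total <- colSums(counts)
    sf <- total / exp(mean(log(total)))
  }
  if (any(sf <= 0)) stop("non-positive size factor; counts too sparse")
  sf
}

#' Differential abundance of taxa between response groups
#'
#' A simplified negative-binomial Wald procedure: taxa observed in fewer
#' than `minPrevalence` samples are removed; per-sample size factors come
#' from the median-of-ratios method (geometric-mean reference over taxa
#' nonzero in every sample, falling back to total-count ratios when no
#' such taxon exists); a single per-taxon dispersion is estimated by
#' method of moments on the normalized counts pooled across groups
#' (floored at 1e-8); the group log2 fold change (responder vs
#' nonresponder) is tested with a Wald statistic using the
#' negative-binomial variance function. There is no dispersion shrinkage,
#' Cook's-distance filtering or independent filtering. When a taxon is
#' entirely zero in one group, the fold change uses a pseudo-count of 0.5
#' on the normalized group means and the taxon is flagged.
#'
#' The enriched set — taxa with raw p < `pThreshold` and |log2FC| >
#' `lfcThreshold` — mirrors the volcano-plot selection rule used for the
#' downstream microbe features; taxa are ranked by effect size |log2FC|.
#'
#' @param counts taxa x samples raw count matrix.
#' @param labels per-sample response labels aligned with the columns.
#' @param pThreshold raw p cutoff for enrichment (default 0.05).
#' @param lfcThreshold |log2FC| cutoff for enrichment (default 1).
#' @param minPrevalence minimum number of samples with a nonzero count
#'   (default 3).
#' @return data.frame with columns `taxon`, `baseMean`, `log2FC`,
#'   `p.value`, `padj` (BH), `effectSize`, `enriched`, `zeroGroup`.
#' @export
differentialAbundance <- function(counts, labels, pThreshold = 0.05,
                                  lfcThreshold = 1, minPrevalence = 3) {
  g <- .responseGroups(labels, minPer = 3)
  x <- counts[, g$keep, drop = FALSE]
  isResp <- g$isResp
  keepTaxa <- rowSums(x > 0) >= minPrevalence
  x <- x[keepTaxa, , drop = FALSE]
  if (!nrow(x)) stop("no taxon passes the prevalence filter")
  sf <- .sizeFactors(x)
  norm <- sweep(x, 2, sf, "/")
  nr <- norm[, isResp, drop = FALSE]; nn <- norm[, !isResp, drop = FALSE]
  n1 <- ncol(nr); n2 <- ncol(nn)
  m1 <- rowMeans(nr); m2 <- rowMeans(nn)
  v1 <- .rowVars(nr); v2 <- .rowVars(nn)
  # pooled method-of-moments dispersion on normalized counts
  poolVar <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  poolMean <- (n1 * m1 + n2 * m2) / (n1 + n2)
  disp <- pmax((poolVar - poolMean) / poolMean^2, 1e-8)
  zeroGroup <- m1 == 0 | m2 == 0
  m1a <- ifelse(zeroGroup, m1 + 0.5, m1)
  m2a <- ifelse(zeroGroup, m2 + 0.5, m2)
  lfc <- log2(m1a / m2a)
  # delta-method Wald on the log ratio with NB variance mu + disp mu^2
  varLog <- (m1a + disp * m1a^2) / (n1 * m1a^2) +
    (m2a + disp * m2a^2) / (n2 * m2a^2)
  z <- log(m1a / m2a) / sqrt(varLog)
  p <- 2 * stats::pnorm(-abs(z))
  padj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(taxon = rownames(x), baseMean = rowMeans(norm),
                    log2FC = unname(lfc), p.value = unname(p),
                    padj = unname(padj), effectSize = abs(unname(lfc)),
                    enriched = unname(p < pThreshold &
                                        abs(lfc) > lfcThreshold),
                    zeroGroup = unname(zeroGroup),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "sizeFactors") <- sf
  out
}
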