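#' Spearman correlation between taxa and gene-set scores
#'
#' Computes the taxa x gene-set grid of Spearman rank correlations over
#' the shared samples (average ranks for ties), with the t-approximation
#' p-value on each rho and BH adjustment over the full grid (all cells
#' are one family). A constant taxon or gene-set vector yields NA with a
#' warning.
#'
#' @param taxaRelabund taxa x samples relative-abundance matrix (by
#'   convention the enriched-taxon subset from
#'   [differentialAbundance()]; any taxa x samples matrix works).
#' @param scoreMatrix gene-sets x samples score matrix (signature
#'   Z-scores or ssGSEA scores).
#' @return list of class `CorrelationMatrix` with components `rho`, `p`,
#'   `padj` (taxa x gene-set matrices) and `n` (shared sample count).
#' @export
correlateTaxaSignatures <- function(taxaRelabund, scoreMatrix) {
  shared <- intersect(colnames(taxaRelabund), colnames(scoreMatrix))
  if (length(shared) < 4)
    stop("need at least 4 shared samples; got ", length(shared))
  a <- taxaRelabund[, shared, drop = FALSE]
  b <- scoreMatrix[, shared, drop = FALSE]
  constA <- apply(a, 1, function(v) length(unique(v)) == 1)
  constB <- apply(b, 1, function(v) length(unique(v)) == 1)
  if (any(constA) || any(constB))
    warning("constant vector(s) yield NA correlations: ",
            paste(c(rownames(a)[constA], rownames(b)[constB]),
                  collapse = ", "))
  n <- length(shared)
  rho <- suppressWarnings(stats::cor(t(a), t(b), method = "spearman"))
  rho[constA, ] <- NA_real_
  rho[, constB] <- NA_real_
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  padj <- matrix(stats::p.adjust(p, method = "BH"), nrow(p), ncol(p),
                 dimnames = dimnames(p))
  structure(list(rho = rho, p = p, padj = padj, n = n),
            class = "CorrelationMatrix")
}

# deterministic dendrogram leaf order: at every merge the subtree with
# the lower merge height comes first; leaf-leaf ties break by label
.leafOrder <- function(hc) {
  labels <- hc$labels
  rec <- function(node) {
    if (node < 0) return(list(order = -node, height = 0,
                              label = labels[-node]))
    a <- rec(hc$merge[node, 1])
    b <- rec(hc$merge[node, 2])
    swap <- if (a$height != b$height) a$height > b$height
            else a$label > b$label
    if (swap) { tmp <- a; a <- b; b <- tmp }
    list(order = c(a$order, b$order), height = hc$height[node],
         label = min(a$label, b$label))
  }
  rec(nrow(hc$merge))$order
}

#' Order a correlation grid for display
#'
#' Gene sets (columns) are ordered by the dendrogram leaf order of
#' agglomerative hierarchical clustering of their correlation profiles
#' (Euclidean distance, complete linkage); at each merge the subtree with
#' the lower height is placed first, so reruns give identical orders.
#' Taxa (rows) are ordered by decreasing effect size with a lexicographic
#' tie-break. NA cells are imputed as 0 for the distance computation only
#' (flagged via `message()`).
#'
#' @param corr a `CorrelationMatrix` from [correlateTaxaSignatures()].
#' @param effectSizes named numeric vector of taxon effect sizes
#'   (|log2FC| from [differentialAbundance()]).
#' @return the reordered `CorrelationMatrix`, with attributes
#'   `columnOrder`, `rowOrder` and `hclust`.
#' @export
clusterOrder <- function(corr, effectSizes) {
  stopifnot(inherits(corr, "CorrelationMatrix"))
  rho <- corr$rho
  es <- effectSizes[rownames(rho)]
  if (anyNA(es))
    stop("effect sizes missing for taxa: ",
         paste(rownames(rho)[is.na(es)], collapse = ", "))
  rowOrd <- order(-es, rownames(rho))
  if (ncol(rho) == 1) {
    colOrd <- 1L
    hc <- NULL
  } else {
    prof <- rho
    if (anyNA(prof)) {
      message(sum(is.na(prof)), " NA cell(s) imputed as 0 for clustering distance")
      prof[is.na(prof)] <- 0
    }
    hc <- stats::hclust(stats::dist(t(prof), method = "euclidean"),
                        method = "complete")
    colOrd <- .leafOrder(hc)
  }
  out <- corr
  for (comp in c("rho", "p", "padj"))
    out[[comp]] <- corr[[comp]][rowOrd, colOrd, drop = FALSE]
  attr(out, "columnOrder") <- colnames(rho)[colOrd]
  attr(out, "rowOrder") <- rownames(rho)[rowOrd]
  attr(out, "hclust") <- hc
  out
}
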