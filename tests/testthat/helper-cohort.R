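# shared fixtures, all generated in code

# reduced-size simulation for unit tests (fast); effect structure as the
# defaults
smallSimConfig <- function(seed = 1, ...) {
  simConfig(nGenes = 400, nTaxa = 60, nSignatures = 8,
            nImmuneSignatures = 4, signatureSizeRange = c(5, 12),
            seed = seed, ...)
}

# null configuration: no planted treatment effects of any kind
nullSimConfig <- function(seed = 1, ...) {
  simConfig(immuneEffect = 0, taxonLog2Fold = 0,
            microbeImmuneCoupling = 0, seed = seed, ...)
}

# deterministic toy expression matrix with labels
toyMatrix <- function(nr = 4, nc = 3, seed = 42, prefix = "G") {
  set.seed(seed)
  m <- matrix(round(stats::runif(nr * nc, 0, 50), 3), nr, nc,
              dimnames = list(sprintf("%s%02d", prefix, seq_len(nr)),
                              sprintf("S%02d", seq_len(nc))))
  m
}

# brute-force AUROC by O(n^2) pairwise concordance counting
bruteAUROC <- function(score, positive) {
  pos <- score[positive]; neg <- score[!positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exact Mann-Whitney U null enumeration for small samples:
# returns the two-sided exact p for observed U of the first sample
exactMannWhitneyP <- function(x, y) {
  nx <- length(x); ny <- length(y)
  all <- c(x, y)
  r <- rank(all)
  uObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, function(idx)
    sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(uObs - mu) - 1e-9)
}
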