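test_that("Spearman grid matches the rank-then-Pearson oracle", {
  set.seed(17)
  n <- 30
  taxa <- matrix(rlnorm(3 * n), 3, n,
                 dimnames = list(paste0("T", 1:3), paste0("S", 1:n)))
  scores <- matrix(rnorm(4 * n), 4, n,
                   dimnames = list(paste0("sig", 1:4), paste0("S", 1:n)))
  scores[1, ] <- taxa[1, ]             # rho = 1
  scores[2, ] <- -taxa[2, ]            # rho = -1
  corr <- correlateTaxaSignatures(taxa, scores)
  expect_equal(corr$rho["T1", "sig1"], 1)
  expect_equal(corr$rho["T2", "sig2"], -1)
  oracle <- matrix(NA_real_, 3, 4)
  for (i in 1:3) for (j in 1:4)
    oracle[i, j] <- stats::cor(rank(taxa[i, ]), rank(scores[j, ]))
  expect_equal(unname(corr$rho), oracle, tolerance = 1e-12)
  # monotone-transform invariance
  corr2 <- correlateTaxaSignatures(log(taxa + 1), scores)
  expect_equal(corr2$rho, corr$rho, tolerance = 1e-12)
  # BH over the full grid, adjusted >= raw
  expect_true(all(corr$padj >= corr$p - 1e-12))
})

test_that("degenerate correlation inputs are handled", {
  taxa <- matrix(c(rep(1, 5), 2, 5, 3, 9, 4), 2, 5, byrow = TRUE,
                 dimnames = list(c("flat", "ok"), paste0("S", 1:5)))
  scores <- matrix(rnorm(5), 1, 5,
                   dimnames = list("sig1", paste0("S", 1:5)))
  expect_warning(corr <- correlateTaxaSignatures(taxa, scores), "constant")
  expect_true(is.na(corr$rho["flat", "sig1"]))
  expect_false(is.na(corr$rho["ok", "sig1"]))
  expect_error(correlateTaxaSignatures(taxa[, 1:3], scores[, 1:3,
                                                           drop = FALSE]),
               "at least 4")
})

test_that("display ordering follows clustering and effect sizes deterministically", {
  set.seed(23)
  n <- 12
  taxa <- matrix(rnorm(3 * n), 3, n,
                 dimnames = list(c("A", "B", "C"), paste0("S", 1:n)))
  base <- rnorm(n)
  scores <- rbind(sig1 = base + rnorm(n, 0, 0.01),
                  sig2 = rnorm(n), sig3 = base + rnorm(n, 0, 0.01),
                  sig4 = rnorm(n), sig5 = -base + rnorm(n))
  colnames(scores) <- paste0("S", 1:n)
  corr <- correlateTaxaSignatures(taxa, scores)
  ordered <- clusterOrder(corr, c(A = 2.0, B = 0.5, C = 1.0))
  expect_identical(rownames(ordered$rho), c("A", "C", "B"))
  # near-identical profiles end up adjacent
  colOrd <- attr(ordered, "columnOrder")
  expect_equal(abs(diff(match(c("sig1", "sig3"), colOrd))), 1)
  # linkage heights equal a brute-force complete-linkage oracle
  hc <- attr(ordered, "hclust")
  d <- as.matrix(dist(t(corr$rho)))
  bruteCompleteHeights <- function(d) {
    act <- lapply(seq_len(nrow(d)), identity)
    hts <- numeric(0)
    while (length(act) > 1) {
      best <- Inf; bi <- bj <- NA
      for (i in seq_along(act)) for (j in seq_len(i - 1)) {
        h <- max(d[act[[i]], act[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
      hts <- c(hts, best)
      act[[bj]] <- c(act[[bj]], act[[bi]])
      act[[bi]] <- NULL
    }
    sort(hts)
  }
  expect_equal(sort(hc$height), bruteCompleteHeights(d), tolerance = 1e-12)
  # deterministic rerun
  again <- clusterOrder(corr, c(A = 2.0, B = 0.5, C = 1.0))
  expect_identical(attr(again, "columnOrder"), colOrd)
  # single column degenerates to the identity order
  one <- correlateTaxaSignatures(taxa, scores[1, , drop = FALSE])
  expect_identical(attr(clusterOrder(one, c(A = 2, B = 1, C = 3)),
                        "columnOrder"), "sig1")
})
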