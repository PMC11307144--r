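test_that("relative abundance divides counts by human reads", {
  counts <- rbind(T1 = c(10, 20), T2 = c(0, 0))
  colnames(counts) <- c("S1", "S2")
  hr <- c(S1 = 1000, S2 = 4000)
  ra <- relativeAbundance(counts, hr)
  expect_equal(ra["T1", "S1"], 0.01)
  expect_equal(unname(ra["T2", ]), c(0, 0))
  # doubling counts and human reads leaves ratios unchanged
  expect_equal(relativeAbundance(2 * counts, 2 * hr), ra)
  expect_error(relativeAbundance(counts, c(S1 = 0, S2 = 1)),
               "non-positive.*S1")
})

test_that("alpha diversity reproduces closed forms", {
  counts <- cbind(uniform = rep(25, 4), single = c(100, 0, 0, 0),
                  mixed = c(5, 3, 1, 1))
  rownames(counts) <- paste0("T", 1:4)
  div <- alphaDiversity(counts)
  u <- div[div$sample == "uniform", ]
  expect_equal(u$shannon, log(4), tolerance = 1e-12)
  expect_equal(u$simpson, 0.75, tolerance = 1e-12)
  expect_equal(u$invSimpson, 4, tolerance = 1e-12)
  expect_equal(u$chao1, u$observed)       # F1 = 0
  s <- div[div$sample == "single", ]
  expect_equal(s$shannon, 0)
  expect_equal(s$simpson, 0)
  expect_equal(s$invSimpson, 1)
  m <- div[div$sample == "mixed", ]
  p <- c(5, 3, 1, 1) / 10
  expect_equal(m$shannon, -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(m$simpson, 1 - sum(p^2), tolerance = 1e-12)
  expect_equal(m$invSimpson, 1 / sum(p^2), tolerance = 1e-12)
  # bias-corrected Chao1: S + F1(F1-1)/(2(F2+1)) = 4 + 2*1/2 = 5
  expect_equal(m$chao1, 5)
  # ACE oracle computed from its definition (rare cutoff 10)
  nRare <- 10; f <- table(c(5, 3, 1, 1))
  cAce <- 1 - 2 / nRare
  gamma2 <- max(4 / cAce * sum(c(1, 3, 5) * (c(1, 3, 5) - 1) *
                                 c(2, 1, 1)) / (nRare * (nRare - 1)) - 1, 0)
  expect_equal(m$ACE, 4 / cAce + 2 / cAce * gamma2, tolerance = 1e-6)

  # invariants: Shannon maximal at uniformity, permutation invariance
  set.seed(4)
  other <- c(40, 30, 20, 10)
  expect_lt(alphaDiversity(cbind(s = other))$shannon, log(4))
  perm <- counts[c(3, 1, 4, 2), , drop = FALSE]
  expect_equal(alphaDiversity(perm)[, -1], div[, -1])

  expect_warning(z <- alphaDiversity(cbind(empty = c(0, 0))), "zero total")
  expect_true(all(is.na(z[1, -1])))
})

test_that("diversity group tests are Welch t-tests", {
  div <- data.frame(sample = paste0("S", 1:10),
                    observed = c(rnorm(5, 20, 2), rnorm(5, 21, 4)),
                    shannon = rnorm(10, 2), simpson = runif(10),
                    invSimpson = rnorm(10, 5), chao1 = rnorm(10, 25),
                    ACE = rnorm(10, 25))
  labels <- rep(c("nonresponder", "responder"), each = 5)
  res <- diversityTest(div, labels)
  for (v in res$index) {
    ref <- t.test(div[[v]][labels == "responder"],
                  div[[v]][labels == "nonresponder"])
    row <- res[res$index == v, ]
    expect_equal(row$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(row$p.value, ref$p.value, tolerance = 1e-12)
  }
  # identical group values give t = 0, p = 1
  div2 <- div; div2$shannon <- rep(c(1, 2, 3, 4, 5), 2)
  row <- diversityTest(div2, labels)[2, ]
  expect_equal(row$t, 0)
  expect_equal(row$p.value, 1, tolerance = 1e-12)
})

test_that("differential abundance is null on identical columns and antisymmetric", {
  counts <- matrix(rep(c(30, 8, 0, 120, 55, 2), 8), ncol = 8,
                   dimnames = list(paste0("T", 1:6), paste0("S", 1:8)))
  labels <- rep(c("nonresponder", "responder"), each = 4)
  res <- suppressMessages(differentialAbundance(counts, labels))
  expect_true(all(res$log2FC == 0))
  expect_false(any(res$enriched))
  expect_true(all(attr(res, "sizeFactors") == 1))

  set.seed(10)
  counts2 <- matrix(rnbinom(6 * 10, mu = 40, size = 1), 6, 10,
                    dimnames = list(paste0("T", 1:6), paste0("S", 1:10)))
  counts2[1, ] <- counts2[1, ] + 5  # keep a taxon nonzero everywhere
  lab2 <- rep(c("nonresponder", "responder"), each = 5)
  a <- differentialAbundance(counts2, lab2)
  b <- differentialAbundance(counts2, rev(lab2))
  expect_equal(a$log2FC, -b$log2FC, tolerance = 1e-12)
  expect_equal(a$p.value, b$p.value, tolerance = 1e-12)
})

test_that("size factors agree with the reference median-of-ratios implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(2)
  counts <- matrix(rnbinom(40 * 12, mu = 60, size = 2) + 1, 40, 12,
                   dimnames = list(paste0("T", 1:40), paste0("S", 1:12)))
  sf <- icibiome:::.sizeFactors(counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-9)
})

test_that("a taxon absent from one group is tested with a pseudo-count and flagged", {
  counts <- rbind(T1 = c(0, 0, 0, 0, 40, 45, 50, 38),
                  T2 = c(20, 25, 18, 22, 21, 19, 24, 20),
                  T3 = c(5, 8, 6, 9, 7, 5, 8, 6))
  colnames(counts) <- paste0("S", 1:8)
  labels <- rep(c("nonresponder", "responder"), each = 4)
  res <- differentialAbundance(counts, labels)
  row <- res[res$taxon == "T1", ]
  expect_true(row$zeroGroup)
  expect_gt(row$log2FC, 1)
  expect_true(is.finite(row$p.value))
})
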