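test_that("log transform is elementwise log2(x + 1)", {
  expect_equal(logTransform(matrix(c(0, 1, 7, 3), 2)),
               matrix(c(0, 1, 3, 2), 2))
  expect_error(logTransform(matrix(-1)), "non-negative")
})

test_that("differential expression handles degenerate genes and thresholds", {
  x <- rbind(
    flat  = rep(5, 8),                      # zero variance, equal means
    const = c(rep(1, 4), rep(3, 4)),        # zero variance, shifted
    same  = c(1, 2, 3, 4, 1, 2, 3, 4),      # identical group means
    up    = c(1, 1.2, 0.8, 1, 4, 4.1, 3.9, 4))
  colnames(x) <- paste0("S", 1:8)
  labels <- rep(c("nonresponder", "responder"), each = 4)
  res <- differentialExpression(x, labels)
  expect_equal(res$p.value[res$gene == "flat"], 1)
  expect_equal(res$log2FC[res$gene == "flat"], 0)
  expect_equal(res$p.value[res$gene == "const"], 0)
  expect_equal(res$log2FC[res$gene == "same"], 0)
  expect_false(res$significant[res$gene == "same"])
  expect_equal(res$log2FC[res$gene == "up"], 3)
  expect_true(res$significant[res$gene == "up"])
  # BH step-up: adjusted p non-decreasing in raw-p rank, never below raw
  ord <- order(res$p.value)
  expect_true(all(diff(res$padj[ord]) >= -1e-12))
  expect_true(all(res$padj >= res$p.value - 1e-12))
})

test_that("signature Z-scores match their definition and oracle", {
  # single gene, values (1, 3): sample-sd standardization forces +/- 0.7071
  m <- matrix(c(1, 3), 1, 2, dimnames = list("G1", c("S1", "S2")))
  sc <- scoreSignatures(m, list(sig = "G1"))
  expect_equal(unname(sc[1, ]), c(-sqrt(0.5), sqrt(0.5)), tolerance = 1e-9)

  # signature of genes with identical Z profiles equals that profile
  prof <- c(2, 5, 3, 9)
  m2 <- rbind(G1 = prof, G2 = 10 * prof + 3, G3 = 0.1 * prof - 7)
  colnames(m2) <- paste0("S", 1:4)
  sc2 <- scoreSignatures(m2, list(sig = c("G1", "G2", "G3")))
  z <- (prof - mean(prof)) / sd(prof)
  expect_equal(unname(sc2[1, ]), z, tolerance = 1e-9)

  # random fixture equals brute-force column means of standardized rows
  set.seed(7)
  m3 <- matrix(rnorm(30), 6, 5,
               dimnames = list(paste0("G", 1:6), paste0("S", 1:5)))
  sig <- c("G2", "G4", "G5")
  sc3 <- scoreSignatures(m3, list(sig = sig))
  zr <- t(apply(m3[sig, ], 1, function(v) (v - mean(v)) / sd(v)))
  expect_equal(unname(sc3[1, ]), unname(colMeans(zr)), tolerance = 1e-12)
  # each used z-row has mean 0 and sd 1
  expect_equal(unname(rowMeans(zr)), rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(apply(zr, 1, sd)), rep(1, 3), tolerance = 1e-9)

  # invariance under per-gene affine maps with positive scale
  m4 <- m3
  m4["G2", ] <- 100 + m3["G2", ]
  m4["G4", ] <- 7 * m3["G4", ]
  expect_equal(scoreSignatures(m4, list(sig = sig)),
               sc3, tolerance = 1e-9)

  expect_warning(nas <- scoreSignatures(m3, list(bad = c("X1", "X2"))),
                 "no usable genes")
  expect_true(all(is.na(nas)))
})

test_that("signature stratification tests separate the response groups", {
  scores <- rbind(sep = c(0, 1, 2, 3, 4, 5),
                  tied = rep(1, 6))
  colnames(scores) <- paste0("S", 1:6)
  labels <- c(rep("nonresponder", 3), rep("responder", 3))
  res <- suppressWarnings(stratifyAndTest(scores, labels))
  expect_equal(res$U[res$signature == "sep"], 9)        # maximal
  expect_equal(res$p.value[res$signature == "tied"], 1) # all tied
  expect_identical(res$nHigh + res$nLow, rep(6L, 2))
})

test_that("Mann-Whitney normal approximation tracks exact enumeration", {
  set.seed(31)
  worst <- 0
  for (i in 1:20) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    x <- rnorm(nx); y <- rnorm(ny, sample(c(0, 1), 1))
    mw <- icibiome:::.mannWhitney(x, y)
    # U equals the rank-sum identity exactly
    expect_equal(mw$U, sum(rank(c(x, y))[1:nx]) - nx * (nx + 1) / 2)
    worst <- max(worst, abs(mw$p.value - exactMannWhitneyP(x, y)))
  }
  expect_lt(worst, 0.08)  # continuity-corrected approximation at n <= 8
})

test_that("AUROC matches its pairwise definition and symmetry", {
  labels <- c(rep("nonresponder", 4), rep("responder", 4))
  perfect <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expect_equal(unname(signatureAUROC(perfect, labels)), 1)
  expect_equal(unname(signatureAUROC(rep(1, 8), labels)), 0.5)
  expect_error(signatureAUROC(perfect, rep("responder", 8)), "at least")
  set.seed(13)
  score <- sample(0:5, 200, replace = TRUE)  # heavy ties
  lab <- sample(c("responder", "nonresponder"), 200, replace = TRUE)
  a <- unname(signatureAUROC(score, lab))
  expect_equal(a, bruteAUROC(score, lab == "responder"))
  expect_equal(a + unname(signatureAUROC(-score, lab)), 1)
})
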