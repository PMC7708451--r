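test_that("TPM normalisation matches the hand-computed example", {
  expect_equal(tpmNormalize(c(10, 90), c(1000, 3000)),
               c(250000, 750000))
  expect_equal(tpmNormalize(5, 2000), 1e6)
  set.seed(1)
  m <- matrix(rpois(60, 30), 10)
  rownames(m) <- paste0("g", 1:10)
  tp <- tpmNormalize(m, runif(10, 500, 3000))
  expect_equal(colSums(tp), rep(1e6, 6), tolerance = 1e-9)
  expect_error(tpmNormalize(c(0, 0), c(100, 100)), "all-zero")
})

test_that("gene filters drop by abundance then variability", {
  m <- rbind(low = c(2, 2, 2), stable = c(100, 100, 100),
             ok = c(10, 30, 20), wild = c(10, 300, 10))
  f <- filterGenes(m, minTpm = 5, rsdMax = 1)
  expect_setequal(f$kept, c("stable", "ok"))
  expect_equal(unname(f$removed["abundance"]), 1)
  # hand computation: [10, 30] has mean 20, sample sd 14.14, RSD 0.707
  f2 <- filterGenes(rbind(g = c(10, 30), h = c(50, 50)), 5, 1)
  expect_equal(unname(f2$summary$rsd[f2$summary$gene_id == "g"]),
               sqrt(2) * 10 / 20, tolerance = 1e-12)
  expect_error(filterGenes(rbind(a = c(1, 1)), 5, 1), "no genes")
})

test_that("filters are idempotent", {
  co <- tinyCohort()
  tpm <- expressionMatrix(co)
  f1 <- filterGenes(tpm)
  f2 <- filterGenes(tpm[f1$kept, ])
  expect_equal(f2$kept, f1$kept)
})

test_that("Box-Cox transform fixed-lambda cases and round trip", {
  expect_equal(boxcoxTransform(c(1, exp(1), exp(2)), 0), c(0, 1, 2))
  expect_equal(boxcoxTransform(c(1, 2, 3), 1), c(0, 1, 2))
  set.seed(3)
  x <- rlnorm(500, 2, 0.7)
  for (lam in c(-0.5, 0, 0.31, 1)) {
    y <- boxcoxTransform(x, lam)
    expect_equal(boxcoxInverse(y, lam), x, tolerance = 1e-9)
  }
  expect_error(boxcoxTransform(c(1, -1), 0.5), "positive")
})

test_that("Box-Cox lambda MLE is consistent and matches MASS profile", {
  set.seed(4)
  x <- rlnorm(1000, 1, 0.5)
  lam <- boxcoxLambda(x)
  expect_lt(abs(lam), 0.15)   # lognormal data: true lambda 0
  skip_if_not_installed("MASS")
  bc <- MASS::boxcox(x ~ 1, lambda = seq(-1, 1, 0.01), plotit = FALSE)
  expect_lt(abs(lam - bc$x[which.max(bc$y)]), 0.02)
})

test_that("length correction leaves residuals orthogonal to log-length", {
  set.seed(5)
  len <- round(runif(200, 300, 3000))
  tgt <- 0.5 * log10(len) + rnorm(200)
  res <- lengthCorrect(tgt, len)
  expect_lt(abs(cor(res, log10(len))), 1e-8)
  # perfect linear fit leaves zero residuals
  res2 <- lengthCorrect(2 * log10(len), len)
  expect_equal(max(abs(res2)), 0, tolerance = 1e-9)
  expect_warning(lengthCorrect(c(1, 2, 3), c(10, 10, 10)), "constant")
})

test_that("variance ratios flag zero-variance genes", {
  m <- rbind(g1 = c(1, 1), g2 = c(3, 3))
  v <- varianceRatio(m)
  expect_true(all(v$infinite))
  m2 <- rbind(g1 = c(1, 2), g2 = c(30, 31), g3 = c(100, 90))
  v2 <- varianceRatio(m2)
  expect_true(all(is.finite(v2$ratios)))
})

test_that("median target pipeline inverts back to median TPM", {
  co <- tinyCohort()
  tpm <- expressionMatrix(co)
  orf <- setNames(co@geneData$len_cds, geneIds(co))
  mt <- medianTarget(tpm, orf)
  back <- invertTarget(mt$summary$target, orf[mt$kept], mt$lambda,
                       mt$lengthFit)
  expect_equal(as.numeric(back), unname(mt$summary$median_tpm),
               tolerance = 1e-6)
  # monotone in median TPM at fixed length: check within a length class
  expect_error(medianTarget(tpm[1:2, , drop = FALSE], orf),
               "at least 3 genes")
})

test_that("lambda frozen on the fitting split is reused unchanged", {
  co <- tinyCohort()
  tpm <- expressionMatrix(co)
  orf <- setNames(co@geneData$len_cds, geneIds(co))
  all <- medianTarget(tpm, orf)
  sub <- medianTarget(tpm, orf, fitIdx = all$kept[1:40])
  lamSub <- boxcoxLambda(all$summary$median_tpm[1:40])
  expect_equal(sub$lambda, lamSub, tolerance = 1e-8)
})
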