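test_that("degenerate grammar yields pure background sequences", {
  cfg <- syntheticConfig(nGenes = 10, nMotifs = 0, nRules = 0,
                         cdsCodonRange = c(50L, 60L))
  co <- generateGenome(cfg, seed = 1)
  expect_equal(nrow(plantedPositions(co)), 0)
  expect_length(grammarTruth(co)@rules, 0)
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- syntheticConfig(nGenes = 25, nMotifs = 4, nRules = 4,
                         cdsCodonRange = c(50L, 80L),
                         adoptProbRange = c(0.2, 0.4))
  a <- generateGenome(cfg, seed = 7)
  b <- generateGenome(cfg, seed = 7)
  for (r in names(a@regions))
    expect_identical(as.character(a@regions[[r]]),
                     as.character(b@regions[[r]]))
  expect_identical(as.data.frame(plantedPositions(a)),
                   as.data.frame(plantedPositions(b)))
  ea <- generateExpression(a, 10, seed = 9)
  eb <- generateExpression(b, 10, seed = 9)
  expect_identical(expressionMatrix(ea), expressionMatrix(eb))
})

test_that("every planted rule is fully carried by at least 3 genes", {
  co <- tinyCohort()
  occ <- truthOccurrence(co)
  for (r in grammarTruth(co)@rules)
    expect_gte(sum(rowSums(occ[, r$motifs, drop = FALSE]) ==
                     length(r$motifs)), 3)
})

test_that("planted instances sit at their recorded positions", {
  co <- tinyCohort()
  pl <- plantedPositions(co)
  truth <- grammarTruth(co)
  w <- ncol(truth@motifs[[1]]$pwm)
  idx <- sample(nrow(pl), 40)
  for (k in idx) {
    seq <- as.character(co@regions[[pl$region[k]]][[pl$gene_id[k]]])
    expect_equal(substr(seq, pl$start[k], pl$start[k] + w - 1),
                 pl$sequence[k])
  }
})

test_that("planted instances all clear their motif's scan threshold", {
  co <- tinyCohort()
  pl <- plantedPositions(co)
  truth <- grammarTruth(co)
  scores <- vapply(seq_len(nrow(pl)), function(k)
    pwmScore(pl$sequence[k], truth@motifs[[pl$motif_id[k]]]$pwm), 0)
  thr <- vapply(pl$motif_id, function(m) truth@motifs[[m]]$threshold, 0)
  expect_true(all(scores >= thr))   # 100% self-recovery
})

test_that("cds structure is valid: ATG start, stop end, frame intact", {
  co <- tinyCohort()
  cds <- as.character(co@regions$cds)
  expect_true(all(nchar(cds) %% 3 == 0))
  expect_true(all(substr(cds, 1, 3) == "ATG"))
  stops <- substr(cds, nchar(cds) - 2, nchar(cds))
  expect_true(all(stops %in% c("TAA", "TAG", "TGA")))
})

test_that("expression emulates the cohort-level statistics", {
  co <- tinyCohort()
  tpm <- expressionMatrix(co)
  expect_true(all(tpm > 0))
  expect_equal(unname(colSums(tpm)), rep(1e6, ncol(tpm)),
               tolerance = 1e-6)
  expect_error(generateExpression(co, nExperiments = 1), "RSD")
})

test_that("zero between-experiment noise gives zero RSD", {
  cfg <- syntheticConfig(nGenes = 30, nMotifs = 3, nRules = 3,
                         cdsCodonRange = c(50L, 60L),
                         noiseSdBetweenMed = 1e-12,
                         noiseSdBetweenSpread = 1e-12)
  co <- generateExpression(generateGenome(cfg, seed = 3), 10, seed = 4)
  r <- rsdVec(expressionMatrix(co))
  expect_lt(max(r), 1e-6)
})

test_that("motif wider than its region is rejected", {
  expect_error(syntheticConfig(nGenes = 10, motifWidth = 60,
                               regionLengths = c(promoter = 100,
                                                 utr5 = 50, utr3 = 50,
                                                 terminator = 80)),
               "longer than its target region")
})

test_that("cross-region rule fraction matches the configured default", {
  co <- tinyCohort()
  tr <- grammarTruth(co)
  regions <- vapply(tr@motifs, `[[`, "", "region")
  frac <- mean(vapply(tr@rules, function(r)
    length(unique(regions[r$motifs])) >= 2, TRUE))
  expect_equal(frac, tr@crossRegionFraction)
  expect_gte(frac, 0.5)
})

test_that("ortholog generator plants the requested rate correlation", {
  cfg <- syntheticConfig(nGenes = 400, nMotifs = 0, nRules = 0,
                         cdsCodonRange = c(60L, 100L))
  co <- generateGenome(cfg, seed = 21)
  # planted correlation ~0 gives near-zero true-rate correlation
  o0 <- generateOrthologs(co, nSpecies = 4, regionRateCorrelation = 0,
                          regions = c("promoter", "cds"), seed = 22)
  expect_lt(abs(cor(o0$trueRates[, "promoter"], o0$trueRates[, "cds"])),
            0.12)
  o5 <- generateOrthologs(co, nSpecies = 4,
                          regionRateCorrelation = 0.5,
                          regions = c("promoter", "cds"), seed = 23)
  expect_equal(cor(o5$trueRates[, "promoter"], o5$trueRates[, "cds"]),
               0.5, tolerance = 0.12)
  expect_error(generateOrthologs(co, nSpecies = 4,
                                 regionRateCorrelation = 1.2),
               "correlation")
})

test_that("zero substitution rate reproduces identical sequences", {
  cfg <- syntheticConfig(nGenes = 5, nMotifs = 0, nRules = 0,
                         cdsCodonRange = c(50L, 60L))
  co <- generateGenome(cfg, seed = 31)
  o <- generateOrthologs(co, nSpecies = 3, regionRateCorrelation = 0,
                         regions = "promoter",
                         meanRate = c(promoter = 0), seed = 32)
  a <- o$alignments[[1]]$promoter
  expect_equal(length(unique(a$seqs)), 1)
  expect_equal(substitutionRate(a)$rate, 0)
})
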