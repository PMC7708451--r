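test_that("FP-growth matches exhaustive enumeration on random matrices", {
  for (s in 1:6) {
    occ <- randomOccurrence(50, 12, density = 0.3, seed = s)
    a <- mineItemsets(occ, minGenes = 3, maxSize = 6)
    b <- enumerateItemsets(occ, minGenes = 3, maxSize = 6)
    expect_setequal(paste(a$itemset, a$support),
                    paste(b$itemset, b$support))
  }
})

test_that("FP-growth worked examples and edge cases", {
  occ <- matrix(TRUE, 3, 2, dimnames = list(paste0("g", 1:3),
                                            c("m1", "m2")))
  out <- mineItemsets(occ, minGenes = 3)
  expect_equal(out$itemset, "m1+m2")
  expect_equal(out$support, 3L)
  expect_equal(nrow(mineItemsets(occ, minGenes = 10)), 0)
  expect_equal(nrow(mineItemsets(occ & FALSE)), 0)
})

test_that("support is anti-monotone in itemset size", {
  occ <- randomOccurrence(60, 8, density = 0.4, seed = 9)
  its <- mineItemsets(occ, minGenes = 1, maxSize = 4)
  supp <- setNames(its$support, its$itemset)
  sets <- strsplit(its$itemset, "+", fixed = TRUE)
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    if (length(s) < 3) next
    for (drop in seq_along(s)) {
      parent <- paste(sort(s[-drop]), collapse = "+")
      if (parent %in% names(supp))
        expect_gte(supp[[parent]], supp[[i]])
    }
  }
})

test_that("chi-squared closed form matches the worked table and oracle", {
  cs <- chiSquared2x2(10, 10, 10, 70)
  expect_equal(cs$statistic, 14.0625, tolerance = 1e-12)
  # generic contingency-test oracle without continuity correction
  o <- suppressWarnings(
    chisq.test(matrix(c(10, 10, 10, 70), 2), correct = FALSE))
  expect_equal(cs$statistic, unname(o$statistic), tolerance = 1e-9)
  expect_equal(cs$p_value, o$p.value, tolerance = 1e-9)
  set.seed(41)
  for (i in 1:5) {
    tb <- matrix(rpois(4, 20) + 1, 2)
    cs <- chiSquared2x2(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])
    o <- suppressWarnings(chisq.test(tb, correct = FALSE))
    expect_equal(cs$statistic, unname(o$statistic), tolerance = 1e-9)
  }
})

test_that("rule statistics: lift, confidence, SNR", {
  ## N=100 genes, A in 20, B in 10, both in 8 -> lift 4
  occ <- matrix(FALSE, 100, 2, dimnames = list(sprintf("g%03d", 1:100),
                                               c("A", "B")))
  occ[1:20, "A"] <- TRUE
  occ[c(1:8, 21:22), "B"] <- TRUE
  tpm <- setNames(rep(10, 100), rownames(occ))
  rs <- ruleStats(c("A", "B"), occ, tpm)
  expect_equal(rs$lift, 0.08 / (0.2 * 0.1), tolerance = 1e-12)
  expect_equal(rs$support, 8)
  # confidence: drop the lexicographically last item (B) -> supp/supp(A)
  expect_equal(rs$confidence, 8 / 20)
  # all-equal carrier expression -> infinite flagged SNR
  expect_true(is.infinite(rs$snr))
  expect_true(rs$snr_infinite)
  tpm2 <- tpm; tpm2[1:8] <- c(5, 6, 7, 8, 9, 10, 11, 12)
  rs2 <- ruleStats(c("A", "B"), occ, tpm2)
  expect_equal(rs2$snr, mean(tpm2[1:8]) / sd(tpm2[1:8]))
})

test_that("BH filtering is monotone in alpha and respects min genes", {
  occ <- randomOccurrence(80, 10, density = 0.35, seed = 10)
  tpm <- setNames(rlnorm(80, 3, 1), rownames(occ))
  rules <- mineRules(occ, tpm, minGenes = 3, maxSize = 3)
  s05 <- significantRules(rules, occ, alpha = 0.05)
  s01 <- significantRules(rules, occ, alpha = 0.01)
  expect_true(all(s01$rules$itemset %in% s05$rules$itemset))
  expect_true(all(s05$rules$support >= 3))
  allP1 <- rules; allP1$p_value <- 1
  expect_equal(nrow(significantRules(allP1, occ)$rules), 0)
})

test_that("BH keeps the realized false discovery rate near alpha", {
  ## independent uniform p-values: expected V/max(R,1) <= alpha
  set.seed(42)
  fdr <- replicate(1000, {
    p <- runif(60)
    q <- p.adjust(p, "BH")
    sum(q < 0.05) / max(1, sum(q < 0.05))
  })
  # all discoveries are false here, so FDP is 1 whenever R > 0;
  # the rate of any discovery at all must stay below alpha
  expect_lte(mean(fdr > 0), 0.05 + 0.02)
})

test_that("planted rules are recovered from the truth occurrence matrix", {
  co <- tinyCohort()
  occ <- truthOccurrence(co)
  tpm <- setNames(apply(expressionMatrix(co), 1, median), geneIds(co))
  rules <- mineRules(occ, tpm, minGenes = 3, maxSize = 3)
  sig <- significantRules(rules, occ, alpha = 0.05)
  planted <- vapply(grammarTruth(co)@rules, function(r)
    paste(sort(r$motifs), collapse = "+"), "")
  expect_gte(mean(planted %in% sig$rules$itemset), 0.75)
})

test_that("specificity contrast computes SNR and recovered range", {
  occ <- matrix(FALSE, 6, 2, dimnames = list(paste0("g", 1:6),
                                             c("mA", "mB")))
  occ[1:3, "mA"] <- TRUE; occ[4:6, "mB"] <- TRUE
  tpm <- setNames(c(1, 2, 4, 100, 120, 150), rownames(occ))
  rules <- data.frame(itemset = "mA+mB", size = 2, support = 0,
                      mean_tpm = NA, snr = NA)
  sc <- specificityContrast(occ, rules, tpm)
  expect_equal(nrow(sc$motifs), 2)
  # identical carrier sets give identical SNR by construction
  rs <- ruleStats("mA", occ, tpm)
  expect_equal(sc$motifs$snr[sc$motifs$item == "mA"],
               rs$snr)
})

test_that("repurposing groups compute fold ranges per shared motif", {
  rules <- data.frame(
    itemset = c("a+b+c", "a+d+e", "b+d+f", "a+b+d"),
    size = 3, support = 5,
    mean_tpm = c(5, 50, 10, 500))
  rg <- repurposingGroups(rules, "common_motif")
  a <- rg$groups[rg$groups$key == "a", ]
  expect_equal(a$n_rules, 3)
  expect_equal(a$fold_range, 100)
  expect_true(rg$frac_over_10x > 0)
  # single-substitution grouping: a+b+c vs a+b+d share pair a+b
  rg2 <- repurposingGroups(rules, "single_substitution")
  expect_true(any(rg2$groups$fold_range == 100))
})

test_that("codon specificity contrasts rules against single motifs", {
  occ <- matrix(FALSE, 6, 2, dimnames = list(paste0("g", 1:6),
                                             c("mA", "mB")))
  occ[1:4, "mA"] <- TRUE; occ[3:6, "mB"] <- TRUE
  cm <- diag(6)[, 1:6]
  rownames(cm) <- rownames(occ)
  # unit basis vectors: every pairwise distance is sqrt(2)
  rules <- data.frame(itemset = "mA+mB", size = 2, support = 2,
                      mean_tpm = 1)
  cs <- codonSpecificity(occ, rules, cm)
  expect_equal(unname(cs$motifs["mA"]), sqrt(2), tolerance = 1e-12)
  expect_equal(unname(cs$rules[1]), sqrt(2), tolerance = 1e-12)
  # identical vectors -> distance 0
  cm2 <- matrix(rep(1 / 64, 6 * 64), 6,
                dimnames = list(rownames(occ), NULL))
  cs2 <- codonSpecificity(occ, rules, cm2)
  expect_equal(unname(cs2$motifs["mA"]), 0)
})
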