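mkWindows <- function(seqs, relevance = NULL, region = "promoter",
                      genes = NULL) {
  n <- length(seqs)
  S4Vectors::DataFrame(
    gene_id = if (is.null(genes)) sprintf("g%03d", seq_len(n)) else genes,
    region = region, offset = 1L, sequence = seqs,
    relevance = if (is.null(relevance)) rev(seq_len(n)) / n else relevance)
}

test_that("window extraction tiles runs and centres short ones", {
  V <- matrix(0, 2, 60)
  M <- matrix(FALSE, 2, 60)
  M[1, 11:35] <- TRUE          # 25-bp run -> 3 windows, last right-aligned
  M[2, 30:33] <- TRUE          # 4-bp run -> centred 10-bp window
  seqs <- list(promoter = setNames(
    c(paste(rep("ACGTT", 12), collapse = ""),
      paste(rep("GGCAT", 12), collapse = "")), c("gA", "gB")))
  rp <- new("RelevanceProfileSet", values = list(promoter = V),
            mask = list(promoter = M), Y = c(1, 1), window = 10L,
            flagged = c(FALSE, FALSE), geneIds = c("gA", "gB"))
  w <- extractWindows(rp, seqs)
  wA <- w[w$gene_id == "gA", ]
  expect_equal(sort(wA$offset), c(11L, 21L, 26L))
  expect_equal(nchar(wA$sequence[1]), 10)
  wB <- w[w$gene_id == "gB", ]
  expect_equal(nrow(wB), 1)
  expect_equal(wB$offset, 27L)   # centred on positions 30:33
  # empty mask -> empty list
  rp@mask$promoter[] <- FALSE
  expect_equal(nrow(extractWindows(rp, seqs)), 0)
})

test_that("greedy identity clustering follows the worked examples", {
  w <- mkWindows(rep("ACGTACGTAC", 5))
  cl <- identityCluster(w, 0.8, minCluster = 5)
  expect_length(cl, 1)
  expect_length(cl[[1]]$members, 5)

  # 9/10 identity joins at cutoff 0.8 (and 0.9)
  w2 <- mkWindows(c(rep("ACGTACGTAC", 4), "ACGTACGTAG"))
  cl2 <- identityCluster(w2, 0.9, minCluster = 5)
  expect_length(cl2, 1)

  # 4 members < minCluster 5 -> nothing emitted
  w3 <- mkWindows(rep("ACGTACGTAC", 4))
  expect_length(identityCluster(w3, 0.8, minCluster = 5), 0)

  # shifted copies join within the +/-2 window
  w4 <- mkWindows(c(rep("AACCGGTTAC", 5), "CCGGTTACGT"))
  cl4 <- identityCluster(w4, 0.8, minCluster = 5, maxShift = 2)
  expect_length(cl4, 1)
  expect_error(identityCluster(mkWindows(c("ACGT", "ACGTACGTAC"))),
               "mixed window lengths")
})

test_that("PWM building applies pseudocounts and edge trimming", {
  w <- mkWindows(rep("AAAAAAAAAA", 5))
  cl <- identityCluster(w, 0.8, minCluster = 5)
  m <- buildPWM(cl[[1]], w, id = "t1")
  expect_equal(colSums(m$pwm), rep(1, ncol(m$pwm)), tolerance = 1e-12)
  expect_equal(unname(m$pwm["A", 1]), 5.25 / 6, tolerance = 1e-12)
  # information content of the pseudocounted column
  p <- c(5.25, 0.25, 0.25, 0.25) / 6
  expect_equal(unname(m$ic[1]), 2 + sum(p * log2(p)), tolerance = 1e-12)
  expect_gt(min(m$ic), 0.2)

  # uniform random columns trim away completely
  set.seed(31)
  rnd <- vapply(1:40, function(i)
    paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = ""), "")
  wr <- mkWindows(rnd, relevance = rep(1, 40))
  clr <- list(list(representative = rnd[1], members = seq_len(40),
                   shifts = rep(0L, 40), region = "promoter"))
  expect_message(mr <- buildPWM(clr[[1]], wr, id = "rnd"),
                 "fully trimmed")
  expect_null(mr)
})

test_that("PWM comparison scores identity, palindromes and nulls", {
  set.seed(32)
  w <- mkWindows(rep("ACGTTGCGCA", 6))
  cl <- identityCluster(w, 0.8)
  m <- buildPWM(cl[[1]], w, id = "a")
  self <- comparePWMs(m, m, nPermutations = 200)
  expect_equal(self$score, 1, tolerance = 1e-12)
  expect_lt(self$p_value, 0.05)

  # palindromic motif equals its reverse complement
  pal <- mkWindows(rep("ACGTGCACGT", 6))
  mp <- buildPWM(identityCluster(pal, 0.8)[[1]], pal, id = "p")
  rc <- mp$pwm[c("T", "G", "C", "A"), rev(seq_len(ncol(mp$pwm)))]
  rownames(rc) <- c("A", "C", "G", "T")
  expect_equal(comparePWMs(mp$pwm, rc, nPermutations = 100)$score, 1,
               tolerance = 1e-12)

  # disjoint consensus motifs are not significant
  a <- mkWindows(rep("AAAAAAAAAA", 6))
  b <- mkWindows(rep("CCCCCCCCCC", 6))
  ma <- buildPWM(identityCluster(a, 0.8)[[1]], a, id = "a")
  mb <- buildPWM(identityCluster(b, 0.8)[[1]], b, id = "b")
  cmp <- comparePWMs(ma, mb, nPermutations = 200)
  expect_gt(cmp$p_value, 0.05)
  expect_error(comparePWMs(ma$pwm[, 1:2], mb$pwm), "overlap")
})

test_that("occurrence matrix uses boolean member semantics", {
  w <- S4Vectors::DataFrame(
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g1"),
    region = "promoter", offset = 1L,
    sequence = rep("ACGTACGTAC", 6),
    relevance = rep(1, 6))
  cl <- identityCluster(w, 0.8, minCluster = 5)
  m <- buildPWM(cl[[1]], w, id = "m1")
  ms <- new("MotifSet", motifs = list(m1 = m), windowSize = 10L,
            identityCutoff = 0.8)
  occ <- occurrenceMatrix(ms, sprintf("g%d", 1:6))
  expect_equal(sum(occ), 5)            # g1 counted once, g6 absent
  expect_true(occ["g1", "m1"])
  expect_false(occ["g6", "m1"])
  expect_equal(unname(attr(occ, "regions")["m1"]), "promoter")
})

test_that("MEME round trip preserves probability matrices", {
  co <- tinyCohort()
  truth <- grammarTruth(co)
  path <- tempfile(fileext = ".meme")
  writeMEME(truth@motifs, path)
  back <- readMEME(path)
  expect_equal(names(back), names(truth@motifs))
  for (id in names(back))
    expect_equal(back[[id]]$pwm, truth@motifs[[id]]$pwm,
                 tolerance = 1e-4)
})

test_that("PWM-scan occurrence mode finds planted instances", {
  co <- tinyCohort()
  truth <- grammarTruth(co)
  tm <- truth@motifs[[1]]
  ms <- new("MotifSet",
            motifs = list(list(id = tm$id, region = tm$region,
                               pwm = tm$pwm, ic = rep(2, ncol(tm$pwm)),
                               members = S4Vectors::DataFrame(
                                 gene_id = character(0)))),
            windowSize = 10L, identityCutoff = 0.8)
  pl <- plantedPositions(co)
  carriers <- unique(pl$gene_id[pl$motif_id == tm$id])
  occ <- occurrenceMatrix(ms, geneIds(co), mode = "scan", cohort = co,
                          scanFraction = 0.39)
  # the planting threshold is ~0.39 of the maximum log-odds, so every
  # planted carrier must be found by rescanning
  expect_true(all(occ[carriers, tm$id]))
})

test_that("swap constructs accept a substituted reporter CDS", {
  co <- tinyCohort()
  tpm <- expressionMatrix(co)
  orf <- setNames(co@geneData$len_cds, geneIds(co))
  mt <- medianTarget(tpm, orf)
  feats <- cohortFeatures(co)
  keep <- match(mt$kept, feats$geneIds)
  feats <- list(seq = feats$seq[keep, , , drop = FALSE],
                num = feats$num[keep, , drop = FALSE],
                regions = feats$regions, geneIds = mt$kept,
                regionLengths = feats$regionLengths)
  spec <- tinyModelSpec()
  m <- buildModel(spec, list(seqLen = dim(feats$seq)[3],
                             numFeatures = ncol(feats$num)), seed = 5)
  m@norm <- list(numMu = rep(0, 72), numSd = rep(1, 72), yMu = 0,
                 ySd = 1, run = NULL)
  gfp <- paste0("ATG", paste(rep("GGTGAA", 40), collapse = ""), "TAA")
  pc <- predictConstructs(m, co, feats, cbind(1:3, 1:3), mt$lambda,
                          mt$lengthFit, cdsOverride = gfp)
  expect_equal(nrow(pc), 3)
  expect_true(all(pc$predicted_tpm > 0))
  # with a common CDS the diagonal no longer reproduces native values
  pc2 <- predictConstructs(m, co, feats, cbind(1:3, 1:3), mt$lambda,
                           mt$lengthFit)
  expect_equal(pc2$fold_change, rep(1, 3), tolerance = 1e-9)
})
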