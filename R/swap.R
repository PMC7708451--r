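#' Split a gene into regulatory halves
#'
#' The promoter half is the promoter plus 5'UTR; the terminator half is
#' the 3'UTR plus terminator. Recombining a gene's own halves
#' reassembles the native gene.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param geneId gene identifier.
#' @return list with `promoter_half` and `terminator_half`, each a list
#'   of `origin` and `sequences`.
#' @export
makeHalves <- function(cohort, geneId) {
  regs <- cohort@regions
  stopifnot(geneId %in% geneIds(cohort))
  pick <- function(r) unname(as.character(regs[[r]][geneId]))
  for (r in REGULATORY_REGIONS)
    if (!nchar(pick(r))) stop(sprintf("missing region %s for %s", r,
                                      geneId))
  list(promoter_half = list(origin = geneId, kind = "promoter_half",
                            sequences = list(promoter = pick("promoter"),
                                             utr5 = pick("utr5"))),
       terminator_half = list(origin = geneId, kind = "terminator_half",
                              sequences = list(utr3 = pick("utr3"),
                                               terminator =
                                                 pick("terminator"))))
}

#' Enumerate promoter-half x terminator-half combinations
#'
#' Lazily yields all n x n (promoter half, terminator half) index pairs
#' without materialising them; `count` is n^2.
#'
#' @param geneIds character vector of n gene ids.
#' @return object of class `swapStream` with `$count`, `$n` and
#'   `$nextBatch(size)` returning a two-column matrix of gene indices
#'   (promoter-half gene, terminator-half gene) or `NULL` when
#'   exhausted.
#' @export
enumerateCombinations <- function(geneIds) {
  n <- length(geneIds)
  stopifnot(n >= 1)
  pos <- 0
  count <- as.numeric(n)^2
  nextBatch <- function(size = 10000L) {
    if (pos >= count) return(NULL)
    take <- min(size, count - pos)
    idx <- pos + seq_len(take)
    pos <<- pos + take
    cbind(promoter = ((idx - 1) %/% n) + 1,
          terminator = ((idx - 1) %% n) + 1)
  }
  structure(list(count = count, n = n, geneIds = geneIds,
                 nextBatch = nextBatch),
            class = "swapStream")
}

#' @export
length.swapStream <- function(x) x$count

#' @export
print.swapStream <- function(x, ...) {
  cat("swapStream:", x$n, "x", x$n, "=", format(x$count, big.mark = ","),
      "combinations\n")
  invisible(x)
}

swapFeatures <- function(cohort, pairs, features, regionLengths,
                         cdsOverride = NULL) {
  ## chimera features: promoter+utr5 and CDS/codon features from the
  ## promoter-half gene; utr3+terminator from the terminator-half gene;
  ## stability covariates recomputed on the chimera
  ids <- features$geneIds
  n <- nrow(pairs)
  pi <- pairs[, 1]; ti <- pairs[, 2]
  ## map feature rows back to cohort rows for the raw sequences
  coPi <- match(ids[pi], geneIds(cohort))
  coTi <- match(ids[ti], geneIds(cohort))
  bounds <- features$regions
  Ltot <- dim(features$seq)[3]
  X <- array(0, dim = c(n, 4L, Ltot))
  for (r in c("promoter", "utr5")) {
    cols <- bounds[[r]]["start"]:bounds[[r]]["end"]
    X[, , cols] <- features$seq[pi, , cols, drop = FALSE]
  }
  for (r in c("utr3", "terminator")) {
    cols <- bounds[[r]]["start"]:bounds[[r]]["end"]
    X[, , cols] <- features$seq[ti, , cols, drop = FALSE]
  }
  num <- features$num[pi, , drop = FALSE]
  utr5 <- as.character(cohort@regions$utr5)[coPi]
  utr3 <- as.character(cohort@regions$utr3)[coTi]
  cds <- if (is.null(cdsOverride)) as.character(cohort@regions$cds)[coPi]
         else rep(cdsOverride, n)
  if (!is.null(cdsOverride))
    for (i in seq_len(n)) num[i, 1:64] <- codonProbs(cds[i])
  for (i in seq_len(n))
    num[i, 65:72] <- as.numeric(stabilityVars(utr5[i], cds[i], utr3[i]))
  list(seq = X, num = num,
       geneIds = sprintf("%s|%s", ids[pi], ids[ti]))
}

#' Predict expression for swap constructs
#'
#' Builds chimera features for each (promoter half, terminator half)
#' pair, predicts with the trained model, inverse-transforms to TPM
#' (ORF length taken from the promoter-half gene) and reports fold
#' change versus the model's native prediction for the promoter-half
#' gene.
#'
#' @param model trained [SeqExprModel-class].
#' @param cohort the [SyntheticCohort-class].
#' @param features list from [cohortFeatures()] on the cohort.
#' @param pairs two-column matrix of gene indices (from a
#'   [enumerateCombinations()] stream) or ids.
#' @param lambda,lengthFit target transform constants from
#'   [medianTarget()].
#' @param tpmFloor clip for out-of-domain inversions.
#' @param cdsOverride optional CDS sequence (e.g. a fluorescent-reporter
#'   ORF) substituted into every construct: codon and stability
#'   covariates are recomputed from it and its length is used for the
#'   inverse transform.
#' @return data.frame: promoter_gene, terminator_gene, predicted_tpm,
#'   native_tpm, fold_change.
#' @export
predictConstructs <- function(model, cohort, features, pairs, lambda,
                              lengthFit, tpmFloor = 1e-3,
                              cdsOverride = NULL) {
  ids <- features$geneIds
  if (is.character(pairs))
    stop("pairs must be a two-column index matrix")
  sf <- swapFeatures(cohort, pairs, features, features$regionLengths,
                     cdsOverride = cdsOverride)
  pred <- predictExpression(model, sf)
  orf <- if (is.null(cdsOverride))
    nchar(as.character(cohort@regions$cds))[
      match(ids[pairs[, 1]], geneIds(cohort))]
  else rep(nchar(cdsOverride), nrow(pairs))
  tpm <- invertTarget(pred, orf, lambda, lengthFit, floor = tpmFloor)
  nativePred <- predictExpression(model, features, idx = pairs[, 1])
  nativeTpm <- invertTarget(nativePred, orf, lambda, lengthFit,
                            floor = tpmFloor)
  data.frame(promoter_gene = ids[pairs[, 1]],
             terminator_gene = ids[pairs[, 2]],
             predicted_tpm = as.numeric(tpm),
             native_tpm = as.numeric(nativeTpm),
             fold_change = as.numeric(tpm) / as.numeric(nativeTpm))
}

#' Dinucleotide-preserving shuffle
#'
#' Altschul-Erickson shuffle: exactly preserves all 16 dinucleotide
#' counts and the first and last base, sampling uniformly among valid
#' shuffles via random edge orderings accepted when the last-edge set
#' forms an arborescence towards the terminal vertex.
#'
#' @param seq character DNA (A/C/G/T only, length >= 2).
#' @param seed optional integer seed.
#' @return shuffled sequence.
#' @export
dinucleotideShuffle <- function(seq, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(toupper(seq), "")[[1]]
  if (length(ch) < 2) stop("sequence too short to shuffle")
  if (any(!ch %in% BASES)) stop("sequence contains non-ACGT characters")
  n <- length(ch)
  verts <- unique(ch)
  if (length(verts) == 1) return(seq)
  from <- ch[-n]; to <- ch[-1]
  last <- ch[n]
  edges <- split(to, factor(from, levels = verts))
  repeat {
    ord <- lapply(edges, sample)
    ## last-edge test: for every vertex except the terminal one, walking
    ## last edges must reach the terminal vertex (arborescence condition)
    ok <- TRUE
    for (v in setdiff(verts, last)) {
      cur <- v
      seen <- character(0)
      while (cur != last) {
        if (cur %in% seen || !length(ord[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- ord[[cur]][length(ord[[cur]])]
      }
      if (!ok) break
    }
    if (!ok) next
    ## walk the trail consuming edges in order
    remaining <- lapply(ord, function(x) x)
    ptr <- stats::setNames(rep(1L, length(verts)), verts)
    outSeq <- character(n)
    outSeq[1] <- ch[1]
    cur <- ch[1]
    for (i in 2:n) {
      nxt <- remaining[[cur]][ptr[cur]]
      ptr[cur] <- ptr[cur] + 1L
      outSeq[i] <- nxt
      cur <- nxt
    }
    return(paste(outSeq, collapse = ""))
  }
}

#' Count dinucleotides
#'
#' @param seq character DNA.
#' @return named 16-vector of adjacent-pair counts.
#' @export
dinucleotideCounts <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  pairs <- paste0(ch[-length(ch)], ch[-1])
  lv <- as.vector(outer(BASES, BASES, paste0))
  table(factor(pairs, levels = lv))
}

#' Native versus shuffled swap effect
#'
#' For each gene in a subset, predicts TPM for swaps of its promoter
#' half with `nPartners` other genes' terminator halves, and for
#' dinucleotide-preserving shuffles of those same terminator halves.
#' Compares the two log fold-change distributions with the
#' Brown-Forsythe (median-centred Levene) test and reports the variance
#' and dynamic-range ratios.
#'
#' @param model trained [SeqExprModel-class].
#' @param cohort the [SyntheticCohort-class].
#' @param features list from [cohortFeatures()].
#' @param lambda,lengthFit transform constants.
#' @param genes gene ids to use as promoter halves (default: all).
#' @param nPartners terminator halves per gene.
#' @param seed integer.
#' @return list with `levene_p`, `variance_ratio`, `range_ratio`,
#'   `native`, `shuffled` (log10 fold changes).
#' @export
shuffleControl <- function(model, cohort, features, lambda, lengthFit,
                           genes = NULL, nPartners = 20, seed = 1L) {
  set.seed(seed)
  ids <- features$geneIds
  if (is.null(genes)) genes <- ids
  gi <- match(genes, ids)
  pairs <- do.call(rbind, lapply(gi, function(i)
    cbind(i, sample(setdiff(seq_along(ids), i), nPartners))))
  native <- predictConstructs(model, cohort, features, pairs, lambda,
                              lengthFit)
  shufCohort <- cohort
  keepIdx <- match(ids, geneIds(cohort))
  for (r in c("utr3", "terminator")) {
    s <- as.character(cohort@regions[[r]])
    s[keepIdx] <- vapply(s[keepIdx], dinucleotideShuffle, "")
    shufCohort@regions[[r]] <- Biostrings::DNAStringSet(
      stats::setNames(s, names(cohort@regions[[r]])))
  }
  shufFeatures <- features
  for (r in c("utr3", "terminator")) {
    b <- features$regions[[r]]
    al <- "left"
    sseq <- as.character(shufCohort@regions[[r]])[keepIdx]
    L <- b["end"] - b["start"] + 1L
    for (i in seq_along(ids))
      shufFeatures$seq[i, , b["start"]:b["end"]] <-
        oneHotEncode(sseq[i], L, align = al)
  }
  shuffled <- predictConstructs(model, shufCohort, shufFeatures, pairs,
                                lambda, lengthFit)
  lf <- log10(native$fold_change)
  ls <- log10(shuffled$fold_change)
  lev <- leveneTest2(lf, ls)
  rng <- function(x) diff(range(x))
  list(levene_p = lev$p_value,
       levene_statistic = lev$statistic,
       variance_ratio = stats::var(lf) / stats::var(ls),
       range_ratio = rng(lf) / rng(ls),
       native = lf, shuffled = ls)
}

# Brown-Forsythe variant of Levene's test for two groups: one-way anova
# on absolute deviations from the group medians
leveneTest2 <- function(x, y) {
  z <- c(abs(x - stats::median(x)), abs(y - stats::median(y)))
  g <- factor(rep(c("a", "b"), c(length(x), length(y))))
  a <- stats::anova(stats::lm(z ~ g))
  list(statistic = a$`F value`[1], p_value = a$`Pr(>F)`[1])
}
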