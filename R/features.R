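#' @importFrom Biostrings DNAStringSet oligonucleotideFrequency width
NULL

BASES <- c("A", "C", "G", "T")

# the 64 codons in lexicographic order AAA..TTT
CODONS <- sort(do.call(paste0,
  expand.grid(BASES, BASES, BASES, stringsAsFactors = FALSE)))
STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(CODONS, STOP_CODONS)

#' One-hot encode a DNA sequence
#'
#' Encodes a sequence as a 4 x `targetLen` binary matrix (rows A, C, G, T).
#' `N` becomes an all-zero column. Sequences shorter than `targetLen` are
#' zero-padded and longer ones truncated; `align` controls which end of the
#' target the real sequence occupies, so that padding (and truncation) fall
#' on the side distal to the CDS: use `"right"` for upstream regions
#' (promoter, 5'UTR) and `"left"` for downstream regions (3'UTR,
#' terminator).
#'
#' @param seq character; DNA over A/C/G/T/N.
#' @param targetLen integer target width in bp.
#' @param align `"right"` or `"left"`.
#' @return 4 x `targetLen` binary matrix with rownames A/C/G/T.
#' @examples
#' oneHotEncode("ACGT", 4)
#' oneHotEncode("AC", 4, align = "right")  # two zero columns on the left
#' @export
oneHotEncode <- function(seq, targetLen, align = c("right", "left")) {
  align <- match.arg(align)
  stopifnot(is.character(seq), length(seq) == 1L, targetLen >= 1)
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% c(BASES, "N"))
  if (length(bad))
    stop(sprintf("invalid character '%s' at offset %d", ch[bad[1]], bad[1]))
  if (length(ch) > targetLen) {
    # keep the CDS-proximal side of over-long sequences
    ch <- if (align == "right") ch[(length(ch) - targetLen + 1):length(ch)]
          else ch[seq_len(targetLen)]
  }
  m <- matrix(0, 4L, targetLen, dimnames = list(BASES, NULL))
  if (length(ch)) {
    pos <- if (align == "right") (targetLen - length(ch) + 1):targetLen
           else seq_along(ch)
    hit <- match(ch, BASES)
    keep <- !is.na(hit)
    m[cbind(hit[keep], pos[keep])] <- 1
  }
  m
}

#' Decode a one-hot matrix back to a sequence
#'
#' Inverse of [oneHotEncode()] on unpadded sequences; all-zero columns
#' decode to `N`.
#'
#' @param m 4 x L binary matrix, rows A/C/G/T.
#' @return character DNA sequence of length `ncol(m)`.
#' @export
decodeOneHot <- function(m) {
  stopifnot(nrow(m) == 4L)
  idx <- max.col(t(m), ties.method = "first")
  out <- BASES[idx]
  out[colSums(m) == 0] <- "N"
  paste(out, collapse = "")
}

#' Codon probabilities of a coding sequence
#'
#' Counts non-overlapping codons of a CDS and normalises the counts to
#' probabilities over the 64 codons in lexicographic order (AAA..TTT).
#' Codons containing `N` are skipped.
#'
#' @param cds character; length divisible by 3.
#' @return named numeric vector of length 64 summing to 1.
#' @examples
#' codonProbs("ATGTAA")  # 0.5 ATG, 0.5 TAA
#' @export
codonProbs <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3")
  cod <- substring(toupper(cds), seq(1, n, 3), seq(3, n, 3))
  cod <- cod[!grepl("N", cod, fixed = TRUE)]
  if (!length(cod)) stop("no countable codons (all contain N)")
  bad <- which(!cod %in% CODONS)
  if (length(bad))
    stop(sprintf("invalid codon '%s'", cod[bad[1]]))
  tab <- table(factor(cod, levels = CODONS))
  out <- as.numeric(tab) / length(cod)
  names(out) <- CODONS
  out
}

#' mRNA stability covariates
#'
#' The 8 numeric covariates used alongside sequence and codon features:
#' lengths of the 5'UTR, ORF and 3'UTR (bp), GC fraction of the 5'- and
#' 3'UTR, and GC fraction at each of the three codon positions of the ORF.
#' GC is computed over non-N positions; an empty UTR yields GC 0 and is
#' recorded in the `"flags"` attribute.
#'
#' @param utr5,cds,utr3 character DNA sequences.
#' @return named numeric vector of length 8, attribute `"flags"`.
#' @export
stabilityVars <- function(utr5, cds, utr3) {
  gc <- function(s) {
    if (!nchar(s)) return(c(0, TRUE))
    ch <- strsplit(toupper(s), "")[[1]]
    nn <- sum(ch != "N")
    if (!nn) return(c(0, TRUE))
    c(sum(ch %in% c("G", "C")) / nn, FALSE)
  }
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3")
  chc <- strsplit(toupper(cds), "")[[1]]
  pos <- rep(1:3, length.out = n)
  gcp <- vapply(1:3, function(p) {
    sel <- chc[pos == p]
    sel <- sel[sel != "N"]
    if (!length(sel)) 0 else sum(sel %in% c("G", "C")) / length(sel)
  }, 0)
  g5 <- gc(utr5); g3 <- gc(utr3)
  out <- c(len_utr5 = nchar(utr5), len_orf = n, len_utr3 = nchar(utr3),
           gc_utr5 = g5[1], gc_utr3 = g3[1],
           gc_codon1 = gcp[1], gc_codon2 = gcp[2], gc_codon3 = gcp[3])
  attr(out, "flags") <- c(empty_utr5 = as.logical(g5[2]),
                          empty_utr3 = as.logical(g3[2]))
  out
}

#' k-mer count features for shallow baselines
#'
#' Overlapping k-mer counts per region, concatenated across regions with
#' region-tagged column names.
#'
#' @param seqs named list of character vectors (one per region, equal gene
#'   counts) or a single character vector (treated as one region).
#' @param k integer vector of k-mer sizes (default 4:6).
#' @return genes x k-mer count matrix.
#' @export
kmerFeatures <- function(seqs, k = 4:6) {
  stopifnot(all(k >= 1))
  if (!is.list(seqs)) seqs <- list(seq = seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("region", seq_along(seqs))
  blocks <- lapply(names(seqs), function(rn) {
    ss <- DNAStringSet(seqs[[rn]])
    sub <- lapply(k, function(kk) {
      if (any(width(ss) < kk))
        warning(sprintf("k=%d exceeds some %s sequence lengths; zero rows",
                        kk, rn))
      m <- oligonucleotideFrequency(ss, width = kk)
      colnames(m) <- paste(rn, colnames(m), sep = "_")
      m
    })
    do.call(cbind, sub)
  })
  do.call(cbind, blocks)
}

#' Region length presets
#'
#' `"scaled"` is the compact default used throughout the synthetic
#' analyses (promoter/5'UTR/3'UTR/terminator = 200/50/50/100 bp);
#' `"full"` sums to the 2150 bp of regulatory sequence used for the
#' full-scale model (1000/300/350/500); `"constricted"` is the short-input
#' preset (400/100/250/250).
#'
#' @param preset one of `"scaled"`, `"full"`, `"constricted"`.
#' @return named integer vector of region lengths (bp).
#' @export
regionPreset <- function(preset = c("scaled", "full", "constricted")) {
  switch(match.arg(preset),
    scaled      = c(promoter = 200L, utr5 = 50L,  utr3 = 50L,  terminator = 100L),
    full        = c(promoter = 1000L, utr5 = 300L, utr3 = 350L, terminator = 500L),
    constricted = c(promoter = 400L, utr5 = 100L, utr3 = 250L, terminator = 250L))
}

REGULATORY_REGIONS <- c("promoter", "utr5", "utr3", "terminator")

#' Assemble model inputs for a cohort
#'
#' Builds the full feature bundle: concatenated one-hot region tensors
#' (promoter, 5'UTR, 3'UTR, terminator, in gene order; upstream regions are
#' right-aligned, downstream left-aligned so padding falls distal to the
#' CDS), the 64 codon probabilities and the 8 stability covariates.
#'
#' @param cohort a [SyntheticCohort-class], or a named list with elements
#'   `promoter`, `utr5`, `cds`, `utr3`, `terminator` (character vectors).
#' @param regionLengths named integer vector as from [regionPreset()].
#' @return list with `seq` (array n x 4 x L_total), `num` (n x 72 matrix),
#'   `regions` (list of column index ranges per region), `geneIds`.
#' @export
cohortFeatures <- function(cohort, regionLengths = regionPreset("scaled")) {
  if (is(cohort, "SyntheticCohort")) {
    seqs <- lapply(cohort@regions, as.character)
    ids <- geneIds(cohort)
  } else {
    seqs <- cohort
    ids <- names(seqs$promoter)
    if (is.null(ids)) ids <- paste0("g", seq_along(seqs$promoter))
  }
  n <- length(seqs$promoter)
  Ltot <- sum(regionLengths[REGULATORY_REGIONS])
  X <- array(0, dim = c(n, 4L, Ltot))
  bounds <- list()
  off <- 0L
  for (r in REGULATORY_REGIONS) {
    L <- regionLengths[[r]]
    al <- if (r %in% c("promoter", "utr5")) "right" else "left"
    for (i in seq_len(n))
      X[i, , (off + 1L):(off + L)] <- oneHotEncode(seqs[[r]][i], L, align = al)
    bounds[[r]] <- c(start = off + 1L, end = off + L)
    off <- off + L
  }
  num <- t(vapply(seq_len(n), function(i) {
    c(codonProbs(seqs$cds[i]),
      as.numeric(stabilityVars(seqs$utr5[i], seqs$cds[i], seqs$utr3[i])))
  }, numeric(72L)))
  colnames(num) <- c(CODONS, "len_utr5", "len_orf", "len_utr3",
                     "gc_utr5", "gc_utr3", "gc_codon1", "gc_codon2",
                     "gc_codon3")
  rownames(num) <- ids
  list(seq = X, num = num, regions = bounds, geneIds = ids,
       regionLengths = regionLengths)
}
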