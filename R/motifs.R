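#' Extract significant relevance windows
#'
#' Maximal runs of significant positions are cut into window-size
#' sequences: runs of at least the window size are tiled left to right
#' with a final right-aligned window; shorter runs are centred and
#' extended to the window size within region bounds.
#'
#' @param profiles a [RelevanceProfileSet-class] with masks (see
#'   [significantPositions()]).
#' @param cohort the [SyntheticCohort-class] (or a named list of
#'   character vectors per region) supplying the sequences.
#' @param window window size (bp); defaults to the profile window.
#' @return `DataFrame` of windows: gene_id, region, offset (1-based),
#'   sequence, relevance (mean over the window).
#' @export
extractWindows <- function(profiles, cohort, window = NULL) {
  if (is.null(window)) window <- profiles@window
  stopifnot(window >= 1)
  seqs <- if (is(cohort, "SyntheticCohort"))
    lapply(cohort@regions, as.character) else cohort
  out <- list()
  for (r in names(profiles@mask)) {
    msk <- profiles@mask[[r]]
    if (!length(msk)) next
    V <- profiles@values[[r]]
    L <- ncol(msk)
    regSeqs <- seqs[[r]][profiles@geneIds]
    for (i in seq_len(nrow(msk))) {
      rl <- rle(msk[i, ])
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      gseq <- regSeqs[i]
      gl <- nchar(gseq)
      for (j in which(rl$values)) {
        rs <- starts[j]; re <- ends[j]
        len <- re - rs + 1L
        if (len >= window) {
          offs <- seq.int(rs, re - window + 1L, by = window)
          if (offs[length(offs)] + window - 1L < re)
            offs <- c(offs, re - window + 1L)
        } else {
          ctr <- floor((rs + re) / 2)
          off <- ctr - floor(window / 2) + 1L
          off <- max(1L, min(off, L - window + 1L))
          offs <- off
        }
        for (off in offs) {
          if (off + window - 1L > gl) next  # shorter real sequence
          sq <- substr(gseq, off, off + window - 1L)
          if (grepl("[^ACGT]", sq)) next
          out[[length(out) + 1L]] <- list(
            gene_id = profiles@geneIds[i], region = r, offset = off,
            sequence = sq,
            relevance = mean(V[i, off:(off + window - 1L)]))
        }
      }
    }
  }
  if (!length(out))
    return(S4Vectors::DataFrame(gene_id = character(0),
                                region = character(0),
                                offset = integer(0),
                                sequence = character(0),
                                relevance = numeric(0)))
  S4Vectors::DataFrame(
    gene_id = vapply(out, `[[`, "", "gene_id"),
    region = vapply(out, `[[`, "", "region"),
    offset = vapply(out, function(x) as.integer(x$offset), 0L),
    sequence = vapply(out, `[[`, "", "sequence"),
    relevance = vapply(out, `[[`, 0, "relevance"))
}

seqToInt <- function(s) match(strsplit(s, "")[[1]], BASES)

# identity of b against representative a at the best ungapped offset in
# -maxShift..maxShift; matches are counted over the overlap but divided
# by the full window length
bestIdentity <- function(aInt, bInt, maxShift = 2L) {
  w <- length(aInt)
  best <- c(id = -1, shift = 0L)
  for (s in (-maxShift):maxShift) {
    ar <- max(1L, 1L + s):min(w, w + s)
    br <- ar - s
    m <- sum(aInt[ar] == bInt[br]) / w
    if (m > best["id"]) best <- c(id = m, shift = s)
  }
  best
}

#' Greedy identity clustering of relevance windows
#'
#' CD-HIT-like incremental scheme: windows are sorted by mean relevance
#' (descending; ties broken by sequence), each window joins the first
#' cluster whose representative matches at or above the identity cutoff
#' under the best ungapped offset (max shift +/- 2 bp), otherwise it
#' founds a new cluster. Clusters below `minCluster` members are
#' discarded.
#'
#' @param windows `DataFrame` from [extractWindows()].
#' @param identityCutoff fraction of matching positions (0.8, 0.85 or
#'   0.9 in the standard settings).
#' @param minCluster minimum cluster size (default 5).
#' @param maxShift maximum alignment shift (bp).
#' @param perRegion cluster windows within each region separately.
#' @return list of clusters; each has `representative`, `members`
#'   (row indices into `windows`), `shifts`, `region`.
#' @export
identityCluster <- function(windows, identityCutoff = 0.8, minCluster = 5,
                            maxShift = 2L, perRegion = TRUE) {
  if (!nrow(windows)) return(list())
  wlen <- nchar(windows$sequence)
  if (length(unique(wlen)) != 1) stop("mixed window lengths")
  groups <- if (perRegion) split(seq_len(nrow(windows)), windows$region)
            else list(all = seq_len(nrow(windows)))
  clusters <- list()
  for (g in groups) {
    ord <- g[order(-windows$relevance[g], windows$sequence[g])]
    ints <- lapply(windows$sequence[ord], seqToInt)
    reps <- list()   # integer vectors of representatives
    mem <- list()
    shf <- list()
    for (i in seq_along(ord)) {
      placed <- FALSE
      for (ci in seq_along(reps)) {
        bi <- bestIdentity(reps[[ci]], ints[[i]], maxShift)
        if (bi["id"] >= identityCutoff) {
          mem[[ci]] <- c(mem[[ci]], ord[i])
          shf[[ci]] <- c(shf[[ci]], bi["shift"])
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        reps[[length(reps) + 1L]] <- ints[[i]]
        mem[[length(mem) + 1L]] <- ord[i]
        shf[[length(shf) + 1L]] <- 0L
      }
    }
    for (ci in seq_along(mem)) {
      if (length(mem[[ci]]) < minCluster) next
      clusters[[length(clusters) + 1L]] <- list(
        representative = paste(BASES[reps[[ci]]], collapse = ""),
        members = mem[[ci]], shifts = as.integer(shf[[ci]]),
        region = windows$region[mem[[ci]][1]])
    }
  }
  clusters
}

icBits <- function(p) 2 + colSums(ifelse(p > 0, p * log2(p), 0))

#' Build a trimmed PWM from a window cluster
#'
#' Aligns member windows at their chosen shifts, counts bases per column
#' with a 0.25 pseudocount per base (columns are normalised over the
#' members covering them), computes per-column information content
#' against a uniform background, and trims terminal columns below 0.2
#' bits.
#'
#' @param cluster one cluster from [identityCluster()].
#' @param windows the window `DataFrame` the cluster indexes into.
#' @param id motif identifier.
#' @param trimBits edge-trimming cutoff (bits).
#' @return motif list (`id`, `region`, `pwm`, `ic`, `members`) or `NULL`
#'   if trimming consumes all columns.
#' @export
buildPWM <- function(cluster, windows, id = "motif", trimBits = 0.2) {
  w <- nchar(windows$sequence[cluster$members[1]])
  sh <- cluster$shifts
  lo <- min(sh); hi <- max(sh)
  width <- w + (hi - lo)
  counts <- matrix(0, 4, width, dimnames = list(BASES, NULL))
  cover <- numeric(width)
  for (i in seq_along(cluster$members)) {
    ints <- seqToInt(windows$sequence[cluster$members[i]])
    off <- sh[i] - lo     # shift s places member at columns (s-lo)+1..
    cols <- (off + 1L):(off + w)
    counts[cbind(ints, cols)] <- counts[cbind(ints, cols)] + 1
    cover[cols] <- cover[cols] + 1
  }
  p <- sweep(counts + 0.25, 2, cover + 1, "/")
  ic <- icBits(p)
  keep <- seq_len(width)
  while (length(keep) && ic[keep[1]] < trimBits) keep <- keep[-1]
  while (length(keep) && ic[keep[length(keep)]] < trimBits)
    keep <- keep[-length(keep)]
  if (!length(keep)) {
    message(sprintf("motif %s fully trimmed; discarded", id))
    return(NULL)
  }
  members <- S4Vectors::DataFrame(
    gene_id = windows$gene_id[cluster$members],
    region = windows$region[cluster$members],
    offset = windows$offset[cluster$members],
    sequence = windows$sequence[cluster$members],
    relevance = windows$relevance[cluster$members],
    shift = cluster$shifts)
  list(id = id, region = cluster$region,
       pwm = p[, keep, drop = FALSE], ic = ic[keep], members = members)
}

#' Discover motifs from significant relevance windows
#'
#' Runs [identityCluster()] and [buildPWM()] over all windows and wraps
#' the result in a [MotifSet-class].
#'
#' @inheritParams identityCluster
#' @inheritParams buildPWM
#' @return a [MotifSet-class].
#' @export
discoverMotifs <- function(windows, identityCutoff = 0.8, minCluster = 5,
                           maxShift = 2L, trimBits = 0.2) {
  cl <- identityCluster(windows, identityCutoff, minCluster, maxShift)
  motifs <- list()
  for (i in seq_along(cl)) {
    m <- buildPWM(cl[[i]], windows, id = sprintf("D%03d", i),
                  trimBits = trimBits)
    if (!is.null(m)) motifs[[m$id]] <- m
  }
  new("MotifSet", motifs = motifs,
      windowSize = as.integer(nchar(windows$sequence[1])),
      identityCutoff = identityCutoff)
}

# per-column Pearson correlation of two 4 x k probability matrices,
# vectorised across columns; zero-variance columns score 0
pwmColCor <- function(a, b) {
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colSums(a^2) - 4 * ma^2
  vb <- colSums(b^2) - 4 * mb^2
  cv <- colSums(a * b) - 4 * ma * mb
  out <- numeric(ncol(a))
  ok <- va > 1e-300 & vb > 1e-300
  out[ok] <- cv[ok] / sqrt(va[ok] * vb[ok])
  out
}

pwmAlignScore <- function(pa, pb, minOverlap = 4L, shiftSlack = 2L) {
  wa <- ncol(pa); wb <- ncol(pb)
  ## offsets are restricted to near-full overlaps (within shiftSlack of
  ## the shorter motif's width, floored at minOverlap): permitting very
  ## short overlaps lets the permutation null ride lucky 4-column
  ## alignments and drowns genuine full-width matches
  minO <- max(minOverlap, min(wa, wb) - shiftSlack)
  best <- -Inf
  for (s in -(wb - minO):(wa - minO)) {
    ar <- max(1L, 1L + s):min(wa, wb + s)
    br <- ar - s
    if (length(ar) < minO) next
    best <- max(best, mean(pwmColCor(pa[, ar, drop = FALSE],
                                     pb[, br, drop = FALSE])))
  }
  best
}

#' Compare two PWMs
#'
#' Similarity = maximum over ungapped offsets (overlap >= `minOverlap`
#' columns) of the mean per-column Pearson correlation between the
#' probability columns. The p-value comes from a null of column-shuffled
#' copies of the second motif; apply Benjamini-Hochberg over all
#' comparisons downstream.
#'
#' @param a,b motifs (as in [MotifSet-class] elements) or bare 4 x w
#'   probability matrices.
#' @param nPermutations shuffles for the null.
#' @param minOverlap minimum aligned columns.
#' @param seed integer.
#' @return list with `score` and `p_value`.
#' @export
comparePWMs <- function(a, b, nPermutations = 500, minOverlap = 4L,
                        shiftSlack = 2L, seed = 1L) {
  pa <- if (is.list(a)) a$pwm else a
  pb <- if (is.list(b)) b$pwm else b
  if (min(ncol(pa), ncol(pb)) < minOverlap)
    stop("overlap impossible: motif shorter than minOverlap")
  obs <- pwmAlignScore(pa, pb, minOverlap, shiftSlack)
  set.seed(seed)
  ge <- 0L
  for (i in seq_len(nPermutations)) {
    perm <- pb[, sample.int(ncol(pb)), drop = FALSE]
    if (pwmAlignScore(pa, perm, minOverlap, shiftSlack) >= obs - 1e-12)
      ge <- ge + 1L
  }
  list(score = obs, p_value = (1 + ge) / (nPermutations + 1))
}

#' Gene x motif occurrence matrix
#'
#' A gene carries a motif iff at least one member window of the motif
#' originates from that gene (boolean semantics). A PWM-rescanning mode
#' (`mode = "scan"`) is available for sensitivity analysis: genes whose
#' region sequence contains a window scoring at least `scanFraction` of
#' the maximal log-odds score count as carriers.
#'
#' @param motifSet a [MotifSet-class].
#' @param geneIds character vector fixing row order.
#' @param mode `"members"` (default) or `"scan"`.
#' @param cohort required for `"scan"`.
#' @param scanFraction fraction of the maximum score.
#' @return logical genes x motifs matrix; attribute `"regions"` maps
#'   motif id to region.
#' @export
occurrenceMatrix <- function(motifSet, geneIds,
                             mode = c("members", "scan"), cohort = NULL,
                             scanFraction = 0.8) {
  mode <- match.arg(mode)
  motifs <- motifSet@motifs
  mids <- vapply(motifs, `[[`, "", "id")
  occ <- matrix(FALSE, length(geneIds), length(motifs),
                dimnames = list(geneIds, mids))
  if (mode == "members") {
    for (m in motifs)
      occ[unique(m$members$gene_id[m$members$gene_id %in% geneIds]),
          m$id] <- TRUE
  } else {
    stopifnot(!is.null(cohort))
    for (m in motifs) {
      lo <- pwmLogOdds(m$pwm)
      thr <- scanFraction * sum(apply(lo, 2, max))
      seqs <- as.character(cohort@regions[[m$region]][geneIds])
      hits <- vapply(seqs, function(s) scanMax(s, lo) >= thr, TRUE)
      occ[hits, m$id] <- TRUE
    }
  }
  attr(occ, "regions") <- vapply(motifs, `[[`, "", "region")
  occ
}

scanMax <- function(seq, lo) {
  ints <- seqToInt(seq)
  w <- ncol(lo)
  L <- length(ints)
  if (L < w) return(-Inf)
  best <- -Inf
  for (s in 1:(L - w + 1)) {
    idx <- ints[s:(s + w - 1)]
    if (anyNA(idx)) next
    best <- max(best, sum(lo[cbind(idx, seq_len(w))]))
  }
  best
}

#' Match discovered motifs against a reference set
#'
#' All-vs-all [comparePWMs()] within matching regions (or globally),
#' Benjamini-Hochberg correction over every comparison, and per-reference
#' recovery (a reference motif is recovered if any discovered motif
#' matches at q < alpha).
#'
#' @param discovered a [MotifSet-class].
#' @param reference list of motifs (e.g. `grammarTruth(cohort)@motifs`).
#' @param alpha FDR level.
#' @param byRegion restrict comparisons to same-region pairs.
#' @param nPermutations permutations per comparison.
#' @return list with `matches` (data.frame), `recovered` (named logical
#'   per reference motif), `recovery` (fraction).
#' @export
motifRecovery <- function(discovered, reference, alpha = 0.05,
                          byRegion = TRUE, nPermutations = 1000) {
  rows <- list()
  for (ref in reference) {
    for (d in discovered@motifs) {
      if (byRegion && !is.null(ref$region) && d$region != ref$region)
        next
      cmp <- comparePWMs(ref, d, nPermutations = nPermutations)
      rows[[length(rows) + 1L]] <- data.frame(
        reference = ref$id, discovered = d$id, score = cmp$score,
        p_value = cmp$p_value)
    }
  }
  if (!length(rows)) {
    rec <- stats::setNames(rep(FALSE, length(reference)),
                           vapply(reference, `[[`, "", "id"))
    return(list(matches = data.frame(), recovered = rec, recovery = 0))
  }
  tab <- do.call(rbind, rows)
  tab$q_value <- stats::p.adjust(tab$p_value, "BH")
  rec <- vapply(reference, function(ref)
    any(tab$q_value[tab$reference == ref$id] < alpha), TRUE)
  names(rec) <- vapply(reference, `[[`, "", "id")
  list(matches = tab, recovered = rec, recovery = mean(rec))
}
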