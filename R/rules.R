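## FP-growth over a boolean gene x motif occurrence matrix.
## Transactions are genes, items are motifs. The implementation follows
## the classic algorithm: items ordered by support, prefix tree with
## header links, recursive conditional-tree mining.

fpNode <- function(item, parent) {
  e <- new.env(parent = emptyenv())
  e$item <- item; e$count <- 0; e$parent <- parent
  e$children <- list()
  e
}

fpInsert <- function(root, items, count, header) {
  node <- root
  for (it in items) {
    child <- node$children[[it]]
    if (is.null(child)) {
      child <- fpNode(it, node)
      node$children[[it]] <- child
      header[[it]] <- c(header[[it]], child)
    }
    child$count <- child$count + count
    node <- child
  }
  header
}

fpMine <- function(transactions, counts, minCount, maxSize, suffix,
                   acc) {
  ## transactions: list of character vectors (already support-ordered)
  supp <- list()
  for (i in seq_along(transactions))
    for (it in transactions[[i]])
      supp[[it]] <- (supp[[it]] %||% 0) + counts[i]
  supp <- unlist(supp)
  supp <- supp[supp >= minCount]
  if (!length(supp)) return(acc)
  ord <- names(sort(supp, decreasing = TRUE))
  ordRank <- stats::setNames(seq_along(ord), ord)
  header <- stats::setNames(vector("list", length(ord)), ord)
  root <- fpNode(NA_character_, NULL)
  for (i in seq_along(transactions)) {
    its <- transactions[[i]]
    its <- its[its %in% ord]
    if (!length(its)) next
    its <- its[order(ordRank[its])]
    header <- fpInsert(root, its, counts[i], header)
  }
  for (it in rev(ord)) {
    newSuffix <- c(it, suffix)
    acc[[paste(sort(newSuffix), collapse = "\r")]] <- supp[[it]]
    if (length(newSuffix) >= maxSize) next
    ## conditional pattern base
    condT <- list(); condC <- numeric(0)
    for (node in header[[it]]) {
      path <- character(0)
      p <- node$parent
      while (!is.null(p) && !is.na(p$item)) {
        path <- c(p$item, path)
        p <- p$parent
      }
      if (length(path)) {
        condT[[length(condT) + 1L]] <- path
        condC <- c(condC, node$count)
      }
    }
    if (length(condT))
      acc <- fpMine(condT, condC, minCount, maxSize, newSuffix, acc)
  }
  acc
}

#' Mine frequent motif itemsets with FP-growth
#'
#' All itemsets of size `2..maxSize` carried by at least `minGenes`
#' genes, found with the FP-growth algorithm (output is identical to
#' exhaustive enumeration; see [enumerateItemsets()]).
#'
#' @param occurrence logical genes x motifs matrix.
#' @param minGenes absolute support floor (default 3 genes).
#' @param maxSize largest itemset (default 6 motifs).
#' @return data.frame with `itemset` (motif ids joined by `+`), `size`,
#'   `support` (gene count).
#' @export
mineItemsets <- function(occurrence, minGenes = 3, maxSize = 6) {
  if (!length(occurrence) || !any(occurrence))
    return(data.frame(itemset = character(0), size = integer(0),
                      support = integer(0)))
  items <- colnames(occurrence)
  if (is.null(items)) items <- paste0("m", seq_len(ncol(occurrence)))
  trans <- apply(occurrence, 1, function(r) items[r], simplify = FALSE)
  trans <- trans[lengths(trans) > 0]
  acc <- fpMine(trans, rep(1, length(trans)), minGenes, maxSize,
                character(0), list())
  if (!length(acc))
    return(data.frame(itemset = character(0), size = integer(0),
                      support = integer(0)))
  keys <- names(acc)
  sizes <- lengths(strsplit(keys, "\r", fixed = TRUE))
  keep <- sizes >= 2
  out <- data.frame(itemset = gsub("\r", "+", keys[keep], fixed = TRUE),
                    size = sizes[keep],
                    support = as.integer(unlist(acc[keep])))
  out[order(-out$support, out$itemset), , drop = FALSE]
}

#' Exhaustive itemset enumeration (reference implementation)
#'
#' Dense brute-force enumeration of all itemsets of size `2..maxSize`
#' with support >= `minGenes`; the independent cross-check for
#' [mineItemsets()].
#'
#' @inheritParams mineItemsets
#' @return data.frame as [mineItemsets()].
#' @export
enumerateItemsets <- function(occurrence, minGenes = 3, maxSize = 6) {
  items <- colnames(occurrence)
  if (is.null(items)) items <- paste0("m", seq_len(ncol(occurrence)))
  res <- list()
  grow <- function(idxSet, rows) {
    supp <- sum(rows)
    if (supp < minGenes) return()
    if (length(idxSet) >= 2)
      res[[paste(items[idxSet], collapse = "+")]] <<-
        c(length(idxSet), supp)
    if (length(idxSet) >= maxSize) return()
    last <- if (length(idxSet)) max(idxSet) else 0L
    for (j in seq_len(ncol(occurrence))) {
      if (j <= last) next
      grow(c(idxSet, j), rows & occurrence[, j])
    }
  }
  grow(integer(0), rep(TRUE, nrow(occurrence)))
  if (!length(res))
    return(data.frame(itemset = character(0), size = integer(0),
                      support = integer(0)))
  keys <- names(res)
  out <- data.frame(
    itemset = vapply(strsplit(keys, "+", fixed = TRUE),
                     function(x) paste(sort(x), collapse = "+"), ""),
    size = vapply(res, `[`, 0, 1),
    support = as.integer(vapply(res, `[`, 0, 2)))
  rownames(out) <- NULL
  out[order(-out$support, out$itemset), , drop = FALSE]
}

#' Closed-form chi-squared for a 2x2 table
#'
#' `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, without continuity
#' correction; 1 degree of freedom.
#'
#' @param a,b,c,d cell counts.
#' @return list with `statistic` and `p_value`.
#' @export
chiSquared2x2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) return(list(statistic = NA_real_, p_value = NA_real_))
  stat <- N * (a * d - b * c)^2 / denom
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Score a motif itemset as a candidate regulatory rule
#'
#' Support, confidence (full-set support over the support of the set
#' minus its lexicographically last motif; other splits via
#' `antecedent`), lift (observed over independence-expected support
#' fraction), chi-squared significance (presence x presence 2x2 table
#' for pairs; observed vs independence-expected full-set count, 1 df,
#' for larger sets) and expression statistics (mean, sample SD and
#' SNR = mu/sigma of carrier-gene median TPM).
#'
#' @param itemset character vector of motif ids.
#' @param occurrence logical genes x motifs matrix.
#' @param medianTpm named per-gene median TPM.
#' @param antecedent optional motif subset defining the confidence split.
#' @return one-row data.frame.
#' @export
ruleStats <- function(itemset, occurrence, medianTpm = NULL,
                      antecedent = NULL) {
  stopifnot(all(itemset %in% colnames(occurrence)))
  n <- nrow(occurrence)
  carrier <- rowSums(occurrence[, itemset, drop = FALSE]) ==
    length(itemset)
  supp <- sum(carrier)
  fracs <- colMeans(occurrence[, itemset, drop = FALSE])
  if (is.null(antecedent))
    antecedent <- setdiff(itemset, sort(itemset)[length(itemset)])
  antCarrier <- rowSums(occurrence[, antecedent, drop = FALSE]) ==
    length(antecedent)
  confidence <- if (sum(antCarrier) == 0) NA_real_
                else supp / sum(antCarrier)
  expFrac <- prod(fracs)
  lift <- if (expFrac == 0) NA_real_ else (supp / n) / expFrac
  flaggedChi <- any(fracs %in% c(0, 1))
  if (length(itemset) == 2 && !flaggedChi) {
    A <- occurrence[, itemset[1]]; B <- occurrence[, itemset[2]]
    chi <- chiSquared2x2(sum(A & B), sum(A & !B), sum(!A & B),
                         sum(!A & !B))
  } else if (!flaggedChi) {
    expected <- n * expFrac
    stat <- (supp - expected)^2 * (1 / expected + 1 / (n - expected))
    chi <- list(statistic = stat,
                p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
  } else chi <- list(statistic = NA_real_, p_value = NA_real_)
  mu <- sdv <- snr <- NA_real_
  snrInf <- FALSE
  if (!is.null(medianTpm) && supp > 0) {
    vals <- medianTpm[rownames(occurrence)[carrier]]
    mu <- mean(vals)
    sdv <- if (supp > 1) stats::sd(vals) else NA_real_
    if (!is.na(sdv)) {
      if (sdv == 0) { snr <- Inf; snrInf <- TRUE } else snr <- mu / sdv
    }
  }
  regions <- attr(occurrence, "regions")
  spanned <- if (!is.null(regions))
    length(unique(regions[itemset])) else NA_integer_
  data.frame(itemset = paste(sort(itemset), collapse = "+"),
             size = length(itemset), support = supp,
             support_frac = supp / n, confidence = confidence,
             lift = lift, chi2 = chi$statistic, p_value = chi$p_value,
             mean_tpm = mu, sd_tpm = sdv, snr = snr,
             snr_infinite = snrInf, regions_spanned = spanned,
             cross_region = !is.na(spanned) && spanned >= 2)
}

#' Mine and score all candidate rules
#'
#' [mineItemsets()] followed by [ruleStats()] for every frequent
#' itemset.
#'
#' @inheritParams mineItemsets
#' @param medianTpm named per-gene median TPM.
#' @return data.frame of scored rules.
#' @export
mineRules <- function(occurrence, medianTpm = NULL, minGenes = 3,
                      maxSize = 6) {
  its <- mineItemsets(occurrence, minGenes, maxSize)
  if (!nrow(its)) return(its)
  rows <- lapply(strsplit(its$itemset, "+", fixed = TRUE), ruleStats,
                 occurrence = occurrence, medianTpm = medianTpm)
  do.call(rbind, rows)
}

#' Significant rules after FDR control
#'
#' Benjamini-Hochberg across all tested itemsets; keeps rules with
#' q < `alpha` carried by at least `minGenes` genes, and reports genome
#' coverage (fraction of genes carrying at least one significant rule).
#'
#' @param rules data.frame from [mineRules()].
#' @param occurrence the occurrence matrix used to mine them.
#' @param alpha FDR level.
#' @param minGenes minimum carrier genes.
#' @return list with `rules` (filtered, with `q_value`), `coverage`.
#' @export
significantRules <- function(rules, occurrence, alpha = 0.05,
                             minGenes = 3) {
  if (!nrow(rules))
    return(list(rules = rules, coverage = 0))
  rules$q_value <- stats::p.adjust(rules$p_value, "BH")
  keep <- !is.na(rules$q_value) & rules$q_value < alpha &
    rules$support >= minGenes
  sig <- rules[keep, , drop = FALSE]
  covered <- rep(FALSE, nrow(occurrence))
  for (s in strsplit(sig$itemset, "+", fixed = TRUE))
    covered <- covered |
      (rowSums(occurrence[, s, drop = FALSE]) == length(s))
  list(rules = sig, coverage = mean(covered))
}

itemSNR <- function(vals) {
  mu <- mean(vals)
  sdv <- if (length(vals) > 1) stats::sd(vals) else NA_real_
  if (is.na(sdv)) return(NA_real_)
  if (sdv == 0) return(Inf)
  mu / sdv
}

#' Expression specificity: single motifs versus rules
#'
#' Per item (motif or rule), the carrier-gene expression mean, SD and
#' SNR; aggregates report the fraction of items with SNR > 1 and the
#' recovered expression range — the log10 span of per-item carrier
#' means over the log10 span of all gene medians.
#'
#' @param occurrence gene x motif matrix.
#' @param rules data.frame of (significant) rules.
#' @param medianTpm named per-gene median TPM.
#' @return list with `motifs`, `rules` (per-item tables) and
#'   `aggregate`.
#' @export
specificityContrast <- function(occurrence, rules, medianTpm) {
  geneSpan <- log10(max(medianTpm) / min(medianTpm))
  perMotif <- do.call(rbind, lapply(colnames(occurrence), function(m) {
    vals <- medianTpm[rownames(occurrence)[occurrence[, m]]]
    if (!length(vals)) return(NULL)
    data.frame(item = m, n = length(vals), mean_tpm = mean(vals),
               snr = itemSNR(vals))
  }))
  perRule <- data.frame(item = rules$itemset, n = rules$support,
                        mean_tpm = rules$mean_tpm, snr = rules$snr)
  range01 <- function(tab) {
    if (is.null(tab) || nrow(tab) < 2) return(NA_real_)
    log10(max(tab$mean_tpm) / min(tab$mean_tpm)) / geneSpan
  }
  list(motifs = perMotif, rules = perRule,
       aggregate = data.frame(
         class = c("motif", "rule"),
         n = c(NROW(perMotif), nrow(perRule)),
         frac_snr_gt1 = c(mean(perMotif$snr > 1, na.rm = TRUE),
                          mean(perRule$snr > 1, na.rm = TRUE)),
         median_snr = c(stats::median(perMotif$snr[
                          is.finite(perMotif$snr)], na.rm = TRUE),
                        stats::median(perRule$snr[is.finite(perRule$snr)],
                                      na.rm = TRUE)),
         recovered_range = c(range01(perMotif), range01(perRule))))
}

#' Motif repurposing across rule groups
#'
#' `common_motif`: groups of rules (>= 3 motifs each) sharing one motif;
#' `single_substitution`: groups of equal-size rules identical except
#' one motif. Each group's fold range is max/min of the rules' carrier
#' mean TPM; reports the fraction of groups exceeding 10x.
#'
#' @param rules data.frame of rules (with `mean_tpm`).
#' @param mode `"common_motif"` or `"single_substitution"`.
#' @return list with `groups` (data.frame) and `frac_over_10x`.
#' @export
repurposingGroups <- function(rules,
                              mode = c("common_motif",
                                       "single_substitution")) {
  mode <- match.arg(mode)
  sets <- strsplit(rules$itemset, "+", fixed = TRUE)
  groupRows <- list()
  if (mode == "common_motif") {
    use <- which(lengths(sets) >= 3)
    motifs <- unique(unlist(sets[use]))
    for (m in motifs) {
      idx <- use[vapply(sets[use], function(s) m %in% s, TRUE)]
      if (length(idx) < 2) next
      vals <- rules$mean_tpm[idx]
      groupRows[[m]] <- data.frame(
        key = m, n_rules = length(idx),
        fold_range = max(vals) / min(vals))
    }
  } else {
    keys <- list()
    for (i in seq_along(sets)) {
      s <- sets[[i]]
      for (drop in seq_along(s)) {
        key <- paste(length(s), paste(s[-drop], collapse = "+"),
                     sep = ":")
        keys[[key]] <- c(keys[[key]], i)
      }
    }
    for (key in names(keys)) {
      idx <- unique(keys[[key]])
      if (length(idx) < 2) next
      vals <- rules$mean_tpm[idx]
      groupRows[[key]] <- data.frame(
        key = key, n_rules = length(idx),
        fold_range = max(vals) / min(vals))
    }
  }
  groups <- if (length(groupRows)) do.call(rbind, groupRows)
            else data.frame(key = character(0), n_rules = integer(0),
                            fold_range = numeric(0))
  rownames(groups) <- NULL
  list(groups = groups,
       frac_over_10x = if (nrow(groups)) mean(groups$fold_range > 10)
                       else NA_real_)
}

#' Codon-usage specificity of motifs and rules
#'
#' Per item, the median pairwise Euclidean distance among carrier-gene
#' codon probability vectors; the contrast reports the range and
#' variance of these medians for rules versus single motifs.
#'
#' @param occurrence gene x motif matrix.
#' @param rules data.frame of rules.
#' @param codonMat genes x 64 codon probability matrix (rownames =
#'   gene ids).
#' @return list with `motifs`, `rules`, `contrast`.
#' @export
codonSpecificity <- function(occurrence, rules, codonMat) {
  medDist <- function(genes) {
    genes <- intersect(genes, rownames(codonMat))
    if (length(genes) < 2) return(NA_real_)
    stats::median(stats::dist(codonMat[genes, , drop = FALSE]))
  }
  perMotif <- vapply(colnames(occurrence), function(m)
    medDist(rownames(occurrence)[occurrence[, m]]), 0)
  sets <- strsplit(rules$itemset, "+", fixed = TRUE)
  perRule <- vapply(sets, function(s) {
    carrier <- rowSums(occurrence[, s, drop = FALSE]) == length(s)
    medDist(rownames(occurrence)[carrier])
  }, 0)
  contrast <- data.frame(
    class = c("motif", "rule"),
    n = c(sum(!is.na(perMotif)), sum(!is.na(perRule))),
    range = c(diff(range(perMotif, na.rm = TRUE)),
              diff(range(perRule, na.rm = TRUE))),
    variance = c(stats::var(perMotif[!is.na(perMotif)]),
                 stats::var(perRule[!is.na(perRule)])))
  list(motifs = perMotif, rules = perRule, contrast = contrast)
}
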