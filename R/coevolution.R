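#' Mask low-confidence and gapped alignment columns
#'
#' Columns with confidence score <= `cutoff`, and columns containing gap
#' characters, are removed.
#'
#' @param aln list with `seqs` (character vector of equal-length aligned
#'   sequences) and `confidence` (per-column scores in [0, 1]).
#' @param cutoff confidence threshold (default 0.2; `<=` is removed).
#' @return the alignment with surviving columns only.
#' @export
maskColumns <- function(aln, cutoff = 0.2) {
  stopifnot(!is.null(aln$seqs), !is.null(aln$confidence))
  M <- do.call(rbind, strsplit(aln$seqs, ""))
  stopifnot(ncol(M) == length(aln$confidence))
  keep <- aln$confidence > cutoff & !apply(M == "-", 2, any)
  if (!any(keep)) stop("all alignment columns removed by masking")
  aln$seqs <- apply(M[, keep, drop = FALSE], 1, paste, collapse = "")
  names(aln$seqs) <- names(M[, 1])
  aln$confidence <- aln$confidence[keep]
  aln
}

#' JC69 substitution rate of an alignment
#'
#' p is the mean pairwise mismatch proportion over all sequence pairs;
#' the Jukes-Cantor correction `-(3/4) ln(1 - 4p/3)` converts it to
#' expected substitutions per site. Saturated alignments (p >= 0.75)
#' yield an infinite, flagged rate.
#'
#' @param aln list with `seqs` (>= 2 equal-length gap-free sequences).
#' @return list with `rate`, `p_mismatch`, `saturated`.
#' @export
substitutionRate <- function(aln) {
  seqs <- aln$seqs
  stopifnot(length(seqs) >= 2)
  L <- unique(nchar(seqs))
  stopifnot(length(L) == 1)
  if (L == 0) stop("zero alignment columns")
  M <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(M)
  mm <- 0; np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    mm <- mm + sum(M[i, ] != M[j, ])
    np <- np + 1
  }
  p <- mm / (np * L)
  if (p >= 0.75)
    return(list(rate = Inf, p_mismatch = p, saturated = TRUE))
  list(rate = -0.75 * log(1 - 4 * p / 3), p_mismatch = p,
       saturated = FALSE)
}

#' Per-region substitution rates for an ortholog set
#'
#' Applies [maskColumns()] and [substitutionRate()] to every gene and
#' region of a [generateOrthologs()] result (or compatible list).
#'
#' @param orthologs list of per-gene region alignment lists.
#' @param cutoff confidence masking threshold.
#' @return genes x regions matrix of rates (Inf where saturated).
#' @export
regionRates <- function(orthologs, cutoff = 0.2) {
  genes <- names(orthologs)
  regions <- names(orthologs[[1]])
  out <- matrix(NA_real_, length(genes), length(regions),
                dimnames = list(genes, regions))
  for (g in genes) for (r in regions) {
    a <- maskColumns(orthologs[[g]][[r]], cutoff)
    out[g, r] <- substitutionRate(a)$rate
  }
  out
}

#' Correlate substitution rates between two regions
#'
#' Pearson correlation across genes; genes with non-finite rates in
#' either region are excluded (count reported).
#'
#' @param rates genes x regions matrix (e.g. from [regionRates()]).
#' @param regionA,regionB column names.
#' @return list with `r`, `p_value`, `n`, `excluded`.
#' @export
correlateRegions <- function(rates, regionA, regionB) {
  a <- rates[, regionA]; b <- rates[, regionB]
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) stop("fewer than 3 genes with finite rates")
  ct <- stats::cor.test(a[ok], b[ok])
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok),
       excluded = sum(!ok))
}
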