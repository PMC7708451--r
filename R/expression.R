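#' TPM normalisation
#'
#' Converts raw counts to transcripts per million: per-gene reads per
#' kilobase rescaled so each experiment sums to 1e6.
#'
#' @param counts non-negative numeric vector (one experiment) or genes x
#'   experiments matrix.
#' @param orfLengths positive gene lengths in bp.
#' @return TPM vector or matrix; every experiment sums to 1e6.
#' @examples
#' tpmNormalize(c(10, 90), c(1000, 3000))  # 250000 750000
#' @export
tpmNormalize <- function(counts, orfLengths) {
  stopifnot(all(orfLengths > 0), all(counts >= 0))
  one <- function(x) {
    if (all(x == 0)) stop("all-zero counts in an experiment")
    rpk <- x / (orfLengths / 1000)
    rpk / sum(rpk) * 1e6
  }
  if (is.matrix(counts)) {
    stopifnot(nrow(counts) == length(orfLengths))
    apply(counts, 2, one)
  } else {
    stopifnot(length(counts) == length(orfLengths))
    one(counts)
  }
}

#' Per-gene relative standard deviation
#'
#' Sample SD over mean across experiments, per gene.
#'
#' @param m genes x experiments matrix.
#' @return numeric RSD per gene.
#' @export
rsdVec <- function(m) {
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  sdv / mu
}

#' Abundance and variability gene filters
#'
#' Drops genes with median TPM below `minTpm`, then genes whose relative
#' standard deviation (sample SD / mean across experiments) is `rsdMax` or
#' higher.
#'
#' @param tpm genes x experiments TPM matrix with rownames.
#' @param minTpm abundance floor (default 5 TPM).
#' @param rsdMax RSD ceiling (default 1).
#' @return list with `kept` (gene ids), `summary` (`DataFrame`: gene_id,
#'   median_tpm, rsd for kept genes) and `removed` (counts per filter).
#' @export
filterGenes <- function(tpm, minTpm = 5, rsdMax = 1) {
  stopifnot(is.matrix(tpm), ncol(tpm) >= 2, !is.null(rownames(tpm)))
  med <- apply(tpm, 1, stats::median)
  pass1 <- med >= minTpm
  rsd <- rsdVec(tpm)
  pass2 <- pass1 & rsd < rsdMax
  removed <- c(abundance = sum(!pass1), variability = sum(pass1 & !pass2))
  if (!any(pass2))
    stop(sprintf("no genes left (removed %d by abundance, %d by RSD)",
                 removed[1], removed[2]))
  list(kept = rownames(tpm)[pass2],
       summary = S4Vectors::DataFrame(gene_id = rownames(tpm)[pass2],
                                      median_tpm = med[pass2],
                                      rsd = rsd[pass2]),
       removed = removed)
}

boxcoxLogLik <- function(lambda, x, slx) {
  y <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  n <- length(x)
  -n / 2 * log(mean((y - mean(y))^2)) + (lambda - 1) * slx
}

#' Box-Cox transform with maximum-likelihood lambda
#'
#' `boxcoxLambda` maximises the profile log-likelihood of the power
#' transform over `interval`; `boxcoxTransform` applies
#' \eqn{(x^\lambda - 1)/\lambda} (\eqn{\ln x} at \eqn{\lambda = 0});
#' `boxcoxInverse` inverts it.
#'
#' @param x strictly positive numeric vector.
#' @param lambda transform exponent.
#' @param y transformed values.
#' @param interval search interval for lambda.
#' @return `boxcoxLambda`: the MLE; the others: transformed / original
#'   scale vectors.
#' @export
boxcoxLambda <- function(x, interval = c(-2, 2)) {
  if (any(x <= 0)) stop("Box-Cox requires strictly positive input")
  slx <- sum(log(x))
  stats::optimize(boxcoxLogLik, interval = interval, x = x, slx = slx,
                  maximum = TRUE)$maximum
}

#' @rdname boxcoxLambda
#' @export
boxcoxTransform <- function(x, lambda) {
  if (any(x <= 0)) stop("Box-Cox requires strictly positive input")
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

#' @rdname boxcoxLambda
#' @export
boxcoxInverse <- function(y, lambda) {
  if (abs(lambda) < 1e-12) exp(y) else (lambda * y + 1)^(1 / lambda)
}

#' Remove gene-length bias from an expression target
#'
#' Ordinary least squares of the transformed expression target on
#' log10(ORF length); the residuals (exactly uncorrelated with the
#' regressor) become the corrected target. The fitted intercept/slope are
#' attached for inversion.
#'
#' @param targets numeric transformed expression values, length >= 3.
#' @param orfLengths positive ORF lengths (bp).
#' @return residual vector with attribute `"fit"` = c(intercept, slope).
#' @export
lengthCorrect <- function(targets, orfLengths) {
  stopifnot(length(targets) == length(orfLengths), length(targets) >= 3,
            all(orfLengths > 0))
  lx <- log10(orfLengths)
  if (stats::sd(lx) == 0) {
    warning("constant ORF lengths; returning mean-centred targets")
    out <- targets - mean(targets)
    attr(out, "fit") <- c(intercept = mean(targets), slope = 0)
    return(out)
  }
  fit <- stats::lm.fit(cbind(1, lx), targets)
  out <- as.numeric(fit$residuals)
  attr(out, "fit") <- c(intercept = fit$coefficients[1],
                        slope = fit$coefficients[2])
  out
}

#' Genome-to-gene expression variance ratios
#'
#' For each gene, the ratio of the across-gene variance of median TPM to
#' that gene's variance across experiments. Genes with zero variance get
#' an infinite ratio and are flagged.
#'
#' @param tpm genes x experiments TPM matrix (>= 2 genes, >= 2
#'   experiments).
#' @return list with `ratios`, `median` (of finite ratios), and
#'   `infinite` (logical flags).
#' @export
varianceRatio <- function(tpm) {
  stopifnot(is.matrix(tpm), nrow(tpm) >= 2, ncol(tpm) >= 2)
  med <- apply(tpm, 1, stats::median)
  vAcross <- stats::var(med)
  vGene <- apply(tpm, 1, stats::var)
  ratios <- ifelse(vGene == 0, Inf, vAcross / vGene)
  list(ratios = ratios, median = stats::median(ratios[is.finite(ratios)]),
       infinite = !is.finite(ratios))
}

#' Build the per-gene modeling target
#'
#' The full target pipeline: filter by abundance and RSD, Box-Cox the
#' median TPM (lambda fitted on `fitIdx` only — pass the training split to
#' avoid leakage), then remove ORF-length bias by OLS residualisation
#' (also fitted on `fitIdx`).
#'
#' @param tpm genes x experiments TPM matrix with rownames.
#' @param orfLengths named vector of ORF lengths (bp) covering the genes.
#' @param minTpm,rsdMax filter thresholds.
#' @param fitIdx gene ids (or indices into the kept genes) on which lambda
#'   and the length fit are estimated; default all kept genes.
#' @return list with `summary` (`DataFrame`: gene_id, median_tpm, rsd,
#'   target), `lambda`, `lengthFit` (intercept/slope on log10 bp) and
#'   `kept`.
#' @export
medianTarget <- function(tpm, orfLengths, minTpm = 5, rsdMax = 1,
                         fitIdx = NULL) {
  flt <- filterGenes(tpm, minTpm = minTpm, rsdMax = rsdMax)
  ids <- flt$kept
  if (length(ids) < 3) stop("need at least 3 genes after filtering")
  med <- flt$summary$median_tpm
  len <- orfLengths[ids]
  if (is.null(fitIdx)) fitIdx <- ids
  fi <- if (is.character(fitIdx)) match(fitIdx, ids) else fitIdx
  fi <- fi[!is.na(fi)]
  if (length(fi) < 3) stop("need at least 3 genes in the fitting split")
  lambda <- boxcoxLambda(med[fi])
  bc <- boxcoxTransform(med, lambda)
  corrFit <- lengthCorrect(bc[fi], len[fi])
  cf <- attr(corrFit, "fit")
  target <- bc - (cf[1] + cf[2] * log10(len))
  s <- flt$summary
  s$target <- target
  list(summary = s, lambda = lambda,
       lengthFit = c(intercept = unname(cf[1]), slope = unname(cf[2])),
       kept = ids)
}

#' Invert the target transform back to TPM
#'
#' Adds back the fitted length term and inverts the Box-Cox transform, so
#' model predictions return to the TPM scale.
#'
#' @param target corrected target values.
#' @param orfLengths ORF lengths (bp) of the same genes.
#' @param lambda,lengthFit as returned by [medianTarget()].
#' @param floor TPM floor for out-of-domain inversions (flagged via
#'   attribute `"clipped"`).
#' @return TPM-scale vector.
#' @export
invertTarget <- function(target, orfLengths, lambda, lengthFit,
                         floor = 1e-3) {
  y <- target + lengthFit[["intercept"]] +
    lengthFit[["slope"]] * log10(orfLengths)
  if (abs(lambda) < 1e-12) {
    out <- exp(y)
    clipped <- rep(FALSE, length(y))
  } else {
    base <- lambda * y + 1
    clipped <- base <= 0
    out <- rep(floor, length(y))
    out[!clipped] <- base[!clipped]^(1 / lambda)
  }
  low <- out < floor
  out[low] <- floor
  attr(out, "clipped") <- clipped | low
  out
}
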