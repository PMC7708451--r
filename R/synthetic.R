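#' Generator configuration
#'
#' Default study conditions for the synthetic cohort: ~3000 genes with
#' compact regulatory regions (200/50/50/100 bp), 20 planted 10-bp motifs,
#' 40 co-occurrence rules with additive log10 effects, AT-rich UTer
#' backgrounds, codon usage coupled to the latent expression quantile, and
#' noise levels calibrated so that most genes sit below RSD 1 while median
#' TPM spans about four orders of magnitude.
#'
#' @param nGenes number of genes.
#' @param regionLengths named lengths as from [regionPreset()].
#' @param cdsCodonRange range of CDS codon counts (incl. start/stop).
#' @param nMotifs,motifWidth planted motif count and width (bp).
#' @param motifDominance probability mass of the consensus base per PWM
#'   column (0.95 gives ~1.6 bits/column).
#' @param nRules number of planted rules.
#' @param ruleSizeProbs probabilities of rule sizes 2 and 3.
#' @param crossRegionFraction fraction of rules spanning >= 2 regions.
#' @param adoptProbRange per-rule gene adoption probability range.
#' @param backgroundPlantProb per-motif background planting probability.
#' @param effectSd SD of rule effects (log10 units).
#' @param ruleMainEffectFraction fraction of each rule's effect carried
#'   additively by its member motifs (spread equally); the remainder
#'   requires full co-occurrence.
#' @param baselineLogExpr baseline log10 expression.
#' @param codonCoupling coupling of codon bias to expression quantile.
#' @param codonEffect additive effect (log10) of the codon mixture weight.
#' @param noiseSdBetweenMed,noiseSdBetweenSpread median and lognormal
#'   spread of the per-gene between-experiment noise SD (log10 units).
#' @param noiseSdResidual SD of the sequence-independent latent residual.
#' @param gc named per-region background GC fractions.
#' @return configuration list.
#' @export
syntheticConfig <- function(nGenes = 3000,
                            regionLengths = regionPreset("scaled"),
                            cdsCodonRange = c(200L, 600L),
                            nMotifs = 20, motifWidth = 10,
                            motifDominance = 0.95,
                            nRules = 40,
                            ruleSizeProbs = c(`2` = 0.75, `3` = 0.25),
                            crossRegionFraction = 0.88,
                            adoptProbRange = c(0.04, 0.10),
                            backgroundPlantProb = 0.01,
                            effectSd = 0.30,
                            ruleMainEffectFraction = 0.5,
                            baselineLogExpr = 1.5,
                            codonCoupling = 0.5,
                            codonEffect = 0.3,
                            noiseSdBetweenMed = 0.15,
                            noiseSdBetweenSpread = 0.8,
                            noiseSdResidual = 0.29,
                            gc = c(promoter = 0.38, utr5 = 0.30,
                                   utr3 = 0.30, terminator = 0.35)) {
  cfg <- as.list(environment())
  stopifnot(cfg$nGenes > 0, all(cfg$regionLengths > 0), cfg$nMotifs >= 0,
            cfg$nRules >= 0, cfg$motifWidth >= 1)
  if (cfg$nMotifs > 0 &&
      cfg$motifWidth > min(cfg$regionLengths[REGULATORY_REGIONS]))
    stop("motif longer than its target region")
  cfg
}

# dinucleotide Markov background: rows mix the stationary base composition
# with a modest self-transition bonus so the chain is genuinely 2nd order
markovBackground <- function(n, len, gcFrac, selfBonus = 0.15) {
  pi0 <- c(A = (1 - gcFrac) / 2, C = gcFrac / 2,
           G = gcFrac / 2, T = (1 - gcFrac) / 2)
  P <- matrix(rep(pi0, each = 4), 4, 4, dimnames = list(BASES, BASES))
  P <- (1 - selfBonus) * P + selfBonus * diag(4)
  out <- matrix(0L, n, len)
  out[, 1] <- sample.int(4, n, replace = TRUE, prob = pi0)
  cum <- t(apply(P, 1, cumsum))
  for (j in 2:len) {
    u <- stats::runif(n)
    prev <- out[, j - 1]
    out[, j] <- 1L + (u > cum[prev, 1]) + (u > cum[prev, 2]) +
      (u > cum[prev, 3])
  }
  out
}

samplePWM <- function(dominance, width) {
  cons <- sample.int(4, width, replace = TRUE)
  pwm <- matrix((1 - dominance) / 3, 4, width, dimnames = list(BASES, NULL))
  pwm[cbind(cons, seq_len(width))] <- dominance
  pwm
}

pwmLogOdds <- function(pwm) log(pwm / 0.25)

# sample an instance from the PWM, rejecting > maxMismatch deviations from
# the consensus so every planted instance clears the recorded threshold
sampleInstance <- function(pwm, maxMismatch = 2L) {
  cons <- apply(pwm, 2, which.max)
  repeat {
    draw <- apply(pwm, 2, function(p) sample.int(4, 1, prob = p))
    if (sum(draw != cons) <= maxMismatch) return(draw)
  }
}

#' Score a sequence window against a PWM
#'
#' Log-odds score (natural log, uniform background) of a sequence under a
#' probability matrix.
#'
#' @param seq character of the same length as the PWM width.
#' @param pwm 4 x w probability matrix.
#' @return numeric score.
#' @export
pwmScore <- function(seq, pwm) {
  idx <- match(strsplit(toupper(seq), "")[[1]], BASES)
  stopifnot(length(idx) == ncol(pwm), !anyNA(idx))
  sum(pwmLogOdds(pwm)[cbind(idx, seq_len(ncol(pwm)))])
}

#' Generate a synthetic genome with a planted regulatory grammar
#'
#' Draws per-gene promoter/5'UTR/CDS/3'UTR/terminator sequences from
#' per-region dinucleotide Markov backgrounds, plants motif instances
#' (sampled from the motif PWMs, non-overlapping, one instance per gene
#' per motif), wires motifs into co-occurrence rules with additive log10
#' effects, and samples the CDS from two opposing codon-bias tables mixed
#' by the gene's latent expression quantile. Every planted rule is
#' guaranteed at least 3 full-carrier genes.
#'
#' @param config list from [syntheticConfig()].
#' @param seed integer seed.
#' @return a [SyntheticCohort-class] (expression slot empty until
#'   [generateExpression()] is called).
#' @export
generateGenome <- function(config = syntheticConfig(), seed = 1L) {
  set.seed(seed)
  n <- config$nGenes
  rl <- config$regionLengths
  ids <- sprintf("g%04d", seq_len(n))

  ## planted motifs: distinct consensus (pairwise Hamming >= 4)
  motifs <- list()
  regionsOfMotifs <- character(0)
  if (config$nMotifs > 0) {
    regW <- rl[REGULATORY_REGIONS] / sum(rl[REGULATORY_REGIONS])
    consMat <- NULL
    while (length(motifs) < config$nMotifs) {
      pwm <- samplePWM(config$motifDominance, config$motifWidth)
      cons <- apply(pwm, 2, which.max)
      if (!is.null(consMat) &&
          any(colSums(consMat != cons) < 4)) next
      consMat <- cbind(consMat, cons)
      id <- sprintf("M%02d", length(motifs) + 1L)
      reg <- sample(REGULATORY_REGIONS, 1, prob = regW)
      lo <- pwmLogOdds(pwm)
      drop <- max(apply(lo, 2, function(c) max(c) - min(c)))
      thr <- sum(apply(lo, 2, max)) - 2 * drop - 1e-9
      motifs[[id]] <- list(id = id, region = reg, pwm = pwm,
                           consensus = paste(BASES[cons], collapse = ""),
                           threshold = thr)
      regionsOfMotifs[id] <- reg
    }
  }

  ## planted rules over the motifs
  rules <- list()
  if (config$nRules > 0 && config$nMotifs >= 2) {
    nCross <- round(config$crossRegionFraction * config$nRules)
    sizes <- sample(as.integer(names(config$ruleSizeProbs)), config$nRules,
                    replace = TRUE, prob = config$ruleSizeProbs)
    seen <- character(0)
    for (k in seq_len(config$nRules)) {
      wantCross <- k <= nCross
      tries <- 0L
      repeat {
        tries <- tries + 1L
        mem <- sample(names(motifs), sizes[k])
        nReg <- length(unique(regionsOfMotifs[mem]))
        ok <- if (wantCross) nReg >= 2 else nReg == 1
        # the requested span may be unsatisfiable for some region draws
        # (e.g. all motifs in one region); relax after enough attempts
        if (!ok && tries > 200L) ok <- TRUE
        if (tries > 2000L)
          stop("cannot draw enough distinct rules; increase nMotifs")
        key <- paste(sort(mem), collapse = "+")
        if (ok && !key %in% seen) { seen <- c(seen, key); break }
      }
      rules[[sprintf("R%02d", k)]] <- list(
        id = sprintf("R%02d", k), motifs = sort(mem),
        effect = stats::rnorm(1, 0, config$effectSd),
        adoptProb = stats::runif(1, config$adoptProbRange[1],
                                 config$adoptProbRange[2]))
    }
  }

  ## which motifs does each gene carry: rule adoption + background
  present <- matrix(FALSE, n, max(config$nMotifs, 1L),
                    dimnames = list(ids, if (config$nMotifs) names(motifs)))
  adopted <- matrix(FALSE, n, max(config$nRules, 1L),
                    dimnames = list(ids, if (config$nRules) names(rules)))
  if (config$nMotifs > 0) {
    for (r in rules) {
      a <- stats::runif(n) < r$adoptProb
      adopted[, r$id] <- a
      present[a, r$motifs] <- TRUE
    }
    bg <- matrix(stats::runif(n * config$nMotifs) <
                   config$backgroundPlantProb, n, config$nMotifs)
    present <- present | bg
    # repair: every rule fully carried by >= 3 genes
    for (r in rules) {
      carriers <- rowSums(present[, r$motifs, drop = FALSE]) ==
        length(r$motifs)
      if (sum(carriers) < 3) {
        extra <- sample(which(!carriers), 3 - sum(carriers))
        present[extra, r$motifs] <- TRUE
        adopted[extra, r$id] <- TRUE
      }
    }
  }

  ## background sequences per region, then motif planting
  regions <- list()
  intToSeq <- function(m) apply(m, 1, function(x)
    paste(BASES[x], collapse = ""))
  plantRows <- list()
  for (reg in REGULATORY_REGIONS) {
    bgm <- markovBackground(n, rl[[reg]], config$gc[[reg]])
    regMotifs <- if (config$nMotifs)
      names(motifs)[regionsOfMotifs == reg] else character(0)
    if (length(regMotifs)) {
      w <- config$motifWidth
      for (i in seq_len(n)) {
        todo <- regMotifs[present[i, regMotifs]]
        if (!length(todo)) next
        occupied <- integer(0)
        for (mid in todo) {
          placed <- FALSE
          for (try in 1:50) {
            s <- sample.int(rl[[reg]] - w + 1L, 1)
            if (!any(abs(s - occupied) < w)) {
              inst <- sampleInstance(motifs[[mid]]$pwm)
              bgm[i, s:(s + w - 1L)] <- inst
              occupied <- c(occupied, s)
              plantRows[[length(plantRows) + 1L]] <- list(
                gene_id = ids[i], motif_id = mid, region = reg,
                start = s,
                sequence = paste(BASES[inst], collapse = ""))
              placed <- TRUE
              break
            }
          }
          if (!placed) present[i, mid] <- FALSE
        }
      }
    }
    regions[[reg]] <- Biostrings::DNAStringSet(
      stats::setNames(intToSeq(bgm), ids))
  }

  ## regulatory score: each rule contributes a main-effect component per
  ## member motif present plus an interaction component on full
  ## co-occurrence
  alpha <- config$ruleMainEffectFraction
  regScore <- rep(config$baselineLogExpr, n)
  for (r in rules) {
    k <- length(r$motifs)
    frac <- rowSums(present[, r$motifs, drop = FALSE]) / k
    fires <- frac == 1
    regScore <- regScore +
      r$effect * (alpha * frac + (1 - alpha) * fires)
  }

  ## CDS: codon mixture weight tied to the expression quantile
  q <- (rank(regScore, ties.method = "random") - 0.5) / n
  w <- config$codonCoupling * q +
    (1 - config$codonCoupling) * stats::runif(n)
  tabs <- codonBiasTables()
  nCod <- sample(config$cdsCodonRange[1]:config$cdsCodonRange[2], n,
                 replace = TRUE)
  cds <- character(n)
  for (i in seq_len(n)) {
    p <- w[i] * tabs$high + (1 - w[i]) * tabs$low
    body <- sample(SENSE_CODONS, nCod[i] - 2L, replace = TRUE, prob = p)
    cds[i] <- paste0("ATG", paste(body, collapse = ""),
                     sample(STOP_CODONS, 1))
  }
  regions$cds <- Biostrings::DNAStringSet(stats::setNames(cds, ids))
  regions <- regions[c("promoter", "utr5", "cds", "utr3", "terminator")]

  plantings <- if (length(plantRows)) {
    S4Vectors::DataFrame(
      gene_id = vapply(plantRows, `[[`, "", "gene_id"),
      motif_id = vapply(plantRows, `[[`, "", "motif_id"),
      region = vapply(plantRows, `[[`, "", "region"),
      start = vapply(plantRows, `[[`, 0L, "start"),
      sequence = vapply(plantRows, `[[`, "", "sequence"))
  } else S4Vectors::DataFrame(gene_id = character(0),
                              motif_id = character(0),
                              region = character(0), start = integer(0),
                              sequence = character(0))

  truth <- new("GrammarTruth", motifs = motifs, rules = rules,
               codonCoupling = config$codonCoupling,
               codonEffect = config$codonEffect,
               baselineLogExpr = config$baselineLogExpr,
               noiseSdBetween = config$noiseSdBetweenMed,
               noiseSdBetweenSpread = config$noiseSdBetweenSpread,
               noiseSdResidual = config$noiseSdResidual,
               crossRegionFraction = if (length(rules))
                 mean(vapply(rules, function(r)
                   length(unique(regionsOfMotifs[r$motifs])) >= 2, TRUE))
                 else 0)

  gd <- S4Vectors::DataFrame(
    gene_id = ids, strand = "+",
    len_promoter = rl[["promoter"]], len_utr5 = rl[["utr5"]],
    len_cds = nchar(cds), len_utr3 = rl[["utr3"]],
    len_terminator = rl[["terminator"]],
    reg_score = regScore, codon_w = w, latent = NA_real_)

  new("SyntheticCohort", geneData = gd, regions = regions,
      plantings = plantings, expression = matrix(numeric(0), 0, 0),
      truth = truth, seed = as.integer(seed))
}

# two opposing codon-bias tables over the sense codons: "high" prefers one
# codon per amino-acid-like group 16-fold, "low" prefers the complement
codonBiasTables <- function() {
  nS <- length(SENSE_CODONS)
  pref <- SENSE_CODONS[seq(1, nS, by = 3)]  # fixed, evenly spread subset
  hi <- ifelse(SENSE_CODONS %in% pref, 16, 1)
  lo <- ifelse(SENSE_CODONS %in% pref, 1, 16)
  list(high = stats::setNames(hi / sum(hi), SENSE_CODONS),
       low = stats::setNames(lo / sum(lo), SENSE_CODONS))
}

#' Generate the expression matrix for a synthetic cohort
#'
#' Per-gene latent log10 level = regulatory score + codon-mixture effect +
#' residual noise; per-experiment values multiply the latent level by
#' lognormal noise with a per-gene SD; each experiment column is then
#' TPM-normalised (sums to 1e6).
#'
#' @param cohort a [SyntheticCohort-class] from [generateGenome()].
#' @param nExperiments number of experiments (>= 2).
#' @param seed integer seed.
#' @return the cohort with the `expression` slot filled and per-gene
#'   latent levels recorded.
#' @export
generateExpression <- function(cohort, nExperiments = 100, seed = 1L) {
  stopifnot(is(cohort, "SyntheticCohort"))
  if (nExperiments < 2) stop("need >= 2 experiments (RSD undefined)")
  set.seed(seed)
  n <- nrow(cohort@geneData)
  tr <- cohort@truth
  latent <- cohort@geneData$reg_score +
    tr@codonEffect * (cohort@geneData$codon_w - 0.5) +
    tr@noiseSdResidual * stats::rnorm(n)
  sdg <- stats::rlnorm(n, meanlog = log(tr@noiseSdBetween),
                       sdlog = tr@noiseSdBetweenSpread)
  vals <- 10^(latent + matrix(stats::rnorm(n * nExperiments), n) * sdg)
  vals <- sweep(vals, 2, colSums(vals), "/") * 1e6
  dimnames(vals) <- list(cohort@geneData$gene_id,
                         sprintf("exp%03d", seq_len(nExperiments)))
  cohort@geneData$latent <- latent
  cohort@expression <- vals
  cohort
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate gap-free ortholog alignments with correlated region rates
#'
#' For each gene and region, evolves `nSpecies` sequences independently
#' from the gene's region sequence on a star tree under the JC69 model.
#' Per-gene promoter and coding branch rates are drawn from a bivariate
#' distribution whose Pearson correlation equals `regionRateCorrelation`;
#' other regions get independent rates. Per-column confidence scores are
#' 1.0.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param nSpecies number of species (>= 3; default 14).
#' @param regionRateCorrelation target promoter-coding rate correlation in
#'   [0, 1).
#' @param regions which regions to emit alignments for.
#' @param meanRate named per-region mean branch rates
#'   (substitutions/site).
#' @param rateCV coefficient of variation of the per-gene rates.
#' @param seed integer seed.
#' @return list with `alignments` (per gene: per region list with `seqs`,
#'   `confidence`) and `trueRates` (genes x regions matrix of branch
#'   rates).
#' @export
generateOrthologs <- function(cohort, nSpecies = 14,
                              regionRateCorrelation = 0.45,
                              regions = c("promoter", "cds", "terminator"),
                              meanRate = c(promoter = 0.30, utr5 = 0.35,
                                           cds = 0.20, utr3 = 0.35,
                                           terminator = 0.30),
                              rateCV = 0.3, seed = 1L) {
  stopifnot(is(cohort, "SyntheticCohort"), nSpecies >= 3)
  rho <- regionRateCorrelation
  if (rho < 0 || rho >= 1) stop("correlation must be in [0, 1)")
  set.seed(seed)
  n <- nrow(cohort@geneData)
  ids <- cohort@geneData$gene_id
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  clamp <- function(z) pmax(1 + rateCV * z, 0.05)
  rates <- matrix(NA_real_, n, length(regions),
                  dimnames = list(ids, regions))
  for (r in regions) {
    z <- switch(r, promoter = z1, cds = z2, stats::rnorm(n))
    rates[, r] <- meanRate[[r]] * clamp(z)
  }
  aln <- vector("list", n)
  names(aln) <- ids
  for (i in seq_len(n)) {
    per <- list()
    for (r in regions) {
      anc <- strsplit(as.character(cohort@regions[[r]][[i]]), "")[[1]]
      L <- length(anc)
      pSub <- 0.75 * (1 - exp(-4 * rates[i, r] / 3))
      seqs <- vapply(seq_len(nSpecies), function(s) {
        x <- anc
        hit <- stats::runif(L) < pSub
        if (any(hit)) {
          cur <- match(x[hit], BASES)
          repl <- ((cur - 1L + sample.int(3, sum(hit), replace = TRUE))
                   %% 4L) + 1L
          x[hit] <- BASES[repl]
        }
        paste(x, collapse = "")
      }, "")
      names(seqs) <- sprintf("sp%02d", seq_len(nSpecies))
      per[[r]] <- list(gene_id = ids[i], region = r, seqs = seqs,
                       confidence = rep(1, L))
    }
    aln[[i]] <- per
  }
  list(alignments = aln, trueRates = rates)
}
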