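#' Occlude a window of a one-hot matrix
#'
#' Sets columns `[start, start + width)` (1-based `start`) to zero —
#' the same encoding as unknown/padded bases — leaving the input
#' unmutated.
#'
#' @param onehot 4 x L matrix.
#' @param start first occluded column (1-based).
#' @param width occlusion width (bp); 0 returns the input unchanged.
#' @return occluded copy.
#' @export
occlude <- function(onehot, start, width) {
  L <- ncol(onehot)
  if (width == 0) return(onehot)
  if (start < 1 || width < 0 || start + width - 1 > L)
    stop("occlusion window out of range")
  out <- onehot
  out[, start:(start + width - 1)] <- 0
  out
}

#' Occlusion relevance profiles
#'
#' Slides a `window`-bp all-zero occlusion along each regulatory region
#' (stride `stride`), recomputes the model prediction, and scores each
#' window as `(Y - Y_occluded) / Y`. Per-position relevance is the mean
#' over all windows covering the position. With `window = "region"`,
#' whole regions are occluded instead. Predictions can be mapped through
#' `transform` (e.g. the inverse target transform onto the positive TPM
#' scale) before the ratio; genes whose transformed |Y| falls below
#' `eps` are flagged and reported as unscaled differences.
#'
#' @param model trained [SeqExprModel-class].
#' @param features list from [cohortFeatures()].
#' @param window occlusion width in bp, or `"region"`.
#' @param stride occlusion stride (bp).
#' @param transform optional function applied to raw predictions.
#' @param eps ratio guard on |Y|.
#' @param idx optional subset of genes (indices or ids).
#' @param chunk prediction batch size.
#' @return a [RelevanceProfileSet-class] (masks empty until
#'   [significantPositions()]).
#' @export
relevanceProfiles <- function(model, features, window = 10L, stride = 1L,
                              transform = NULL, eps = 1e-6, idx = NULL,
                              chunk = 2048L) {
  nAll <- dim(features$seq)[1]
  idx <- if (is.null(idx)) seq_len(nAll)
         else if (is.character(idx)) match(idx, features$geneIds) else idx
  n <- length(idx)
  if (is.null(transform)) transform <- identity
  sub <- list(seq = features$seq[idx, , , drop = FALSE],
              num = features$num[idx, , drop = FALSE],
              geneIds = features$geneIds[idx],
              regions = features$regions)
  ## layout and covariate standardisation are computed once; each
  ## occlusion only zeroes layout columns before a direct forward pass
  nm <- model@norm
  spec <- model@spec
  L0 <- dim(sub$seq)[3]
  Bfull <- seqToLayout(sub$seq)
  numStd <- sweep(sweep(sub$num, 2, nm$numMu), 2, nm$numSd, "/")
  rawPredict <- function(B) {
    out <- NULL
    for (cs in seq(1, n, by = chunk)) {
      ce <- min(cs + chunk - 1, n)
      colSel <- as.vector(outer(seq_len(L0), (cs:ce - 1L) * L0, "+"))
      fw <- netForward(model@weights, spec, B[, colSel, drop = FALSE],
                       numStd[cs:ce, , drop = FALSE], ce - cs + 1L, L0,
                       training = FALSE, run = nm$run)
      out <- c(out, as.numeric(fw$pred))
    }
    stats::setNames(
      as.numeric(sweep(sweep(matrix(out, ncol = 1), 2, nm$ySd, "*"),
                       2, nm$yMu, "+")),
      sub$geneIds)
  }
  Y <- transform(rawPredict(Bfull))
  flagged <- abs(Y) < eps
  values <- list()
  wholeRegion <- identical(window, "region")
  allCols <- (seq_len(n) - 1L) * L0
  for (r in names(features$regions)) {
    b <- features$regions[[r]]
    L <- b["end"] - b["start"] + 1L
    w <- if (wholeRegion) L else as.integer(window)
    if (w > L) stop(sprintf("window %d exceeds region %s length %d",
                            w, r, L))
    starts <- seq.int(1L, L - w + 1L, by = stride)
    WR <- matrix(0, n, length(starts))
    for (si in seq_along(starts)) {
      occCols <- as.vector(outer(
        (b["start"] + starts[si] - 1L):(b["start"] + starts[si] + w - 2L),
        allCols, "+"))
      Bocc <- Bfull
      Bocc[, occCols] <- 0
      Yo <- transform(rawPredict(Bocc))
      d <- Y - Yo
      WR[, si] <- ifelse(flagged, d, d / Y)
    }
    # per-position mean over covering windows
    V <- matrix(0, n, L)
    cnt <- numeric(L)
    for (si in seq_along(starts)) {
      cols <- starts[si]:(starts[si] + w - 1L)
      V[, cols] <- V[, cols] + WR[, si]
      cnt[cols] <- cnt[cols] + 1
    }
    covered <- cnt > 0
    V[, covered] <- sweep(V[, covered, drop = FALSE], 2, cnt[covered], "/")
    rownames(V) <- sub$geneIds
    values[[r]] <- V
  }
  new("RelevanceProfileSet", values = values, mask = list(), Y = Y,
      window = if (wholeRegion) -1L else as.integer(window),
      flagged = flagged, geneIds = sub$geneIds)
}

#' Cohort-level significance masks
#'
#' Z-scores the relevance values against the pooled cohort distribution
#' of each region and flags positions with |z| at or above `cutoffSd`.
#'
#' @param profiles a [RelevanceProfileSet-class] (>= 2 genes).
#' @param cutoffSd significance cutoff in standard deviations.
#' @return the profile set with masks filled; per-region mean significant
#'   bp per gene in attribute `"meanSignificantBp"`.
#' @export
significantPositions <- function(profiles, cutoffSd = 2) {
  stopifnot(length(profiles@geneIds) >= 2)
  masks <- list()
  meanBp <- numeric(0)
  for (r in names(profiles@values)) {
    V <- profiles@values[[r]]
    mu <- mean(V)
    sdv <- stats::sd(as.numeric(V))
    if (sdv == 0) {
      warning(sprintf("zero relevance variance in region %s; empty mask", r))
      masks[[r]] <- matrix(FALSE, nrow(V), ncol(V),
                           dimnames = dimnames(V))
    } else {
      masks[[r]] <- abs(V - mu) / sdv >= cutoffSd
    }
    meanBp[r] <- mean(rowSums(masks[[r]]))
  }
  profiles@mask <- masks
  attr(profiles@mask, "meanSignificantBp") <- meanBp
  profiles
}

#' Consensus clustering of relevance profiles
#'
#' Repeatedly subsamples the genes, partitions each subsample around
#' medoids under the Pearson correlation distance, and aggregates
#' co-clustering frequencies into a consensus matrix per k. Final labels
#' come from PAM on 1 - consensus. k is selected as the smallest k whose
#' within-minus-between consensus separation gains less than 10% when
#' moving to k + 1.
#'
#' @param profiles a [RelevanceProfileSet-class] or a genes x features
#'   numeric matrix (profiles are concatenated across regions).
#' @param kRange candidate cluster numbers.
#' @param reps subsampling repetitions (>= 2).
#' @param subsample fraction of genes per repetition.
#' @param seed integer.
#' @return list with `k`, `labels`, `consensus` (list of matrices),
#'   `separation` (per k).
#' @export
consensusCluster <- function(profiles, kRange = 2:6, reps = 50,
                             subsample = 0.8, seed = 1L) {
  if (reps < 2) stop("need >= 2 repetitions")
  X <- if (is(profiles, "RelevanceProfileSet"))
    do.call(cbind, profiles@values) else profiles
  n <- nrow(X)
  stopifnot(n >= max(kRange) + 1)
  set.seed(seed)

  runConsensus <- function(M, seedLocal) {
    set.seed(seedLocal)   # paired subsample draws for data and null
    D <- 1 - stats::cor(t(M))
    D[is.na(D)] <- 1
    m <- ceiling(subsample * n)
    hits <- matrix(0, n, n)
    cons <- lapply(kRange, function(k) matrix(0, n, n))
    names(cons) <- as.character(kRange)
    for (r in seq_len(reps)) {
      s <- sort(sample.int(n, m))
      hits[s, s] <- hits[s, s] + 1
      for (ki in seq_along(kRange)) {
        cl <- cluster::pam(stats::as.dist(D[s, s]), kRange[ki],
                           pamonce = 5)$clustering
        cons[[ki]][s, s] <- cons[[ki]][s, s] +
          outer(cl, cl, "==")
      }
    }
    sep <- numeric(length(kRange))
    labels <- vector("list", length(kRange))
    for (ki in seq_along(kRange)) {
      CM <- cons[[ki]] / pmax(hits, 1)
      diag(CM) <- 1
      cons[[ki]] <- CM
      cl <- cluster::pam(stats::as.dist(1 - CM), kRange[ki],
                         pamonce = 5)$clustering
      labels[[ki]] <- cl
      same <- outer(cl, cl, "==")
      diag(same) <- NA
      within <- mean(CM[which(same)], na.rm = TRUE)
      between <- if (any(!same, na.rm = TRUE))
        mean(CM[which(!same)], na.rm = TRUE) else 0
      sep[ki] <- within - between
    }
    list(sep = sep, labels = labels, cons = cons)
  }

  Xnull <- apply(X, 2, sample)
  ## null calibration: a column-permuted copy destroys the row structure
  ## but keeps the marginals; its separation profile (computed with the
  ## same subsample draws) is the baseline a structureless cloud attains
  obs <- runConsensus(X, seed + 1L)
  nul <- runConsensus(Xnull, seed + 1L)
  sepAdj <- obs$sep - nul$sep

  kSel <- kRange[length(kRange)]
  for (ki in seq_along(kRange)) {
    if (ki == length(kRange)) { kSel <- kRange[ki]; break }
    gain <- (sepAdj[ki + 1] - sepAdj[ki]) / max(abs(sepAdj[ki]), 0.05)
    ## advance only when k+1 still shows genuine structure above the
    ## permutation baseline
    if (gain < 0.1 || sepAdj[ki + 1] < 0.2) { kSel <- kRange[ki]; break }
  }
  ki <- match(kSel, kRange)
  list(k = kSel, labels = obs$labels[[ki]], consensus = obs$cons,
       separation = stats::setNames(obs$sep, kRange),
       null_separation = stats::setNames(nul$sep, kRange))
}
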