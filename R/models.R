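#' Architecture and optimiser settings for the sequence model
#'
#' Three convolution blocks (conv -> optional batch-norm -> ReLU ->
#' max-pool -> dropout) over the concatenated one-hot regions, flattened
#' and joined with the 72 numeric covariates before two fully connected
#' blocks and a linear (or softmax) output. Mean-squared-error loss, Adam
#' optimiser, uniform (He) weight initialisation.
#'
#' @param convFilters,kernels,pools,strides,dilations integer vectors of
#'   length 3 (one per conv block).
#' @param fcWidths integer vector of length 2.
#' @param dropout dropout rate applied after conv and FC blocks.
#' @param batchnorm logical; apply batch normalisation after conv and FC
#'   layers.
#' @param lr,batchSize,epochs,patience optimiser settings; training stops
#'   after `patience` epochs without validation improvement.
#' @param lrDecayFactor,lrDecayPatience halve-on-plateau schedule: after
#'   `lrDecayPatience` epochs without improvement the learning rate is
#'   multiplied by `lrDecayFactor` (floor 1e-5).
#' @param outputDim output width (1 for expression, 64 for codon
#'   vectors).
#' @param outputActivation `"identity"` or `"softmax"`.
#' @return validated spec list.
#' @export
modelSpec <- function(convFilters = c(64, 64, 128),
                      kernels = c(30, 10, 10),
                      pools = c(4, 4, 4),
                      strides = c(1, 1, 1),
                      dilations = c(1, 1, 1),
                      fcWidths = c(128, 64),
                      dropout = 0.2, batchnorm = FALSE,
                      lr = 1e-3, batchSize = 64, epochs = 40,
                      patience = 10, lrDecayFactor = 0.5,
                      lrDecayPatience = 5, outputDim = 1,
                      outputActivation = c("identity", "softmax")) {
  spec <- as.list(environment())
  spec$outputActivation <- match.arg(outputActivation)
  if (length(spec$convFilters) != 3 || length(spec$fcWidths) != 2)
    stop("expected 3 conv blocks and 2 FC layers")
  if (any(c(spec$convFilters, spec$kernels, spec$pools, spec$strides,
            spec$dilations, spec$fcWidths, spec$batchSize,
            spec$outputDim) <= 0))
    stop("all layer sizes must be positive")
  if (spec$dropout < 0 || spec$dropout >= 1) stop("dropout must be in [0,1)")
  spec
}

heUniform <- function(nin, nout) {
  lim <- sqrt(6 / nin)
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

convGeom <- function(L, k, stride, dilation) {
  span <- (k - 1) * dilation + 1
  if (span > L) stop(sprintf("kernel span %d exceeds input length %d",
                             span, L))
  list(span = span, Lout = (L - span) %/% stride + 1L)
}

#' Build an untrained sequence-to-expression network
#'
#' @param spec list from [modelSpec()].
#' @param inputShape list with `seqLen` (bp of concatenated one-hot
#'   input) and `numFeatures` (numeric covariate count).
#' @param seed integer; weight initialisation seed.
#' @return a [SeqExprModel-class].
#' @export
buildModel <- function(spec = modelSpec(), inputShape, seed = 1L) {
  set.seed(seed)
  L <- inputShape$seqLen
  Cin <- 4L
  weights <- list()
  for (b in 1:3) {
    g <- convGeom(L, spec$kernels[b], spec$strides[b], spec$dilations[b])
    weights[[paste0("convW", b)]] <-
      heUniform(spec$kernels[b] * Cin, spec$convFilters[b])
    weights[[paste0("convB", b)]] <- numeric(spec$convFilters[b])
    if (spec$batchnorm) {
      weights[[paste0("convG", b)]] <- rep(1, spec$convFilters[b])
      weights[[paste0("convBe", b)]] <- numeric(spec$convFilters[b])
    }
    L <- g$Lout %/% spec$pools[b]
    if (L < 1) stop("pooling reduced the sequence below 1 position")
    Cin <- spec$convFilters[b]
  }
  flat <- L * Cin
  hin <- flat + inputShape$numFeatures
  for (f in 1:2) {
    weights[[paste0("fcW", f)]] <- heUniform(hin, spec$fcWidths[f])
    weights[[paste0("fcB", f)]] <- numeric(spec$fcWidths[f])
    if (spec$batchnorm) {
      weights[[paste0("fcG", f)]] <- rep(1, spec$fcWidths[f])
      weights[[paste0("fcBe", f)]] <- numeric(spec$fcWidths[f])
    }
    hin <- spec$fcWidths[f]
  }
  weights$outW <- heUniform(hin, spec$outputDim)
  weights$outB <- numeric(spec$outputDim)
  new("SeqExprModel", spec = spec, weights = weights,
      norm = list(), history = data.frame(),
      inputShape = c(inputShape, list(flat = flat)))
}

## ---- layer primitives -------------------------------------------------
## conv activations live in C x (n*L) matrices (channel-major; column
## index = (sample-1)*L + position) so im2col gathers copy contiguous
## columns; FC activations are ordinary n x width matrices

seqToLayout <- function(X) {
  # X: array (n, 4, L) -> 4 x (n*L)
  matrix(aperm(X, c(2, 3, 1)), nrow = 4L)
}

convStarts <- function(n, L, k, stride, dilation) {
  g <- convGeom(L, k, stride, dilation)
  starts <- (seq_len(g$Lout) - 1L) * stride + 1L
  list(cols = rep((seq_len(n) - 1L) * L, each = g$Lout) + starts,
       Lout = g$Lout)
}

convForward <- function(B, n, L, W, b, k, stride, dilation) {
  cs <- convStarts(n, L, k, stride, dilation)
  Xcol <- cpp_im2col(B, cs$cols, k, dilation)
  Z <- crossprod(W, Xcol) + b
  list(Z = Z, cols = cs$cols, Lout = cs$Lout, Xcol = Xcol)
}

convBackward <- function(dZ, cf, Bdim, W, k, dilation) {
  dW <- tcrossprod(cf$Xcol, dZ)
  db <- rowSums(dZ)
  dXcol <- W %*% dZ
  dB <- cpp_conv_bwd_scatter(dXcol, cf$cols, Bdim[1], k, dilation, Bdim[2])
  list(dB = dB, dW = dW, db = db)
}

poolForward <- function(Z, n, L, p) {
  out <- cpp_pool_fwd(Z, n, L, p)
  list(M = out$M, J = out$J, L2 = out$L2, p = p, n = n, L = L)
}

poolBackward <- function(dM, pf, nColsIn, C) {
  cpp_pool_bwd(dM, pf$J, pf$n, pf$L, pf$p)
}

## batch norm over channels: rows for conv activations, columns for FC
bnForward <- function(A, gamma, beta, training, run, byRow,
                      momentum = 0.9, eps = 1e-5) {
  if (byRow) {
    if (training) {
      mu <- rowMeans(A)
      v <- rowMeans((A - mu)^2)
      run$mean <- momentum * run$mean + (1 - momentum) * mu
      run$var <- momentum * run$var + (1 - momentum) * v
    } else { mu <- run$mean; v <- run$var }
    xhat <- (A - mu) / sqrt(v + eps)
    out <- xhat * gamma + beta
  } else {
    if (training) {
      mu <- colMeans(A)
      v <- colMeans(sweep(A, 2, mu)^2)
      run$mean <- momentum * run$mean + (1 - momentum) * mu
      run$var <- momentum * run$var + (1 - momentum) * v
    } else { mu <- run$mean; v <- run$var }
    xhat <- sweep(sweep(A, 2, mu), 2, sqrt(v + eps), "/")
    out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  }
  list(out = out, xhat = xhat, v = v, run = run, eps = eps, byRow = byRow)
}

bnBackward <- function(dOut, cache, gamma) {
  if (cache$byRow) {
    m <- ncol(dOut)
    dGamma <- rowSums(dOut * cache$xhat)
    dBeta <- rowSums(dOut)
    dXhat <- dOut * gamma
    iv <- 1 / sqrt(cache$v + cache$eps)
    dA <- (dXhat - rowMeans(dXhat) -
             cache$xhat * rowMeans(dXhat * cache$xhat)) * iv
  } else {
    m <- nrow(dOut)
    dGamma <- colSums(dOut * cache$xhat)
    dBeta <- colSums(dOut)
    dXhat <- sweep(dOut, 2, gamma, "*")
    iv <- 1 / sqrt(cache$v + cache$eps)
    dA <- sweep(dXhat -
                  matrix(colMeans(dXhat), m, ncol(dOut), byrow = TRUE) -
                  sweep(cache$xhat, 2, colMeans(dXhat * cache$xhat), "*"),
                2, iv, "*")
  }
  list(dA = dA, dGamma = dGamma, dBeta = dBeta)
}

softmaxRows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

## full forward pass; returns prediction and (optionally) caches
netForward <- function(W, spec, Bseq, num, n, L0, training = FALSE,
                       dropMask = NULL, run = NULL, cache = FALSE) {
  caches <- list()
  B <- Bseq; L <- L0
  for (b in 1:3) {
    cf <- convForward(B, n, L, W[[paste0("convW", b)]],
                      W[[paste0("convB", b)]], spec$kernels[b],
                      spec$strides[b], spec$dilations[b])
    Z <- cf$Z
    bnc <- NULL
    if (spec$batchnorm) {
      bnc <- bnForward(Z, W[[paste0("convG", b)]], W[[paste0("convBe", b)]],
                       training, run[[paste0("conv", b)]], byRow = TRUE)
      if (training) run[[paste0("conv", b)]] <- bnc$run
      Z <- bnc$out
    }
    R <- Z > 0
    Z <- Z * R
    pf <- poolForward(Z, n, cf$Lout, spec$pools[b])
    M <- pf$M
    dm <- NULL
    if (training && spec$dropout > 0) {
      dm <- dropMask[[paste0("conv", b)]]
      M <- M * dm
    }
    if (cache) caches[[b]] <- list(Bdim = dim(B), Lin = L, cf = cf,
                                   bnc = bnc, relu = R, pf = pf, dm = dm)
    else caches[[b]] <- list()
    B <- M; L <- pf$L2
  }
  Cfin <- nrow(B)
  Flat <- t(matrix(B, nrow = Cfin * L))
  H <- cbind(Flat, num)
  fcCaches <- list()
  for (f in 1:2) {
    Hin <- H
    Z <- sweep(H %*% W[[paste0("fcW", f)]], 2, W[[paste0("fcB", f)]], "+")
    bnc <- NULL
    if (spec$batchnorm) {
      bnc <- bnForward(Z, W[[paste0("fcG", f)]], W[[paste0("fcBe", f)]],
                       training, run[[paste0("fc", f)]], byRow = FALSE)
      if (training) run[[paste0("fc", f)]] <- bnc$run
      Z <- bnc$out
    }
    R <- Z > 0
    Z <- Z * R
    dm <- NULL
    if (training && spec$dropout > 0) {
      dm <- dropMask[[paste0("fc", f)]]
      Z <- Z * dm
    }
    fcCaches[[f]] <- list(Hin = Hin, bnc = bnc, relu = R, dm = dm)
    H <- Z
  }
  Zout <- sweep(H %*% W$outW, 2, W$outB, "+")
  pred <- if (spec$outputActivation == "softmax") softmaxRows(Zout) else Zout
  list(pred = pred, caches = caches, fcCaches = fcCaches, Hlast = H,
       Lfin = L, Cfin = Cfin, run = run)
}

netBackward <- function(W, spec, fw, dPred, n) {
  grads <- list()
  dZout <- if (spec$outputActivation == "softmax") {
    S <- fw$pred
    S * (dPred - rowSums(dPred * S))
  } else dPred
  grads$outW <- crossprod(fw$Hlast, dZout)
  grads$outB <- colSums(dZout)
  dH <- tcrossprod(dZout, W$outW)
  for (f in 2:1) {
    cc <- fw$fcCaches[[f]]
    if (!is.null(cc$dm)) dH <- dH * cc$dm
    dZ <- dH * cc$relu
    if (spec$batchnorm) {
      bb <- bnBackward(dZ, cc$bnc, W[[paste0("fcG", f)]])
      grads[[paste0("fcG", f)]] <- bb$dGamma
      grads[[paste0("fcBe", f)]] <- bb$dBeta
      dZ <- bb$dA
    }
    grads[[paste0("fcW", f)]] <- crossprod(cc$Hin, dZ)
    grads[[paste0("fcB", f)]] <- colSums(dZ)
    dH <- tcrossprod(dZ, W[[paste0("fcW", f)]])
  }
  dFlat <- dH[, seq_len(fw$Cfin * fw$Lfin), drop = FALSE]
  dB <- matrix(t(dFlat), nrow = fw$Cfin)
  for (b in 3:1) {
    cc <- fw$caches[[b]]
    if (!is.null(cc$dm)) dB <- dB * cc$dm
    dZ <- poolBackward(dB, cc$pf, n * cc$cf$Lout, nrow(dB))
    dZ <- dZ * cc$relu
    if (spec$batchnorm) {
      bb <- bnBackward(dZ, cc$bnc, W[[paste0("convG", b)]])
      grads[[paste0("convG", b)]] <- bb$dGamma
      grads[[paste0("convBe", b)]] <- bb$dBeta
      dZ <- bb$dA
    }
    cb <- convBackward(dZ, cc$cf, cc$Bdim, W[[paste0("convW", b)]],
                       spec$kernels[b], spec$dilations[b])
    grads[[paste0("convW", b)]] <- cb$dW
    grads[[paste0("convB", b)]] <- cb$db
    dB <- cb$dB
  }
  grads
}

adamInit <- function(W) lapply(W, function(w) list(m = w * 0, v = w * 0))

adamStep <- function(W, grads, state, lr, t, b1 = 0.9, b2 = 0.999,
                     eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st <- state[[nm]]
    st$m <- b1 * st$m + (1 - b1) * g
    st$v <- b2 * st$v + (1 - b2) * g^2
    mh <- st$m / (1 - b1^t)
    vh <- st$v / (1 - b2^t)
    W[[nm]] <- W[[nm]] - lr * mh / (sqrt(vh) + eps)
    state[[nm]] <- st
  }
  list(W = W, state = state)
}

#' 80/10/10 split plan
#'
#' Random, disjoint and exhaustive partition of the gene ids into
#' training, validation and test sets.
#'
#' @param ids character gene ids.
#' @param fractions numeric length 3 summing to 1.
#' @param seed integer.
#' @return list with `train`, `validation`, `test`.
#' @export
splitPlan <- function(ids, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3)
  set.seed(seed)
  ids <- sample(ids)
  n <- length(ids)
  nTr <- round(fractions[1] * n)
  nVa <- round(fractions[2] * n)
  list(train = ids[seq_len(nTr)],
       validation = ids[nTr + seq_len(nVa)],
       test = ids[(nTr + nVa + 1):n])
}

#' Train the sequence-to-expression network
#'
#' Mini-batch Adam on mean squared error. Numeric covariates and targets
#' are standardised with training-split statistics. The returned model
#' carries the weights from the epoch with minimal validation MSE and the
#' full per-epoch history; training stops early after `patience` epochs
#' without improvement.
#'
#' @param model untrained [SeqExprModel-class] from [buildModel()].
#' @param features list from [cohortFeatures()].
#' @param targets named numeric vector (or genes x k matrix for
#'   multi-output models) covering the split ids.
#' @param split list from [splitPlan()].
#' @param seed integer; batching/dropout seed.
#' @param verbose print per-epoch MSE.
#' @param initWeights optional weight list (e.g. from a previously
#'   trained model of identical architecture) to start from.
#' @return trained [SeqExprModel-class].
#' @export
trainModel <- function(model, features, targets, split, seed = 1L,
                       verbose = FALSE, initWeights = NULL) {
  spec <- model@spec
  set.seed(seed)
  ids <- features$geneIds
  Y <- if (is.matrix(targets)) targets else
    matrix(targets, ncol = 1, dimnames = list(names(targets), NULL))
  tr <- match(split$train, ids); va <- match(split$validation, ids)
  stopifnot(!anyNA(tr), !anyNA(va))
  numMu <- colMeans(features$num[tr, , drop = FALSE])
  numSd <- apply(features$num[tr, , drop = FALSE], 2, stats::sd)
  numSd[numSd == 0] <- 1
  numStd <- sweep(sweep(features$num, 2, numMu), 2, numSd, "/")
  yMu <- colMeans(Y[split$train, , drop = FALSE])
  ySd <- apply(Y[split$train, , drop = FALSE], 2, stats::sd)
  ySd[ySd == 0] <- 1
  if (spec$outputActivation == "softmax") { yMu[] <- 0; ySd[] <- 1 }
  Ystd <- sweep(sweep(Y, 2, yMu), 2, ySd, "/")
  L0 <- dim(features$seq)[3]
  W <- if (is.null(initWeights)) model@weights else initWeights
  state <- adamInit(W)
  run <- NULL
  if (spec$batchnorm) {
    run <- list()
    for (b in 1:3) run[[paste0("conv", b)]] <-
      list(mean = numeric(spec$convFilters[b]),
           var = rep(1, spec$convFilters[b]))
    for (f in 1:2) run[[paste0("fc", f)]] <-
      list(mean = numeric(spec$fcWidths[f]), var = rep(1, spec$fcWidths[f]))
  }
  model@norm <- list(numMu = numMu, numSd = numSd, yMu = yMu, ySd = ySd,
                     run = run)

  seqLayout <- function(idx) {
    sub <- features$seq[idx, , , drop = FALSE]
    seqToLayout(sub)
  }
  valA <- seqLayout(va)
  valNum <- numStd[va, , drop = FALSE]
  valY <- Ystd[split$validation, , drop = FALSE]

  evalMse <- function(Wcur, runCur) {
    fw <- netForward(Wcur, spec, valA, valNum, length(va), L0,
                     training = FALSE, run = runCur)
    mean((fw$pred - valY)^2)
  }

  history <- data.frame(epoch = integer(), train_mse = numeric(),
                        val_mse = numeric())
  best <- list(mse = Inf, W = W, run = run)
  t <- 0L
  stall <- 0L
  lrCur <- spec$lr
  lrStall <- 0L
  nTr <- length(tr)
  for (epoch in seq_len(spec$epochs)) {
    ord <- sample(nTr)
    epochLoss <- 0
    nb <- 0L
    for (s in seq(1, nTr, by = spec$batchSize)) {
      sel <- tr[ord[s:min(s + spec$batchSize - 1, nTr)]]
      n <- length(sel)
      A <- seqLayout(sel)
      num <- numStd[sel, , drop = FALSE]
      yb <- Ystd[ids[sel], , drop = FALSE]
      dropMask <- NULL
      if (spec$dropout > 0) {
        keep <- 1 - spec$dropout
        dropMask <- list()
        # pool output rows per conv block: recompute geometry
        Lc <- L0
        for (b in 1:3) {
          g <- convGeom(Lc, spec$kernels[b], spec$strides[b],
                        spec$dilations[b])
          Lc <- g$Lout %/% spec$pools[b]
          dropMask[[paste0("conv", b)]] <-
            matrix(stats::rbinom(n * Lc * spec$convFilters[b], 1, keep),
                   spec$convFilters[b], n * Lc) / keep
        }
        for (f in 1:2) dropMask[[paste0("fc", f)]] <-
          matrix(stats::rbinom(n * spec$fcWidths[f], 1, keep),
                 n, spec$fcWidths[f]) / keep
      }
      fw <- netForward(W, spec, A, num, n, L0, training = TRUE,
                       dropMask = dropMask, run = run, cache = TRUE)
      run <- fw$run
      err <- fw$pred - yb
      loss <- mean(err^2)
      if (!is.finite(loss))
        stop("non-finite training loss; check inputs/learning rate")
      dPred <- 2 * err / length(err)
      grads <- netBackward(W, spec, fw, dPred, n)
      t <- t + 1L
      upd <- adamStep(W, grads, state, lrCur, t)
      W <- upd$W; state <- upd$state
      epochLoss <- epochLoss + loss; nb <- nb + 1L
    }
    vm <- evalMse(W, run)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_mse = epochLoss / nb,
                                         val_mse = vm))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      epochLoss / nb, vm))
    if (vm < best$mse - 1e-6) {
      best <- list(mse = vm, W = W, run = run)
      stall <- 0L
      lrStall <- 0L
    } else {
      stall <- stall + 1L
      lrStall <- lrStall + 1L
    }
    if (lrStall >= spec$lrDecayPatience && lrCur > 1e-5) {
      lrCur <- max(1e-5, lrCur * spec$lrDecayFactor)
      lrStall <- 0L
    }
    if (stall >= spec$patience) break
  }
  model@weights <- best$W
  model@norm$run <- best$run
  model@history <- history
  model
}

#' Predict with a trained network
#'
#' @param model trained [SeqExprModel-class].
#' @param features list from [cohortFeatures()] (or a compatible list
#'   with `seq` and `num`).
#' @param idx optional gene indices/ids to score.
#' @param chunk evaluation batch size.
#' @return numeric vector (or matrix for multi-output models) on the
#'   target scale used in training.
#' @export
predictExpression <- function(model, features, idx = NULL, chunk = 1024L) {
  spec <- model@spec
  nAll <- dim(features$seq)[1]
  idx <- if (is.null(idx)) seq_len(nAll)
         else if (is.character(idx)) match(idx, features$geneIds) else idx
  nm <- model@norm
  num <- sweep(sweep(features$num[idx, , drop = FALSE], 2, nm$numMu),
               2, nm$numSd, "/")
  L0 <- dim(features$seq)[3]
  out <- NULL
  for (s in seq(1, length(idx), by = chunk)) {
    sub <- idx[s:min(s + chunk - 1, length(idx))]
    A <- seqToLayout(features$seq[sub, , , drop = FALSE])
    fw <- netForward(model@weights, spec, A, num[s:min(s + chunk - 1,
                                                       length(idx)), ,
                                                 drop = FALSE],
                     length(sub), L0, training = FALSE, run = nm$run)
    out <- rbind(out, fw$pred)
  }
  pred <- sweep(sweep(out, 2, nm$ySd, "*"), 2, nm$yMu, "+")
  if (spec$outputDim == 1) {
    pred <- as.numeric(pred)
    names(pred) <- features$geneIds[idx]
  } else rownames(pred) <- features$geneIds[idx]
  pred
}

#' Goodness-of-fit report
#'
#' Coefficient of determination R^2 = 1 - SS_residual / SS_total, where
#' SS_residual is the squared prediction error (so R^2 can be negative),
#' plus the two-tailed F-test of the observed-on-predicted univariate
#' regression.
#'
#' @param predictions,observations equal-length numeric vectors, n >= 3.
#' @return list with `mse`, `r_squared`, `f_statistic`, `f_pvalue`, `n`.
#' @export
evaluateModel <- function(predictions, observations) {
  stopifnot(length(predictions) == length(observations),
            length(observations) >= 3)
  ssTot <- sum((observations - mean(observations))^2)
  if (ssTot == 0) stop("zero total sum of squares")
  ssRes <- sum((observations - predictions)^2)
  n <- length(observations)
  if (stats::sd(predictions) == 0) {
    fst <- 0; fp <- 1
  } else {
    fit <- stats::lm(observations ~ predictions)
    a <- suppressWarnings(stats::anova(fit))
    fst <- a$`F value`[1]; fp <- a$`Pr(>F)`[1]
  }
  list(mse = ssRes / n, r_squared = 1 - ssRes / ssTot,
       f_statistic = fst, f_pvalue = fp, n = n)
}

knnRegress <- function(xTrain, yTrain, xNew, k) {
  d2 <- outer(rowSums(xNew^2), rowSums(xTrain^2), "+") -
    2 * xNew %*% t(xTrain)
  apply(d2, 1, function(dr) mean(yTrain[order(dr)[seq_len(k)]]))
}

#' Shallow regression baselines
#'
#' Tabular baselines over k-mer and numeric features: plain linear
#' regression (falls back to ridge with a warning on singular designs),
#' glmnet ridge/lasso/elastic-net (lambda selected on the validation
#' split), random forest, epsilon-SVR and k-nearest-neighbour regression.
#' Hyperparameters are selected on the validation split by MSE; the test
#' split is scored once.
#'
#' @param x feature matrix with rownames; `y` named numeric targets.
#' @param y named numeric vector.
#' @param algorithm one of `"linear"`, `"ridge"`, `"lasso"`,
#'   `"elasticnet"`, `"randomforest"`, `"svm"`, `"knn"`.
#' @param split list from [splitPlan()].
#' @param ... passed to the underlying fitter.
#' @return list: evaluation report (as [evaluateModel()]) plus
#'   `predictions`.
#' @export
shallowBaseline <- function(x, y, algorithm = c("linear", "ridge", "lasso",
                                                "elasticnet",
                                                "randomforest", "svm",
                                                "knn"),
                            split, ...) {
  algorithm <- match.arg(algorithm)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  xt <- x[split$train, , drop = FALSE]; yt <- y[split$train]
  xv <- x[split$validation, , drop = FALSE]; yv <- y[split$validation]
  xs <- x[split$test, , drop = FALSE]; ys <- y[split$test]
  glmnetPick <- function(alpha) {
    fit <- glmnet::glmnet(xt, yt, alpha = alpha)
    pv <- stats::predict(fit, xv)
    best <- which.min(colMeans((pv - yv)^2))
    list(fit = fit, s = fit$lambda[best])
  }
  pred <- switch(algorithm,
    linear = {
      df <- data.frame(y = yt, xt, check.names = FALSE)
      fit <- stats::lm(y ~ ., data = df)
      if (anyNA(stats::coef(fit))) {
        warning("singular design for linear regression; using ridge")
        g <- glmnetPick(0)
        as.numeric(stats::predict(g$fit, xs, s = g$s))
      } else
        as.numeric(stats::predict(fit,
                                  data.frame(xs, check.names = FALSE)))
    },
    ridge = { g <- glmnetPick(0)
              as.numeric(stats::predict(g$fit, xs, s = g$s)) },
    lasso = { g <- glmnetPick(1)
              as.numeric(stats::predict(g$fit, xs, s = g$s)) },
    elasticnet = { g <- glmnetPick(0.5)
                   as.numeric(stats::predict(g$fit, xs, s = g$s)) },
    randomforest = {
      fit <- randomForest::randomForest(xt, yt, ...)
      as.numeric(stats::predict(fit, xs))
    },
    svm = {
      fit <- e1071::svm(xt, yt, ...)
      as.numeric(stats::predict(fit, xs))
    },
    knn = {
      ks <- c(3, 5, 10, 20)
      ks <- ks[ks <= nrow(xt)]
      mses <- vapply(ks, function(k)
        mean((knnRegress(xt, yt, xv, k) - yv)^2), 0)
      knnRegress(xt, yt, xs, ks[which.min(mses)])
    })
  rep <- evaluateModel(pred, ys)
  rep$predictions <- stats::setNames(pred, split$test)
  rep$algorithm <- algorithm
  rep
}

#' Predict the codon vector from regulatory DNA
#'
#' Trains the network with a 64-way softmax head on codon probability
#' targets using only the regulatory one-hot input (the numeric branch is
#' fed zeros), and reports the pooled test R^2 over all (gene, codon)
#' pairs after removing each codon's global mean (so a cohort without
#' coupling scores ~0).
#'
#' @param features list from [cohortFeatures()].
#' @param split list from [splitPlan()].
#' @param spec optional [modelSpec()] override (outputDim/activation are
#'   forced).
#' @param seed integer.
#' @return list with `model`, `pooled_r2`, `predictions` (test genes x
#'   64, rows sum to 1).
#' @export
codonFromRegulatory <- function(features, split, spec = NULL, seed = 1L) {
  if (is.null(spec)) spec <- modelSpec()
  spec$outputDim <- 64L
  spec$outputActivation <- "softmax"
  targets <- features$num[, CODONS, drop = FALSE]
  feats <- features
  feats$num <- matrix(0, nrow(features$num), 1,
                      dimnames = list(rownames(features$num), "null"))
  model <- buildModel(spec, list(seqLen = dim(features$seq)[3],
                                 numFeatures = 1L), seed = seed)
  model <- trainModel(model, feats, targets, split, seed = seed)
  pred <- predictExpression(model, feats, idx = split$test)
  obs <- targets[split$test, , drop = FALSE]
  mu <- colMeans(targets[split$train, , drop = FALSE])
  ssRes <- sum((obs - pred)^2)
  ssTot <- sum(sweep(obs, 2, mu)^2)
  list(model = model, pooled_r2 = 1 - ssRes / ssTot, predictions = pred)
}

#' Random hyperparameter search
#'
#' Lightweight replacement for a full tree-structured search: trains one
#' model per candidate spec (or per seed) and keeps the one with the
#' minimal validation MSE, mirroring the validation-selection rule used
#' for model choice.
#'
#' @param candidates list of [modelSpec()] lists.
#' @param features,targets,split as in [trainModel()].
#' @param seeds one seed per candidate (recycled).
#' @param verbose print per-candidate validation MSE.
#' @return list with `model` (best trained model), `valMse`, `index`.
#' @export
randomSearch <- function(candidates, features, targets, split,
                         seeds = seq_along(candidates),
                         verbose = FALSE) {
  stopifnot(length(candidates) >= 1)
  seeds <- rep_len(seeds, length(candidates))
  best <- NULL
  for (i in seq_along(candidates)) {
    spec <- candidates[[i]]
    m <- buildModel(spec, list(seqLen = dim(features$seq)[3],
                               numFeatures = ncol(features$num)),
                    seed = seeds[i])
    m <- trainModel(m, features, targets, split, seed = seeds[i])
    vm <- min(m@history$val_mse)
    if (verbose) message(sprintf("candidate %d: val MSE %.4f", i, vm))
    if (is.null(best) || vm < best$valMse)
      best <- list(model = m, valMse = vm, index = i)
  }
  best
}


#' Consecutive training: sequence branch first, then joint fine-tuning
#'
#' Stage one trains the network with the numeric covariates zeroed, so
#' the convolutional branch must explain the target on its own; stage
#' two restarts from those weights with the full inputs. This
#' weight-transfer schedule counters the tendency of the (easier)
#' numeric branch to dominate early training and leave the motif
#' filters underdeveloped.
#'
#' @param spec a [modelSpec()] list; stage-one epochs/patience can be
#'   overridden with `stage1Epochs`/`stage1Patience`.
#' @param features,targets,split,seed as in [trainModel()].
#' @param stage1Epochs,stage1Patience stage-one schedule (defaults: the
#'   spec's epochs, run in full).
#' @param nRestarts independent stage-one restarts; the restart with the
#'   minimal stage-one validation MSE seeds stage two (validation-MSE
#'   model selection, as used for architecture choice).
#' @param keepStage1 also return the selected sequence-only stage-one
#'   model (useful for sequence-attribution analyses, where a model
#'   that never saw the numeric covariates gives the cleanest occlusion
#'   relevance).
#' @return trained [SeqExprModel-class] (stage-two model; its history
#'   carries `stage1_epochs` and `stage1_val_mse` attributes), or, with
#'   `keepStage1`, a list with `model` and `stage1Model`.
#' @export
trainConsecutive <- function(spec, features, targets, split, seed = 1L,
                             stage1Epochs = spec$epochs,
                             stage1Patience = stage1Epochs,
                             nRestarts = 1L, keepStage1 = FALSE) {
  seqOnly <- features
  seqOnly$num <- features$num * 0
  spec1 <- spec
  spec1$epochs <- stage1Epochs
  spec1$patience <- stage1Patience
  shape <- list(seqLen = dim(features$seq)[3],
                numFeatures = ncol(features$num))
  best1 <- NULL
  vals <- numeric(0)
  for (r in seq_len(nRestarts)) {
    sr <- seed + (r - 1L) * 100L
    m1 <- buildModel(spec1, shape, seed = sr)
    m1 <- trainModel(m1, seqOnly, targets, split, seed = sr)
    v <- min(m1@history$val_mse)
    vals <- c(vals, v)
    if (is.null(best1) || v < best1$val) best1 <- list(m = m1, val = v)
  }
  m2 <- buildModel(spec, shape, seed = seed + 1L)
  m2 <- trainModel(m2, features, targets, split, seed = seed + 1L,
                   initWeights = best1$m@weights)
  attr(m2@history, "stage1_epochs") <- nrow(best1$m@history)
  attr(m2@history, "stage1_val_mse") <- vals
  if (keepStage1) list(model = m2, stage1Model = best1$m) else m2
}
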