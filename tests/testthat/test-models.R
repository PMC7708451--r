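test_that("model spec validation rejects degenerate architectures", {
  expect_error(modelSpec(convFilters = c(0, 4, 4)), "positive")
  expect_error(modelSpec(convFilters = c(4, 4)), "3 conv blocks")
  expect_error(modelSpec(dropout = 1), "dropout")
})

test_that("split plans are disjoint, exhaustive and seed-stable", {
  ids <- sprintf("g%03d", 1:97)
  sp <- splitPlan(ids, seed = 5)
  expect_setequal(c(sp$train, sp$validation, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$train, sp$validation), 0)
  sp2 <- splitPlan(ids, seed = 5)
  expect_identical(sp, sp2)
  expect_false(identical(sp, splitPlan(ids, seed = 6)))
})

test_that("forward pass is deterministic and finite without dropout", {
  set.seed(11)
  spec <- tinyModelSpec()
  n <- 4; L <- 60
  X <- array(0, c(n, 4, L))
  for (i in 1:n) X[cbind(i, sample(4, L, TRUE), 1:L)] <- 1
  feats <- list(seq = X, num = matrix(rnorm(n * 5), n),
                geneIds = paste0("g", 1:n))
  m <- buildModel(spec, list(seqLen = L, numFeatures = 5), seed = 2)
  m@norm <- list(numMu = rep(0, 5), numSd = rep(1, 5), yMu = 0, ySd = 1,
                 run = NULL)
  p1 <- predictExpression(m, feats)
  p2 <- predictExpression(m, feats)
  expect_identical(p1, p2)
  expect_true(all(is.finite(p1)))
})

test_that("backprop gradients match numeric differentiation", {
  set.seed(12)
  spec <- modelSpec(convFilters = c(3, 3, 4), kernels = c(5, 3, 3),
                    pools = c(2, 2, 2), fcWidths = c(6, 4), dropout = 0)
  n <- 3; L <- 40
  X <- array(0, c(n, 4, L))
  for (i in 1:n) X[cbind(i, sample(4, L, TRUE), 1:L)] <- 1
  num <- matrix(rnorm(n * 4), n)
  y <- matrix(rnorm(n), n, 1)
  model <- buildModel(spec, list(seqLen = L, numFeatures = 4), seed = 3)
  A <- regGrammar:::seqToLayout(X)
  W <- model@weights
  lossFn <- function(W) {
    fw <- regGrammar:::netForward(W, spec, A, num, n, L)
    mean((fw$pred - y)^2)
  }
  fw <- regGrammar:::netForward(W, spec, A, num, n, L, training = TRUE,
                                cache = TRUE)
  gr <- regGrammar:::netBackward(W, spec, fw, 2 * (fw$pred - y) / n, n)
  worst <- 0
  for (nm in names(gr)) {
    g <- gr[[nm]]
    for (j in sample(length(g), min(4, length(g)))) {
      Wp <- W; Wp[[nm]][j] <- Wp[[nm]][j] + 1e-6
      Wm <- W; Wm[[nm]][j] <- Wm[[nm]][j] - 1e-6
      ng <- (lossFn(Wp) - lossFn(Wm)) / 2e-6
      worst <- max(worst, abs(ng - g[j]) / max(abs(ng), abs(g[j]), 1e-8))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("training on constant targets converges to near-zero MSE", {
  set.seed(13)
  spec <- tinyModelSpec(epochs = 80, patience = 80, lr = 1e-2,
                        lrDecayPatience = 80)
  n <- 48; L <- 60
  X <- array(0, c(n, 4, L))
  for (i in 1:n) X[cbind(i, sample(4, L, TRUE), 1:L)] <- 1
  ids <- sprintf("g%02d", 1:n)
  feats <- list(seq = X, num = matrix(rnorm(n * 5), n,
                                      dimnames = list(ids, NULL)),
                geneIds = ids)
  y <- setNames(rep(0, n), ids)
  sp <- list(train = ids[1:36], validation = ids[37:42],
             test = ids[43:48])
  m <- buildModel(spec, list(seqLen = L, numFeatures = 5), seed = 4)
  m <- trainModel(m, feats, y, sp, seed = 5)
  # constant target: sd on the training split is 0 so targets pass
  # through unstandardised; validation MSE must collapse
  expect_lte(min(m@history$val_mse), 1e-3)
})

test_that("selected checkpoint has the minimal validation MSE", {
  set.seed(14)
  spec <- tinyModelSpec(epochs = 6)
  n <- 40; L <- 60
  X <- array(0, c(n, 4, L))
  for (i in 1:n) X[cbind(i, sample(4, L, TRUE), 1:L)] <- 1
  ids <- sprintf("g%02d", 1:n)
  feats <- list(seq = X, num = matrix(rnorm(n * 5), n,
                                      dimnames = list(ids, NULL)),
                geneIds = ids)
  y <- setNames(rnorm(n), ids)
  sp <- list(train = ids[1:30], validation = ids[31:35],
             test = ids[36:40])
  m <- buildModel(spec, list(seqLen = L, numFeatures = 5), seed = 6)
  m <- trainModel(m, feats, y, sp, seed = 7)
  pred <- predictExpression(m, feats, idx = sp$validation)
  yMu <- m@norm$yMu; ySd <- m@norm$ySd
  valMse <- mean(((pred - yMu) / ySd - (y[sp$validation] - yMu) / ySd)^2)
  expect_equal(valMse, min(m@history$val_mse), tolerance = 1e-8)
})

test_that("evaluation implements R^2 = 1 - SSres/SStot with F-test", {
  ev <- evaluateModel(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ev$r_squared, 1)
  ev2 <- evaluateModel(c(2, 2, 2), c(1, 2, 3))
  expect_equal(ev2$r_squared, 0)
  # worked triple: SSres = 8, SStot = 2 -> R^2 = -3
  ev3 <- evaluateModel(c(3, 2, 1), c(1, 2, 3))
  expect_equal(ev3$r_squared, -3)
  expect_error(evaluateModel(c(1, 2, 3), c(2, 2, 2)), "total sum")
  # brute-force agreement on random vectors
  set.seed(15)
  for (i in 1:5) {
    p <- rnorm(30); o <- rnorm(30)
    ev <- evaluateModel(p, o)
    expect_equal(ev$r_squared,
                 1 - sum((o - p)^2) / sum((o - mean(o))^2),
                 tolerance = 1e-12)
    ct <- summary(lm(o ~ p))
    expect_equal(ev$f_statistic, unname(ct$fstatistic[1]),
                 tolerance = 1e-9)
  }
})

test_that("shallow baselines recover an exact linear signal", {
  set.seed(16)
  n <- 120
  x <- matrix(rpois(n * 6, 5), n,
              dimnames = list(sprintf("g%03d", 1:n), paste0("k", 1:6)))
  y <- setNames(3 * x[, 2] - 1, rownames(x))
  sp <- splitPlan(rownames(x), seed = 8)
  r <- shallowBaseline(x, y, "linear", sp)
  expect_gte(r$r_squared, 0.999)
  rr <- shallowBaseline(x, y, "ridge", sp)
  expect_gte(rr$r_squared, 0.9)
  rk <- shallowBaseline(x, y + rnorm(n, 0, 0.1), "knn", sp)
  expect_gte(rk$r_squared, 0.5)
})

test_that("singular designs fall back from linear to ridge", {
  set.seed(17)
  n <- 40
  x <- matrix(rnorm(n * 3), n,
              dimnames = list(sprintf("g%03d", 1:n), paste0("k", 1:3)))
  x <- cbind(x, dup = x[, 1])   # exactly collinear
  y <- setNames(x[, 1] + rnorm(n, 0, 0.01), rownames(x))
  sp <- splitPlan(rownames(x), seed = 9)
  expect_warning(r <- shallowBaseline(x, y, "linear", sp), "singular")
  expect_gte(r$r_squared, 0.8)
})

test_that("codon-vector prediction head emits normalised probabilities", {
  co <- tinyCohort()
  feats <- cohortFeatures(co)
  sp <- splitPlan(feats$geneIds, seed = 30)
  out <- codonFromRegulatory(feats, sp,
                             spec = tinyModelSpec(epochs = 2),
                             seed = 31)
  expect_equal(unname(rowSums(out$predictions)),
               rep(1, length(sp$test)), tolerance = 1e-6)
  expect_true(is.finite(out$pooled_r2))
  expect_equal(dim(out$predictions), c(length(sp$test), 64L))
})
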