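test_that("compound scaling follows the power law", {
  expect_equal(compoundScale(1.2, 1.1, 1.15, 0), c(d = 1, w = 1, r = 1))
  expect_equal(compoundScale(1.2, 1.1, 1.15, 1),
               c(d = 1.2, w = 1.1, r = 1.15))
  expect_equal(compoundScale(1.2, 1.1, 1.15, 2),
               c(d = 1.2 * 1.2, w = 1.1 * 1.1, r = 1.15 * 1.15))
  # multiplicative in phi
  s1 <- compoundScale(1.2, 1.1, 1.15, 0.7)
  s2 <- compoundScale(1.2, 1.1, 1.15, 1.3)
  expect_equal(s1 * s2, compoundScale(1.2, 1.1, 1.15, 2), tolerance = 1e-12)
  expect_error(compoundScale(-1, 1.1, 1.15, 1), "positive")
})

test_that("depthwise separable convolution composes depthwise and pointwise", {
  set.seed(1)
  # identity depthwise kernel + identity pointwise reproduces the input
  x <- randTensor(6, 6, 4, 2)
  dwI <- array(0, c(3, 3, 4)); dwI[2, 2, ] <- 1
  pwI <- diag(4)
  expect_equal(depthwiseSeparable(x, dwI, pwI), x, tolerance = 1e-12)
  # parameter count formula
  expect_equal(dscParamCount(8, 3, 16), 200)
  expect_equal(dscParamCount(8, 3, 16, bias = TRUE), 216)
  # random case against the naive two-stage oracle
  x <- randTensor(5, 5, 8, 1)
  dw <- array(rnorm(9 * 8), c(3, 3, 8))
  pw <- matrix(rnorm(8 * 16), 8, 16)
  got <- depthwiseSeparable(x, dw, pw)
  mid <- refDWConv(x, dw, 1, 1)
  ref <- refConv2d(mid, array(pw, c(1, 1, 8, 16)), NULL, 1, 0)
  expect_equal(got, ref, tolerance = 1e-5)
  expect_error(depthwiseSeparable(x, array(0, c(4, 4, 8)), pw), "odd")
})

test_that("the SE gate is a sigmoid bottleneck over pooled channels", {
  # zero weights and biases give sigma(0) = 0.5 everywhere
  w0 <- list(W1 = matrix(0, 2, 8), b1 = numeric(2),
             W2 = matrix(0, 8, 2), b2 = numeric(8))
  x <- randTensor(5, 5, 8, 3, seed = 2)
  expect_equal(seGate(x, w0), matrix(0.5, 8, 3))
  # gates lie strictly inside (0, 1)
  w <- seGateInit(8, reduction = 4, seed = 3)
  g <- seGate(x, w)
  expect_true(all(g > 0 & g < 1))
  # a spatially constant map reduces to a scalar two-layer forward pass
  cvec <- rnorm(8)
  xc <- array(rep(cvec, each = 16), c(4, 4, 8, 1))
  oracle <- sigmoidRef(w$W2 %*% pmax(w$W1 %*% cvec + w$b1, 0) + w$b2)
  expect_equal(seGate(xc, w), matrix(oracle, 8, 1), tolerance = 1e-10)
  expect_error(seGateInit(8, reduction = 16), "hidden")
})

test_that("MBConv blocks respect the inverted-residual contract", {
  x <- randTensor(8, 8, 6, 2, seed = 4)
  # stride 2: spatial size halves and no residual is added
  b2 <- newMBConv(6, 6, 3, stride = 2, expansion = 6, seed = 5)
  y2 <- mbconvForward(b2, x)
  expect_equal(dim(y2), c(4, 4, 6, 2))
  # zero projection weights with skip: block is the identity
  b1 <- newMBConv(6, 6, 3, stride = 1, expansion = 6, seed = 6)
  b1$project$params$w[] <- 0
  expect_equal(mbconvForward(b1, x), x, tolerance = 1e-12)
  # residual decomposition: y - F(x) = x
  b3 <- newMBConv(6, 6, 5, stride = 1, expansion = 6, seed = 7)
  y <- mbconvForward(b3, x)
  b3$skip <- FALSE
  fx <- mbconvForward(b3, x)
  b3$skip <- TRUE
  expect_equal(y - fx, x, tolerance = 1e-6)
  # channel change disables the skip: output shape follows cout
  b4 <- newMBConv(6, 9, 3, stride = 1, expansion = 6, seed = 8)
  expect_equal(dim(mbconvForward(b4, x)), c(8, 8, 9, 2))
})

test_that("CBAM attention maps gate without amplifying", {
  x <- randTensor(6, 6, 16, 2, seed = 9)
  cb <- newCBAM(16, reduction = 4, seed = 10)
  mc <- cbamChannel(x, cb)
  expect_equal(dim(mc), c(16, 2))
  expect_true(all(mc > 0 & mc < 1))
  fp <- applyChannelGate(x, mc)
  ms <- cbamSpatial(fp, cb)
  expect_equal(dim(ms), c(6, 6, 1, 2))
  expect_true(all(ms > 0 & ms < 1))
  # serial composition equals the one-shot refinement
  expect_identical(applySpatialGate(fp, ms), cbamApply(x, cb))
  # multiplicative refinement: zero in, zero out; magnitudes never grow
  expect_equal(cbamApply(array(0, dim(x)), cb), array(0, dim(x)))
  f2 <- cbamApply(x, cb)
  expect_true(all(abs(f2) < abs(x) | x == 0))

  # spatially constant input: Mc = sigma(2 * MLP(c)) since avg = max pools
  cvec <- rnorm(16)
  xc <- array(rep(cvec, each = 25), c(5, 5, 16, 1))
  mlp <- cb$params$W2 %*% pmax(cb$params$W1 %*% cvec + cb$params$b1, 0) +
    cb$params$b2
  expect_equal(cbamChannel(xc, cb), matrix(sigmoidRef(2 * mlp), 16, 1),
               tolerance = 1e-10)
  # channel-uniform refined tensor: Ms constant in the interior, where the
  # 7x7 window sees no zero padding
  xu <- array(rep(rnorm(1), 9 * 9 * 16), c(9, 9, 16, 1))
  msu <- cbamSpatial(xu, cb)
  expect_lt(diff(range(msu[4:6, 4:6, 1, 1])), 1e-12)

  # full-map oracle: explicit pooling, shared MLP and 7x7 convolution
  mcRef <- {
    savg <- apply(x, c(3, 4), mean)
    smax <- apply(x, c(3, 4), max)
    m1 <- cb$params$W2 %*% pmax(cb$params$W1 %*% savg + cb$params$b1, 0) +
      cb$params$b2
    m2 <- cb$params$W2 %*% pmax(cb$params$W1 %*% smax + cb$params$b1, 0) +
      cb$params$b2
    sigmoidRef(m1 + m2)
  }
  expect_equal(mc, mcRef, tolerance = 1e-6)
  cp <- array(0, c(6, 6, 2, 2))
  cp[, , 1, ] <- apply(fp, c(1, 2, 4), mean)
  cp[, , 2, ] <- apply(fp, c(1, 2, 4), max)
  msRef <- sigmoidRef(refConv2d(cp, cb$params$wsp, cb$params$bsp, 1, 3))
  expect_equal(ms, msRef, tolerance = 1e-5)
})

test_that("the assembled network reproduces the stated shape ladder", {
  net <- buildNetwork(seed = 1)
  x <- randTensor(224, 224, 3, 1, seed = 11)
  env <- net@modules
  stem <- ctgvision:::nnForward(env$stemConv, x, FALSE)
  expect_equal(dim(stem), c(112, 112, 32, 1))
  r <- ctgvision:::netForward(net, x, taps = TRUE)
  expect_equal(dim(r$logits), c(2, 1))
  expect_equal(env$poolDims[1:3], c(7, 7, 320))   # final 320 x 7 x 7 feature
  # stage taps for the embedding analysis
  expect_equal(nrow(r$taps$stage3), 28 * 28 * 40)
  expect_equal(nrow(r$taps$stage6), 7 * 7 * 192)
  expect_equal(nrow(r$taps$postCBAM), 320)
  expect_error(networkForward(net, randTensor(64, 64, 3, 1)), "224")
  # expanded head variant widens the pooled feature to 1280
  net2 <- buildNetwork(seed = 1, expandedHead = TRUE)
  r2 <- networkForward(net2, x)
  expect_equal(dim(r2), c(2, 1))
  expect_gt(networkParameterCount(net2), networkParameterCount(net))
})

test_that("early stopping bookkeeping follows the patience rule", {
  s <- earlyStopSchedule(c(1.0, 0.9, 0.95, 0.96, 0.97, 0.98, 0.99),
                         patience = 5)
  expect_equal(s$stopEpoch, 7)
  expect_equal(s$bestEpoch, 2)
  s2 <- earlyStopSchedule(c(1, 0.9, 0.8, 0.7), patience = 5)
  expect_equal(s2$stopEpoch, 4)
  expect_equal(s2$bestEpoch, 4)
})

test_that("training is deterministic and learns a trivial contrast", {
  # two obviously different input patterns
  set.seed(12)
  n <- 16
  x <- array(0, c(224, 224, 3, n))
  y <- rep(0:1, n / 2)
  for (i in seq_len(n)) {
    block <- if (y[i] == 1) 1:112 else 113:224
    x[block, , , i] <- x[block, , , i] + 3
    x[, , , i] <- x[, , , i] + rnorm(224 * 224 * 3, sd = 0.3)
  }
  cfgT <- trainConfig(learningRate = 1e-3, batchSize = 8, maxEpochs = 2,
                      seed = 99)
  netA <- buildNetwork(seed = 3)
  fitA <- trainModel(netA, x[, , , 1:12], y[1:12], cfgT,
                     valX = x[, , , 13:16], valY = y[13:16])
  netB <- buildNetwork(seed = 3)
  fitB <- trainModel(netB, x[, , , 1:12], y[1:12], cfgT,
                     valX = x[, , , 13:16], valY = y[13:16])
  expect_identical(fitA$net@modules$fc$params$w, fitB$net@modules$fc$params$w)
  expect_identical(fitA$history, fitB$history)
  expect_equal(nrow(fitA$history), 2)
  sc <- predictScores(fitA$net, x)
  expect_true(all(sc > 0 & sc < 1))
  expect_error(trainModel(netA, x[, , , integer(0), drop = FALSE],
                          integer(0), cfgT, x, y), "empty")
})
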