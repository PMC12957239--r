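#' Compound scaling of depth, width and resolution
#'
#' EfficientNet scales a baseline architecture jointly along network depth,
#' width and input resolution with a single coefficient `phi`: the depth,
#' width and resolution factors are `alpha^phi`, `beta^phi` and `gamma^phi`.
#'
#' @param alpha,beta,gamma positive per-dimension base coefficients.
#' @param phi non-negative compound coefficient.
#' @return named numeric `c(d, w, r)` of scaling factors.
#' @examples
#' compoundScale(1.2, 1.1, 1.15, phi = 0) # c(1, 1, 1)
#' compoundScale(1.2, 1.1, 1.15, phi = 1)
#' @export
compoundScale <- function(alpha, beta, gamma, phi) {
  if (any(c(alpha, beta, gamma) <= 0))
    stop("alpha, beta and gamma must be positive")
  if (phi < 0) stop("phi must be non-negative")
  c(d = alpha^phi, w = beta^phi, r = gamma^phi)
}

#' Depthwise separable convolution
#'
#' Factorizes a spatial convolution into a per-channel depthwise step
#' followed by a pointwise (1x1) channel-mixing step:
#' `DSC(X) = PointwiseConv(DepthwiseConv(X))`.
#'
#' @param x input tensor, array with dim `c(H, W, C, N)`.
#' @param dw depthwise kernel, array `c(k, k, C)`; `k` must be odd
#'   (same-padding `k %/% 2` is applied).
#' @param pw pointwise weights, matrix `(C, Cout)`.
#' @param bias optional numeric vector of length `Cout`.
#' @param stride stride of the depthwise step.
#' @return output tensor `c(Ho, Wo, Cout, N)`.
#' @seealso [dscParamCount()]
#' @export
depthwiseSeparable <- function(x, dw, pw, bias = NULL, stride = 1L) {
  k <- dim(dw)[1]
  if (k %% 2 == 0) stop("kernel size must be odd")
  if (dim(dw)[2] != k) stop("depthwise kernel must be square")
  if (dim(dw)[3] != dim(x)[3]) stop("depthwise kernel channel mismatch")
  h <- .cpp_dwconv_fwd(x, dw, as.integer(stride), k %/% 2L)
  wp <- array(pw, dim = c(1, 1, nrow(pw), ncol(pw)))
  .cpp_conv2d_fwd(h, wp, bias, 1L, 0L)
}

#' Parameter count of a depthwise separable convolution
#'
#' @param cin input channels; @param k odd kernel size; @param cout output
#'   channels; @param bias include pointwise bias terms?
#' @return integer parameter count `cin*k^2 + cin*cout (+ cout)`.
#' @examples
#' dscParamCount(8, 3, 16) # 72 + 128 = 200
#' @export
dscParamCount <- function(cin, k, cout, bias = FALSE) {
  cin * k^2 + cin * cout + if (bias) cout else 0L
}

#' Initialize and apply a squeeze-and-excitation gate
#'
#' The SE gate recalibrates channels of a feature map `F` via
#' `Mc = sigmoid(W2 . relu(W1 . GAP(F)))`, a two-layer bottleneck over the
#' globally average-pooled channel vector. `seGate` returns the gate values;
#' the caller applies them multiplicatively (see [applyChannelGate()]).
#'
#' @param channels number of feature channels `C`.
#' @param reduction bottleneck reduction ratio; the hidden width is
#'   `floor(channels / reduction)` and must be at least 1.
#' @param seed optional seed for weight initialization.
#' @return `seGateInit`: list of weights `W1, b1, W2, b2`;
#'   `seGate`: gate matrix `(C, N)` with entries strictly in (0, 1).
#' @examples
#' w <- seGateInit(8, reduction = 4, seed = 1)
#' x <- array(rnorm(5 * 5 * 8 * 2), c(5, 5, 8, 2))
#' g <- seGate(x, w)
#' stopifnot(all(g > 0 & g < 1))
#' @export
seGateInit <- function(channels, reduction = 4L, seed = NULL) {
  hidden <- floor(channels / reduction)
  if (hidden < 1L)
    stop("reduction ", reduction, " leaves no hidden units for ",
         channels, " channels")
  if (!is.null(seed)) set.seed(seed)
  list(W1 = nnInitDense(hidden, channels), b1 = numeric(hidden),
       W2 = nnInitDense(channels, hidden), b2 = numeric(channels))
}

#' @rdname seGateInit
#' @param x feature tensor `c(H, W, C, N)`.
#' @param weights weight list from `seGateInit` (or hand-built of the same
#'   shapes).
#' @export
seGate <- function(x, weights) {
  s <- .cpp_gap_fwd(x)
  h <- pmax(weights$W1 %*% s + weights$b1, 0)
  sigmoidMat(weights$W2 %*% h + weights$b2)
}

#' Apply a channel gate or spatial map multiplicatively
#'
#' @param x feature tensor `c(H, W, C, N)`.
#' @param gate channel gate matrix `(C, N)` (for `applyChannelGate`) or
#'   spatial map tensor `c(H, W, 1, N)` (for `applySpatialGate`).
#' @return gated tensor of the same shape as `x`.
#' @export
applyChannelGate <- function(x, gate) .cpp_scale_ch_fwd(x, gate)

#' @rdname applyChannelGate
#' @export
applySpatialGate <- function(x, gate) .cpp_scale_sp_fwd(x, gate)

#' Create a mobile inverted bottleneck (MBConv) block
#'
#' The block expands channels with a 1x1 convolution (skipped when
#' `expansion = 1`), applies a depthwise spatial convolution with
#' squeeze-and-excitation recalibration, projects back with a 1x1
#' convolution, and adds the inverted residual `Y = X + F(X)` iff
#' `stride = 1` and input and output channel counts agree. Batch
#' normalization and SiLU follow each convolution except the projection,
#' which is normalized but not activated.
#'
#' @param cin,cout input/output channels.
#' @param kernel odd depthwise kernel size (3 or 5).
#' @param stride spatial stride (1 or 2).
#' @param expansion channel expansion factor (1 for MBConv1, 6 for MBConv6).
#' @param seReduction SE bottleneck ratio relative to `cin`.
#' @param seed optional initialization seed.
#' @return an opaque block object for [mbconvForward()].
#' @export
newMBConv <- function(cin, cout, kernel, stride, expansion,
                      seReduction = 4L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nnMBConv(cin, cout, kernel, stride, expansion, seReduction)
}

#' Forward pass through an MBConv block
#'
#' @param block object from [newMBConv()].
#' @param x input tensor `c(H, W, cin, N)`.
#' @param training use batch statistics (TRUE) or running statistics (FALSE)
#'   in the batch-normalization layers.
#' @return output tensor `c(Ho, Wo, cout, N)`.
#' @export
mbconvForward <- function(block, x, training = FALSE) {
  stopifnot(inherits(block, "nnModule"), block$type == "mbconv")
  nnForward(block, x, training)
}

#' Convolutional block attention (CBAM)
#'
#' CBAM refines a feature map `F` in two serial stages. The channel module
#' pools `F` spatially by both average and max pooling, passes each pooled
#' vector through a shared two-layer MLP, and gates channels with
#' `Mc = sigmoid(MLP(AvgPool(F)) + MLP(MaxPool(F)))`. The spatial module
#' pools the channel-refined `F' = Mc (x) F` across channels (mean and max),
#' convolves the 2-channel map with a 7x7 kernel, and gates positions with
#' `Ms = sigmoid(conv7x7([AvgPool(F'); MaxPool(F')]))`. The refined output
#' is `F'' = Ms (x) F'`; both maps lie strictly in (0, 1), so refinement
#' never increases any activation magnitude.
#'
#' @param channels number of feature channels.
#' @param reduction channel-MLP bottleneck ratio.
#' @param seed optional initialization seed.
#' @return `newCBAM`: an opaque module. `cbamChannel`: channel map `(C, N)`.
#'   `cbamSpatial`: spatial map `c(H, W, 1, N)` computed from the
#'   channel-refined tensor. `cbamApply`: the refined tensor `F''`.
#' @examples
#' cb <- newCBAM(16, reduction = 4, seed = 1)
#' x <- array(rnorm(6 * 6 * 16 * 2), c(6, 6, 16, 2))
#' f2 <- cbamApply(x, cb)
#' stopifnot(all(abs(f2) <= abs(x)))
#' @export
newCBAM <- function(channels, reduction = 16L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nnCBAM(channels, reduction)
}

#' @rdname newCBAM
#' @param x feature tensor `c(H, W, C, N)`; for `cbamSpatial` the
#'   channel-refined tensor `F'`.
#' @param cbam module from `newCBAM`.
#' @export
cbamChannel <- function(x, cbam) {
  stopifnot(inherits(cbam, "nnModule"), cbam$type == "cbam")
  savg <- .cpp_gap_fwd(x)
  smax <- .cpp_gmax_fwd(x)$val
  ha <- pmax(cbam$params$W1 %*% savg + cbam$params$b1, 0)
  hm <- pmax(cbam$params$W1 %*% smax + cbam$params$b1, 0)
  sigmoidMat((cbam$params$W2 %*% ha + cbam$params$b2) +
             (cbam$params$W2 %*% hm + cbam$params$b2))
}

#' @rdname newCBAM
#' @export
cbamSpatial <- function(x, cbam) {
  stopifnot(inherits(cbam, "nnModule"), cbam$type == "cbam")
  if (dim(x)[1] < 1 || dim(x)[2] < 1) stop("spatial dimensions must be >= 1")
  cp <- .cpp_chpool_fwd(x)
  sigmoidMat(.cpp_conv2d_fwd(cp$out, cbam$params$wsp, cbam$params$bsp, 1L, 3L))
}

#' @rdname newCBAM
#' @export
cbamApply <- function(x, cbam) {
  mc <- cbamChannel(x, cbam)
  fp <- applyChannelGate(x, mc)
  ms <- cbamSpatial(fp, cbam)
  applySpatialGate(fp, ms)
}

# Canonical B0 stage schedule: widths / repeats / kernels / strides /
# expansion. Stage 1 is MBConv1; the rest are MBConv6.
.B0_STAGES <- data.frame(
  stage = 1:7,
  blockType = c("MBConv1", rep("MBConv6", 6)),
  kernel = c(3L, 3L, 5L, 3L, 5L, 5L, 3L),
  stride = c(1L, 2L, 2L, 2L, 1L, 2L, 1L),
  outChannels = c(16L, 24L, 40L, 80L, 112L, 192L, 320L),
  repeats = c(1L, 2L, 2L, 3L, 3L, 4L, 1L),
  expansion = c(1L, rep(6L, 6))
)

#' Build the CBAM-enhanced EfficientNet-B0 classifier
#'
#' Assembles the network: a 3x3 stride-2 stem convolution with batch
#' normalization and SiLU mapping a `3 x 224 x 224` input to `32 x 112 x 112`;
#' the B0 schedule of MBConv stages (widths 16/24/40/80/112/192/320, repeats
#' 1/2/2/3/3/4/1, kernels 3/3/5/3/5/5/3, strides 1/2/2/2/1/2/1) ending at a
#' `320 x 7 x 7` feature map; a CBAM block refining that feature; adaptive
#' average pooling to a 320-vector; dropout; and a fully connected layer to
#' `numClasses` logits. With `expandedHead = TRUE` a 1x1 convolution to 1280
#' channels (with BN and SiLU) is inserted between CBAM and pooling.
#'
#' Weights are randomly initialized from the given seed; no pretrained
#' weights are required or downloaded.
#'
#' @param numClasses number of output logits (default 2:
#'   reassuring / non-reassuring).
#' @param seed initialization seed.
#' @param cbamReduction CBAM channel-MLP reduction ratio.
#' @param seReduction SE reduction ratio inside MBConv blocks.
#' @param dropout dropout probability before the final layer (active only
#'   during training).
#' @param expandedHead insert the canonical 1x1 expansion to 1280 channels
#'   before pooling.
#' @return A [CTGNetwork-class] object.
#' @examples
#' net <- buildNetwork(seed = 1)
#' x <- array(rnorm(224 * 224 * 3), c(224, 224, 3, 1))
#' logits <- networkForward(net, x)
#' dim(logits) # 2 x 1
#' @export
buildNetwork <- function(numClasses = 2L, seed = 0L, cbamReduction = 16L,
                         seReduction = 4L, dropout = 0.2,
                         expandedHead = FALSE) {
  set.seed(seed)
  env <- new.env(parent = emptyenv())
  env$stemConv <- nnConv(3L, 32L, 3L, stride = 2L, pad = 1L)
  env$stemBN <- nnBN(32L)
  env$stemSiLU <- nnModule("silu")
  blocks <- list()
  cin <- 32L
  blockStage <- integer()
  for (s in seq_len(nrow(.B0_STAGES))) {
    st <- .B0_STAGES[s, ]
    for (r in seq_len(st$repeats)) {
      stride <- if (r == 1L) st$stride else 1L
      blocks[[length(blocks) + 1L]] <-
        nnMBConv(cin, st$outChannels, st$kernel, stride, st$expansion,
                 seReduction)
      blockStage <- c(blockStage, st$stage)
      cin <- st$outChannels
    }
  }
  env$blocks <- blocks
  env$blockStage <- blockStage
  env$cbam <- nnCBAM(320L, cbamReduction)
  if (expandedHead) {
    env$headConv <- nnConv(320L, 1280L, 1L)
    env$headBN <- nnBN(1280L)
    env$headSiLU <- nnModule("silu")
    featDim <- 1280L
  } else {
    featDim <- 320L
  }
  env$dropout <- nnModule("dropout", p = dropout)
  env$fc <- nnLinear(featDim, as.integer(numClasses))

  prims <- c(nnCollect(env$stemConv), nnCollect(env$stemBN))
  for (b in blocks) prims <- c(prims, nnCollect(b))
  prims <- c(prims, nnCollect(env$cbam))
  if (expandedHead) prims <- c(prims, nnCollect(env$headConv), nnCollect(env$headBN))
  prims <- c(prims, nnCollect(env$fc))
  env$prims <- prims

  spec <- data.frame(
    stage = c("stem", paste0("stage", .B0_STAGES$stage), "cbam", "head"),
    operator = c("conv3x3 s2 + BN + SiLU",
                 paste0(.B0_STAGES$blockType, " k", .B0_STAGES$kernel,
                        " s", .B0_STAGES$stride, " x", .B0_STAGES$repeats),
                 "channel + spatial attention",
                 if (expandedHead) "conv1x1 1280 + pool + FC" else "pool + FC"),
    outChannels = c(32L, .B0_STAGES$outChannels, 320L, as.integer(numClasses)),
    outSize = c(112L, 112L, 56L, 28L, 14L, 14L, 7L, 7L, 7L, 1L)
  )
  new("CTGNetwork", spec = spec, modules = env,
      numClasses = as.integer(numClasses), seed = as.integer(seed),
      config = list(cbamReduction = cbamReduction, seReduction = seReduction,
                    dropout = dropout, expandedHead = expandedHead))
}

# full forward; taps optionally records intermediate features for the staged
# embedding analysis: raw input, end of stage 3, end of stage 6, and the
# post-CBAM pooled vector.
netForward <- function(net, x, training = FALSE, taps = FALSE) {
  env <- net@modules
  d <- dim(x)
  if (length(d) != 4 || d[1] != 224 || d[2] != 224 || d[3] != 3)
    stop("input must be a 224 x 224 x 3 x N tensor")
  tapList <- list()
  if (taps) tapList$raw <- matrix(x, nrow = prod(d[1:3]))
  h <- nnForward(env$stemConv, x, training)
  h <- nnForward(env$stemBN, h, training)
  h <- nnForward(env$stemSiLU, h, training)
  for (i in seq_along(env$blocks)) {
    h <- nnForward(env$blocks[[i]], h, training)
    if (taps) {
      isLast <- i == length(env$blocks) || env$blockStage[i + 1L] != env$blockStage[i]
      if (isLast && env$blockStage[i] == 3L)
        tapList$stage3 <- matrix(h, nrow = prod(dim(h)[1:3]))
      if (isLast && env$blockStage[i] == 6L)
        tapList$stage6 <- matrix(h, nrow = prod(dim(h)[1:3]))
    }
  }
  h <- nnForward(env$cbam, h, training)
  if (!is.null(env$headConv)) {
    h <- nnForward(env$headConv, h, training)
    h <- nnForward(env$headBN, h, training)
    h <- nnForward(env$headSiLU, h, training)
  }
  pooled <- .cpp_gap_fwd(h)                      # (feat, N)
  if (taps) tapList$postCBAM <- pooled
  env$poolDims <- dim(h)
  p <- nnForward(env$dropout, pooled, training)
  logits <- nnForward(env$fc, p, training)
  if (taps) list(logits = logits, taps = tapList) else logits
}

#' Forward pass through the network
#'
#' @param net a [CTGNetwork-class] from [buildNetwork()].
#' @param x input tensor `c(224, 224, 3, N)` (see [asBatchTensor()]).
#' @param training use batch statistics and dropout.
#' @return logits matrix `(numClasses, N)`.
#' @export
networkForward <- function(net, x, training = FALSE) {
  netForward(net, x, training = training, taps = FALSE)
}

#' Total number of trainable parameters
#' @param net a [CTGNetwork-class].
#' @return integer count.
#' @export
networkParameterCount <- function(net) {
  sum(vapply(net@modules$prims,
             function(m) sum(vapply(m$params, length, 1L)), 1))
}

# softmax cross-entropy; y is 0/1 with 1 = non_reassuring (logit row 2)
netLossGrad <- function(net, x, y, training = TRUE) {
  env <- net@modules
  logits <- netForward(net, x, training = training)
  n <- ncol(logits)
  mx <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, mx))
  p <- sweep(ex, 2, colSums(ex), "/")
  rows <- y + 1L
  loss <- -mean(log(pmax(p[cbind(rows, seq_len(n))], 1e-12)))
  onehot <- matrix(0, nrow(logits), n)
  onehot[cbind(rows, seq_len(n))] <- 1
  dlogits <- (p - onehot) / n
  list(loss = loss, probs = p, dlogits = dlogits)
}

netBackward <- function(net, dlogits) {
  env <- net@modules
  d <- nnBackward(net@modules$fc, dlogits)
  d <- nnBackward(env$dropout, d)
  pd <- env$poolDims
  d <- .cpp_gap_bwd(d, pd[1], pd[2])
  if (!is.null(env$headConv)) {
    d <- nnBackward(env$headSiLU, d)
    d <- nnBackward(env$headBN, d)
    d <- nnBackward(env$headConv, d)
  }
  d <- nnBackward(env$cbam, d)
  for (i in rev(seq_along(env$blocks)))
    d <- nnBackward(env$blocks[[i]], d)
  d <- nnBackward(env$stemSiLU, d)
  d <- nnBackward(env$stemBN, d)
  d <- nnBackward(env$stemConv, d)
  d
}

#' Training configuration
#'
#' Defaults follow the reference training protocol for clinical-scale data:
#' Adam with initial learning rate 1e-4, batch size 64, weight decay 1e-5,
#' cross-entropy loss and early stopping with patience 5 epochs on the
#' validation loss.
#'
#' @param learningRate Adam learning rate.
#' @param batchSize minibatch size (capped at the training-set size).
#' @param weightDecay L2 penalty added to gradients.
#' @param earlyStopPatience epochs without validation-loss improvement
#'   before stopping.
#' @param maxEpochs maximum number of epochs.
#' @param seed RNG seed for shuffling and dropout.
#' @return a list of class `TrainConfig`.
#' @export
trainConfig <- function(learningRate = 1e-4, batchSize = 64L,
                        weightDecay = 1e-5, earlyStopPatience = 5L,
                        maxEpochs = 30L, seed = 0L) {
  stopifnot(learningRate > 0, batchSize >= 1, weightDecay >= 0,
            earlyStopPatience >= 1, maxEpochs >= 1)
  structure(list(optimizer = "adam", loss = "cross_entropy",
                 learningRate = learningRate, batchSize = as.integer(batchSize),
                 weightDecay = weightDecay,
                 earlyStopPatience = as.integer(earlyStopPatience),
                 maxEpochs = as.integer(maxEpochs), seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Early-stopping bookkeeping
#'
#' Given a sequence of per-epoch validation losses, returns the epoch at
#' which training stops (the first epoch after which the loss has failed to
#' improve for `patience` consecutive epochs, or the last epoch) and the
#' best epoch whose weights are restored.
#'
#' @param valLoss numeric vector of validation losses by epoch.
#' @param patience consecutive non-improving epochs tolerated.
#' @return list with `stopEpoch` and `bestEpoch`.
#' @examples
#' earlyStopSchedule(c(1.0, 0.9, 0.95, 0.96, 0.97, 0.98, 0.99), patience = 5)
#' @export
earlyStopSchedule <- function(valLoss, patience = 5L) {
  best <- Inf; bestEpoch <- 0L; bad <- 0L
  for (e in seq_along(valLoss)) {
    if (valLoss[e] < best) {
      best <- valLoss[e]; bestEpoch <- e; bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) return(list(stopEpoch = e, bestEpoch = bestEpoch))
    }
  }
  list(stopEpoch = length(valLoss), bestEpoch = bestEpoch)
}

#' Train the network
#'
#' Minibatch Adam training with cross-entropy loss and early stopping on
#' the validation loss (patience per `config`); the best-epoch weights are
#' restored before returning. Fully deterministic for a fixed config seed.
#'
#' @param net a [CTGNetwork-class]; updated in place (its parameter store is
#'   an environment) and also returned.
#' @param x training tensor `c(224, 224, 3, N)`.
#' @param y integer labels, 0 = reassuring, 1 = non_reassuring.
#' @param config a [trainConfig()].
#' @param valX,valY validation split (required; early stopping monitors it).
#' @param verbose print per-epoch progress.
#' @return list with `net` and `history` (data.frame of epoch, train loss,
#'   validation loss and accuracy).
#' @export
trainModel <- function(net, x, y, config = trainConfig(), valX, valY,
                       verbose = FALSE) {
  n <- dim(x)[4]
  if (n == 0) stop("empty training data")
  if (missing(valX) || missing(valY)) stop("a validation split is required")
  y <- as.integer(y); valY <- as.integer(valY)
  set.seed(config$seed)
  bs <- min(config$batchSize, n)
  mods <- net@modules$prims
  hist <- data.frame(epoch = integer(), trainLoss = numeric(),
                     valLoss = numeric(), valAccuracy = numeric())
  best <- Inf; bestSnap <- NULL; bad <- 0L; step <- 0L
  for (epoch in seq_len(config$maxEpochs)) {
    ord <- sample.int(n)
    losses <- numeric()
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      xb <- x[, , , idx, drop = FALSE]
      nnZeroGrads(mods)
      lg <- netLossGrad(net, xb, y[idx], training = TRUE)
      netBackward(net, lg$dlogits)
      step <- step + 1L
      nnAdamStep(mods, lr = config$learningRate,
                 weightDecay = config$weightDecay, step = step)
      losses <- c(losses, lg$loss)
      if (step %% 2L == 0L) gc(FALSE)   # cap garbage between collections
    }
    nnClearCaches(mods)
    gc(FALSE)                     # bound heap growth across epochs
    val <- netEvaluate(net, valX, valY)
    hist <- rbind(hist, data.frame(epoch = epoch, trainLoss = mean(losses),
                                   valLoss = val$loss, valAccuracy = val$accuracy))
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f acc %.3f",
                      epoch, mean(losses), val$loss, val$accuracy))
    if (val$loss < best) {
      best <- val$loss; bad <- 0L
      bestSnap <- nnParamSnapshot(mods)
      bestState <- lapply(mods, function(m) list(rm = m$runMean, rv = m$runVar))
    } else {
      bad <- bad + 1L
      if (bad >= config$earlyStopPatience) break
    }
  }
  if (!is.null(bestSnap)) {
    nnParamRestore(mods, bestSnap)
    for (i in seq_along(mods)) {
      if (!is.null(bestState[[i]]$rm)) {
        mods[[i]]$runMean <- bestState[[i]]$rm
        mods[[i]]$runVar <- bestState[[i]]$rv
      }
    }
  }
  list(net = net, history = hist)
}

netEvaluate <- function(net, x, y, batch = 32L) {
  n <- dim(x)[4]
  probs <- matrix(NA_real_, net@numClasses, n)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    lg <- netLossGrad(net, x[, , , idx, drop = FALSE], y[idx], training = FALSE)
    probs[, idx] <- lg$probs
  }
  nnClearCaches(net@modules$prims)
  pred <- apply(probs, 2, which.max) - 1L
  rows <- y + 1L
  loss <- -mean(log(pmax(probs[cbind(rows, seq_len(n))], 1e-12)))
  list(loss = loss, accuracy = mean(pred == y), probs = probs)
}

#' Predicted probability of the non-reassuring class
#'
#' @param net a trained [CTGNetwork-class].
#' @param x input tensor `c(224, 224, 3, N)`.
#' @param batch evaluation minibatch size.
#' @return numeric vector of length N of positive-class probabilities.
#' @export
predictScores <- function(net, x, batch = 32L) {
  n <- dim(x)[4]
  out <- numeric(n)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    logits <- netForward(net, x[, , , idx, drop = FALSE], training = FALSE)
    mx <- apply(logits, 2, max)
    ex <- exp(sweep(logits, 2, mx))
    out[idx] <- ex[2, ] / colSums(ex)
  }
  nnClearCaches(net@modules$prims)
  out
}

#' Stack ModelInput objects into a batch tensor
#'
#' @param inputs list of [ModelInput-class] objects.
#' @return array `c(224, 224, 3, N)`.
#' @export
asBatchTensor <- function(inputs) {
  n <- length(inputs)
  out <- array(0, c(224L, 224L, 3L, n))
  for (i in seq_len(n)) out[, , , i] <- inputs[[i]]@tensor
  out
}
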