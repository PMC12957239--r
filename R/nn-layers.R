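# Internal layer-module system for the CBAM-enhanced EfficientNet-B0.
#
# A module is an environment holding `params` (named list of arrays),
# `grads` (same shapes, accumulated by the backward pass) and a forward
# cache. Tensors are arrays with dim = c(H, W, C, N). Backward passes are
# hand-derived; every kernel has a brute-force oracle in the test suite.

nnModule <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list()
  e$grads <- list()
  e$cache <- NULL
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(paste0("nn_", type), "nnModule")
  e
}

# He/Kaiming-normal initialization for convolution weights
nnInitConv <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

nnInitDense <- function(dout, din) {
  matrix(stats::rnorm(dout * din, 0, sqrt(2 / din)), dout, din)
}

# ----------------------------------------------------------- primitives ---

nnConv <- function(cin, cout, kernel, stride = 1L, pad = (kernel - 1L) %/% 2L,
                   bias = FALSE) {
  m <- nnModule("conv", cin = cin, cout = cout, kernel = kernel,
                stride = as.integer(stride), pad = as.integer(pad),
                hasBias = bias)
  m$params$w <- nnInitConv(kernel, kernel, cin, cout)
  if (bias) m$params$b <- numeric(cout)
  m
}

nnDWConv <- function(channels, kernel, stride = 1L) {
  m <- nnModule("dwconv", channels = channels, kernel = kernel,
                stride = as.integer(stride), pad = (kernel - 1L) %/% 2L)
  m$params$w <- array(stats::rnorm(kernel * kernel * channels, 0,
                                   sqrt(2 / (kernel * kernel))),
                      dim = c(kernel, kernel, channels))
  m
}

nnBN <- function(channels, eps = 1e-5, momentum = 0.1) {
  m <- nnModule("bn", channels = channels, eps = eps, momentum = momentum)
  m$params$gamma <- rep(1, channels)
  m$params$beta <- rep(0, channels)
  m$runMean <- rep(0, channels)
  m$runVar <- rep(1, channels)
  m
}

nnLinear <- function(din, dout) {
  m <- nnModule("linear", din = din, dout = dout)
  m$params$w <- nnInitDense(dout, din)
  m$params$b <- numeric(dout)
  m
}

# SE gate: hidden width floor(cBase / reduction); errors if that is zero.
nnSE <- function(channels, cBase, reduction = 4L) {
  hidden <- floor(cBase / reduction)
  if (hidden < 1L)
    stop("SE reduction ", reduction, " leaves no hidden units for ",
         cBase, " channels")
  m <- nnModule("se", channels = channels, hidden = hidden)
  m$params$W1 <- nnInitDense(hidden, channels)
  m$params$b1 <- numeric(hidden)
  m$params$W2 <- nnInitDense(channels, hidden)
  m$params$b2 <- numeric(channels)
  m
}

nnCBAM <- function(channels, reduction = 16L) {
  hidden <- floor(channels / reduction)
  if (hidden < 1L)
    stop("CBAM reduction ", reduction, " leaves no hidden units for ",
         channels, " channels")
  m <- nnModule("cbam", channels = channels, hidden = hidden)
  m$params$W1 <- nnInitDense(hidden, channels)
  m$params$b1 <- numeric(hidden)
  m$params$W2 <- nnInitDense(channels, hidden)
  m$params$b2 <- numeric(channels)
  m$params$wsp <- nnInitConv(7, 7, 2, 1)
  m$params$bsp <- 0
  m
}

nnMBConv <- function(cin, cout, kernel, stride, expansion, seReduction = 4L) {
  cexp <- cin * expansion
  m <- nnModule("mbconv", cin = cin, cout = cout, kernel = kernel,
                stride = as.integer(stride), expansion = expansion,
                skip = (stride == 1L && cin == cout))
  m$expand <- if (expansion > 1) nnConv(cin, cexp, 1L) else NULL
  m$bn1 <- if (expansion > 1) nnBN(cexp) else NULL
  m$dw <- nnDWConv(cexp, kernel, stride)
  m$bn2 <- nnBN(cexp)
  m$se <- nnSE(cexp, cBase = cin, reduction = seReduction)
  m$project <- nnConv(cexp, cout, 1L)
  m$bn3 <- nnBN(cout)
  m
}

# ------------------------------------------------------- forward/backward ---

sigmoidMat <- function(x) 1 / (1 + exp(-x))

# caches for backpropagation are kept only for training-mode forwards;
# inference passes retain no activation references
nnForward <- function(m, x, training = FALSE) {
  switch(m$type,
    conv = {
      b <- if (m$hasBias) m$params$b else NULL
      y <- .cpp_conv2d_fwd(x, m$params$w, b, m$stride, m$pad)
      if (training) m$cache <- list(x = x)
      y
    },
    dwconv = {
      y <- .cpp_dwconv_fwd(x, m$params$w, m$stride, m$pad)
      if (training) m$cache <- list(x = x)
      y
    },
    bn = {
      if (training) {
        st <- .cpp_bn_stats(x)
        m$runMean <- (1 - m$momentum) * m$runMean + m$momentum * st$mean
        nEff <- prod(dim(x)[c(1, 2, 4)])
        unbias <- if (nEff > 1) nEff / (nEff - 1) else 1
        m$runVar <- (1 - m$momentum) * m$runVar + m$momentum * st$var * unbias
        m$cache <- list(x = x, mean = st$mean, var = st$var)
        .cpp_bn_apply(x, st$mean, st$var, m$params$gamma, m$params$beta, m$eps)
      } else {
        .cpp_bn_apply(x, m$runMean, m$runVar, m$params$gamma, m$params$beta, m$eps)
      }
    },
    silu = {
      if (training) {
        r <- .cpp_silu_fwd(x, TRUE)
        m$cache <- list(x = x, sig = r$sig)
        r$y
      } else {
        .cpp_silu_fwd(x)
      }
    },
    se = {
      s <- .cpp_gap_fwd(x)                       # (C, N)
      h <- m$params$W1 %*% s + m$params$b1
      hr <- pmax(h, 0)
      g <- sigmoidMat(m$params$W2 %*% hr + m$params$b2)
      y <- .cpp_scale_ch_fwd(x, g)
      if (training) m$cache <- list(x = x, s = s, hr = hr, g = g)
      y
    },
    cbam = nnCBAMForward(m, x, training),
    mbconv = {
      h <- x
      if (!is.null(m$expand)) {
        h <- nnForward(m$expand, h, training)
        h <- nnForward(m$bn1, h, training)
        m$silu1 <- m$silu1 %||% nnModule("silu")
        h <- nnForward(m$silu1, h, training)
      }
      h <- nnForward(m$dw, h, training)
      h <- nnForward(m$bn2, h, training)
      m$silu2 <- m$silu2 %||% nnModule("silu")
      h <- nnForward(m$silu2, h, training)
      h <- nnForward(m$se, h, training)
      h <- nnForward(m$project, h, training)
      h <- nnForward(m$bn3, h, training)
      if (m$skip) h <- h + x
      h
    },
    linear = {
      if (training) m$cache <- list(x = x)       # x: (din, N)
      m$params$w %*% x + m$params$b
    },
    dropout = {
      if (training && m$p > 0) {
        keep <- (stats::runif(length(x)) >= m$p) / (1 - m$p)
        dim(keep) <- dim(x)
        m$cache <- list(keep = keep)
        x * keep
      } else {
        m$cache <- list(keep = NULL)
        x
      }
    },
    stop("unknown module type: ", m$type)
  )
}

nnCBAMForward <- function(m, x, training = FALSE) {
  savg <- .cpp_gap_fwd(x)
  mx <- .cpp_gmax_fwd(x)
  ha <- pmax(m$params$W1 %*% savg + m$params$b1, 0)
  hm <- pmax(m$params$W1 %*% mx$val + m$params$b1, 0)
  mlpA <- m$params$W2 %*% ha + m$params$b2
  mlpM <- m$params$W2 %*% hm + m$params$b2
  Mc <- sigmoidMat(mlpA + mlpM)                  # (C, N)
  Fp <- .cpp_scale_ch_fwd(x, Mc)
  cp <- .cpp_chpool_fwd(Fp)
  pre <- .cpp_conv2d_fwd(cp$out, m$params$wsp, m$params$bsp, 1L, 3L)
  Ms <- sigmoidMat(pre)                          # (H, W, 1, N)
  y <- .cpp_scale_sp_fwd(Fp, Ms)
  if (training)
    m$cache <- list(x = x, savg = savg, smaxVal = mx$val, smaxIdx = mx$idx,
                    ha = ha, hm = hm, Mc = Mc, Fp = Fp, cpOut = cp$out,
                    cpIdx = cp$idx, Ms = Ms)
  y
}

nnAccGrad <- function(m, name, g) {
  if (is.null(m$grads[[name]])) m$grads[[name]] <- g
  else m$grads[[name]] <- m$grads[[name]] + g
  invisible(NULL)
}

nnBackward <- function(m, dy) {
  switch(m$type,
    conv = {
      r <- .cpp_conv2d_bwd(m$cache$x, m$params$w, dy, m$stride, m$pad, m$hasBias)
      m$cache <- NULL
      nnAccGrad(m, "w", r$dw)
      if (m$hasBias) nnAccGrad(m, "b", r$db)
      r$dx
    },
    dwconv = {
      r <- .cpp_dwconv_bwd(m$cache$x, m$params$w, dy, m$stride, m$pad)
      m$cache <- NULL
      nnAccGrad(m, "w", r$dw)
      r$dx
    },
    bn = {
      r <- .cpp_bn_bwd(m$cache$x, dy, m$cache$mean, m$cache$var,
                       m$params$gamma, m$eps)
      m$cache <- NULL
      nnAccGrad(m, "gamma", r$dgamma)
      nnAccGrad(m, "beta", r$dbeta)
      r$dx
    },
    silu = {
      dx <- .cpp_silu_bwd(dy, m$cache$x, m$cache$sig)
      m$cache <- NULL
      dx
    },
    se = {
      cc <- m$cache
      m$cache <- NULL
      r <- .cpp_scale_ch_bwd(cc$x, cc$g, dy)
      dz2 <- r$ds * cc$g * (1 - cc$g)
      nnAccGrad(m, "W2", dz2 %*% t(cc$hr))
      nnAccGrad(m, "b2", rowSums(dz2))
      dh <- t(m$params$W2) %*% dz2
      dz1 <- dh * (cc$hr > 0)
      nnAccGrad(m, "W1", dz1 %*% t(cc$s))
      nnAccGrad(m, "b1", rowSums(dz1))
      ds <- t(m$params$W1) %*% dz1
      d <- dim(cc$x)
      r$dx + .cpp_gap_bwd(ds, d[1], d[2])
    },
    cbam = nnCBAMBackward(m, dy),
    mbconv = {
      dxSkip <- if (m$skip) dy else NULL
      d <- nnBackward(m$bn3, dy)
      d <- nnBackward(m$project, d)
      d <- nnBackward(m$se, d)
      d <- nnBackward(m$silu2, d)
      d <- nnBackward(m$bn2, d)
      d <- nnBackward(m$dw, d)
      if (!is.null(m$expand)) {
        d <- nnBackward(m$silu1, d)
        d <- nnBackward(m$bn1, d)
        d <- nnBackward(m$expand, d)
      }
      if (!is.null(dxSkip)) d + dxSkip else d
    },
    linear = {
      nnAccGrad(m, "w", dy %*% t(m$cache$x))
      m$cache <- NULL
      nnAccGrad(m, "b", rowSums(dy))
      t(m$params$w) %*% dy
    },
    dropout = {
      keep <- m$cache$keep
      m$cache <- NULL
      if (is.null(keep)) dy else dy * keep
    },
    stop("unknown module type: ", m$type)
  )
}

nnCBAMBackward <- function(m, dy) {
  cc <- m$cache
  m$cache <- NULL
  d <- dim(cc$x)
  rsp <- .cpp_scale_sp_bwd(cc$Fp, cc$Ms, dy)
  dpre <- rsp$dm * cc$Ms * (1 - cc$Ms)
  rc <- .cpp_conv2d_bwd(cc$cpOut, m$params$wsp, dpre, 1L, 3L, TRUE)
  nnAccGrad(m, "wsp", rc$dw)
  nnAccGrad(m, "bsp", rc$db)
  dFp <- rsp$dx + .cpp_chpool_bwd(rc$dx, cc$cpIdx, d[3])

  rch <- .cpp_scale_ch_bwd(cc$x, cc$Mc, dFp)
  dz <- rch$ds * cc$Mc * (1 - cc$Mc)             # flows to both MLP branches
  dxTotal <- rch$dx
  for (branch in c("avg", "max")) {
    hb <- if (branch == "avg") cc$ha else cc$hm
    sb <- if (branch == "avg") cc$savg else cc$smaxVal
    nnAccGrad(m, "W2", dz %*% t(hb))
    nnAccGrad(m, "b2", rowSums(dz))
    dh <- t(m$params$W2) %*% dz
    dz1 <- dh * (hb > 0)
    nnAccGrad(m, "W1", dz1 %*% t(sb))
    nnAccGrad(m, "b1", rowSums(dz1))
    dsb <- t(m$params$W1) %*% dz1
    dxTotal <- dxTotal +
      if (branch == "avg") .cpp_gap_bwd(dsb, d[1], d[2])
      else .cpp_gmax_bwd(dsb, cc$smaxIdx, d[1], d[2])
  }
  dxTotal
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ------------------------------------------------------------ housekeeping ---

# every environment reachable from a module that itself carries params
nnCollect <- function(m) {
  out <- list()
  if (length(m$params)) out <- list(m)
  for (nm in c("expand", "bn1", "dw", "bn2", "se", "project", "bn3"))
    if (!is.null(m[[nm]])) out <- c(out, nnCollect(m[[nm]]))
  out
}

nnZeroGrads <- function(mods) {
  for (m in mods) m$grads <- list()
  invisible(NULL)
}

nnClearCaches <- function(mods) {
  for (m in mods) {
    m$cache <- NULL
    for (nm in c("silu1", "silu2"))
      if (!is.null(m[[nm]])) m[[nm]]$cache <- NULL
  }
  invisible(NULL)
}

nnParamSnapshot <- function(mods) lapply(mods, function(m) m$params)

nnParamRestore <- function(mods, snap) {
  for (i in seq_along(mods)) mods[[i]]$params <- snap[[i]]
  invisible(NULL)
}

# Adam with decoupled-from-loss L2 term added to the gradient
nnAdamStep <- function(mods, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weightDecay = 0, step = 1) {
  bc1 <- 1 - beta1^step
  bc2 <- 1 - beta2^step
  for (m in mods) {
    if (is.null(m$adamM)) { m$adamM <- list(); m$adamV <- list() }
    for (k in names(m$params)) {
      g <- m$grads[[k]]
      if (is.null(g)) next
      if (weightDecay > 0) g <- g + weightDecay * m$params[[k]]
      if (is.null(m$adamM[[k]])) {
        m$adamM[[k]] <- g * 0
        m$adamV[[k]] <- g * 0
      }
      m$adamM[[k]] <- beta1 * m$adamM[[k]] + (1 - beta1) * g
      m$adamV[[k]] <- beta2 * m$adamV[[k]] + (1 - beta2) * g * g
      m$params[[k]] <- m$params[[k]] -
        lr * (m$adamM[[k]] / bc1) / (sqrt(m$adamV[[k]] / bc2) + eps)
    }
  }
  invisible(NULL)
}
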