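# Brute-force reference implementations used as independent oracles.
# These deliberately use plain nested loops and none of the package's
# computational kernels.

# reference dense 2-d convolution; x (H,W,C,N), w (kh,kw,Cin,Cout)
refConv2d <- function(x, w, bias = NULL, stride = 1, pad = 0) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  kd <- dim(w); kh <- kd[1]; kw <- kd[2]; Cout <- kd[4]
  Ho <- (H + 2 * pad - kh) %/% stride + 1
  Wo <- (W + 2 * pad - kw) %/% stride + 1
  y <- array(0, c(Ho, Wo, Cout, N))
  for (n in 1:N) for (co in 1:Cout) for (oh in 1:Ho) for (ow in 1:Wo) {
    acc <- 0
    for (ci in 1:C) for (ki in 1:kh) for (kj in 1:kw) {
      hi <- (oh - 1) * stride - pad + ki
      wi <- (ow - 1) * stride - pad + kj
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
        acc <- acc + x[hi, wi, ci, n] * w[ki, kj, ci, co]
    }
    y[oh, ow, co, n] <- acc + if (is.null(bias)) 0 else bias[co]
  }
  y
}

# reference depthwise convolution; w (k,k,C)
refDWConv <- function(x, w, stride = 1, pad = NULL) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  k <- dim(w)[1]
  if (is.null(pad)) pad <- k %/% 2
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  y <- array(0, c(Ho, Wo, C, N))
  for (n in 1:N) for (c in 1:C) for (oh in 1:Ho) for (ow in 1:Wo) {
    acc <- 0
    for (ki in 1:k) for (kj in 1:k) {
      hi <- (oh - 1) * stride - pad + ki
      wi <- (ow - 1) * stride - pad + kj
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
        acc <- acc + x[hi, wi, c, n] * w[ki, kj, c]
    }
    y[oh, ow, c, n] <- acc
  }
  y
}

sigmoidRef <- function(z) 1 / (1 + exp(-z))

# central finite differences of scalar-valued f at x
numGrad <- function(f, x, eps = 1e-6) {
  g <- if (is.null(dim(x))) numeric(length(x)) else array(0, dim = dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# all-pairs AUC oracle (concordant pairs, ties counted half)
refAUC <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# direct cumulative-precision AP oracle (assumes no tied scores)
refAP <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  l <- labels[ord]
  nPos <- sum(l)
  tp <- 0; ap <- 0
  for (k in seq_along(l)) {
    if (l[k]) {
      tp <- tp + 1
      ap <- ap + tp / k
    }
  }
  ap / nPos
}

randTensor <- function(..., seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- c(...)
  array(rnorm(prod(d)), d)
}
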