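# Every computational kernel is checked against a brute-force oracle and,
# for the backward passes, against central finite differences.

cpp <- function(name) get(name, envir = asNamespace("ctgvision"))

test_that("dense convolution matches the brute-force oracle", {
  set.seed(1)
  cases <- list(list(k = 3, s = 1, p = 1, cin = 3, cout = 4),
                list(k = 3, s = 2, p = 1, cin = 2, cout = 5),
                list(k = 7, s = 1, p = 3, cin = 2, cout = 1),
                list(k = 1, s = 1, p = 0, cin = 6, cout = 4))
  for (cs in cases) {
    x <- randTensor(9, 8, cs$cin, 2)
    w <- randTensor(cs$k, cs$k, cs$cin, cs$cout)
    b <- rnorm(cs$cout)
    y <- cpp(".cpp_conv2d_fwd")(x, w, b, cs$s, cs$p)
    expect_equal(y, refConv2d(x, w, b, cs$s, cs$p), tolerance = 1e-10)
    y0 <- cpp(".cpp_conv2d_fwd")(x, w, NULL, cs$s, cs$p)
    expect_equal(y0, refConv2d(x, w, NULL, cs$s, cs$p), tolerance = 1e-10)
  }
})

test_that("dense convolution backward matches finite differences", {
  set.seed(2)
  x <- randTensor(6, 5, 2, 2)
  w <- randTensor(3, 3, 2, 3)
  b <- rnorm(3)
  r <- randTensor(3, 3, 3, 2)       # random cotangent, stride 2 pad 1
  lossFn <- function(x, w, b) sum(cpp(".cpp_conv2d_fwd")(x, w, b, 2L, 1L) * r)
  dy <- r
  g <- cpp(".cpp_conv2d_bwd")(x, w, dy, 2L, 1L, TRUE)
  expect_equal(g$dx, numGrad(function(z) lossFn(z, w, b), x), tolerance = 1e-6)
  expect_equal(g$dw, numGrad(function(z) lossFn(x, z, b), w), tolerance = 1e-6)
  expect_equal(as.numeric(g$db), numGrad(function(z) lossFn(x, w, z), b),
               tolerance = 1e-6)
})

test_that("depthwise convolution matches the oracle, forward and backward", {
  set.seed(3)
  for (cfg in list(c(k = 3, s = 1), c(k = 3, s = 2), c(k = 5, s = 2))) {
    kk <- cfg[["k"]]; ss <- cfg[["s"]]
    x <- randTensor(8, 7, 3, 2)
    w <- array(rnorm(kk^2 * 3), c(kk, kk, 3))
    p <- kk %/% 2
    y <- cpp(".cpp_dwconv_fwd")(x, w, ss, p)
    expect_equal(y, refDWConv(x, w, ss, p), tolerance = 1e-10)
    r <- array(rnorm(length(y)), dim(y))
    g <- cpp(".cpp_dwconv_bwd")(x, w, r, ss, p)
    lossFn <- function(x, w) sum(cpp(".cpp_dwconv_fwd")(x, w, ss, p) * r)
    expect_equal(g$dx, numGrad(function(z) lossFn(z, w), x), tolerance = 1e-6)
    expect_equal(g$dw, numGrad(function(z) lossFn(x, z), w), tolerance = 1e-6)
  }
})

test_that("batch normalization statistics, transform and gradient are exact", {
  set.seed(4)
  x <- randTensor(5, 4, 3, 2) * 2 + 1
  st <- cpp(".cpp_bn_stats")(x)
  for (c in 1:3) {
    expect_equal(st$mean[c], mean(x[, , c, ]))
    expect_equal(st$var[c], mean((x[, , c, ] - mean(x[, , c, ]))^2))
  }
  gamma <- rnorm(3); beta <- rnorm(3); eps <- 1e-5
  y <- cpp(".cpp_bn_apply")(x, st$mean, st$var, gamma, beta, eps)
  for (c in 1:3)
    expect_equal(y[, , c, ],
                 gamma[c] * (x[, , c, ] - st$mean[c]) /
                   sqrt(st$var[c] + eps) + beta[c],
                 tolerance = 1e-12)
  # backward through the batch statistics
  r <- randTensor(5, 4, 3, 2)
  lossFn <- function(x, gamma, beta) {
    s <- cpp(".cpp_bn_stats")(x)
    sum(cpp(".cpp_bn_apply")(x, s$mean, s$var, gamma, beta, eps) * r)
  }
  g <- cpp(".cpp_bn_bwd")(x, r, st$mean, st$var, gamma, eps)
  expect_equal(g$dx, numGrad(function(z) lossFn(z, gamma, beta), x),
               tolerance = 1e-5)
  expect_equal(as.numeric(g$dgamma),
               numGrad(function(z) lossFn(x, z, beta), gamma), tolerance = 1e-6)
  expect_equal(as.numeric(g$dbeta),
               numGrad(function(z) lossFn(x, gamma, z), beta), tolerance = 1e-6)
})

test_that("SiLU activation and pooling kernels agree with plain R", {
  set.seed(5)
  x <- randTensor(4, 4, 3, 2) * 3
  expect_equal(cpp(".cpp_silu_fwd")(x), x * sigmoidRef(x), tolerance = 1e-12)
  ct <- randTensor(4, 4, 3, 2)
  dx <- cpp(".cpp_silu_bwd")(ct, x)
  expect_equal(dx, numGrad(function(z) {
    sum(z * sigmoidRef(z) * ct)
  }, x), tolerance = 1e-6)

  g <- cpp(".cpp_gap_fwd")(x)
  expect_equal(g[2, 1], mean(x[, , 2, 1]))
  mx <- cpp(".cpp_gmax_fwd")(x)
  expect_equal(mx$val[3, 2], max(x[, , 3, 2]))
  dval <- matrix(rnorm(6), 3, 2)
  dxm <- cpp(".cpp_gmax_bwd")(dval, mx$idx, 4L, 4L)
  expect_equal(sum(dxm != 0), 6)
  expect_equal(dxm[, , 3, 2][which.max(x[, , 3, 2])], dval[3, 2])

  cpools <- cpp(".cpp_chpool_fwd")(x)
  expect_equal(cpools$out[2, 3, 1, 1], mean(x[2, 3, , 1]))
  expect_equal(cpools$out[2, 3, 2, 1], max(x[2, 3, , 1]))
  dout <- randTensor(4, 4, 2, 2)
  dxc <- cpp(".cpp_chpool_bwd")(dout, cpools$idx, 3L)
  lossFn <- function(z) {
    o <- cpp(".cpp_chpool_fwd")(z)$out
    sum(o * dout)
  }
  expect_equal(dxc, numGrad(lossFn, x), tolerance = 1e-6)
})

test_that("broadcast gating kernels and their gradients are exact", {
  set.seed(6)
  x <- randTensor(3, 4, 5, 2)
  s <- matrix(runif(10), 5, 2)
  y <- cpp(".cpp_scale_ch_fwd")(x, s)
  expect_equal(y[, , 4, 2], x[, , 4, 2] * s[4, 2], tolerance = 1e-12)
  r <- randTensor(3, 4, 5, 2)
  g <- cpp(".cpp_scale_ch_bwd")(x, s, r)
  expect_equal(g$dx, numGrad(function(z) sum(cpp(".cpp_scale_ch_fwd")(z, s) * r), x),
               tolerance = 1e-6)
  expect_equal(g$ds, matrix(numGrad(function(z) sum(cpp(".cpp_scale_ch_fwd")(x, z) * r), s), 5, 2),
               tolerance = 1e-6)

  m <- array(runif(3 * 4 * 2), c(3, 4, 1, 2))
  y2 <- cpp(".cpp_scale_sp_fwd")(x, m)
  expect_equal(y2[, , 3, 1], x[, , 3, 1] * m[, , 1, 1], tolerance = 1e-12)
  g2 <- cpp(".cpp_scale_sp_bwd")(x, m, r)
  expect_equal(g2$dx, numGrad(function(z) sum(cpp(".cpp_scale_sp_fwd")(z, m) * r), x),
               tolerance = 1e-6)
  expect_equal(g2$dm, array(numGrad(function(z) sum(cpp(".cpp_scale_sp_fwd")(x, z) * r), m),
                            c(3, 4, 1, 2)), tolerance = 1e-6)
})

test_that("a full MBConv block backpropagates exact gradients", {
  set.seed(7)
  block <- newMBConv(4, 4, kernel = 3, stride = 1, expansion = 6,
                     seReduction = 4, seed = 7)
  x <- randTensor(5, 5, 4, 2)
  r <- randTensor(5, 5, 4, 2)
  y <- ctgvision:::nnForward(block, x, training = TRUE)
  ctgvision:::nnZeroGrads(ctgvision:::nnCollect(block))
  y <- ctgvision:::nnForward(block, x, training = TRUE)
  dx <- ctgvision:::nnBackward(block, r)
  lossFn <- function(z) sum(ctgvision:::nnForward(block, z, training = TRUE) * r)
  expect_equal(dx, numGrad(lossFn, x, eps = 1e-5), tolerance = 1e-4)
  # and a parameter gradient, via the depthwise weights
  dwMod <- block$dw
  gotDW <- dwMod$grads$w
  lossW <- function(z) {
    old <- dwMod$params$w
    dwMod$params$w <- z
    on.exit(dwMod$params$w <- old)
    sum(ctgvision:::nnForward(block, x, training = TRUE) * r)
  }
  expect_equal(gotDW, numGrad(lossW, dwMod$params$w, eps = 1e-5),
               tolerance = 1e-4)
})
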