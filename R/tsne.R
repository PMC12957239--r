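# Exact (non-approximated) t-SNE for small sample counts, used to embed
# staged network features in 2-D. Standard formulation: Gaussian input
# affinities calibrated per point to a target perplexity by bisection,
# symmetrized; Student-t output affinities; gradient descent with momentum
# and early exaggeration.

tsnePerplexityCalibrate <- function(D2, perplexity, tol = 1e-5, maxTries = 50) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    betaMin <- -Inf; betaMax <- Inf
    di <- D2[i, -i]
    for (tries in seq_len(maxTries)) {
      p <- exp(-di * beta)
      sumP <- sum(p)
      if (sumP == 0) { H <- 0; p[] <- 0 }
      else {
        H <- log(sumP) + beta * sum(di * p) / sumP
        p <- p / sumP
      }
      if (abs(H - logU) < tol) break
      if (H > logU) {
        betaMin <- beta
        beta <- if (is.finite(betaMax)) (beta + betaMax) / 2 else beta * 2
      } else {
        betaMax <- beta
        beta <- if (is.finite(betaMin)) (beta + betaMin) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P
}

#' Exact t-SNE embedding
#'
#' @param x numeric matrix, one row per sample.
#' @param dims output dimensionality (2).
#' @param perplexity target perplexity; capped at `(n - 1)/3`.
#' @param seed RNG seed (fixed seed gives identical coordinates).
#' @param maxIter gradient-descent iterations.
#' @return `n x dims` matrix of embedding coordinates.
#' @export
tsneExact <- function(x, dims = 2L, perplexity = 30, seed = 0L,
                      maxIter = 1000L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) stop("need at least 4 samples")
  perplexity <- min(perplexity, (n - 1) / 3)
  if (perplexity < 1) stop("too few samples for the requested perplexity")
  sq <- rowSums(x^2)
  D2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(x), 0)
  P <- tsnePerplexityCalibrate(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, .Machine$double.eps)
  withLocalSeed(seed, {
    Y <- matrix(rnorm(n * dims, sd = 1e-4), n, dims)
    dY <- matrix(0, n, dims)
    gains <- matrix(1, n, dims)
    momentum <- 0.5
    eta <- 200
    exag <- 4
    Pe <- P * exag
    for (iter in seq_len(maxIter)) {
      if (iter == 101L) { Pe <- P; momentum <- 0.8 }
      sqy <- rowSums(Y^2)
      num <- 1 / (1 + pmax(outer(sqy, sqy, "+") - 2 * tcrossprod(Y), 0))
      diag(num) <- 0
      Q <- pmax(num / sum(num), .Machine$double.eps)
      L <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      dY <- momentum * dY - eta * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}
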