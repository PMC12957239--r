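# Evaluation: confusion-matrix metrics, ROC/AUC, PR/AP, stratified k-fold
# cross-validation, staged embeddings and cohort-comparison statistics.

#' Confusion matrix from predicted and true labels
#'
#' @param predicted,truth logical or 0/1 vectors (TRUE/1 = non_reassuring),
#'   or character vectors with the canonical labels.
#' @return a [ConfusionMatrix-class].
#' @export
confusionFromLabels <- function(predicted, truth) {
  toPos <- function(v) {
    if (is.character(v)) v == "non_reassuring" else as.logical(v)
  }
  p <- toPos(predicted); t <- toPos(truth)
  stopifnot(length(p) == length(t))
  confusionMatrix2x2(tp = sum(p & t), fp = sum(p & !t),
                     fn = sum(!p & t), tn = sum(!p & !t))
}

#' Scalar metrics from a confusion matrix
#'
#' Computes the threshold-dependent metrics with Non-Reassuring as the
#' positive class: accuracy `(tp+tn)/N`, sensitivity (recall) `tp/(tp+fn)`,
#' specificity `tn/(tn+fp)`, precision `tp/(tp+fp)`, the positive-class F1
#' and the macro F1 (mean of the per-class F1 scores). Ratios with a zero
#' denominator are returned as `NaN` with a warning.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return named numeric vector `accuracy, sensitivity, specificity,
#'   precision, f1_positive, f1_macro`.
#' @examples
#' # aggregated 5-fold counts with 55 false negatives and 64 false positives
#' # over 602 non-reassuring and 1,020 reassuring recordings:
#' m <- metricsFromConfusion(confusionMatrix2x2(547, 64, 55, 956))
#' round(100 * m["accuracy"], 2) # 92.66
#' @export
metricsFromConfusion <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  tp <- cm@tp; fp <- cm@fp; fn <- cm@fn; tn <- cm@tn
  n <- tp + fp + fn + tn
  if (n == 0) stop("confusion matrix totals must be positive")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)")
      return(NaN)
    }
    num / den
  }
  sens <- ratio(tp, tp + fn, "sensitivity")
  spec <- ratio(tn, tn + fp, "specificity")
  prec <- ratio(tp, tp + fp, "precision")
  f1pos <- ratio(2 * tp, 2 * tp + fp + fn, "positive-class F1")
  f1neg <- ratio(2 * tn, 2 * tn + fn + fp, "negative-class F1")
  c(accuracy = (tp + tn) / n, sensitivity = sens, specificity = spec,
    precision = prec, f1_positive = f1pos, f1_macro = mean(c(f1pos, f1neg)))
}

#' Area under the ROC curve (rank formulation)
#'
#' AUC by the Mann-Whitney statistic with midranks for ties: the
#' probability that a random positive outranks a random negative, counting
#' ties as one half.
#'
#' @param scores numeric classifier scores (higher = more non-reassuring).
#' @param labels logical or 0/1 vector, TRUE = positive (non-reassuring).
#' @return AUC in \[0, 1\].
#' @export
rocAUC <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)                     # midranks handle ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (area under the precision-recall curve)
#'
#' Step-wise, non-interpolated AP: `sum_k (R_k - R_{k-1}) * P_k` over the
#' ranked list, evaluated at each distinct score threshold (tie-safe).
#'
#' @inheritParams rocAUC
#' @return AP in \[0, 1\].
#' @export
prAP <- function(scores, labels) {
  labels <- as.logical(labels)
  nPos <- sum(labels)
  if (nPos == 0) stop("no positive examples")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  cumTP <- cumsum(l)
  cumP <- seq_along(l)
  # thresholds = last index of each distinct score value
  thr <- which(c(s[-1] != s[-length(s)], TRUE))
  prec <- cumTP[thr] / cumP[thr]
  rec <- cumTP[thr] / nPos
  sum(diff(c(0, rec)) * prec)
}

#' Random-ranking baseline of average precision
#'
#' For a random ranking the expected precision at every recall level equals
#' the positive-class prevalence, so the baseline AP is `nPos/(nPos+nNeg)`.
#'
#' @param nPos,nNeg class counts.
#' @return the prevalence.
#' @examples
#' randomBaselineAP(602, 1020) # 0.37
#' @export
randomBaselineAP <- function(nPos, nNeg) nPos / (nPos + nNeg)

#' Stratified k-fold assignments
#'
#' Partitions indices into `k` folds with per-fold class proportions within
#' one sample of the global proportions: within each class the shuffled
#' indices are dealt out as evenly as possible, remainders going to the
#' currently smallest folds so fold sizes also stay balanced.
#'
#' @param labels logical or 0/1 class vector.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer vector of fold ids (1..k), one per sample.
#' @export
stratifiedKFold <- function(labels, k = 5L, seed = 0L) {
  labels <- as.logical(labels)
  n <- length(labels)
  if (min(sum(labels), sum(!labels)) < k)
    stop("each class must have at least k members")
  fold <- integer(n)
  withLocalSeed(seed, {
    foldSize <- integer(k)
    for (cls in c(TRUE, FALSE)) {
      idx <- sample(which(labels == cls))
      m <- length(idx)
      base <- m %/% k
      rem <- m %% k
      recipients <- order(foldSize)       # smallest folds take the remainder
      counts <- rep(base, k)
      if (rem > 0) counts[recipients[seq_len(rem)]] <- base + 1L
      pos <- 1L
      for (f in seq_len(k)) {
        if (counts[f] > 0) {
          fold[idx[pos:(pos + counts[f] - 1L)]] <- f
          pos <- pos + counts[f]
        }
        foldSize[f] <- foldSize[f] + counts[f]
      }
    }
  })
  fold
}

#' Aggregate per-fold results into a FoldReport
#'
#' @param perFold list of `list(metrics = <named numeric>,
#'   cm = <ConfusionMatrix>)`, one per fold.
#' @return a [FoldReport-class] with per-metric mean and sample SD across
#'   folds and the elementwise sum of the fold confusion matrices.
#' @export
aggregateFolds <- function(perFold) {
  if (length(perFold) < 2) stop("need at least two folds to aggregate")
  mat <- do.call(rbind, lapply(perFold, function(f) f$metrics))
  df <- as.data.frame(mat)
  df$fold <- seq_len(nrow(df))
  counts <- rowSums(vapply(perFold, function(f) confusionCounts(f$cm),
                           numeric(4)))
  new("FoldReport",
      perFold = df[, c("fold", setdiff(names(df), "fold"))],
      foldMean = colMeans(mat),
      foldSD = apply(mat, 2, sd),
      aggregated = confusionMatrix2x2(counts["tp"], counts["fp"],
                                      counts["fn"], counts["tn"]))
}

#' Layer-staged 2-D embeddings of network features
#'
#' Extracts features at four stages of the classifier — the raw input, the
#' end of backbone stage 3 (shallow), the end of stage 6 (deep) and the
#' post-attention pooled vector — and reduces each to two dimensions with
#' t-SNE (exact gradient, fixed seed), for visualizing how class
#' separability evolves through the network.
#'
#' @param net a trained [CTGNetwork-class].
#' @param x input tensor `c(224, 224, 3, N)`.
#' @param perplexity t-SNE perplexity; capped at `(N - 1)/3`.
#' @param seed RNG seed for the embedding initialization.
#' @param maxIter t-SNE iterations.
#' @param batch forward-pass minibatch size.
#' @return named list of four `N x 2` matrices: `raw`, `stage3`, `stage6`,
#'   `postCBAM`.
#' @export
stagedEmbeddings <- function(net, x, perplexity = 30, seed = 0L,
                             maxIter = 1000L, batch = 32L) {
  n <- dim(x)[4]
  if (n < 8) stop("too few samples for a meaningful embedding")
  feats <- NULL
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    r <- netForward(net, x[, , , idx, drop = FALSE], training = FALSE,
                    taps = TRUE)
    if (is.null(feats)) feats <- lapply(r$taps, function(m) matrix(NA_real_, nrow(m), n))
    for (nm in names(r$taps)) feats[[nm]][, idx] <- r$taps[[nm]]
  }
  nnClearCaches(net@modules$prims)
  lapply(feats, function(f) tsneExact(t(f), perplexity = perplexity,
                                      seed = seed, maxIter = maxIter))
}

#' Cohort comparison statistics
#'
#' Compares two study populations row by row: continuous rows (summarized
#' by n, mean, sd per group) with Welch's unequal-variance t-test computed
#' from the summary statistics, and categorical rows (2x2 counts) with the
#' continuity-corrected chi-square test.
#'
#' @param table data.frame with columns `name`, `type`
#'   (`"continuous"`/`"categorical"`), and either `n1, mean1, sd1, n2,
#'   mean2, sd2` or `x1, n1, x2, n2` (event count and group size).
#' @return the table with columns `statistic` and `p` appended.
#' @examples
#' tab <- data.frame(name = "apgar_lt7", type = "categorical",
#'                   x1 = 36, n1 = 1622, x2 = 19, n2 = 552)
#' round(cohortCompare(tab)$p, 3) # 0.155
#' @export
cohortCompare <- function(table) {
  stat <- p <- numeric(nrow(table))
  for (i in seq_len(nrow(table))) {
    row <- table[i, ]
    if (row$type == "continuous") {
      if (row$sd1 == 0 && row$sd2 == 0)
        stop("zero variance in both groups for row ", row$name)
      se2 <- row$sd1^2 / row$n1 + row$sd2^2 / row$n2
      t <- (row$mean1 - row$mean2) / sqrt(se2)
      df <- se2^2 / (row$sd1^4 / (row$n1^2 * (row$n1 - 1)) +
                     row$sd2^4 / (row$n2^2 * (row$n2 - 1)))
      stat[i] <- t
      p[i] <- 2 * pt(-abs(t), df)
    } else if (row$type == "categorical") {
      m <- matrix(c(row$x1, row$n1 - row$x1, row$x2, row$n2 - row$x2),
                  2, 2, byrow = TRUE)
      ct <- suppressWarnings(chisq.test(m, correct = TRUE))
      stat[i] <- unname(ct$statistic)
      p[i] <- ct$p.value
    } else stop("unknown row type: ", row$type)
  }
  table$statistic <- stat
  table$p <- p
  table
}
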