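test_that("confusion-matrix metrics match their closed forms", {
  cm <- confusionMatrix2x2(tp = 50, fp = 10, fn = 5, tn = 35)
  m <- metricsFromConfusion(cm)
  expect_equal(unname(m["accuracy"]), 85 / 100)
  expect_equal(unname(m["sensitivity"]), 50 / 55)
  expect_equal(unname(m["specificity"]), 35 / 45)
  expect_equal(unname(m["precision"]), 50 / 60)
  expect_equal(unname(m["f1_positive"]), 100 / (100 + 10 + 5))
  # perfect classifier: every ratio metric is one
  mp <- metricsFromConfusion(confusionMatrix2x2(10, 0, 0, 20))
  expect_true(all(mp[c("accuracy", "sensitivity", "specificity",
                       "precision", "f1_positive", "f1_macro")] == 1))
  # macro F1 of a symmetric matrix equals the positive-class F1
  ms <- metricsFromConfusion(confusionMatrix2x2(40, 7, 7, 40))
  expect_equal(unname(ms["f1_macro"]), unname(ms["f1_positive"]))
  # zero denominators surface as NaN with a warning
  expect_warning(m0 <- metricsFromConfusion(confusionMatrix2x2(0, 0, 5, 10)),
                 "undefined")
  expect_true(is.nan(m0["precision"]))
  # labels route: counts derive from prediction/truth pairs
  cm2 <- confusionFromLabels(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
  expect_equal(confusionCounts(cm2), c(tp = 1, fp = 1, fn = 0, tn = 1))
})

test_that("rank-based AUC matches the all-pairs oracle and is invariant", {
  expect_equal(rocAUC(c(1, 2, 3, 10, 11), c(F, F, F, T, T)), 1)
  set.seed(21)
  for (i in 1:5) {
    scores <- round(rnorm(20), 1)         # rounding forces some ties
    labels <- runif(20) > 0.5
    if (length(unique(labels)) < 2) next
    expect_equal(rocAUC(scores, labels), refAUC(scores, labels),
                 tolerance = 1e-12)
    # invariance under a strictly monotone transform
    expect_equal(rocAUC(exp(2 * scores), labels), rocAUC(scores, labels))
  }
  # independence between score and label gives ~0.5
  set.seed(22)
  s <- rnorm(4000); l <- runif(4000) > 0.5
  expect_lt(abs(rocAUC(s, l) - 0.5), 0.03)
  expect_error(rocAUC(1:5, rep(TRUE, 5)), "both classes")
})

test_that("average precision matches direct summation and its baseline", {
  expect_equal(prAP(c(9, 8, 7, 1, 2), c(T, T, T, F, F)), 1)
  set.seed(23)
  for (i in 1:5) {
    scores <- rnorm(10)
    labels <- runif(10) > 0.6
    if (!any(labels)) next
    expect_equal(prAP(scores, labels), refAP(scores, labels),
                 tolerance = 1e-12)
  }
  expect_equal(randomBaselineAP(602, 1020), 602 / 1622)
  # AP of a random ranking converges to the prevalence
  set.seed(24)
  n <- 10000
  labels <- c(rep(TRUE, 3700), rep(FALSE, 6300))
  expect_lt(abs(prAP(rnorm(n), labels) - 0.37), 0.02)
  expect_error(prAP(1:4, rep(FALSE, 4)), "positive")
})

test_that("stratified folds balance classes and sizes", {
  labels <- c(rep(TRUE, 37), rep(FALSE, 63))
  fold <- stratifiedKFold(labels, k = 5, seed = 31)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(as.vector(table(fold)), rep(20, 5))
  posPerFold <- tapply(labels, fold, sum)
  expect_true(all(posPerFold %in% c(7, 8)))
  # partition: union is everything, disjoint by construction
  expect_equal(length(fold), 100)
  expect_identical(fold, stratifiedKFold(labels, k = 5, seed = 31))
  expect_false(identical(fold, stratifiedKFold(labels, k = 5, seed = 32)))
  expect_error(stratifiedKFold(c(TRUE, rep(FALSE, 20)), k = 5, seed = 1),
               "at least k")
})

test_that("fold aggregation reports mean, sample SD and summed counts", {
  mk <- function(acc, tp, fp, fn, tn)
    list(metrics = c(accuracy = acc), cm = confusionMatrix2x2(tp, fp, fn, tn))
  same <- aggregateFolds(list(mk(0.9, 5, 1, 1, 13), mk(0.9, 5, 1, 1, 13)))
  expect_equal(unname(same@foldSD["accuracy"]), 0)
  two <- aggregateFolds(list(mk(0.9, 9, 1, 1, 9), mk(1.0, 10, 0, 0, 10)))
  expect_equal(unname(two@foldMean["accuracy"]), 0.95)
  expect_equal(unname(two@foldSD["accuracy"]), sd(c(0.9, 1)))
  expect_equal(confusionCounts(two@aggregated),
               c(tp = 19, fp = 1, fn = 1, tn = 19))
  expect_error(aggregateFolds(list(mk(1, 1, 0, 0, 1))), "two folds")
  # aggregated-confusion accuracy equals the sample-weighted fold mean
  f1 <- confusionMatrix2x2(8, 2, 1, 9)    # n = 20, acc 17/20
  f2 <- confusionMatrix2x2(4, 0, 2, 4)    # n = 10, acc 8/10
  agg <- aggregateFolds(list(
    list(metrics = metricsFromConfusion(f1), cm = f1),
    list(metrics = metricsFromConfusion(f2), cm = f2)))
  aggAcc <- unname(metricsFromConfusion(agg@aggregated)["accuracy"])
  expect_equal(aggAcc, (17 + 8) / 30)
  expect_equal(aggAcc, (20 * 17 / 20 + 10 * 8 / 10) / 30)
})

test_that("cohort comparison reproduces the published group statistics", {
  tab <- data.frame(
    name = c("nulliparous", "male_sex", "apgar_lt7"),
    type = "categorical",
    x1 = c(1080, 838, 36), n1 = 1622,
    x2 = c(376, 286, 19), n2 = 552)
  res <- cohortCompare(tab)
  expect_equal(round(res$p, 3), c(0.543, 0.992, 0.155))
  # identical composition: corrected chi-square gives p = 1
  same <- cohortCompare(data.frame(name = "x", type = "categorical",
                                   x1 = 30, n1 = 100, x2 = 30, n2 = 100))
  expect_equal(same$p, 1)
  # Welch's test from summary statistics agrees with t.test on raw samples
  set.seed(41)
  g1 <- rnorm(40); g1 <- (g1 - mean(g1)) / sd(g1) * 1.3 + 5.0
  g2 <- rnorm(25); g2 <- (g2 - mean(g2)) / sd(g2) * 0.8 + 4.4
  cont <- cohortCompare(data.frame(
    name = "cont", type = "continuous",
    n1 = 40, mean1 = 5.0, sd1 = 1.3, n2 = 25, mean2 = 4.4, sd2 = 0.8))
  ref <- t.test(g1, g2)
  expect_equal(cont$p, ref$p.value, tolerance = 1e-10)
  expect_equal(unname(cont$statistic), unname(ref$statistic),
               tolerance = 1e-10)
  expect_error(cohortCompare(data.frame(
    name = "zv", type = "continuous",
    n1 = 10, mean1 = 1, sd1 = 0, n2 = 10, mean2 = 1, sd2 = 0)),
    "zero variance")
})

test_that("exact t-SNE embeds deterministically", {
  set.seed(51)
  x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 6), 20))
  e1 <- tsneExact(x, perplexity = 5, seed = 3, maxIter = 250)
  e2 <- tsneExact(x, perplexity = 5, seed = 3, maxIter = 250)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(40L, 2L))
  # well-separated input clusters stay separated in the embedding
  d11 <- as.matrix(dist(e1))[1:20, 1:20]
  d12 <- as.matrix(dist(e1))[1:20, 21:40]
  expect_gt(mean(d12), mean(d11))
  expect_error(tsneExact(x[1:3, ]), "at least 4")
})
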