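test_that("binarization keeps gray >= 65 and handles RGB and edge cases", {
  expect_identical(binarize(matrix(64, 3, 3)), matrix(FALSE, 3, 3))
  m <- matrix(0, 3, 3); m[2, 2] <- 65
  expect_identical(binarize(m), m == 65)
  # RGB converts through Rec. 601 luminance first
  rgb <- array(0, c(2, 2, 3))
  rgb[1, 1, ] <- c(255, 255, 255)   # white -> 255
  rgb[2, 2, ] <- c(64, 64, 64)      # gray 64 -> below threshold
  bm <- binarize(rgb)
  expect_true(bm[1, 1]); expect_false(bm[2, 2])
  expect_error(binarize(matrix(numeric(0), 0, 0)), "empty")
})

test_that("pixel-to-value mapping is the stated linear model", {
  rs <- regionSpec(c(11, 161, 1, 100), "FHR")   # h = 150, 1 bpm per row
  expect_equal(pixelToValue(161, rs), 60)
  expect_equal(pixelToValue(11, rs), 210)
  expect_equal(pixelToValue(86, rs), 135)       # midpoint
  # agrees with independent interpolation over the endpoint anchors
  rows <- seq(11, 161, by = 0.5)
  oracle <- approx(x = c(161, 11), y = c(60, 210), xout = rows)$y
  expect_equal(pixelToValue(rows, rs), oracle, tolerance = 1e-9)
  expect_error(pixelToValue(10, rs), "outside")
  expect_error(pixelToValue(162, rs), "outside")
  # UC regions span 0-100 mmHg
  ru <- regionSpec(c(1, 101, 1, 50), "UC")
  expect_equal(pixelToValue(c(101, 51, 1), ru), c(0, 50, 100))
})

test_that("raising the trace by k rows raises values by k steps", {
  rs <- regionSpec(c(11, 161, 1, 100), "FHR")
  step <- (210 - 60) / 150
  y <- c(150, 120, 61)
  for (k in 1:5)
    expect_equal(pixelToValue(y - k, rs) - pixelToValue(y, rs),
                 rep(k * step, 3), tolerance = 1e-12)
})

test_that("trace extraction takes column medians and interpolates gaps", {
  # region 151 rows x 11 cols, FHR axis, 1 bpm per row; 10 samples at 1 Hz
  rs <- regionSpec(c(1, 151, 1, 11), "FHR")
  mask <- matrix(FALSE, 151, 11)
  # columns 1..10 are the sampled columns for t = 0..9 s
  mask[c(10, 11, 12), 1:3] <- TRUE               # median row 11
  mask[111, 4:6] <- TRUE                         # 100 bpm (row 151-40)
  # columns 7,8,9 empty -> gap; column 10 at 106 bpm (row 105)
  mask[105, 10] <- TRUE
  tr <- extractTrace(mask, rs, durationS = 10, outRate = 1)
  expect_equal(length(tr), 10)
  expect_equal(signalValues(tr)[1:3], rep(pixelToValue(11, rs), 3))
  expect_equal(signalValues(tr)[4:6], rep(100, 3))
  expect_equal(signalValues(tr)[7:9], c(101.5, 103.0, 104.5))
  expect_identical(validMask(tr),
                   c(rep(TRUE, 6), FALSE, FALSE, FALSE, TRUE))
  # edge gaps hold the nearest valid value
  mask2 <- matrix(FALSE, 151, 11)
  mask2[111, 5:10] <- TRUE
  tr2 <- extractTrace(mask2, rs, durationS = 10, outRate = 1)
  expect_equal(signalValues(tr2), rep(100, 10))
  expect_equal(sum(validMask(tr2)), 6)
  # an entirely empty region is an error
  expect_error(extractTrace(matrix(FALSE, 151, 11), rs, 10, 1), "no trace")
})

test_that("splicing concatenates chronologically and validates inputs", {
  a <- traceSignal(rep(100, 2400), 4, "FHR")
  b <- traceSignal(rep(120, 2400), 4, "FHR", startTime = 600)
  s <- spliceSegments(a, b)
  expect_equal(length(s), 4800)
  expect_equal(signalValues(s)[2401], 120)
  expect_equal(signalValues(s)[1:2400], rep(100, 2400))
  # identity on empty second segment
  empty <- traceSignal(numeric(0), 4, "FHR")
  expect_identical(spliceSegments(a, empty), a)
  expect_error(spliceSegments(a, traceSignal(1:10, 4, "UC")), "channel")
  expect_error(spliceSegments(a, traceSignal(1:10, 2, "FHR")), "rate")
})

test_that("standardized model input is 224x224x3 with zero mean unit sd", {
  p <- signalParams(seed = 5, variabilityAmp = 8,
                    ucEvents = list(c(300, 80, 60)))
  mi <- standardizeToInput(simulateFHR(p), simulateUC(p))
  expect_equal(dim(mi@tensor), c(224L, 224L, 3L))
  expect_lt(abs(mean(mi@tensor)), 1e-6)
  sdPop <- sqrt(mean((mi@tensor - mean(mi@tensor))^2))
  expect_equal(sdPop, 1, tolerance = 1e-6)
  expect_true(all(c("mean", "sd") %in% names(mi@normalization)))
  # the three channels are replicates of one canvas
  expect_identical(mi@tensor[, , 1], mi@tensor[, , 3])
  # with the variance guard triggered the tensor degenerates to all zeros
  mi0 <- standardizeToInput(simulateFHR(p), simulateUC(p), eps = 1e9)
  expect_true(all(mi0@tensor == 0))
  short <- signalParams(durationS = 600, seed = 1)
  expect_error(standardizeToInput(simulateFHR(short), simulateUC(short)),
               "20 minutes")
})

test_that("digitizing a rendered chart recovers the signals", {
  layout <- defaultChartLayout()
  # noiseless constant trace: error bounded by the vertical quantization step
  p <- signalParams(baselineBpm = 140, variabilityAmp = 0, ucTone = 30,
                    seed = 1)
  rc <- renderChart(simulateFHR(p), simulateUC(p), layout)
  dg <- digitizeChart(rc$image)
  expect_equal(length(dg$fhr), 4800)
  expect_equal(length(dg$uc), 4800)
  b <- layout@regionBoxes
  stepF <- 150 / (b[1, 2] - b[1, 1])
  expect_true(all(abs(signalValues(dg$fhr) - 140) <= stepF))
  stepU <- 100 / (b[2, 2] - b[2, 1])
  expect_true(all(abs(signalValues(dg$uc) - 30) <= stepU))
  # a page with no ink at all fails loudly
  blank <- new("ChartImage", pixels = matrix(0, layout@pageSize[2],
                                             layout@pageSize[1]),
               layout = layout)
  expect_error(digitizeChart(blank), "no trace")
})

test_that("round-trip error stays within tolerance for realistic traces", {
  layout <- defaultChartLayout()
  for (seed in 1:3) {
    s <- makeDataset(1, classRatio = 0.5, seed = seed, layout = layout)[[1]]
    dg <- digitizeChart(s$image)
    rmseF <- sqrt(mean((signalValues(dg$fhr) -
                          signalValues(s$truth@fhr))^2))
    rmseU <- sqrt(mean((signalValues(dg$uc) -
                          signalValues(s$truth@uc))^2))
    expect_lt(rmseF, 2)
    expect_lt(rmseU, 2)
  }
})
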