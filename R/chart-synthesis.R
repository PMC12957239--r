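# Synthetic CTG recordings and chart pages with exact ground truth.

withLocalSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulation parameters for one synthetic CTG recording
#'
#' Describes a 20-minute recording: an FHR baseline with band-limited
#' variability, Gaussian-bump accelerations and decelerations, and a UC
#' channel of resting tone plus Gaussian contraction bumps. Late
#' decelerations carry a lag after the associated contraction peak.
#'
#' @param baselineBpm FHR baseline in bpm.
#' @param variabilityAmp peak-to-peak FHR variability amplitude in bpm.
#' @param accelEvents list of `c(onset_s, duration_s, amplitude_bpm)`.
#' @param decelEvents list of `c(onset_s, duration_s, depth_bpm, lag_s)`;
#'   `lag_s` records the delay of the dip nadir after the UC peak.
#' @param ucEvents list of `c(peak_time_s, duration_s, peak_mmHg)`.
#' @param ucTone resting uterine tone in mmHg (non-negative).
#' @param durationS recording duration in seconds (default 1200 s = 20 min).
#' @param sampleRate sampling rate in Hz (default 4).
#' @param label `"reassuring"` or `"non_reassuring"`.
#' @param seed RNG seed for the variability component.
#' @return a `SignalParams` list.
#' @export
signalParams <- function(baselineBpm = 140, variabilityAmp = 10,
                         accelEvents = list(), decelEvents = list(),
                         ucEvents = list(), ucTone = 10, durationS = 1200,
                         sampleRate = 4, label = "reassuring", seed = 0L) {
  stopifnot(durationS > 0, sampleRate > 0, variabilityAmp >= 0)
  if (ucTone < 0) stop("negative resting tone is not a valid input")
  if (!label %in% .LABELS) stop("label must be 'reassuring' or 'non_reassuring'")
  checkEvent <- function(ev, k, what) {
    if (length(ev) < k) stop("malformed ", what, " event")
    if (ev[1] < 0 || ev[1] + ev[2] > durationS)
      stop(what, " event lies outside the recording duration")
  }
  for (ev in accelEvents) checkEvent(ev, 3, "acceleration")
  for (ev in decelEvents) checkEvent(ev, 3, "deceleration")
  for (ev in ucEvents) {
    if (length(ev) < 3) stop("malformed contraction event")
    if (ev[1] < 0 || ev[1] > durationS)
      stop("contraction event lies outside the recording duration")
  }
  structure(list(baselineBpm = baselineBpm, variabilityAmp = variabilityAmp,
                 accelEvents = accelEvents, decelEvents = decelEvents,
                 ucEvents = ucEvents, ucTone = ucTone, durationS = durationS,
                 sampleRate = sampleRate, label = label, seed = as.integer(seed)),
            class = "SignalParams")
}

# Gaussian bump of given peak amplitude, supported on [onset, onset+dur]
gaussBump <- function(t, onset, dur, amp) {
  center <- onset + dur / 2
  sigma <- dur / 6
  out <- amp * exp(-0.5 * ((t - center) / sigma)^2)
  out[t < onset | t > onset + dur] <- 0
  out
}

# band-limited oscillation with unit peak amplitude (sum of random-phase
# sinusoids in the 0.03-0.3 Hz band, normalized by its own maximum)
bandOscillation <- function(t, nComp = 24L) {
  f <- runif(nComp, 0.03, 0.3)
  ph <- runif(nComp, 0, 2 * pi)
  a <- runif(nComp, 0.3, 1)
  osc <- (sin(outer(t, 2 * pi * f) + rep(ph, each = length(t))) %*% a)[, 1]
  m <- max(abs(osc))
  if (m > 0) osc / m else osc
}

#' Simulate a fetal-heart-rate trace
#'
#' Baseline plus band-limited variability, plus additive Gaussian-bump
#' accelerations and subtractive decelerations, clipped to the chart's FHR
#' range of 60--210 bpm. Deterministic for a fixed `params$seed`.
#'
#' @param params a [signalParams()] object.
#' @return a [TraceSignal-class] with channel `"FHR"`.
#' @examples
#' p <- signalParams(baselineBpm = 140, variabilityAmp = 0,
#'                   accelEvents = list(c(100, 30, 20)), seed = 1)
#' max(signalValues(simulateFHR(p))) # 160 at the bump center
#' @export
simulateFHR <- function(params) {
  stopifnot(inherits(params, "SignalParams"))
  n <- round(params$durationS * params$sampleRate)
  t <- (seq_len(n) - 1) / params$sampleRate
  v <- rep(params$baselineBpm, n)
  if (params$variabilityAmp > 0)
    v <- v + withLocalSeed(params$seed,
                           bandOscillation(t)) * params$variabilityAmp / 2
  for (ev in params$accelEvents) v <- v + gaussBump(t, ev[1], ev[2], ev[3])
  for (ev in params$decelEvents) v <- v - gaussBump(t, ev[1], ev[2], ev[3])
  traceSignal(pmin(pmax(v, 60), 210), params$sampleRate, "FHR")
}

#' Simulate a uterine-contraction trace
#'
#' Resting tone plus Gaussian contraction bumps centered at each event's
#' peak time, clipped to the chart's UC range of 0--100 mmHg.
#'
#' @param params a [signalParams()] object; `ucEvents` entries are
#'   `c(peak_time_s, duration_s, peak_mmHg)` with the bump supported on
#'   `peak_time +/- duration/2`.
#' @return a [TraceSignal-class] with channel `"UC"`.
#' @export
simulateUC <- function(params) {
  stopifnot(inherits(params, "SignalParams"))
  n <- round(params$durationS * params$sampleRate)
  t <- (seq_len(n) - 1) / params$sampleRate
  v <- rep(params$ucTone, n)
  for (ev in params$ucEvents)
    v <- v + gaussBump(t, ev[1] - ev[2] / 2, ev[2], ev[3] - params$ucTone)
  traceSignal(pmin(pmax(v, 0), 100), params$sampleRate, "UC")
}

# value -> image row for a region box (inverse of the pixel-to-value map):
# the bottom row maps to vmin, the top row to vmax, h = rowMax - rowMin.
valueToRow <- function(v, box, vmin, vmax) {
  h <- box[2] - box[1]
  box[2] - round((v - vmin) / (vmax - vmin) * h)
}

# draw one region's trace into mask (in place via returned indices):
# per column the vertical span between consecutive column rows is filled,
# then thickened downward; nearest-neighbor placement, no anti-aliasing.
drawRegionTrace <- function(mask, sig, segIndex, box, vmin, vmax, thickness,
                            segDuration = 600) {
  cols <- box[3]:box[4]
  w <- length(cols)
  tcol <- (seq_len(w) - 1) / (w - 1) * segDuration + segIndex * segDuration
  tsig <- (seq_along(sig@values) - 1) / sig@sampleRate
  v <- approx(tsig, sig@values, xout = pmin(tcol, max(tsig)), rule = 2)$y
  r <- valueToRow(v, box, vmin, vmax)
  r <- pmin(pmax(r, box[1]), box[2])
  for (j in seq_len(w)) {
    lo <- if (j == 1) r[1] else min(r[j], r[j - 1])
    hi <- if (j == 1) r[1] else max(r[j], r[j - 1])
    hi <- min(hi + thickness - 1L, box[2])
    mask[lo:hi, cols[j]] <- TRUE
  }
  mask
}

#' Render a 20-minute recording as a gridded chart page
#'
#' Draws the four curve regions of a CTG report: the first 10 minutes of
#' FHR and UC in the upper two regions and the second 10 minutes in the
#' lower two. The value-to-row placement is the exact inverse of the linear
#' pixel-to-value mapping used by [pixelToValue()]. Grid lines and shadow
#' bands are drawn at their (sub-threshold) gray levels beneath the trace;
#' the trace is drawn last at `traceGray >= 65`, and the exact set of trace
#' pixels is returned as the ground-truth mask.
#'
#' @param fhr,uc [TraceSignal-class] objects covering 20 minutes at a common
#'   sample rate.
#' @param layout a [ChartLayout-class].
#' @param label ground-truth class label stored alongside the signals.
#' @return list with `image` ([ChartImage-class]) and `truth`
#'   ([GroundTruth-class]).
#' @export
renderChart <- function(fhr, uc, layout = defaultChartLayout(),
                        label = "reassuring") {
  if (abs(duration(fhr) - 1200) > 1e-9 || abs(duration(uc) - 1200) > 1e-9)
    stop("signals must cover 20 minutes (1200 s) to fill the four regions")
  if (fhr@sampleRate != uc@sampleRate)
    stop("fhr and uc must share a sample rate")
  W <- layout@pageSize[1]; H <- layout@pageSize[2]
  page <- matrix(0, H, W)
  b <- layout@regionBoxes
  # shadow bands: alternating horizontal stripes inside each region
  for (i in 1:4) {
    rows <- b[i, 1]:b[i, 2]
    band <- ((rows - b[i, 1]) %/% layout@gridSpacing[2]) %% 2 == 1
    page[rows[band], b[i, 3]:b[i, 4]] <- layout@shadowGray
  }
  # grid lines
  for (i in 1:4) {
    gcols <- seq(b[i, 3], b[i, 4], by = layout@gridSpacing[1])
    grows <- seq(b[i, 1], b[i, 2], by = layout@gridSpacing[2])
    page[b[i, 1]:b[i, 2], gcols] <- layout@gridGray
    page[grows, b[i, 3]:b[i, 4]] <- layout@gridGray
  }
  mask <- matrix(FALSE, H, W)
  regionOrder <- list(list(sig = fhr, seg = 0L, row = 1L, rng = c(60, 210)),
                      list(sig = uc, seg = 0L, row = 2L, rng = c(0, 100)),
                      list(sig = fhr, seg = 1L, row = 3L, rng = c(60, 210)),
                      list(sig = uc, seg = 1L, row = 4L, rng = c(0, 100)))
  for (rg in regionOrder)
    mask <- drawRegionTrace(mask, rg$sig, rg$seg, b[rg$row, ],
                            rg$rng[1], rg$rng[2], layout@traceThickness)
  page[mask] <- layout@traceGray
  image <- new("ChartImage", pixels = page, layout = layout)
  truth <- new("GroundTruth", fhr = fhr, uc = uc, label = label,
               traceMask = mask)
  list(image = image, truth = truth)
}

# class-conditional parameter draws (seed must already be set)
drawParams <- function(label, durationS = 1200, sampleRate = 4, seed) {
  baseline <- runif(1, 120, 160)
  tone <- runif(1, 5, 15)
  # contractions every 2-3 minutes
  ucEvents <- list()
  tpeak <- runif(1, 80, 140)
  while (tpeak < durationS - 60) {
    ucEvents[[length(ucEvents) + 1L]] <-
      c(tpeak, runif(1, 60, 90), runif(1, 40, 80))
    tpeak <- tpeak + runif(1, 120, 180)
  }
  accel <- list(); decel <- list()
  if (label == "reassuring") {
    variability <- runif(1, 5, 15)
    nAcc <- sample(3:6, 1)
    for (i in seq_len(nAcc)) {
      dur <- runif(1, 15, 30)
      onset <- runif(1, 30, durationS - dur - 30)
      accel[[i]] <- c(onset, dur, runif(1, 15, 25))
    }
  } else {
    variability <- runif(1, 1, 3)
    for (ev in ucEvents) {
      lag <- runif(1, 20, 60)
      dur <- runif(1, 30, 60)
      onset <- ev[1] + lag - dur / 2
      if (onset >= 0 && onset + dur <= durationS)
        decel[[length(decel) + 1L]] <- c(onset, dur, runif(1, 20, 40), lag)
    }
  }
  signalParams(baselineBpm = baseline, variabilityAmp = variability,
               accelEvents = accel, decelEvents = decel, ucEvents = ucEvents,
               ucTone = tone, durationS = durationS, sampleRate = sampleRate,
               label = label, seed = seed)
}

#' Generate a labeled synthetic chart dataset
#'
#' Draws `round(n * classRatio)` non-reassuring and the rest reassuring
#' recordings and renders each as a chart page. Reassuring morphology:
#' moderate variability (5--15 bpm peak-to-peak) with accelerations of at
#' least 15 bpm for at least 15 s. Non-reassuring morphology: reduced
#' variability (at most 3 bpm) with decelerations whose nadir lags the
#' contraction peak by 20--60 s. Bit-identical reproducible for a fixed
#' seed.
#'
#' @param n number of recordings.
#' @param classRatio fraction of non-reassuring recordings, in (0, 1).
#' @param seed RNG seed.
#' @param layout a [ChartLayout-class] used for every page.
#' @return list of `n` elements, each `list(image =, truth =, params =)`.
#' @export
makeDataset <- function(n, classRatio = 0.5, seed = 0L,
                        layout = defaultChartLayout()) {
  plan <- datasetPlan(n, classRatio, seed)
  lapply(seq_len(n), function(i)
    synthesizeSample(plan$labels[i], plan$seeds[i], layout))
}

# label sequence and per-sample seeds for a dataset: the deterministic
# skeleton shared by makeDataset() and the streaming experiment runner
datasetPlan <- function(n, classRatio, seed) {
  stopifnot(n > 0)
  if (classRatio <= 0 || classRatio >= 1)
    stop("classRatio must lie strictly between 0 and 1")
  nPos <- round(n * classRatio)
  withLocalSeed(seed, {
    labels <- sample(c(rep("non_reassuring", nPos),
                       rep("reassuring", n - nPos)))
    seeds <- sample.int(.Machine$integer.max, n)
    list(labels = labels, seeds = seeds)
  })
}

synthesizeSample <- function(label, sampleSeed, layout) {
  withLocalSeed(sampleSeed, {
    p <- drawParams(label, seed = sampleSeed)
    fhr <- simulateFHR(p)
    uc <- simulateUC(p)
    rc <- renderChart(fhr, uc, layout, label = label)
    list(image = rc$image, truth = rc$truth, params = p)
  })
}

#' Write a synthetic chart sample to disk
#'
#' Writes the page as PNG, the ground-truth signals as two-column CSV files
#' (`time_s`, value) and a JSON sidecar with label, layout and seed.
#'
#' @param sample one element of [makeDataset()] output.
#' @param dir output directory (created if missing).
#' @param basename file stem.
#' @return invisibly, the paths written.
#' @export
writeChartSample <- function(sample, dir, basename = "chart") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pngPath <- file.path(dir, paste0(basename, ".png"))
  png::writePNG(sample$image@pixels / 255, pngPath)
  tr <- sample$truth
  paths <- pngPath
  for (ch in c("fhr", "uc")) {
    sig <- slot(tr, ch)
    p <- file.path(dir, paste0(basename, "_", ch, ".csv"))
    write.csv(data.frame(
      time_s = (seq_along(sig@values) - 1) / sig@sampleRate,
      value = sig@values), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  lay <- sample$image@layout
  sidecar <- list(label = tr@label, seed = sample$params$seed,
                  layout = list(pageSize = lay@pageSize,
                                regionBoxes = lay@regionBoxes,
                                gridSpacing = lay@gridSpacing,
                                grays = list(grid = lay@gridGray,
                                             shadow = lay@shadowGray,
                                             trace = lay@traceGray),
                                traceThickness = lay@traceThickness))
  jp <- file.path(dir, paste0(basename, ".json"))
  jsonlite::write_json(sidecar, jp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jp))
}

#' Read a chart page image from disk
#'
#' Reads a PNG or simple grayscale image and wraps it with a layout.
#'
#' @param path PNG file path.
#' @param layout the [ChartLayout-class] describing the page.
#' @return a [ChartImage-class].
#' @export
readChartImage <- function(path, layout = defaultChartLayout()) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) {
    if (dim(px)[3] >= 3)
      px <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
    else px <- px[, , 1]
  }
  new("ChartImage", pixels = round(px * 255), layout = layout)
}
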