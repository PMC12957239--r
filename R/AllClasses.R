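#' TraceSignal: a uniformly sampled physical-unit time series
#'
#' Holds one digitized or simulated channel of a CTG recording: FHR in
#' beats per minute or UC pressure in mmHg, sampled uniformly, together with
#' a per-sample validity mask (columns where no trace pixel was found are
#' invalid and carry interpolated values).
#'
#' @slot values numeric vector of physical values (bpm or mmHg).
#' @slot valid logical vector, same length as `values`.
#' @slot sampleRate sampling rate in Hz.
#' @slot channel `"FHR"` or `"UC"`.
#' @slot startTime start time of the first sample in seconds.
#' @export
setClass("TraceSignal", representation(
  values = "numeric", valid = "logical", sampleRate = "numeric",
  channel = "character", startTime = "numeric"
))

setValidity("TraceSignal", function(object) {
  msg <- character()
  if (length(object@values) != length(object@valid))
    msg <- c(msg, "values and valid must have equal length")
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive number")
  if (!object@channel %in% c("FHR", "UC"))
    msg <- c(msg, "channel must be 'FHR' or 'UC'")
  if (length(msg)) msg else TRUE
})

#' Construct a TraceSignal
#'
#' @param values numeric vector of physical values.
#' @param sampleRate sampling rate in Hz.
#' @param channel `"FHR"` or `"UC"`.
#' @param valid logical validity mask (default: all valid).
#' @param startTime start time in seconds (default 0).
#' @return A [TraceSignal-class] object.
#' @examples
#' ts <- traceSignal(rep(140, 40), sampleRate = 4, channel = "FHR")
#' duration(ts)
#' @export
traceSignal <- function(values, sampleRate, channel,
                        valid = rep(TRUE, length(values)), startTime = 0) {
  new("TraceSignal", values = as.numeric(values), valid = valid,
      sampleRate = as.numeric(sampleRate), channel = channel,
      startTime = as.numeric(startTime))
}

#' ChartLayout: page geometry tying pixels to time and value axes
#'
#' Describes a rendered CTG report page: page size, the four curve-region
#' bounding boxes in reading order (FHR first 10 min, UC first 10 min, FHR
#' second 10 min, UC second 10 min), grid geometry and the gray levels of
#' grid, shadow and trace ink. Gray levels must respect the global
#' binarization threshold of 65: grid and shadow fall below it, trace ink at
#' or above it.
#'
#' @slot pageSize integer c(width, height) in pixels.
#' @slot regionBoxes 4x4 integer matrix, rows `FHR1, UC1, FHR2, UC2`,
#'   columns `rowMin, rowMax, colMin, colMax` (1-based, inclusive).
#' @slot gridSpacing integer c(horizontal, vertical) grid pitch in pixels.
#' @slot gridGray,shadowGray,traceGray gray levels in 0--255.
#' @slot traceThickness vertical trace thickness in pixels.
#' @export
setClass("ChartLayout", representation(
  pageSize = "integer", regionBoxes = "matrix", gridSpacing = "integer",
  gridGray = "integer", shadowGray = "integer", traceGray = "integer",
  traceThickness = "integer"
))

setValidity("ChartLayout", function(object) {
  msg <- character()
  b <- object@regionBoxes
  if (!identical(dim(b), c(4L, 4L)))
    msg <- c(msg, "regionBoxes must be a 4x4 matrix")
  if (object@gridGray >= 65L || object@shadowGray >= 65L)
    msg <- c(msg, "grid and shadow gray levels must be below 65")
  if (object@traceGray < 65L)
    msg <- c(msg, "trace gray level must be at least 65")
  if (object@traceThickness < 1L)
    msg <- c(msg, "traceThickness must be >= 1")
  if (identical(dim(b), c(4L, 4L))) {
    if (any(b[, 1] > b[, 2]) || any(b[, 3] > b[, 4]))
      msg <- c(msg, "degenerate region box")
    if (any(b[, 1] < 1L) || any(b[, 2] > object@pageSize[2]) ||
        any(b[, 3] < 1L) || any(b[, 4] > object@pageSize[1]))
      msg <- c(msg, "region boxes must lie within the page")
    # pairwise disjoint
    for (i in 1:3) for (j in (i + 1):4) {
      rOverlap <- b[i, 1] <= b[j, 2] && b[j, 1] <= b[i, 2]
      cOverlap <- b[i, 3] <= b[j, 4] && b[j, 3] <= b[i, 4]
      if (rOverlap && cOverlap) msg <- c(msg, "region boxes must be disjoint")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Default chart layout
#'
#' A 1200x800 page with the four 10-minute curve regions stacked vertically
#' (FHR/UC for the first 10 minutes above FHR/UC for the second), a light
#' grid, shadow bands, and trace ink bright enough to survive threshold-65
#' binarization.
#'
#' @param pageWidth,pageHeight page size in pixels.
#' @param gridSpacing grid pitch c(horizontal, vertical) in pixels.
#' @param gridGray,shadowGray,traceGray gray levels (0--255); grid and shadow
#'   must be `< 65`, trace `>= 65`.
#' @param traceThickness vertical trace thickness in pixels.
#' @return A [ChartLayout-class] object.
#' @examples
#' defaultChartLayout()
#' @export
defaultChartLayout <- function(pageWidth = 1200L, pageHeight = 800L,
                               gridSpacing = c(25L, 25L),
                               gridGray = 40L, shadowGray = 25L,
                               traceGray = 255L, traceThickness = 2L) {
  pageWidth <- as.integer(pageWidth); pageHeight <- as.integer(pageHeight)
  margin <- 10L
  gap <- 8L
  regionH <- (pageHeight - 2L * margin - 3L * gap) %/% 4L
  colMin <- margin + 1L
  colMax <- pageWidth - margin
  boxes <- matrix(0L, 4, 4,
                  dimnames = list(c("FHR1", "UC1", "FHR2", "UC2"),
                                  c("rowMin", "rowMax", "colMin", "colMax")))
  for (i in 1:4) {
    top <- margin + 1L + (i - 1L) * (regionH + gap)
    boxes[i, ] <- c(top, top + regionH - 1L, colMin, colMax)
  }
  new("ChartLayout", pageSize = c(pageWidth, pageHeight), regionBoxes = boxes,
      gridSpacing = as.integer(gridSpacing), gridGray = as.integer(gridGray),
      shadowGray = as.integer(shadowGray), traceGray = as.integer(traceGray),
      traceThickness = as.integer(traceThickness))
}

#' ChartImage: a rendered or loaded CTG report page
#'
#' @slot pixels numeric matrix (height x width) of 8-bit gray values 0--255.
#' @slot layout the [ChartLayout-class] tying pixels to axes.
#' @export
setClass("ChartImage", representation(pixels = "matrix", layout = "ChartLayout"))

setValidity("ChartImage", function(object) {
  p <- object@pixels
  if (nrow(p) != object@layout@pageSize[2] || ncol(p) != object@layout@pageSize[1])
    return("pixel matrix does not match layout page size")
  if (any(p < 0 | p > 255)) return("pixel values must lie in 0..255")
  TRUE
})

#' GroundTruth: exact reference for a synthetic chart
#'
#' @slot fhr,uc the simulated [TraceSignal-class] series.
#' @slot label `"reassuring"` or `"non_reassuring"`.
#' @slot traceMask logical matrix of exactly the rendered trace pixels.
#' @export
setClass("GroundTruth", representation(
  fhr = "TraceSignal", uc = "TraceSignal", label = "character",
  traceMask = "matrix"
))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (!object@label %in% .LABELS)
    msg <- c(msg, "label must be 'reassuring' or 'non_reassuring'")
  if (object@fhr@sampleRate != object@uc@sampleRate ||
      length(object@fhr@values) != length(object@uc@values))
    msg <- c(msg, "fhr and uc must share sample rate and duration")
  if (length(msg)) msg else TRUE
})

#' RegionSpec: one curve region and its value axis
#'
#' Encodes the linear pixel-to-value mapping of a curve region: the pixel
#' box, the channel and 10-minute segment it holds, and the value range
#' `[vmin, vmax]` spanned by the region's full height. The bottom row of the
#' box maps to `vmin` and the top row to `vmax`; the valid-region height `h`
#' is the row span `rowMax - rowMin`.
#'
#' @slot box integer c(rowMin, rowMax, colMin, colMax), 1-based inclusive.
#' @slot channel `"FHR"` or `"UC"`.
#' @slot segmentIndex 0 for the first 10 minutes, 1 for the second.
#' @slot vmin,vmax value range (60--210 bpm for FHR, 0--100 mmHg for UC).
#' @export
setClass("RegionSpec", representation(
  box = "integer", channel = "character", segmentIndex = "integer",
  vmin = "numeric", vmax = "numeric"
))

setValidity("RegionSpec", function(object) {
  msg <- character()
  if (length(object@box) != 4L || object@box[1] > object@box[2] ||
      object@box[3] > object@box[4])
    msg <- c(msg, "box must be c(rowMin, rowMax, colMin, colMax) with positive extent")
  if (object@box[2] <= object@box[1])
    msg <- c(msg, "region height h must be > 0")
  if (object@vmin >= object@vmax) msg <- c(msg, "vmin must be < vmax")
  if (!object@channel %in% c("FHR", "UC"))
    msg <- c(msg, "channel must be 'FHR' or 'UC'")
  if (length(msg)) msg else TRUE
})

#' Construct a RegionSpec
#'
#' @param box integer c(rowMin, rowMax, colMin, colMax).
#' @param channel `"FHR"` (axis 60--210 bpm) or `"UC"` (axis 0--100 mmHg).
#' @param segmentIndex 0 (first 10 min) or 1 (second 10 min).
#' @return A [RegionSpec-class] object with the channel's canonical value
#'   range.
#' @examples
#' regionSpec(c(11, 196, 11, 1190), "FHR", 0)
#' @export
regionSpec <- function(box, channel = c("FHR", "UC"), segmentIndex = 0L) {
  channel <- match.arg(channel)
  rng <- if (channel == "FHR") c(60, 210) else c(0, 100)
  new("RegionSpec", box = as.integer(box), channel = channel,
      segmentIndex = as.integer(segmentIndex), vmin = rng[1], vmax = rng[2])
}

#' ModelInput: a standardized 224x224 network input
#'
#' @slot tensor numeric array 224 x 224 x 3 (rows x cols x channels),
#'   Z-score normalized.
#' @slot normalization named numeric c(mean, sd) used for normalization.
#' @export
setClass("ModelInput", representation(tensor = "array", normalization = "numeric"))

setValidity("ModelInput", function(object) {
  d <- dim(object@tensor)
  if (length(d) != 3L || d[1] != 224L || d[2] != 224L || d[3] != 3L)
    return("tensor must be 224 x 224 x 3")
  if (any(!is.finite(object@tensor))) return("tensor must be finite")
  TRUE
})

#' ConfusionMatrix: 2x2 counts with Non-Reassuring as the positive class
#'
#' @slot tp,fp,fn,tn non-negative counts. Positives are Non-Reassuring
#'   recordings, negatives Reassuring ones.
#' @export
setClass("ConfusionMatrix",
         representation(tp = "numeric", fp = "numeric",
                        fn = "numeric", tn = "numeric"))

setValidity("ConfusionMatrix", function(object) {
  v <- c(object@tp, object@fp, object@fn, object@tn)
  if (any(v < 0) || any(v != round(v))) return("counts must be non-negative integers")
  TRUE
})

#' Construct a ConfusionMatrix from counts
#'
#' @param tp,fp,fn,tn counts (positive class = Non-Reassuring).
#' @return A [ConfusionMatrix-class] object.
#' @examples
#' confusionMatrix2x2(tp = 547, fp = 64, fn = 55, tn = 956)
#' @export
confusionMatrix2x2 <- function(tp, fp, fn, tn) {
  new("ConfusionMatrix", tp = as.numeric(tp), fp = as.numeric(fp),
      fn = as.numeric(fn), tn = as.numeric(tn))
}

#' FoldReport: per-fold and aggregated cross-validation results
#'
#' @slot perFold data.frame, one row per fold, one column per metric.
#' @slot foldMean,foldSD named numeric vectors across folds (sample SD).
#' @slot aggregated elementwise sum of the fold confusion matrices.
#' @export
setClass("FoldReport", representation(
  perFold = "data.frame", foldMean = "numeric", foldSD = "numeric",
  aggregated = "ConfusionMatrix"
))

#' CTGNetwork: the CBAM-enhanced EfficientNet-B0 classifier
#'
#' Wraps the network's parameter store (an environment of layer modules)
#' together with its stage-by-stage architecture description and the seed
#' used for initialization.
#'
#' @slot spec data.frame describing stem, stages and head with shape
#'   contracts.
#' @slot modules environment holding the layer modules and parameters.
#' @slot numClasses number of output logits.
#' @slot seed integer seed used for weight initialization.
#' @slot config list of architecture options (CBAM reduction, dropout,
#'   expanded head flag).
#' @export
setClass("CTGNetwork", representation(
  spec = "data.frame", modules = "environment", numClasses = "integer",
  seed = "integer", config = "list"
))

# ------------------------------------------------------------ show methods

setMethod("show", "TraceSignal", function(object) {
  ok <- sum(object@valid)
  cat(sprintf("TraceSignal [%s] %d samples @ %g Hz (%.1f s), %d valid (%.1f%%)\n",
              object@channel, length(object@values), object@sampleRate,
              length(object@values) / object@sampleRate, ok,
              100 * ok / max(1L, length(object@values))))
  if (ok > 0)
    cat(sprintf("  range of valid values: [%.2f, %.2f]\n",
                min(object@values[object@valid]), max(object@values[object@valid])))
})

setMethod("show", "ChartLayout", function(object) {
  cat(sprintf("ChartLayout %dx%d px, grid %dx%d px (gray %d), shadow %d, trace %d (thickness %d)\n",
              object@pageSize[1], object@pageSize[2],
              object@gridSpacing[1], object@gridSpacing[2], object@gridGray,
              object@shadowGray, object@traceGray, object@traceThickness))
  print(object@regionBoxes)
})

setMethod("show", "ChartImage", function(object) {
  cat(sprintf("ChartImage %dx%d px (height x width), gray range [%d, %d]\n",
              nrow(object@pixels), ncol(object@pixels),
              as.integer(min(object@pixels)), as.integer(max(object@pixels))))
})

setMethod("show", "ConfusionMatrix", function(object) {
  m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2, 2,
              dimnames = list(truth = c("non_reassuring", "reassuring"),
                              predicted = c("non_reassuring", "reassuring")))
  cat("ConfusionMatrix (positive class = non_reassuring)\n")
  print(m)
})

setMethod("show", "FoldReport", function(object) {
  k <- nrow(object@perFold)
  cat(sprintf("FoldReport over %d folds (mean +/- sd):\n", k))
  for (nm in names(object@foldMean))
    cat(sprintf("  %-18s %.4f +/- %.4f\n", nm, object@foldMean[nm], object@foldSD[nm]))
  cat("aggregated counts: ")
  cat(sprintf("tp=%d fp=%d fn=%d tn=%d\n", as.integer(object@aggregated@tp),
              as.integer(object@aggregated@fp), as.integer(object@aggregated@fn),
              as.integer(object@aggregated@tn)))
})

setMethod("show", "CTGNetwork", function(object) {
  cat(sprintf("CTGNetwork: CBAM-enhanced EfficientNet-B0 (%d classes, seed %d)\n",
              object@numClasses, object@seed))
  cat(sprintf("  parameters: %s\n", format(networkParameterCount(object), big.mark = ",")))
  print(object@spec, row.names = FALSE)
})

# ------------------------------------------------------------- accessors

#' @describeIn traceSignal Number of samples in a TraceSignal.
#' @param x a `TraceSignal`.
#' @export
setMethod("length", "TraceSignal", function(x) length(x@values))

#' Accessors for TraceSignal
#'
#' @param x a [TraceSignal-class].
#' @return `signalValues`: numeric vector; `validMask`: logical vector;
#'   `sampleRate`: Hz; `channelType`: `"FHR"` or `"UC"`; `duration`: seconds.
#' @name TraceSignal-accessors
NULL

#' @rdname TraceSignal-accessors
#' @export
signalValues <- function(x) x@values

#' @rdname TraceSignal-accessors
#' @export
validMask <- function(x) x@valid

#' @rdname TraceSignal-accessors
#' @export
sampleRate <- function(x) x@sampleRate

#' @rdname TraceSignal-accessors
#' @export
channelType <- function(x) x@channel

#' @rdname TraceSignal-accessors
#' @export
duration <- function(x) length(x@values) / x@sampleRate

#' Accessors for ConfusionMatrix counts
#'
#' @param x a [ConfusionMatrix-class].
#' @return named numeric vector c(tp, fp, fn, tn).
#' @examples
#' confusionCounts(confusionMatrix2x2(5, 1, 2, 10))
#' @export
confusionCounts <- function(x) {
  c(tp = x@tp, fp = x@fp, fn = x@fn, tn = x@tn)
}

#' Pixel matrix of a chart image
#' @param x a [ChartImage-class].
#' @return numeric matrix (height x width) of gray values.
#' @export
chartPixels <- function(x) x@pixels

#' Layout of a chart image
#' @param x a [ChartImage-class].
#' @return the [ChartLayout-class].
#' @export
chartLayout <- function(x) x@layout
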