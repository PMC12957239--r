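# Digitization: binarize away grid/shadow, extract per-region traces,
# map pixel rows to physical units, resample, splice, standardize.

#' Threshold binarization of a chart image
#'
#' Converts the image to 8-bit grayscale (RGB images via Rec. 601 luminance)
#' and keeps pixels whose gray value is at least `threshold`. The background
#' grid and shadows of CTG reports print darker than the trace ink, so a
#' global threshold of 65 removes them while preserving the curves; a pixel
#' exactly at the threshold counts as foreground.
#'
#' @param image a [ChartImage-class], a numeric matrix of gray values
#'   (0--255, or 0--1 which is rescaled), or an H x W x 3 RGB array.
#' @param threshold global gray threshold (default 65).
#' @return logical matrix, `TRUE` where the trace survives.
#' @examples
#' binarize(matrix(c(64, 65), 1)) # FALSE TRUE
#' @export
binarize <- function(image, threshold = 65L) {
  px <- if (is(image, "ChartImage")) image@pixels else image
  if (is.array(px) && length(dim(px)) == 3) {
    if (dim(px)[3] < 3) px <- px[, , 1]
    else px <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  }
  if (!is.matrix(px)) stop("image must be a matrix, 3-d array or ChartImage")
  if (length(px) == 0) stop("empty image")
  if (max(px) <= 1 && min(px) >= 0) px <- px * 255
  px >= threshold
}

#' Linear pixel-to-value mapping
#'
#' Maps an image row inside a curve region to its physical value by the
#' linear model `v = vmin + y'/h * (vmax - vmin)`, where `y'` is the row
#' index measured upward from the bottom edge of the valid region and
#' `h = rowMax - rowMin` is the region height. Image row indices grow
#' downward while values grow upward, hence the bottom row maps to `vmin`
#' and the top row to `vmax`.
#'
#' @param y image row(s), 1-based; fractional rows are allowed (e.g. the
#'   median of an even-length pixel run).
#' @param region a [RegionSpec-class].
#' @return physical value(s) in `[vmin, vmax]`.
#' @examples
#' rs <- regionSpec(c(11, 161, 1, 100), "FHR")
#' pixelToValue(161, rs) # 60 (bottom row)
#' pixelToValue(11, rs)  # 210 (top row)
#' @export
pixelToValue <- function(y, region) {
  b <- region@box
  if (any(y < b[1] - 1e-9 | y > b[2] + 1e-9))
    stop("row index outside the region's valid rows")
  h <- b[2] - b[1]
  yUp <- b[2] - y
  region@vmin + yUp / h * (region@vmax - region@vmin)
}

#' Extract a resampled trace from a binary mask region
#'
#' Samples the region at fixed horizontal intervals determined by the
#' region width and the recording duration. In each sampled column the
#' trace row is the median row of foreground pixels (robust to trace
#' thickness and speckles); rows are mapped to physical units with
#' [pixelToValue()]. Columns with no foreground are marked invalid and
#' filled by linear interpolation between the nearest valid neighbours;
#' gaps at the edges are held at the nearest valid value.
#'
#' @param mask logical matrix from [binarize()].
#' @param region a [RegionSpec-class] inside the mask bounds.
#' @param durationS duration spanned by the region (default 600 s).
#' @param outRate output sampling rate in Hz.
#' @return a [TraceSignal-class] of length `durationS * outRate`.
#' @export
extractTrace <- function(mask, region, durationS = 600, outRate = 4) {
  stopifnot(outRate > 0)
  b <- region@box
  if (b[1] < 1 || b[2] > nrow(mask) || b[3] < 1 || b[4] > ncol(mask))
    stop("region lies outside the mask bounds")
  n <- round(durationS * outRate)
  tOut <- (seq_len(n) - 1) / outRate
  cols <- b[3] + round(tOut / durationS * (b[4] - b[3]))
  sub <- mask[b[1]:b[2], , drop = FALSE]
  medRow <- rep(NA_real_, n)
  hits <- which(sub[, cols, drop = FALSE], arr.ind = TRUE)
  if (nrow(hits) == 0)
    stop("no trace found in region (", region@channel, " segment ",
         region@segmentIndex, ")")
  byCol <- split(hits[, 1], hits[, 2])
  idx <- as.integer(names(byCol))
  medRow[idx] <- vapply(byCol, stats::median, 1) + b[1] - 1
  valid <- !is.na(medRow)
  values <- rep(NA_real_, n)
  values[valid] <- pixelToValue(medRow[valid], region)
  if (!all(valid))
    values <- approx(tOut[valid], values[valid], xout = tOut, rule = 2)$y
  traceSignal(values, outRate, region@channel, valid = valid,
              startTime = region@segmentIndex * durationS)
}

#' Concatenate two consecutive trace segments chronologically
#'
#' @param seg1,seg2 [TraceSignal-class] objects with the same channel and
#'   sample rate; `seg1` precedes `seg2`. An empty `seg2` returns `seg1`
#'   unchanged.
#' @return the spliced [TraceSignal-class].
#' @export
spliceSegments <- function(seg1, seg2) {
  if (length(seg2) == 0) return(seg1)
  if (seg1@channel != seg2@channel) stop("channel mismatch in splice")
  if (seg1@sampleRate != seg2@sampleRate) stop("sample-rate mismatch in splice")
  traceSignal(c(seg1@values, seg2@values), seg1@sampleRate, seg1@channel,
              valid = c(seg1@valid, seg2@valid), startTime = seg1@startTime)
}

#' Region specifications implied by a chart layout
#'
#' @param layout a [ChartLayout-class].
#' @return list of four [RegionSpec-class] objects in reading order
#'   (FHR first 10 min, UC first 10 min, FHR second, UC second).
#' @export
layoutRegions <- function(layout) {
  b <- layout@regionBoxes
  list(regionSpec(b[1, ], "FHR", 0L), regionSpec(b[2, ], "UC", 0L),
       regionSpec(b[3, ], "FHR", 1L), regionSpec(b[4, ], "UC", 1L))
}

#' Digitize a chart page back to physical-unit series
#'
#' Composes the digitization pipeline: threshold binarization, column-wise
#' trace extraction from each of the four curve regions, pixel-to-value
#' mapping, resampling to `outRate`, and chronological splicing of the two
#' 10-minute segments per channel into complete 20-minute sequences.
#'
#' @param image a [ChartImage-class] (or gray matrix with `layout` given).
#' @param layout region geometry; defaults to the image's own layout.
#' @param outRate output sampling rate in Hz (default 4, the convention of
#'   the external signal database).
#' @param threshold binarization threshold.
#' @return list with `fhr` and `uc` [TraceSignal-class] objects of length
#'   `1200 * outRate`.
#' @export
digitizeChart <- function(image, layout = NULL, outRate = 4, threshold = 65L) {
  if (is.null(layout)) {
    if (!is(image, "ChartImage"))
      stop("layout must be supplied for a bare pixel matrix")
    layout <- image@layout
  }
  mask <- binarize(image, threshold)
  regions <- layoutRegions(layout)
  traces <- lapply(regions, extractTrace, mask = mask, durationS = 600,
                   outRate = outRate)
  list(fhr = spliceSegments(traces[[1]], traces[[3]]),
       uc = spliceSegments(traces[[2]], traces[[4]]))
}

#' Standardize a digitized recording into the 224 x 224 model input
#'
#' Re-renders the reconstructed 20-minute FHR and UC series as line plots
#' on a blank 224 x 224 canvas — FHR in the upper half against its
#' 60--210 bpm axis, UC in the lower half against 0--100 mmHg, both with the
#' same linear value-to-row scaling used on the chart — then replicates the
#' canvas to 3 channels and applies per-image Z-score normalization
#' `(x - mean)/sd` with an epsilon guard (a zero-variance canvas yields an
#' all-zero tensor). The mean and sd are recorded in the returned object.
#'
#' @param fhr,uc [TraceSignal-class] objects covering the full 20 minutes.
#' @param eps variance guard.
#' @return a [ModelInput-class].
#' @export
standardizeToInput <- function(fhr, uc, eps = 1e-8) {
  if (abs(duration(fhr) - 1200) > 1e-9 || abs(duration(uc) - 1200) > 1e-9)
    stop("signals must cover the full 20 minutes")
  canvas <- matrix(0, 224, 224)
  drawHalf <- function(canvas, sig, rows, rng) {
    box <- c(rows[1], rows[2], 1L, 224L)
    t <- (0:223) / 223 * 1200
    tsig <- (seq_along(sig@values) - 1) / sig@sampleRate
    v <- approx(tsig, sig@values, xout = pmin(t, max(tsig)), rule = 2)$y
    r <- valueToRow(v, box, rng[1], rng[2])
    r <- pmin(pmax(r, box[1]), box[2])
    for (j in 1:224) {
      lo <- if (j == 1) r[1] else min(r[j], r[j - 1])
      hi <- if (j == 1) r[1] else max(r[j], r[j - 1])
      canvas[lo:hi, j] <- 1
    }
    canvas
  }
  canvas <- drawHalf(canvas, fhr, c(1L, 112L), c(60, 210))
  canvas <- drawHalf(canvas, uc, c(113L, 224L), c(0, 100))
  m <- mean(canvas)
  s <- sqrt(mean((canvas - m)^2))
  norm <- if (s < eps) canvas * 0 else (canvas - m) / s
  tensor <- array(rep(norm, 3), c(224L, 224L, 3L))
  new("ModelInput", tensor = tensor,
      normalization = c(mean = m, sd = s))
}

#' Write digitized signals as CSV
#'
#' Columns: `time_s, fhr_bpm, uc_mmhg, valid_fhr, valid_uc`.
#'
#' @param fhr,uc [TraceSignal-class] objects at a common rate.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeDigitizedCSV <- function(fhr, uc, path) {
  stopifnot(length(fhr) == length(uc))
  write.csv(data.frame(
    time_s = (seq_along(fhr@values) - 1) / fhr@sampleRate,
    fhr_bpm = fhr@values, uc_mmhg = uc@values,
    valid_fhr = fhr@valid, valid_uc = uc@valid), path, row.names = FALSE)
  invisible(path)
}
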