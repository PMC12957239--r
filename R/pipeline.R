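# Orchestration: label mapping, the external WFDB signal adapter, and the
# end-to-end experiment runner.

#' Map annotation sources to the binary triage label
#'
#' Two labeling schemes are supported. `figo_binary` follows expert visual
#' interpretation: FIGO category I (normal) maps to reassuring, while the
#' suspicious (II) and abnormal (III) categories are amalgamated into
#' non-reassuring. `ph_threshold` uses the objective umbilical-artery pH
#' outcome: `pH >= 7.05` is reassuring (the boundary value inclusive) and
#' `pH < 7.05` non-reassuring.
#'
#' @param figo `"normal"`, `"suspicious"` or `"abnormal"` (may be NULL).
#' @param ph numeric umbilical-artery pH (may be NULL).
#' @param scheme `"figo_binary"` or `"ph_threshold"`.
#' @return `"reassuring"` or `"non_reassuring"`.
#' @examples
#' mapLabel(figo = "suspicious", scheme = "figo_binary") # non_reassuring
#' mapLabel(ph = 7.05, scheme = "ph_threshold")          # reassuring
#' @export
mapLabel <- function(figo = NULL, ph = NULL,
                     scheme = c("figo_binary", "ph_threshold")) {
  scheme <- match.arg(scheme)
  if (scheme == "figo_binary") {
    if (is.null(figo)) stop("figo_binary labeling requires a FIGO category")
    figo <- match.arg(figo, c("normal", "suspicious", "abnormal"))
    if (figo == "normal") "reassuring" else "non_reassuring"
  } else {
    if (is.null(ph)) stop("ph_threshold labeling requires a pH value")
    if (ph >= 7.05) "reassuring" else "non_reassuring"
  }
}

# ------------------------------------------------------------------ WFDB ---

#' Write a two-channel CTG record in WFDB format
#'
#' Writes a minimal WFDB record (format 16, little-endian 16-bit integers)
#' with FHR and UC channels and the umbilical-artery pH in a header comment.
#' Intended for interoperability tests and fixtures.
#'
#' @param path record path without extension (writes `path.hea`, `path.dat`).
#' @param fhr,uc [TraceSignal-class] objects at a common rate.
#' @param ph umbilical-artery pH stored as a header comment.
#' @param gain ADC units per physical unit.
#' @return invisibly, `path`.
#' @export
writeWFDBRecord <- function(path, fhr, uc, ph, gain = 100) {
  stopifnot(length(fhr) == length(uc), fhr@sampleRate == uc@sampleRate)
  record <- basename(path)
  n <- length(fhr)
  adc <- rbind(round(fhr@values * gain), round(uc@values * gain))
  storage.mode(adc) <- "integer"
  hea <- c(
    sprintf("%s 2 %g %d", record, fhr@sampleRate, n),
    sprintf("%s.dat 16 %g(0)/bpm 16 0 %d 0 0 FHR", record, gain, adc[1, 1]),
    sprintf("%s.dat 16 %g(0)/mmHg 16 0 %d 0 0 UC", record, gain, adc[2, 1]),
    sprintf("#pH:%.2f", ph))
  writeLines(hea, paste0(path, ".hea"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(as.vector(adc)), con, size = 2, endian = "little")
  invisible(path)
}

#' Load a WFDB CTG record
#'
#' Reads a WFDB header/signal pair (format 16), extracts the FHR and UC
#' channels by their description fields, converts ADC units to physical
#' units via gain and baseline, resamples to `outRate`, marks FHR dropout
#' samples (value 0) invalid and fills them by linear interpolation, crops
#' recordings longer than 20 minutes to the final 20 minutes, and derives
#' the binary label from the pH header comment.
#'
#' @param path record path without extension.
#' @param outRate delivered sampling rate (default 4 Hz).
#' @return list with `fhr`, `uc` ([TraceSignal-class]), `ph` and `label`.
#' @export
loadWFDBRecord <- function(path, outRate = 4) {
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) stop("header file not found: ", hea)
  lines <- readLines(hea)
  comments <- grep("^#", lines, value = TRUE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  nsamp <- as.integer(top[4])
  sigs <- lapply(lines[1 + seq_len(nsig)], function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    gainSpec <- tok[3]
    gain <- as.numeric(sub("\\(.*", "", gainSpec))
    baseline <- if (grepl("\\(", gainSpec))
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gainSpec)) else 0
    fmt <- sub("x.*", "", tok[2])
    list(file = tok[1], format = fmt, gain = gain, baseline = baseline,
         desc = if (length(tok) >= 9) paste(tok[9:length(tok)], collapse = " ")
                else "")
  })
  if (any(vapply(sigs, function(s) s$format != "16", TRUE)))
    stop("only WFDB format 16 is supported")
  datPath <- file.path(dirname(path), sigs[[1]]$file)
  raw <- readBin(datPath, "integer", n = nsig * nsamp, size = 2,
                 signed = TRUE, endian = "little")
  m <- matrix(raw, nrow = nsig)
  descs <- toupper(vapply(sigs, `[[`, "", "desc"))
  chIdx <- function(name) {
    i <- grep(name, descs)
    if (length(i) == 0) stop("record is missing the ", name, " channel")
    i[1]
  }
  iF <- chIdx("FHR"); iU <- chIdx("UC")
  phys <- function(i) (m[i, ] - sigs[[i]]$baseline) / sigs[[i]]$gain
  fhrRaw <- phys(iF); ucRaw <- phys(iU)
  phMatch <- regmatches(comments, regexpr("pH\\s*[:= ]\\s*([0-9.]+)", comments))
  if (length(phMatch) == 0) stop("record is missing the pH metadata comment")
  ph <- as.numeric(sub(".*?([0-9.]+)$", "\\1", phMatch[1]))

  resample <- function(v, valid) {
    tIn <- (seq_along(v) - 1) / fs
    nOut <- floor(max(tIn) * outRate) + 1
    tOut <- (seq_len(nOut) - 1) / outRate
    vOk <- approx(tIn[valid], v[valid], xout = tOut, rule = 2)$y
    validOut <- approx(tIn, as.numeric(valid), xout = tOut, rule = 2)$y >= 0.5
    list(values = vOk, valid = validOut)
  }
  fhrValid <- fhrRaw != 0
  if (!any(fhrValid)) stop("FHR channel contains only dropout samples")
  f <- resample(fhrRaw, fhrValid)
  u <- resample(ucRaw, rep(TRUE, length(ucRaw)))
  fhr <- traceSignal(f$values, outRate, "FHR", valid = f$valid)
  uc <- traceSignal(u$values, outRate, "UC", valid = u$valid)
  # crop to the final 20 minutes (closest to delivery)
  maxLen <- round(1200 * outRate)
  if (length(fhr) > maxLen) {
    keep <- (length(fhr) - maxLen + 1):length(fhr)
    fhr <- traceSignal(fhr@values[keep], outRate, "FHR", valid = fhr@valid[keep])
    uc <- traceSignal(uc@values[keep], outRate, "UC", valid = uc@valid[keep])
  }
  list(fhr = fhr, uc = uc, ph = ph,
       label = mapLabel(ph = ph, scheme = "ph_threshold"))
}

# ------------------------------------------------------------- experiment ---

#' Experiment configuration
#'
#' @param n number of synthetic recordings.
#' @param classRatio fraction of non-reassuring recordings.
#' @param seed master seed for synthesis, folds, initialization, training.
#' @param layout a [ChartLayout-class], or NULL to use the default.
#' @param layoutFile optional path to a layout JSON file (takes precedence
#'   over `layout`); must exist at configuration time.
#' @param train a [trainConfig()].
#' @param mode `"holdout"` (single stratified train/validation split) or
#'   `"cv"` (stratified k-fold cross-validation).
#' @param folds number of folds for `"cv"`.
#' @param valFraction validation fraction for `"holdout"` and for the inner
#'   early-stopping split in `"cv"`.
#' @param outDir optional output directory for artifacts.
#' @return a `RunConfig` list.
#' @export
runConfig <- function(n = 200L, classRatio = 0.5, seed = 0L, layout = NULL,
                      layoutFile = NULL, train = trainConfig(),
                      mode = c("holdout", "cv"), folds = 5L,
                      valFraction = 0.2, outDir = NULL) {
  mode <- match.arg(mode)
  if (!is.null(layoutFile)) {
    if (!file.exists(layoutFile))
      stop("layout file does not exist: ", layoutFile)
    layout <- readChartLayoutJSON(layoutFile)
  }
  if (is.null(layout)) layout <- defaultChartLayout()
  structure(list(n = as.integer(n), classRatio = classRatio,
                 seed = as.integer(seed), layout = layout, train = train,
                 mode = mode, folds = as.integer(folds),
                 valFraction = valFraction, outDir = outDir),
            class = "RunConfig")
}

#' Read a chart layout from a JSON sidecar
#'
#' @param path JSON file as written by [writeChartSample()] (the `layout`
#'   element) or a bare layout JSON of the same shape.
#' @return a [ChartLayout-class].
#' @export
readChartLayoutJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(j$layout)) j <- j$layout
  boxes <- matrix(as.integer(unlist(j$regionBoxes)), 4, 4,
                  dimnames = list(c("FHR1", "UC1", "FHR2", "UC2"),
                                  c("rowMin", "rowMax", "colMin", "colMax")))
  new("ChartLayout", pageSize = as.integer(j$pageSize), regionBoxes = boxes,
      gridSpacing = as.integer(j$gridSpacing),
      gridGray = as.integer(j$grays[["grid"]]),
      shadowGray = as.integer(j$grays[["shadow"]]),
      traceGray = as.integer(j$grays[["trace"]]),
      traceThickness = as.integer(j$traceThickness))
}

configManifest <- function(cfg) {
  summ <- list(
    n = cfg$n, classRatio = cfg$classRatio, seed = cfg$seed,
    mode = cfg$mode, folds = cfg$folds, valFraction = cfg$valFraction,
    train = unclass(cfg$train),
    layout = list(pageSize = cfg$layout@pageSize,
                  regionBoxes = as.vector(cfg$layout@regionBoxes),
                  gridSpacing = cfg$layout@gridSpacing,
                  grays = c(cfg$layout@gridGray, cfg$layout@shadowGray,
                            cfg$layout@traceGray),
                  traceThickness = cfg$layout@traceThickness),
    package = as.character(utils::packageVersion("ctgvision")))
  js <- jsonlite::toJSON(summ, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(js, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  list(config = summ, hash = hash)
}

# synthesize, digitize and standardize one page at a time so that only the
# 224 x 224 tensors are held in memory, never the full-resolution pages
streamDatasetTensor <- function(n, classRatio, seed, layout, outRate = 4,
                                verbose = FALSE) {
  plan <- datasetPlan(n, classRatio, seed)
  x <- array(0, c(224L, 224L, 3L, n))
  for (i in seq_len(n)) {
    s <- synthesizeSample(plan$labels[i], plan$seeds[i], layout)
    dg <- digitizeChart(s$image, layout, outRate = outRate)
    x[, , , i] <- standardizeToInput(dg$fhr, dg$uc)@tensor
    if (i %% 25 == 0) gc(FALSE)   # page matrices are large; keep heap tight
    if (verbose && i %% 50 == 0) message("  prepared ", i, "/", n)
  }
  list(x = x, y = as.integer(plan$labels == "non_reassuring"))
}

#' Run a full synthesize-digitize-train-evaluate experiment
#'
#' Generates a synthetic labeled chart dataset, digitizes every page back to
#' physical-unit series, standardizes them to 224 x 224 model inputs, trains
#' the CBAM-enhanced EfficientNet-B0 and evaluates it — either on a single
#' stratified holdout split or with stratified k-fold cross-validation
#' (metrics aggregated as mean +/- SD and summed confusion matrices). All
#' randomness derives from the config seed; a manifest records the config
#' and its hash so artifacts are reproducible.
#'
#' @param cfg a [runConfig()].
#' @param verbose print progress.
#' @return for `"holdout"`: list with `metrics`, `auc`, `ap`, `history`,
#'   `cm`, `manifest`, `net`. For `"cv"`: list with `report`
#'   ([FoldReport-class]), `manifest`.
#' @export
runExperiment <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "RunConfig"))
  manifest <- configManifest(cfg)
  if (verbose) message("synthesizing and digitizing ", cfg$n, " charts")
  dt <- streamDatasetTensor(cfg$n, cfg$classRatio, cfg$seed, cfg$layout,
                            verbose = verbose)
  x <- dt$x; y <- dt$y

  evalSplit <- function(trainIdx, valIdx, seedOffset = 0L) {
    net <- buildNetwork(seed = cfg$seed + seedOffset)
    tc <- cfg$train
    tc$seed <- cfg$seed + seedOffset
    fit <- trainModel(net, x[, , , trainIdx, drop = FALSE], y[trainIdx],
                      config = tc, valX = x[, , , valIdx, drop = FALSE],
                      valY = y[valIdx], verbose = verbose)
    scores <- predictScores(fit$net, x[, , , valIdx, drop = FALSE])
    cm <- confusionFromLabels(scores > 0.5, y[valIdx] == 1L)
    metrics <- metricsFromConfusion(cm)
    metrics <- c(metrics, auc = rocAUC(scores, y[valIdx] == 1L),
                 average_precision = prAP(scores, y[valIdx] == 1L))
    list(metrics = metrics, cm = cm, history = fit$history,
         scores = scores, net = fit$net)
  }

  if (cfg$mode == "holdout") {
    kSplit <- max(2L, round(1 / cfg$valFraction))
    fold <- stratifiedKFold(y == 1L, k = kSplit, seed = cfg$seed)
    valIdx <- which(fold == 1L)
    trainIdx <- which(fold != 1L)
    r <- evalSplit(trainIdx, valIdx)
    out <- list(metrics = r$metrics, auc = unname(r$metrics["auc"]),
                ap = unname(r$metrics["average_precision"]),
                history = r$history, cm = r$cm, manifest = manifest,
                net = r$net)
  } else {
    fold <- stratifiedKFold(y == 1L, k = cfg$folds, seed = cfg$seed)
    perFold <- list()
    for (f in seq_len(cfg$folds)) {
      if (verbose) message("fold ", f, "/", cfg$folds)
      testIdx <- which(fold == f)
      rest <- which(fold != f)
      inner <- stratifiedKFold(y[rest] == 1L,
                               k = max(2L, round(1 / cfg$valFraction)),
                               seed = cfg$seed + f)
      net <- buildNetwork(seed = cfg$seed + f)
      tc <- cfg$train; tc$seed <- cfg$seed + f
      fit <- trainModel(net, x[, , , rest[inner != 1L], drop = FALSE],
                        y[rest[inner != 1L]], config = tc,
                        valX = x[, , , rest[inner == 1L], drop = FALSE],
                        valY = y[rest[inner == 1L]], verbose = verbose)
      scores <- predictScores(fit$net, x[, , , testIdx, drop = FALSE])
      cm <- confusionFromLabels(scores > 0.5, y[testIdx] == 1L)
      metrics <- c(metricsFromConfusion(cm),
                   auc = rocAUC(scores, y[testIdx] == 1L),
                   average_precision = prAP(scores, y[testIdx] == 1L))
      perFold[[f]] <- list(metrics = metrics, cm = cm)
    }
    out <- list(report = aggregateFolds(perFold), manifest = manifest)
  }

  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    if (cfg$mode == "holdout") {
      jsonlite::write_json(list(metrics = as.list(out$metrics),
                                confusion = as.list(confusionCounts(out$cm))),
                           file.path(cfg$outDir, "report.json"),
                           auto_unbox = TRUE, digits = NA)
      write.csv(out$history, file.path(cfg$outDir, "history.csv"),
                row.names = FALSE)
    } else {
      rep <- out$report
      jsonlite::write_json(
        list(mean = as.list(rep@foldMean), sd = as.list(rep@foldSD),
             aggregated_confusion = as.list(confusionCounts(rep@aggregated))),
        file.path(cfg$outDir, "report.json"), auto_unbox = TRUE, digits = NA)
      write.csv(rep@perFold, file.path(cfg$outDir, "folds.csv"),
                row.names = FALSE)
    }
  }
  out
}
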