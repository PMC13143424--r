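# Recording-level cleaning, normalization, windowing and the HR<->LR
# degradation / naive-upsampling operators.

#' FIR filter specification
#'
#' @param notchHz mains notch frequency (NA disables the notch).
#' @param bandLo,bandHi passband edges in Hz; must satisfy
#'   \code{0 < bandLo < bandHi < rate/2} at application time.
#' @param firOrder number of filter taps minus one; default
#'   \code{3 * rate / bandLo}, rounded to the next even order (odd tap count,
#'   type-I linear phase).
#' @param windowFn taper name passed to the windowed-sinc design ("hamming").
#' @return list with class \code{"eegsr_filter_spec"}.
#' @export
filterSpec <- function(notchHz = 50, bandLo = 0.5, bandHi = 40,
                       firOrder = NULL, windowFn = "hamming") {
  structure(list(notchHz = notchHz, bandLo = bandLo, bandHi = bandHi,
                 firOrder = firOrder, windowFn = windowFn),
            class = "eegsr_filter_spec")
}

#' Train/validation/test split specification
#'
#' @param train,val,test fractions summing to 1.
#' @param seed shuffling seed.
#' @export
splitSpec <- function(train = 0.8, val = 0.1, test = 0.1, seed = 1) {
  if (abs(train + val + test - 1) > 1e-9) stop("fractions must sum to 1")
  structure(list(train = train, val = val, test = test,
                 seed = as.integer(seed)),
            class = "eegsr_split_spec")
}

#' Flag flatline and saturated channels
#'
#' A channel is a flatline when its variance is below 1e-10, and a
#' saturation when all consecutive differences are below 1e-8 in absolute
#' value (without being a flatline); otherwise it is good.
#'
#' @param x an [EEGWindow-class] or channels x samples matrix.
#' @return character vector of per-channel flags
#'   ("good", "flatline", "saturation").
#' @export
detectBadChannels <- function(x) {
  if (is(x, "EEGWindow")) x <- windowData(x)
  v <- apply(x, 1, stats::var)
  maxDiff <- apply(x, 1, function(r) max(abs(diff(r))))
  flags <- rep("good", nrow(x))
  flags[maxDiff < 1e-8] <- "saturation"
  flags[v < 1e-10] <- "flatline"
  flags
}

#' Reject or spline-repair a window with bad channels
#'
#' Windows with more than 30% bad channels are rejected (returns NULL);
#' otherwise bad channels are replaced by spherical-spline interpolation
#' from the good ones.
#'
#' @param window an [EEGWindow-class].
#' @param flags output of [detectBadChannels()]; recomputed when missing.
#' @param ... passed to [sphericalSplineReconstruct()].
#' @return the (possibly repaired) [EEGWindow-class], or NULL when rejected.
#' @export
rejectOrRepair <- function(window, flags = detectBadChannels(window), ...) {
  bad <- which(flags != "good")
  if (length(bad) == 0) return(window)
  if (length(bad) / length(flags) > 0.30) return(NULL)
  good <- setdiff(seq_along(flags), bad)
  X <- windowData(window)
  X[bad, ] <- sphericalSplineReconstruct(X, good, bad,
                                         windowMontage(window), ...)
  window@data <- X
  window
}

# windowed-sinc FIR taps via signal::fir1
.designFIR <- function(spec, rate) {
  if (spec$bandLo <= 0 || spec$bandHi <= spec$bandLo ||
      spec$bandHi >= rate / 2)
    stop(sprintf("passband [%g, %g] Hz infeasible at rate %g Hz",
                 spec$bandLo, spec$bandHi, rate))
  ord <- spec$firOrder
  if (is.null(ord)) ord <- ceiling(3 * rate / spec$bandLo)
  if (ord %% 2 == 1) ord <- ord + 1      # even order, odd tap count
  win <- switch(spec$windowFn, hamming = signal::hamming(ord + 1),
                hanning = signal::hanning(ord + 1),
                stop("unknown windowFn"))
  band <- signal::fir1(ord, c(spec$bandLo, spec$bandHi) / (rate / 2),
                       type = "pass", window = win)
  notch <- NULL
  if (is.finite(spec$notchHz) && spec$notchHz > spec$bandLo &&
      spec$notchHz < rate / 2) {
    lo <- max(spec$notchHz - 2, 0.01)
    hi <- min(spec$notchHz + 2, rate / 2 - 0.01)
    notch <- signal::fir1(ord, c(lo, hi) / (rate / 2), type = "stop",
                          window = win)
  }
  list(band = as.numeric(band), notch = if (!is.null(notch)) as.numeric(notch))
}

# zero-phase application: symmetric taps centered, forward and backward,
# with reflection padding against edge transients
.zeroPhaseFilter <- function(x, h) {
  np <- length(h)
  n <- length(x)
  pre <- x[pmin(n, seq(np + 1, 2, by = -1))]
  post <- x[pmax(1, seq(n - 1, n - np, by = -1))]
  xp <- c(pre, x, post)
  y <- stats::filter(xp, h, method = "convolution", sides = 2)
  y <- stats::filter(y, h, method = "convolution", sides = 2)
  as.numeric(y[(np + 1):(np + n)])
}

#' Apply notch + bandpass FIR filtering (zero phase)
#'
#' A mains notch (when enabled and inside the band) is applied first,
#' followed by the windowed-sinc bandpass. Both are applied forward and
#' backward (zero phase, squared magnitude response).
#'
#' @param x an [EEGWindow-class] or channels x samples matrix.
#' @param spec a [filterSpec()].
#' @param rate sampling rate in Hz (taken from the window when omitted).
#' @return filtered object of the same type as \code{x}.
#' @export
applyFilters <- function(x, spec = filterSpec(), rate = NULL) {
  isWin <- is(x, "EEGWindow")
  if (isWin) {
    rate <- samplingRate(x)
    X <- windowData(x)
  } else X <- x
  if (is.null(rate)) stop("rate required when x is a matrix")
  fir <- .designFIR(spec, rate)
  out <- t(apply(X, 1, function(r) {
    if (!is.null(fir$notch)) r <- .zeroPhaseFilter(r, fir$notch)
    .zeroPhaseFilter(r, fir$band)
  }))
  if (isWin) { x@data <- out; x } else out
}

#' Per-channel z-scoring with optional common average reference
#'
#' Each channel is centred and scaled as \code{(x - mu) / (sigma + 1e-8)}
#' with the population sigma; with \code{commonAverage = TRUE} the mean
#' across channels is subtracted first.
#'
#' @param x an [EEGWindow-class] or channels x samples matrix.
#' @param commonAverage apply a common average reference before scaling.
#' @return object of the same type as \code{x}.
#' @export
zscoreWindow <- function(x, commonAverage = FALSE) {
  isWin <- is(x, "EEGWindow")
  X <- if (isWin) windowData(x) else x
  if (commonAverage) X <- sweep(X, 2, colMeans(X))
  X <- .zscoreMatrix(X)
  if (isWin) { x@data <- X; x } else X
}

#' Segment a recording into windows and split train/val/test
#'
#' Cuts non-overlapping consecutive windows of \code{duration} seconds, then
#' shuffles with the split seed and partitions by the split fractions
#' (test and validation sizes are floors; the remainder trains).
#'
#' @param data channels x samples recording matrix.
#' @param rate sampling rate, Hz.
#' @param montage the [Montage-class] for the rows.
#' @param duration window length in seconds (2 by default).
#' @param split a [splitSpec()].
#' @param labels optional integer label per window (recycled); default -1.
#' @return list with elements \code{train}, \code{val}, \code{test}, each a
#'   list of [EEGWindow-class].
#' @export
segmentAndSplit <- function(data, rate, montage, duration = 2,
                            split = splitSpec(), labels = -1L) {
  S <- round(rate * duration)
  nw <- floor(ncol(data) / S)
  if (nw < 3) stop("recording too short: fewer than 3 windows")
  labels <- rep_len(as.integer(labels), nw)
  windows <- lapply(seq_len(nw), function(w)
    new("EEGWindow", data = data[, ((w - 1) * S + 1):(w * S), drop = FALSE],
        rate = rate, duration = duration, label = labels[w],
        montage = montage))
  set.seed(split$seed)
  ord <- sample.int(nw)
  nTest <- floor(nw * split$test)
  nVal <- floor(nw * split$val)
  idxTest <- ord[seq_len(nTest)]
  idxVal <- ord[nTest + seq_len(nVal)]
  idxTrain <- ord[(nTest + nVal + 1):nw]
  list(train = windows[idxTrain], val = windows[idxVal],
       test = windows[idxTest])
}

#' Super-resolution task constructors
#'
#' \code{spatialTask} removes electrodes, keeping the coverage-maximizing
#' subset from [selectLrSubset()] (or an explicit one); \code{temporalTask}
#' decimates the sampling rate.
#'
#' @param montage the high-density [Montage-class].
#' @param factor upsampling factor (2, 4 or 8; 1 is the identity).
#' @param lrChannels optional explicit 1-based retained channel indices.
#' @return an [SRTask-class].
#' @export
spatialTask <- function(montage, factor, lrChannels = NULL) {
  if (is.null(lrChannels)) lrChannels <- selectLrSubset(montage, factor)
  if (length(lrChannels) * factor != nChannels(montage))
    stop("lrChannels times factor must equal the montage size")
  new("SRTask", mode = "spatial", factor = as.integer(factor),
      lrChannels = as.integer(lrChannels), lrRate = NA_real_)
}

#' @rdname spatialTask
#' @param hrRate high-resolution sampling rate in Hz.
#' @export
temporalTask <- function(hrRate, factor) {
  new("SRTask", mode = "temporal", factor = as.integer(factor),
      lrChannels = integer(0), lrRate = hrRate / factor)
}

#' Degrade a high-resolution window to its low-resolution counterpart
#'
#' Spatial mode keeps the task's channel rows (order preserved, time axis
#' untouched); temporal mode keeps every factor-th sample starting at sample
#' 0 (anti-aliasing is assumed from the prior bandpass).
#'
#' @param hr an [EEGWindow-class].
#' @param task an [SRTask-class].
#' @return the low-resolution [EEGWindow-class].
#' @export
degradeWindow <- function(hr, task) {
  if (task@mode == "spatial") {
    if (task@factor == 1L) return(hr)
    idx <- task@lrChannels
    if (any(idx < 1) || any(idx > nChannels(hr)))
      stop("lrChannels out of range")
    new("EEGWindow", data = windowData(hr)[idx, , drop = FALSE],
        rate = samplingRate(hr), duration = hr@duration,
        label = windowLabel(hr),
        montage = montageSubset(windowMontage(hr), idx))
  } else {
    if (task@factor == 1L) return(hr)
    S <- ncol(windowData(hr))
    if (S %% task@factor != 0)
      stop("factor must divide the sample count")
    keep <- seq(1, S, by = task@factor)
    new("EEGWindow", data = windowData(hr)[, keep, drop = FALSE],
        rate = samplingRate(hr) / task@factor, duration = hr@duration,
        label = windowLabel(hr), montage = windowMontage(hr))
  }
}

#' @rdname degradeWindow
#' @export
degradeSpatial <- function(hr, task) {
  stopifnot(task@mode == "spatial")
  degradeWindow(hr, task)
}

#' @rdname degradeWindow
#' @export
degradeTemporal <- function(hr, task) {
  stopifnot(task@mode == "temporal")
  degradeWindow(hr, task)
}

#' Naive upsampling of a low-resolution window to the HR shape
#'
#' Spatial mode places the LR rows at their HR montage positions and fills
#' the rest with zeros; temporal mode linearly interpolates each channel
#' onto the HR time grid (holding the last LR sample beyond the final LR
#' point, so the output length is exactly factor times the LR length).
#'
#' @param lr the low-resolution [EEGWindow-class].
#' @param task an [SRTask-class].
#' @param montage the high-density target [Montage-class].
#' @return HR-shaped numeric matrix.
#' @export
upsampleToHrShape <- function(lr, task, montage) {
  X <- windowData(lr)
  if (task@mode == "spatial") {
    out <- matrix(0, nChannels(montage), ncol(X))
    out[task@lrChannels, ] <- X
    out
  } else {
    Llr <- ncol(X)
    Lhr <- Llr * task@factor
    pos <- (seq_len(Lhr) - 1) / task@factor + 1
    t(apply(X, 1, function(r)
      stats::approx(seq_len(Llr), r, xout = pos, rule = 2)$y))
  }
}

#' Spherical-spline upsampling baseline (spatial mode)
#'
#' The classical non-learned baseline: LR channels are copied through
#' unchanged and missing channels are filled by spherical-spline
#' interpolation (one transfer matrix applied to every time sample).
#'
#' @inheritParams upsampleToHrShape
#' @param ... passed to [splineTransferMatrix()].
#' @return HR-shaped numeric matrix.
#' @export
splineUpsampleBaseline <- function(lr, task, montage, ...) {
  if (task@mode != "spatial") stop("spline baseline applies to spatial tasks")
  X <- windowData(lr)
  out <- matrix(0, nChannels(montage), ncol(X))
  out[task@lrChannels, ] <- X
  missing <- setdiff(seq_len(nChannels(montage)), task@lrChannels)
  if (length(missing))
    out[missing, ] <- sphericalSplineReconstruct(out, task@lrChannels,
                                                 missing, montage, ...)
  out
}

#' Read a plain-text multichannel recording
#'
#' Expects a delimited text file with one column per channel (header row of
#' channel names) and one row per sample.
#'
#' @param path file path.
#' @param rate sampling rate in Hz.
#' @param sep field separator (default comma).
#' @return list with \code{data} (channels x samples matrix, rownames =
#'   channel names) and \code{rate}.
#' @export
readRecordingText <- function(path, rate, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE)
  list(data = t(as.matrix(tab)), rate = rate)
}
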