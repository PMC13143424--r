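# Welch spectral estimation (power and cross spectra) on stats::fft.
# Fixed conventions for determinism: Hann taper, 50% overlap, segment
# length min(L, 256), one-sided density scaling.

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

# windowed one-sided FFT segments: returns complex (nFreqBins x nSegments)
.welchSegments <- function(x, segLength, overlap = 0.5) {
  L <- length(x)
  segLength <- min(segLength, L)
  step <- max(1, floor(segLength * (1 - overlap)))
  starts <- seq(1, L - segLength + 1, by = step)
  w <- .hann(segLength)
  nf <- segLength %/% 2 + 1
  out <- matrix(0i, nf, length(starts))
  for (k in seq_along(starts)) {
    seg <- x[starts[k] + seq_len(segLength) - 1] * w
    out[, k] <- stats::fft(seg)[seq_len(nf)]
  }
  attr(out, "segLength") <- segLength
  attr(out, "wNorm") <- sum(w^2)
  out
}

#' Welch power spectral density
#'
#' Hann-tapered segments of length \code{min(L, segLength)} with 50%
#' overlap, averaged one-sided density.
#'
#' @param x numeric vector, or channels x samples matrix (per-row PSDs).
#' @param rate sampling rate, Hz.
#' @param segLength maximum segment length (default 256).
#' @return list with \code{freq} (Hz) and \code{psd} (vector, or channels x
#'   frequency matrix).
#' @export
welchPsd <- function(x, rate, segLength = 256) {
  if (is.matrix(x)) {
    res <- apply(x, 1, function(r) welchPsd(r, rate, segLength)$psd)
    f <- welchPsd(x[1, ], rate, segLength)$freq
    return(list(freq = f, psd = t(res)))
  }
  Fm <- .welchSegments(x, segLength)
  segLength <- attr(Fm, "segLength")
  scale <- 1 / (rate * attr(Fm, "wNorm"))
  p <- rowMeans(Mod(Fm)^2) * scale
  nf <- length(p)
  p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]          # one-sided doubling
  list(freq = (seq_len(nf) - 1) * rate / segLength, psd = p)
}

#' Welch cross-spectral density of two channels
#'
#' @param x,y numeric vectors of equal length.
#' @inheritParams welchPsd
#' @return list with \code{freq}, complex \code{sxy}, and real \code{sxx},
#'   \code{syy}.
#' @export
welchCsd <- function(x, y, rate, segLength = 256) {
  Fx <- .welchSegments(x, segLength)
  Fy <- .welchSegments(y, segLength)
  segLength <- attr(Fx, "segLength")
  scale <- 1 / (rate * attr(Fx, "wNorm"))
  list(freq = (seq_len(nrow(Fx)) - 1) * rate / segLength,
       sxy = rowMeans(Fx * Conj(Fy)) * scale,
       sxx = rowMeans(Mod(Fx)^2) * scale,
       syy = rowMeans(Mod(Fy)^2) * scale)
}
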