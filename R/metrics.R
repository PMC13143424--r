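# Reconstruction-fidelity metrics: energy-normalized error, per-channel
# correlation, 1-D structural similarity, log-scale signal-to-error ratios,
# topographic smoothness, band-power preservation, imaginary coherence and
# the Frechet feature distance.

.asMat <- function(x) if (is(x, "EEGWindow")) windowData(x) else x

#' Normalized mean squared error
#'
#' \eqn{\|\hat X - X\|_2^2 / \|X\|_2^2} over all entries.
#' @param xhat,x reconstruction and reference ([EEGWindow-class] or matrix),
#'   same shape.
#' @export
nmse <- function(xhat, x) {
  xhat <- .asMat(xhat); x <- .asMat(x)
  stopifnot(all(dim(xhat) == dim(x)))
  e <- sum(x^2)
  if (e == 0) stop("zero-energy reference signal")
  sum((xhat - x)^2) / e
}

#' Mean per-channel Pearson correlation
#'
#' Pearson correlation per channel, averaged across the montage; constant
#' channels are excluded with a warning.
#' @inheritParams nmse
#' @export
pcc <- function(xhat, x) {
  xhat <- .asMat(xhat); x <- .asMat(x)
  stopifnot(all(dim(xhat) == dim(x)))
  r <- vapply(seq_len(nrow(x)), function(c) {
    if (stats::sd(xhat[c, ]) == 0 || stats::sd(x[c, ]) == 0) NA_real_
    else stats::cor(xhat[c, ], x[c, ])
  }, numeric(1))
  if (anyNA(r)) warning("constant channel(s) excluded from PCC")
  mean(r, na.rm = TRUE)
}

# valid-mode weighted sliding moments
.slideMean <- function(v, w) {
  n <- length(w)
  out <- stats::filter(v, rev(w), method = "convolution", sides = 1)
  as.numeric(out[n:length(v)])
}

#' 1-D structural similarity
#'
#' Per-channel sliding-window SSIM (Gaussian window of length 11, sigma
#' 1.5; c1 = (0.01 R)^2, c2 = (0.03 R)^2 with R the dynamic range of the
#' reference), averaged over window positions and channels. Signals shorter
#' than the window fall back to one global window.
#' @inheritParams nmse
#' @export
ssimMetric <- function(xhat, x) {
  xhat <- .asMat(xhat); x <- .asMat(x)
  stopifnot(all(dim(xhat) == dim(x)))
  R <- diff(range(x))
  if (R == 0) R <- 1
  c1 <- (0.01 * R)^2
  c2 <- (0.03 * R)^2
  L <- ncol(x)
  if (L >= 11) {
    g <- exp(-((seq_len(11) - 6)^2) / (2 * 1.5^2))
  } else {
    g <- rep(1, L)
  }
  g <- g / sum(g)
  perChan <- vapply(seq_len(nrow(x)), function(c) {
    a <- xhat[c, ]; b <- x[c, ]
    mua <- .slideMean(a, g); mub <- .slideMean(b, g)
    va <- .slideMean(a^2, g) - mua^2
    vb <- .slideMean(b^2, g) - mub^2
    cab <- .slideMean(a * b, g) - mua * mub
    mean(((2 * mua * mub + c1) * (2 * cab + c2)) /
         ((mua^2 + mub^2 + c1) * (va + vb + c2)))
  }, numeric(1))
  mean(perChan)
}

#' Peak signal-to-noise ratio (dB), MAX = 1 for normalized signals
#'
#' @inheritParams nmse
#' @return \code{10 log10(1 / MSE)}; \code{Inf} when the reconstruction is
#'   exact.
#' @export
psnr <- function(xhat, x) {
  xhat <- .asMat(xhat); x <- .asMat(x)
  mse <- mean((xhat - x)^2)
  if (mse == 0) return(Inf)
  10 * log10(1 / mse)
}

#' Signal-to-noise ratio of a reconstruction (dB)
#'
#' \eqn{10 \log_{10}(\|X\|_2^2 / \|\hat X - X\|_2^2)}.
#' @inheritParams nmse
#' @export
snr <- function(xhat, x) {
  xhat <- .asMat(xhat); x <- .asMat(x)
  err <- sum((xhat - x)^2)
  if (err == 0) return(Inf)
  10 * log10(sum(x^2) / err)
}

#' Topographic smoothness (discrete Laplacian residual)
#'
#' Builds a k-nearest-neighbour graph on the montage (great-circle
#' distance); the residual of a channel at each time sample is its value
#' minus the mean of its neighbours. Returns the mean squared residual over
#' channels and time (0 for spatially constant fields; scales
#' quadratically with amplitude).
#'
#' @param xhat reconstruction ([EEGWindow-class] or matrix).
#' @param montage the [Montage-class] (taken from the window when omitted).
#' @param k number of neighbours (default 4).
#' @export
topoSmoothness <- function(xhat, montage = NULL, k = 4) {
  if (is(xhat, "EEGWindow") && is.null(montage)) montage <- windowMontage(xhat)
  X <- .asMat(xhat)
  C <- nrow(X)
  if (C < k + 1) stop("need more channels than neighbours")
  D <- greatCircleDist(montage@positions)
  res <- X
  for (c in seq_len(C)) {
    d <- D[c, -c]
    thr <- sort(d)[k] + 1e-12        # include ties for permutation stability
    nb <- setdiff(which(D[c, ] <= thr), c)
    res[c, ] <- X[c, ] - colMeans(X[nb, , drop = FALSE])
  }
  mean(res^2)
}

#' Per-band log band-power mean absolute error
#'
#' Welch band powers per channel; returns
#' \eqn{|\log \hat P_i - \log P_i|} averaged over channels, per band.
#'
#' @inheritParams nmse
#' @param rate sampling rate, Hz (taken from windows when available).
#' @param bands named list of c(lo, hi) band edges; defaults to
#'   [eegBands()] clipped to the Nyquist range.
#' @return named numeric vector, one value per band.
#' @export
bandpowerMae <- function(xhat, x, rate = NULL, bands = NULL) {
  if (is(x, "EEGWindow") && is.null(rate)) rate <- samplingRate(x)
  xhat <- .asMat(xhat); x <- .asMat(x)
  if (is.null(rate)) stop("rate required")
  if (is.null(bands)) {
    bands <- Filter(function(b) b[1] < rate / 2, eegBands())
    bands <- lapply(bands, function(b) c(b[1], min(b[2], rate / 2)))
  }
  ph <- welchPsd(xhat, rate)
  pr <- welchPsd(x, rate)
  vapply(bands, function(b) {
    sel <- ph$freq >= b[1] & ph$freq <= b[2]
    if (!any(sel)) stop("empty band after discretization")
    df <- ph$freq[2] - ph$freq[1]
    bh <- rowSums(ph$psd[, sel, drop = FALSE]) * df
    br <- rowSums(pr$psd[, sel, drop = FALSE]) * df
    mean(abs(log(bh) - log(br)))
  }, numeric(1))
}

#' Mean imaginary coherence between channel pairs
#'
#' Welch cross-spectra per channel pair; coherency
#' \eqn{S_{xy}/\sqrt{S_{xx} S_{yy}}}; returns the mean of the absolute
#' imaginary part over pairs and band bins. Insensitive to zero-lag
#' (volume-conducted) coupling and to common amplitude scaling.
#'
#' @param x an [EEGWindow-class] or channels x samples matrix.
#' @param rate sampling rate (from the window when omitted).
#' @param band c(lo, hi) Hz analysis band; defaults to the whole axis.
#' @export
imagCoherence <- function(x, rate = NULL, band = NULL) {
  if (is(x, "EEGWindow") && is.null(rate)) rate <- samplingRate(x)
  X <- .asMat(x)
  if (is.null(rate)) stop("rate required")
  C <- nrow(X)
  if (C < 2) stop("need at least two channels")
  vals <- c()
  for (i in seq_len(C - 1)) for (j in (i + 1):C) {
    cs <- welchCsd(X[i, ], X[j, ], rate)
    coh <- cs$sxy / sqrt(cs$sxx * cs$syy)
    sel <- if (is.null(band)) rep(TRUE, length(cs$freq))
           else cs$freq >= band[1] & cs$freq <= band[2]
    vals <- c(vals, abs(Im(coh[sel])))
  }
  mean(vals)
}

#' Frechet distance between two Gaussians
#'
#' \eqn{\|\mu_1-\mu_2\|^2 + Tr(\Sigma_1 + \Sigma_2 -
#' 2(\Sigma_1\Sigma_2)^{1/2})}; the trace of the matrix square root is
#' computed from the eigenvalues of \eqn{\Sigma_1 \Sigma_2} with negative
#' values clipped at zero.
#'
#' @param mu1,mu2 mean vectors.
#' @param sigma1,sigma2 symmetric PSD covariance matrices.
#' @export
frechetDistance <- function(mu1, sigma1, mu2, sigma2) {
  sigma1 <- as.matrix(sigma1); sigma2 <- as.matrix(sigma2)
  if (max(abs(sigma1 - t(sigma1))) > 1e-8 ||
      max(abs(sigma2 - t(sigma2))) > 1e-8)
    stop("covariance matrices must be symmetric")
  ev <- eigen(sigma1 %*% sigma2, only.values = TRUE)$values
  ev <- pmax(Re(ev), 0)
  sum((mu1 - mu2)^2) + sum(diag(sigma1)) + sum(diag(sigma2)) -
    2 * sum(sqrt(ev))
}

#' Fixed-seed random convolutional feature extractor
#'
#' A stand-in for a pretrained EEG feature network: random (but fixed-seed)
#' depthwise-mixing convolution, ReLU, then global mean/max/sd pooling and
#' a random linear map to \code{dim} features. Weights are generated once
#' per channel count and cached, so features are deterministic.
#'
#' @param dim feature dimension.
#' @param seed weight seed.
#' @return function mapping an [EEGWindow-class] or matrix to a length-dim
#'   feature vector.
#' @export
defaultFeatureExtractor <- function(dim = 16, seed = 42) {
  cacheEnv <- new.env(parent = emptyenv())
  function(w) {
    X <- .asMat(w)
    C <- nrow(X)
    key <- as.character(C)
    if (is.null(cacheEnv[[key]])) {
      set.seed(seed + C)
      cacheEnv[[key]] <- list(
        W = array(stats::rnorm(8 * C * 5, sd = 1 / sqrt(5 * C)), c(8, C, 5)),
        P = matrix(stats::rnorm(dim * 24, sd = 1 / sqrt(24)), dim, 24))
    }
    wts <- cacheEnv[[key]]
    p <- list("fe.W" = wts$W, "fe.b" = numeric(8))
    h <- .fwdConv1d(p, "fe", array(X, c(dim(X), 1)))$y[, , 1]
    h <- pmax(h, 0)
    feats <- c(rowMeans(h), apply(h, 1, max), apply(h, 1, stats::sd))
    as.numeric(wts$P %*% feats)
  }
}

#' Frechet distance between feature distributions of two window sets
#'
#' Fits Gaussian moments to extractor features of real and reconstructed
#' windows and returns their Frechet distance.
#'
#' @param real,fake lists of [EEGWindow-class] (or matrices).
#' @param extractor feature function; default [defaultFeatureExtractor()].
#' @export
eegFid <- function(real, fake, extractor = defaultFeatureExtractor()) {
  if (length(real) < 2 || length(fake) < 2)
    stop("need at least 2 windows per side")
  Fr <- t(vapply(real, extractor, numeric(length(extractor(real[[1]])))))
  Ff <- t(vapply(fake, extractor, numeric(ncol(Fr))))
  frechetDistance(colMeans(Fr), stats::cov(Fr), colMeans(Ff), stats::cov(Ff))
}

#' Full metric report for a reconstruction
#'
#' @inheritParams nmse
#' @param rate sampling rate (from windows when available).
#' @param montage montage for the topographic metrics.
#' @param fid optional precomputed Frechet feature distance.
#' @return named list (JSON-serializable) with all fidelity metrics plus
#'   the Welch conventions used.
#' @export
metricReport <- function(xhat, x, rate = NULL, montage = NULL, fid = NULL) {
  if (is(x, "EEGWindow")) {
    if (is.null(rate)) rate <- samplingRate(x)
    if (is.null(montage)) montage <- windowMontage(x)
  }
  bp <- bandpowerMae(xhat, x, rate)
  mseVal <- mean((.asMat(xhat) - .asMat(x))^2)
  list(nmse = nmse(xhat, x), pcc = pcc(xhat, x),
       ssim = ssimMetric(xhat, x), psnr_db = psnr(xhat, x),
       snr_db = snr(xhat, x), mse = mseVal, rmse = sqrt(mseVal),
       topo_smoothness = if (!is.null(montage) &&
                             nrow(.asMat(xhat)) >= 5)
         topoSmoothness(xhat, montage) else NA_real_,
       bandpower_mae = as.list(bp),
       imag_coherence = imagCoherence(xhat, rate = rate),
       fid = fid,
       welch = list(segLength = 256, overlap = 0.5, window = "hann"))
}
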