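#' @import methods
#' @importFrom stats fft rnorm runif sd var setNames
NULL

#' Electrode montage on the unit sphere
#'
#' A named set of scalp electrodes with 3-D head-frame positions
#' (x right, y front, z up), projected onto the unit sphere. Only the
#' angular geometry is used downstream (spherical-spline interpolation,
#' leadfield gains, coverage-maximizing channel subsets), so unit-sphere
#' positions lose nothing.
#'
#' @slot names character vector of electrode labels (10-10 nomenclature or
#'   synthetic grid labels), unique.
#' @slot positions numeric C x 3 matrix of unit-norm positions.
#' @slot rank integer vector, the canonical 0-based order of each electrode;
#'   always a permutation of \code{0:(C-1)}.
#' @seealso [buildStandardMontage()], [selectLrSubset()]
#' @export
setClass("Montage",
  representation(names = "character", positions = "matrix", rank = "integer"),
  validity = function(object) {
    C <- length(object@names)
    msg <- character(0)
    if (anyDuplicated(object@names)) msg <- c(msg, "electrode names must be unique")
    if (!is.numeric(object@positions) || nrow(object@positions) != C ||
        ncol(object@positions) != 3)
      msg <- c(msg, "positions must be a C x 3 numeric matrix")
    else {
      if (!all(is.finite(object@positions))) msg <- c(msg, "positions must be finite")
      else {
        nrm <- sqrt(rowSums(object@positions^2))
        if (any(abs(nrm - 1) > 1e-9))
          msg <- c(msg, "positions must have unit norm (within 1e-9)")
      }
    }
    if (length(object@rank) != C || !identical(sort(object@rank), 0:(C - 1) + 0L))
      msg <- c(msg, "rank must be a permutation of 0..C-1")
    if (length(msg)) msg else TRUE
  })

#' One fixed-duration multichannel EEG segment
#'
#' Holds a channels x samples real matrix together with its sampling rate,
#' duration, integer class label and the montage it was recorded (or
#' simulated) on. Values are typically in per-channel z-scored units.
#'
#' @slot data numeric channels x samples matrix.
#' @slot rate sampling rate in Hz.
#' @slot duration window length in seconds; \code{samples == round(rate * duration)}.
#' @slot label integer class id (0-based; -1 means unlabelled).
#' @slot montage the [Montage-class] the rows refer to.
#' @export
setClass("EEGWindow",
  representation(data = "matrix", rate = "numeric", duration = "numeric",
                 label = "integer", montage = "Montage"),
  validity = function(object) {
    msg <- character(0)
    if (!all(is.finite(object@data))) msg <- c(msg, "data must be finite")
    if (nrow(object@data) != length(object@montage@names))
      msg <- c(msg, "data must have one row per montage electrode")
    if (ncol(object@data) != round(object@rate * object@duration))
      msg <- c(msg, "samples must equal round(rate * duration)")
    if (object@rate <= 0) msg <- c(msg, "rate must be positive")
    if (length(msg)) msg else TRUE
  })

#' Super-resolution task specification
#'
#' Describes one degradation/reconstruction setting: spatial mode removes
#' electrodes (keeping \code{lrChannels}), temporal mode decimates the
#' sampling rate by \code{factor}.
#'
#' @slot mode "spatial" or "temporal".
#' @slot factor integer upsampling factor (2, 4 or 8; 1 is the identity).
#' @slot lrChannels ordered 1-based row indices of the retained low-density
#'   channels (spatial mode; empty otherwise).
#' @slot lrRate low-resolution sampling rate in Hz (temporal mode; NA otherwise).
#' @export
setClass("SRTask",
  representation(mode = "character", factor = "integer",
                 lrChannels = "integer", lrRate = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (!object@mode %in% c("spatial", "temporal"))
      msg <- c(msg, "mode must be 'spatial' or 'temporal'")
    if (object@factor < 1L) msg <- c(msg, "factor must be >= 1")
    if (object@mode == "spatial" && length(object@lrChannels) == 0 &&
        object@factor > 1L)
      msg <- c(msg, "spatial task needs lrChannels")
    if (object@mode == "temporal" && !is.finite(object@lrRate))
      msg <- c(msg, "temporal task needs a finite lrRate")
    if (length(msg)) msg else TRUE
  })

#' Diffusion noise schedule
#'
#' The variance schedule of the forward diffusion process: per-step noise
#' variances \eqn{\beta_t}, \eqn{\alpha_t = 1 - \beta_t} and cumulative
#' products \eqn{\bar\alpha_t} governing the marginal
#' \eqn{x_t = \sqrt{\bar\alpha_t} x_0 + \sqrt{1-\bar\alpha_t}\,\epsilon}.
#'
#' @slot nSteps number of diffusion steps T.
#' @slot beta,alpha,alphaBar numeric length-T vectors (t = 1..T maps to
#'   timestep 0..T-1).
#' @slot predictionType what the denoiser outputs: "sample" (clean signal)
#'   or "epsilon" (the added noise).
#' @slot clipSamples logical; whether samplers clip predictions to [-1, 1]
#'   (disabled by default).
#' @export
setClass("NoiseSchedule",
  representation(nSteps = "integer", beta = "numeric", alpha = "numeric",
                 alphaBar = "numeric", predictionType = "character",
                 clipSamples = "logical"),
  validity = function(object) {
    msg <- character(0)
    Tn <- object@nSteps
    if (length(object@beta) != Tn || length(object@alphaBar) != Tn)
      msg <- c(msg, "beta and alphaBar must have length nSteps")
    if (any(object@beta <= 0) || any(object@beta >= 1))
      msg <- c(msg, "beta must lie in (0, 1)")
    if (any(diff(object@alphaBar) >= 0))
      msg <- c(msg, "alphaBar must be strictly decreasing")
    if (object@alphaBar[1] <= 0.9)
      msg <- c(msg, "alphaBar[1] must stay near 1 (beta[1] too large)")
    if (!object@predictionType %in% c("sample", "epsilon"))
      msg <- c(msg, "predictionType must be 'sample' or 'epsilon'")
    if (length(msg)) msg else TRUE
  })
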