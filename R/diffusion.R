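# Noise schedule, forward noising, the training objective and the
# one-step / multi-step samplers.

#' Build the DDPM noise schedule
#'
#' The default shape interpolates the per-step noise variance linearly in t
#' between the stated endpoints, so min(beta) = betaMin and max(beta) =
#' betaMax exactly and the terminal marginal is essentially pure noise
#' (alpha-bar at T-1 below 1e-2). The alternative "cosine" shape computes
#' the squared-cosine alpha-bar curve (offset s = 0.008, per-step beta
#' capped at 0.999), converts it to raw betas and affinely rescales them to
#' the same endpoints; because the cosine curve concentrates its largest
#' betas in the last few steps, the rescaled variant keeps substantial
#' signal at t = T-1 and is provided for comparison only (see the methods
#' vignette).
#'
#' @param nSteps number of diffusion steps T (default 1000).
#' @param betaMin,betaMax endpoints of the beta range.
#' @param predictionType "sample" (denoiser outputs the clean signal,
#'   default) or "epsilon" (outputs the noise).
#' @param clipSamples clip sampler outputs to [-1, 1] (disabled by default).
#' @param shape "linear" (default) or "cosine" (rescaled squared-cosine).
#' @return a [NoiseSchedule-class].
#' @export
makeSchedule <- function(nSteps = 1000, betaMin = 1e-4, betaMax = 0.015,
                         predictionType = c("sample", "epsilon"),
                         clipSamples = FALSE,
                         shape = c("linear", "cosine")) {
  predictionType <- match.arg(predictionType)
  shape <- match.arg(shape)
  if (!(betaMin > 0 && betaMin < betaMax && betaMax < 1))
    stop("need 0 < betaMin < betaMax < 1")
  Tn <- as.integer(nSteps)
  if (shape == "linear") {
    beta <- seq(betaMin, betaMax, length.out = Tn)
  } else {
    s <- 0.008
    f <- function(t) cos((t / Tn + s) / (1 + s) * pi / 2)^2
    abar <- f(0:Tn) / f(0)
    beta <- pmin(1 - abar[-1] / abar[-(Tn + 1)], 0.999)
    beta <- betaMin + (beta - min(beta)) / (max(beta) - min(beta)) *
            (betaMax - betaMin)
  }
  alpha <- 1 - beta
  new("NoiseSchedule", nSteps = Tn, beta = beta, alpha = alpha,
      alphaBar = cumprod(alpha), predictionType = predictionType,
      clipSamples = clipSamples)
}

#' Forward diffusion noising
#'
#' \eqn{x_t = \sqrt{\bar\alpha_t}\, x_0 + \sqrt{1-\bar\alpha_t}\,\epsilon}.
#'
#' @param x0 clean signal (matrix or \code{(C, L, B)} array).
#' @param eps standard-normal noise, same shape.
#' @param t 0-based timestep, scalar or one per batch element.
#' @param schedule a [NoiseSchedule-class].
#' @export
addNoise <- function(x0, eps, t, schedule) {
  if (any(t < 0) || any(t >= schedule@nSteps)) stop("timestep out of range")
  ab <- schedule@alphaBar[t + 1L]
  if (length(t) == 1 || length(dim(x0)) < 3)
    return(sqrt(ab) * x0 + sqrt(1 - ab) * eps)
  out <- x0
  for (b in seq_len(dim(x0)[3]))
    out[, , b] <- sqrt(ab[b]) * x0[, , b] + sqrt(1 - ab[b]) * eps[, , b]
  out
}

#' Sampler specification
#'
#' @param mode "one_step" (single denoiser call at t = T-1), "ddpm"
#'   (ancestral) or "ddim" (deterministic, eta = 0).
#' @param nSteps number of reverse steps (multi-step modes).
#' @param init "noise" or "noise_plus_upsampled_lr" (biases the start
#'   toward the upsampled LR signal).
#' @param initNoiseScale standard deviation of the initialization noise.
#' @export
samplerSpec <- function(mode = c("one_step", "ddpm", "ddim"), nSteps = 50,
                        init = c("noise", "noise_plus_upsampled_lr"),
                        initNoiseScale = 1) {
  structure(list(mode = match.arg(mode), nSteps = as.integer(nSteps),
                 init = match.arg(init), initNoiseScale = initNoiseScale),
            class = "eegsr_sampler_spec")
}

# denoiser dispatch: a fitted model, or a plain function(xt, t, lrUp) used
# as an oracle/stub in tests and diagnostics
.callDenoiser <- function(model, xt, t, lrUp, montage, labels) {
  if (is.function(model)) {
    .bumpDenoiser(t)
    return(model(xt, t, lrUp))
  }
  dibimaForward(model, xt, t = t, lrUp = lrUp, montage = montage,
                labels = labels)
}

# convert a model prediction into a clean-sample estimate at timestep t
.toX0 <- function(pred, xt, t, schedule) {
  if (schedule@predictionType == "sample") return(pred)
  ab <- schedule@alphaBar[t + 1L]
  (xt - sqrt(1 - ab) * pred) / sqrt(ab)
}

#' One-step diffusion sampling
#'
#' Initializes at the maximum timestep from scaled Gaussian noise
#' (optionally biased by the upsampled LR signal), performs exactly one
#' denoiser call at t = T-1, and returns the clean-sample prediction
#' without clipping (unless the schedule enables it). Violating the
#' single-call contract raises an error.
#'
#' @param model a diffusion model from [initModel()].
#' @param schedule a [NoiseSchedule-class].
#' @param lrUp HR-shaped upsampled-LR conditioning matrix/array.
#' @param spec a [samplerSpec()] with mode "one_step".
#' @param montage,labels conditioning inputs per the model flags.
#' @return HR-shaped reconstruction.
#' @export
oneStepSample <- function(model, schedule, lrUp, spec = samplerSpec(),
                          montage = NULL, labels = NULL) {
  stopifnot(spec$mode == "one_step")
  before <- getCounters()$denoiserCalls
  tMax <- schedule@nSteps - 1L
  x <- array(stats::rnorm(length(lrUp), sd = spec$initNoiseScale),
             dim(.as3d(lrUp)))
  if (length(dim(lrUp)) == 2) x <- x[, , 1]
  if (spec$init == "noise_plus_upsampled_lr") x <- x + lrUp
  y <- .callDenoiser(model, x, tMax, lrUp, montage, labels)
  y <- .toX0(y, x, tMax, schedule)
  if (schedule@clipSamples) y <- pmin(1, pmax(-1, y))
  if (getCounters()$denoiserCalls - before != 1)
    stop("one-step contract violated: more than one denoiser call")
  y
}

#' Multi-step reference samplers (DDPM / DDIM)
#'
#' Standard reverse recursion over a strided timestep subsequence, using
#' the model's clean-sample estimate to reconstruct the implied noise at
#' each step. DDIM is the deterministic eta = 0 variant; DDPM adds the
#' ancestral posterior noise (zero at the final step).
#'
#' @inheritParams oneStepSample
#' @param spec a [samplerSpec()] with mode "ddpm" or "ddim".
#' @export
multiStepSample <- function(model, schedule, lrUp, spec, montage = NULL,
                            labels = NULL) {
  stopifnot(spec$mode %in% c("ddpm", "ddim"))
  Tn <- schedule@nSteps
  if (spec$nSteps < 1 || spec$nSteps > Tn) stop("invalid number of steps")
  ts <- unique(round(seq(Tn - 1, 0, length.out = spec$nSteps)))
  x <- array(stats::rnorm(length(lrUp), sd = spec$initNoiseScale),
             dim(.as3d(lrUp)))
  if (length(dim(lrUp)) == 2) x <- x[, , 1]
  if (spec$init == "noise_plus_upsampled_lr") x <- x + lrUp
  for (k in seq_along(ts)) {
    t <- ts[k]
    pred <- .callDenoiser(model, x, t, lrUp, montage, labels)
    x0hat <- .toX0(pred, x, t, schedule)
    if (schedule@clipSamples) x0hat <- pmin(1, pmax(-1, x0hat))
    ab <- schedule@alphaBar[t + 1L]
    epshat <- (x - sqrt(ab) * x0hat) / sqrt(1 - ab)
    abPrev <- if (k < length(ts)) schedule@alphaBar[ts[k + 1] + 1L] else 1
    if (spec$mode == "ddim") {
      x <- sqrt(abPrev) * x0hat + sqrt(1 - abPrev) * epshat
    } else {
      aEff <- ab / abPrev
      bEff <- 1 - aEff
      mean <- sqrt(abPrev) * bEff / (1 - ab) * x0hat +
              sqrt(aEff) * (1 - abPrev) / (1 - ab) * x
      sig <- sqrt(bEff * (1 - abPrev) / (1 - ab))
      if (k < length(ts)) {
        zz <- array(stats::rnorm(length(x)), if (is.null(dim(x)))
          length(x) else dim(x))
        x <- mean + sig * zz
      } else x <- mean
    }
  }
  x
}

#' One diffusion training step
#'
#' Draws a uniform timestep per batch element, noises the HR targets,
#' runs the conditioned denoiser and returns the mean-squared error against
#' the schedule's training target (clean signal for "sample", the noise for
#' "epsilon"), together with the parameter gradients.
#'
#' @param model diffusion model.
#' @param schedule a [NoiseSchedule-class].
#' @param batch list with \code{hr} (C, L, B) array, \code{lrUp} (same
#'   shape), optional \code{labels}, optional \code{montage}.
#' @param biasHighT with probability 1/2 train at t = T-1 instead of a
#'   uniform draw (exposes the model to the maximum-noise regime used by
#'   one-step sampling); off by default.
#' @return list with \code{loss} (scalar) and \code{grads} (named list).
#' @export
trainingStep <- function(model, schedule, batch, biasHighT = FALSE) {
  stopifnot(model$cfg$diffusion)
  hr <- .as3d(batch$hr)
  B <- dim(hr)[3]
  Tn <- schedule@nSteps
  t <- sample.int(Tn, B, replace = TRUE) - 1L
  if (biasHighT) {
    hi <- stats::runif(B) < 0.5
    t[hi] <- Tn - 1L
  }
  eps <- array(stats::rnorm(length(hr)), dim(hr))
  xt <- addNoise(hr, eps, t, schedule)
  target <- if (schedule@predictionType == "sample") hr else eps
  cfg <- model$cfg
  if (cfg$conditioning$lr) {
    lu <- .as3d(batch$lrUp)
    xin <- array(0, c(2 * dim(hr)[1], dim(hr)[2], B))
    xin[seq_len(dim(hr)[1]), , ] <- xt
    xin[dim(hr)[1] + seq_len(dim(hr)[1]), , ] <- lu
  } else xin <- xt
  tEmb <- embedTimestep(t, cfg$tDim)
  fw <- .fwdModel(model, xin, tEmb = tEmb, labels = batch$labels,
                  montage = batch$montage, train = TRUE)
  pred <- fw$y +
    if (cfg$conditioning$lr && cfg$residual) .as3d(batch$lrUp) else 0
  resid <- pred - target
  loss <- mean(resid^2)
  if (!is.finite(loss))
    stop(sprintf("non-finite diffusion loss (timesteps: %s)",
                 paste(t, collapse = ", ")))
  dY <- 2 * resid / length(resid)
  bw <- .bwdModel(model, fw$cache, dY)
  list(loss = loss, grads = bw$g, t = t)
}
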