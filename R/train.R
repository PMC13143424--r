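# Seeded training loops (regression and diffusion), evaluation over test
# windows, ablation grids and checkpointing.

#' Training configuration
#'
#' @param epochs training epochs (reference defaults: 30 regression, 50
#'   diffusion).
#' @param batchSize minibatch size.
#' @param lr,lrEnd AdamW learning rate with cosine decay from \code{lr} to
#'   \code{lrEnd}.
#' @param weightDecay decoupled weight decay.
#' @param clipNorm global gradient-norm clip.
#' @param seed training seed (parameters, shuffling, noise draws).
#' @param patience early-stopping patience on validation NMSE.
#' @export
trainConfig <- function(epochs = 30, batchSize = 32, lr = 1e-3,
                        lrEnd = 1e-5, weightDecay = 1e-4, clipNorm = 1,
                        seed = 1, patience = 10) {
  stopifnot(epochs >= 1, lr > 0)
  structure(list(epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize), lr = lr, lrEnd = lrEnd,
                 weightDecay = weightDecay, clipNorm = clipNorm,
                 seed = as.integer(seed), patience = as.integer(patience)),
            class = "eegsr_train_config")
}

#' Stack windows and their degraded/upsampled inputs into batch arrays
#'
#' @param windows list of HR [EEGWindow-class].
#' @param task an [SRTask-class].
#' @param montage the HR [Montage-class].
#' @return list with \code{hr}, \code{lrUp} arrays (C, S, B) and
#'   \code{labels}.
#' @export
prepareBatchArrays <- function(windows, task, montage) {
  B <- length(windows)
  C <- nChannels(montage)
  S <- ncol(windowData(windows[[1]]))
  hr <- array(0, c(C, S, B))
  lrUp <- array(0, c(C, S, B))
  for (b in seq_len(B)) {
    hr[, , b] <- windowData(windows[[b]])
    lr <- degradeWindow(windows[[b]], task)
    lrUp[, , b] <- upsampleToHrShape(lr, task, montage)
  }
  list(hr = hr, lrUp = lrUp,
       labels = vapply(windows, windowLabel, integer(1)))
}

.gradNorm <- function(g) sqrt(sum(vapply(g, function(a) sum(a^2),
                                         numeric(1))))

.adamwUpdate <- function(params, grads, opt, lr, wd, clip,
                         b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  gn <- .gradNorm(grads)
  if (is.finite(gn) && gn > clip) grads <- lapply(grads, `*`, clip / gn)
  opt$step <- opt$step + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(opt$m[[nm]])) { opt$m[[nm]] <- g * 0; opt$v[[nm]] <- g * 0 }
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    mh <- opt$m[[nm]] / (1 - b1^opt$step)
    vh <- opt$v[[nm]] / (1 - b2^opt$step)
    params[[nm]] <- params[[nm]] -
      lr * (mh / (sqrt(vh) + eps) + wd * params[[nm]])
  }
  params
}

# one regression minibatch: forward, MSE vs HR, backward
.regressionStep <- function(model, batch) {
  cfg <- model$cfg
  fw <- .fwdModel(model, batch$lrUp, labels = batch$labels,
                  montage = batch$montage, train = TRUE)
  pred <- fw$y +
    if (cfg$conditioning$lr && cfg$residual) batch$lrUp else 0
  resid <- pred - batch$hr
  loss <- mean(resid^2)
  if (!is.finite(loss)) stop("non-finite regression loss")
  bw <- .bwdModel(model, fw$cache, 2 * resid / length(resid))
  list(loss = loss, grads = bw$g)
}

# batched reconstruction of a prepared array set (eval mode)
.reconstructArrays <- function(model, schedule, arr, montage,
                               sampler = NULL, batchSize = 32) {
  cfg <- model$cfg
  B <- dim(arr$hr)[3]
  out <- array(0, dim(arr$hr))
  labels <- if (cfg$conditioning$label) arr$labels else NULL
  mon <- if (cfg$conditioning$positions) montage else NULL
  for (start in seq(1, B, by = batchSize)) {
    idx <- start:min(B, start + batchSize - 1)
    lu <- arr$lrUp[, , idx, drop = FALSE]
    lb <- if (!is.null(labels)) labels[idx]
    if (cfg$diffusion) {
      sp <- if (is.null(sampler))
        samplerSpec("one_step", init = "noise_plus_upsampled_lr") else sampler
      out[, , idx] <- if (sp$mode == "one_step")
        oneStepSample(model, schedule, lu, sp, mon, lb)
      else multiStepSample(model, schedule, lu, sp, mon, lb)
    } else {
      out[, , idx] <- bimaForward(model, lu, mon, lb)
    }
  }
  out
}

.valNmse <- function(model, schedule, arr, montage, sampler = NULL) {
  rec <- .reconstructArrays(model, schedule, arr, montage, sampler)
  sum((rec - arr$hr)^2) / sum(arr$hr^2)
}

#' Train a super-resolution model
#'
#' Regression mode minimizes MSE between the reconstruction and the HR
#' target; diffusion mode runs the denoising objective of
#' [trainingStep()]. AdamW with cosine learning-rate decay and global
#' gradient clipping; per-epoch validation NMSE is logged (one-step
#' sampling for diffusion models) and the best-validation parameters are
#' retained. Fully reproducible from the seed on a single CPU thread.
#'
#' @param splits list with \code{train} and \code{val} window lists (a
#'   \code{test} element is carried through untouched).
#' @param modelCfg a [modelConfig()].
#' @param schedule a [NoiseSchedule-class] (diffusion) or NULL (regression).
#' @param trainCfg a [trainConfig()].
#' @param task an [SRTask-class].
#' @param montage the HR [Montage-class].
#' @param verbose print per-epoch progress.
#' @return list (class \code{eegsr_fit}) with \code{model}, \code{history}
#'   data frame, \code{schedule}, \code{task}.
#' @export
trainModel <- function(splits, modelCfg, schedule = NULL,
                       trainCfg = trainConfig(), task, montage,
                       verbose = FALSE) {
  diffusion <- isTRUE(modelCfg$diffusion)
  if (diffusion && is.null(schedule))
    stop("diffusion training needs a schedule")
  set.seed(trainCfg$seed)
  model <- initModel(modelCfg, seed = trainCfg$seed)
  trainArr <- prepareBatchArrays(splits$train, task, montage)
  valArr <- prepareBatchArrays(splits$val, task, montage)
  nTrain <- dim(trainArr$hr)[3]
  nBatches <- max(1, floor(nTrain / trainCfg$batchSize))
  totalSteps <- trainCfg$epochs * nBatches
  opt <- new.env(parent = emptyenv())
  opt$step <- 0; opt$m <- list(); opt$v <- list()
  best <- list(nmse = Inf, params = model$params, epoch = 0)
  hist <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                     valNmse = numeric(0))
  sinceBest <- 0
  for (ep in seq_len(trainCfg$epochs)) {
    ord <- sample.int(nTrain)
    losses <- numeric(nBatches)
    for (bi in seq_len(nBatches)) {
      idx <- ord[(bi - 1) * trainCfg$batchSize +
                   seq_len(min(trainCfg$batchSize,
                               nTrain - (bi - 1) * trainCfg$batchSize))]
      batch <- list(hr = trainArr$hr[, , idx, drop = FALSE],
                    lrUp = trainArr$lrUp[, , idx, drop = FALSE],
                    labels = if (modelCfg$conditioning$label)
                      trainArr$labels[idx],
                    montage = if (modelCfg$conditioning$positions) montage)
      res <- if (diffusion) trainingStep(model, schedule, batch)
             else .regressionStep(model, batch)
      losses[bi] <- res$loss
      frac <- opt$step / max(1, totalSteps)
      lrNow <- trainCfg$lrEnd +
        0.5 * (trainCfg$lr - trainCfg$lrEnd) * (1 + cos(pi * frac))
      model$params <- .adamwUpdate(model$params, res$grads, opt, lrNow,
                                   trainCfg$weightDecay, trainCfg$clipNorm)
    }
    vn <- .valNmse(model, schedule, valArr, montage)
    hist <- rbind(hist, data.frame(epoch = ep, trainLoss = mean(losses),
                                   valNmse = vn))
    if (verbose)
      message(sprintf("epoch %d: train loss %.5f, val NMSE %.4f",
                      ep, mean(losses), vn))
    if (vn < best$nmse) {
      best <- list(nmse = vn, params = model$params, epoch = ep)
      sinceBest <- 0
    } else {
      sinceBest <- sinceBest + 1
      if (sinceBest >= trainCfg$patience) break
    }
  }
  model$params <- best$params
  structure(list(model = model, history = hist, schedule = schedule,
                 task = task, bestEpoch = best$epoch,
                 trainCfg = trainCfg),
            class = "eegsr_fit")
}

#' Evaluate a trained model or a classical baseline on test windows
#'
#' Reconstructs every window (one-step sampling by default for diffusion
#' models, direct forward for regression, transfer-matrix interpolation for
#' the baselines) and aggregates the metric suite as mean and standard
#' deviation over windows.
#'
#' @param fit an \code{eegsr_fit} from [trainModel()], or one of
#'   \code{"zero_pad"} / \code{"spline"}, or a function
#'   \code{(lrWindow, task, montage) -> matrix}.
#' @param testWindows list of HR [EEGWindow-class].
#' @param task an [SRTask-class] (taken from the fit when omitted).
#' @param montage HR montage.
#' @param sampler optional [samplerSpec()] override for diffusion fits.
#' @return list with \code{mean}, \code{sd} (named metric vectors) and
#'   \code{perWindow} data frame.
#' @export
evaluateModel <- function(fit, testWindows, task = NULL, montage,
                          sampler = NULL) {
  if (inherits(fit, "eegsr_fit") && is.null(task)) task <- fit$task
  if (is.null(task)) stop("task required")
  arr <- prepareBatchArrays(testWindows, task, montage)
  B <- dim(arr$hr)[3]
  if (inherits(fit, "eegsr_fit")) {
    rec <- .reconstructArrays(fit$model, fit$schedule, arr, montage, sampler)
  } else {
    recon <- if (is.function(fit)) fit
      else if (identical(fit, "zero_pad"))
        function(lr, task, montage) upsampleToHrShape(lr, task, montage)
      else if (identical(fit, "spline"))
        function(lr, task, montage) splineUpsampleBaseline(lr, task, montage)
      else stop("unknown baseline: ", fit)
    rec <- array(0, dim(arr$hr))
    for (b in seq_len(B)) {
      lr <- degradeWindow(testWindows[[b]], task)
      rec[, , b] <- recon(lr, task, montage)
    }
  }
  rate <- samplingRate(testWindows[[1]])
  per <- lapply(seq_len(B), function(b) {
    r <- metricReport(rec[, , b], arr$hr[, , b], rate = rate,
                      montage = montage)
    unlist(r[c("nmse", "pcc", "ssim", "psnr_db", "snr_db", "mse", "rmse")])
  })
  perDf <- as.data.frame(do.call(rbind, per))
  list(mean = colMeans(perDf), sd = apply(perDf, 2, stats::sd),
       perWindow = perDf)
}

#' Run a one-axis ablation grid
#'
#' Trains and evaluates one model per grid value while holding everything
#' else at the supplied baseline, mirroring a one-factor-at-a-time
#' protocol. Supported axes: \code{"mamba_diffusion"} (the four
#' presence/absence configurations), \code{"conditioning"} (none, lr,
#' lr_pos, lr_pos_label), \code{"sampling_init"} (noise,
#' noise_plus_upsampled_lr), \code{"version"}, \code{"d_model"},
#' \code{"d_state"}, \code{"n_blocks"}, \code{"n_layers"}.
#'
#' @param axis axis name.
#' @param values axis values; defaults to the reference grid for the axis.
#' @param baseCfg baseline [modelConfig()].
#' @param schedule [NoiseSchedule-class] for diffusion rows.
#' @param trainCfg,splits,task,montage as in [trainModel()].
#' @return data frame, one row per grid value with the aggregate metrics.
#' @export
runAblation <- function(axis, values = NULL, baseCfg, schedule,
                        trainCfg, splits, task, montage) {
  defaults <- list(
    mamba_diffusion = list(c(FALSE, FALSE), c(FALSE, TRUE), c(TRUE, FALSE),
                           c(TRUE, TRUE)),
    conditioning = list("none", "lr", "lr_pos", "lr_pos_label"),
    sampling_init = list("noise", "noise_plus_upsampled_lr"),
    version = list(1, 2), d_model = list(32, 64, 128),
    d_state = list(8, 16), n_blocks = list(1, 2, 3), n_layers = list(1, 2))
  if (is.null(values)) values <- defaults[[axis]]
  if (is.null(values)) stop("unknown ablation axis: ", axis)
  rows <- lapply(values, function(v) {
    cfg <- baseCfg
    sched <- schedule
    sampler <- NULL
    if (axis == "mamba_diffusion") {
      cfg$bottleneck <- if (v[1]) "bimamba" else "conv"
      cfg$diffusion <- v[2]
    } else if (axis == "conditioning") {
      cfg$conditioning <- list(lr = v != "none",
                               positions = v %in% c("lr_pos", "lr_pos_label"),
                               label = v == "lr_pos_label")
      cfg$diffusion <- TRUE
    } else if (axis == "sampling_init") {
      cfg$diffusion <- TRUE
      sampler <- samplerSpec("one_step", init = v)
    } else if (axis == "version") cfg$backbone$block$version <- v
    else if (axis == "d_model") cfg$backbone$block$dModel <- v
    else if (axis == "d_state") cfg$backbone$block$dState <- v
    else if (axis == "n_blocks") cfg$backbone$nBlocks <- v
    else if (axis == "n_layers") cfg$backbone$nLayers <- v
    if (axis %in% c("version", "d_model", "d_state"))
      cfg$backbone$block <- do.call(mambaBlockConfig, cfg$backbone$block[
        c("version", "dModel", "dState", "dConv", "expand", "nHeads")])
    if (!cfg$diffusion) sched <- NULL
    fit <- trainModel(splits, cfg, sched, trainCfg, task, montage)
    ev <- evaluateModel(fit, splits$test, task, montage, sampler)
    c(value = paste(v, collapse = "+"), as.list(ev$mean))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r,
                                                check.names = FALSE)))
}

#' Save / load a model checkpoint
#'
#' Single-file archive holding the configuration, named parameter tensors,
#' normalization state, schedule and training history.
#'
#' @param fit an \code{eegsr_fit} (or bare model).
#' @param path file path (RDS).
#' @export
saveCheckpoint <- function(fit, path) {
  model <- if (inherits(fit, "eegsr_fit")) fit$model else fit
  obj <- list(cfg = model$cfg, params = model$params,
              state = as.list(model$state),
              schedule = if (inherits(fit, "eegsr_fit")) fit$schedule,
              history = if (inherits(fit, "eegsr_fit")) fit$history,
              task = if (inherits(fit, "eegsr_fit")) fit$task)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  st <- new.env(parent = emptyenv())
  for (nm in names(obj$state)) st[[nm]] <- obj$state[[nm]]
  model <- list(cfg = obj$cfg, params = obj$params, state = st)
  structure(list(model = model, history = obj$history,
                 schedule = obj$schedule, task = obj$task,
                 bestEpoch = NA, trainCfg = NULL), class = "eegsr_fit")
}

#' Print a parameter-count summary of a model
#'
#' @param model model object (or \code{eegsr_fit}).
#' @export
modelSummary <- function(model) {
  if (inherits(model, "eegsr_fit")) model <- model$model
  pc <- countParams(model)
  cat(sprintf("total parameters: %d\n", pc$total))
  for (nm in names(pc$byModule))
    cat(sprintf("  %-10s %d\n", nm, pc$byModule[[nm]]))
  invisible(pc)
}
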