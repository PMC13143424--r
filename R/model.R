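# Encoder-bottleneck-decoder trunks: a deterministic regression model and a
# conditional diffusion denoiser sharing the same architecture. The encoder
# is a stack of strided (x2) convolutions with width doubling; the
# bottleneck is either the bidirectional Mamba stack or a plain
# conv/batchnorm/LeakyReLU/dropout stack; the decoder mirrors the encoder
# with zero-stuffing (fractionally strided) convolutions. Conditioning:
# the upsampled LR signal is channel-concatenated (diffusion) or is the
# input itself (regression) with a global residual connection; electrode
# position embeddings add a per-channel bias at the input; label and
# timestep embeddings are added to feature maps, broadcast over time.

#' Model configuration
#'
#' @param hrChannels,hrSamples high-resolution output shape;
#'   \code{hrSamples} must be divisible by \code{2^depth}.
#' @param baseWidth encoder feature channels at the first stage (doubled per
#'   stage).
#' @param depth number of x2 downsampling stages.
#' @param bottleneck "bimamba" (bidirectional Mamba stack) or "conv"
#'   (Conv1d/BatchNorm/LeakyReLU/Dropout ablation variant).
#' @param backbone a [bimambaStackConfig()]; its block \code{dModel} sets
#'   the bottleneck working width.
#' @param conditioning logical flags \code{list(lr=, positions=, label=)}.
#' @param diffusion TRUE for the denoiser (adds the timestep stream and the
#'   noisy-input channel group).
#' @param nClasses label vocabulary size (one extra null id is reserved for
#'   unconditional use).
#' @param dropout dropout rate in the conv bottleneck.
#' @param posDim,tDim embedding widths for positions and timesteps.
#' @export
modelConfig <- function(hrChannels, hrSamples, baseWidth = 64, depth = 2,
                        bottleneck = c("bimamba", "conv"),
                        backbone = bimambaStackConfig(),
                        conditioning = list(lr = TRUE, positions = FALSE,
                                            label = FALSE),
                        diffusion = FALSE, nClasses = 2, dropout = 0.1,
                        posDim = 8, tDim = baseWidth, residual = TRUE) {
  bottleneck <- match.arg(bottleneck)
  stopifnot(hrSamples %% 2^depth == 0)
  cond <- utils::modifyList(list(lr = TRUE, positions = FALSE, label = FALSE),
                            conditioning)
  widths <- baseWidth * 2^(seq_len(depth) - 1)
  list(hrChannels = as.integer(hrChannels),
       hrSamples = as.integer(hrSamples), baseWidth = baseWidth,
       depth = depth, widths = widths, bottleneck = bottleneck,
       backbone = backbone, conditioning = cond, diffusion = diffusion,
       nClasses = as.integer(nClasses), dropout = dropout, posDim = posDim,
       tDim = tDim, residual = residual)
}

.inputChannels <- function(cfg) {
  if (cfg$diffusion) cfg$hrChannels * (1L + as.integer(cfg$conditioning$lr))
  else cfg$hrChannels
}

#' Initialize a model
#'
#' @param cfg a [modelConfig()].
#' @param seed parameter seed.
#' @return model object: list with \code{$cfg}, flat \code{$params}, and a
#'   \code{$state} environment (batch-norm running statistics).
#' @export
initModel <- function(cfg, seed = 1) {
  set.seed(seed)
  p <- list()
  cin <- .inputChannels(cfg)
  w <- cfg$widths
  wB <- w[cfg$depth]
  for (i in seq_len(cfg$depth))
    p <- c(p, .initConv1d(sprintf("enc%d", i),
                          if (i == 1) cin else w[i - 1], w[i], 4))
  if (cfg$bottleneck == "bimamba") {
    dM <- cfg$backbone$block$dModel
    p <- c(p, .initLinear("binproj", wB, dM))
    p <- c(p, .initBiMambaStack("bs", cfg$backbone))
    p <- c(p, .initLinear("boutproj", dM, wB))
  } else {
    for (j in 1:2) {
      p <- c(p, .initConv1d(sprintf("cb%d", j), wB, wB, 3))
      p <- c(p, .initBatchNorm(sprintf("cbn%d", j), wB))
    }
  }
  for (i in seq(cfg$depth, 1))
    p <- c(p, .initConv1d(sprintf("dec%d", i), w[i],
                          if (i == 1) w[1] else w[i - 1], 3))
  p <- c(p, .initConv1d("head", w[1], cfg$hrChannels, 3,
                        scale = 1e-3))          # near-zero output head
  if (cfg$conditioning$positions) {
    p <- c(p, .initEmbedding("pos", cfg$hrChannels, cfg$posDim))
    p <- c(p, .initLinear("posC", 3, cfg$posDim, bias = FALSE))
    p <- c(p, .initLinear("posW", cfg$posDim, 1, bias = FALSE))
  }
  if (cfg$conditioning$label)
    p <- c(p, .initEmbedding("lab", cfg$nClasses + 1L, w[1]))
  if (cfg$diffusion) {
    p <- c(p, .initLinear("tmap", cfg$tDim, cfg$tDim))
    for (i in seq_len(cfg$depth))
      p <- c(p, .initLinear(sprintf("ts%d", i), cfg$tDim, w[i]))
  }
  list(cfg = cfg, params = p, state = new.env(parent = emptyenv()))
}

#' Sinusoidal timestep encoding
#'
#' Deterministic sinusoidal features of a diffusion timestep (the learned
#' map on top of it lives inside the model).
#'
#' @param t integer timestep(s), 0-based.
#' @param dim embedding dimension (even).
#' @return length(t) x dim matrix.
#' @export
embedTimestep <- function(t, dim) {
  stopifnot(dim %% 2 == 0, all(t >= 0))
  half <- dim %/% 2
  freq <- exp(-log(10000) * (seq_len(half) - 1) / max(1, half - 1))
  ang <- outer(as.numeric(t), freq)
  cbind(sin(ang), cos(ang))
}

#' Standalone embedding helpers
#'
#' \code{positionEmbedder}/\code{positionEmbed} implement the learnable
#' rank-indexed electrode embedding summed with a linear map of the 3-D
#' coordinates; \code{labelEmbedder}/\code{labelEmbed} the class-label
#' table with a reserved null id (\code{nClasses}) for unconditional use.
#'
#' @param nChannels,nClasses table sizes.
#' @param dim embedding dimension.
#' @param seed init seed.
#' @export
positionEmbedder <- function(nChannels, dim = 8, seed = 1) {
  set.seed(seed)
  structure(c(.initEmbedding("pos", nChannels, dim),
              .initLinear("posC", 3, dim, bias = FALSE)),
            class = "eegsr_pos_embedder")
}

#' @rdname positionEmbedder
#' @param emb an embedder object.
#' @param ranks 0-based electrode ranks.
#' @param coords matrix of 3-D positions (one row per rank).
#' @export
positionEmbed <- function(emb, ranks, coords) {
  if (anyDuplicated(ranks)) stop("rank collision in position embedding")
  E <- emb[["pos.E"]]
  W <- emb[["posC.W"]]
  E[ranks + 1L, , drop = FALSE] + coords %*% t(W)
}

#' @rdname positionEmbedder
#' @export
labelEmbedder <- function(nClasses, dim = 16, seed = 1) {
  set.seed(seed)
  structure(.initEmbedding("lab", nClasses + 1L, dim),
            class = "eegsr_label_embedder", nClasses = nClasses)
}

#' @rdname positionEmbedder
#' @param labels 0-based label ids; the null id equals \code{nClasses}.
#' @export
labelEmbed <- function(emb, labels) {
  n <- attr(emb, "nClasses")
  if (any(labels < 0) || any(labels > n)) stop("label id out of range")
  emb[["lab.E"]][labels + 1L, , drop = FALSE]
}

# per-channel position bias from the model's own tables
.posBias <- function(params, cfg, montage) {
  emb <- params[["pos.E"]] + montage@positions %*% t(params[["posC.W"]])
  as.numeric(emb %*% t(params[["posW.W"]]))   # one scalar per HR channel
}

# ---- trunk forward / backward ---------------------------------------------

# input: xin (Cin, L, B); tEmb: B x tDim sinusoidal features or NULL;
# labels: length-B 0-based ids or NULL; montage for position bias or NULL
.fwdModel <- function(model, xin, tEmb = NULL, labels = NULL, montage = NULL,
                      train = FALSE) {
  cfg <- model$cfg
  p <- model$params
  ca <- list()
  h <- xin
  B <- dim(h)[3]
  if (cfg$conditioning$positions) {
    if (is.null(montage)) stop("positions conditioning needs a montage")
    pb <- .posBias(p, cfg, montage)
    ngrp <- dim(h)[1] %/% cfg$hrChannels
    h <- h + rep(pb, ngrp)               # channel-identity bias per group
    ca$posBias <- TRUE
    ca$montagePositions <- montage@positions
  }
  if (cfg$diffusion) {
    tm <- .fwdLinear(p, "tmap", array(t(tEmb), c(cfg$tDim, 1, B)))
    tAct <- .fwdSiLU(tm$y)
    ca$tm <- tm; ca$tAct <- tAct
  }
  ca$enc <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    cv <- .fwdConv1d(p, sprintf("enc%d", i), h, stride = 2, pad = c(1, 1))
    hh <- cv$y
    st <- list(cv = cv)
    Lh <- dim(hh)[2]
    if (cfg$diffusion) {
      ts <- .fwdLinear(p, sprintf("ts%d", i), ca$tAct$y)
      hh <- hh + ts$y[, rep(1, Lh), , drop = FALSE]   # broadcast over time
      st$ts <- ts
    }
    if (i == 1 && cfg$conditioning$label) {
      if (is.null(labels)) stop("label conditioning needs labels")
      le <- .fwdEmbedding(p, "lab", as.integer(labels))
      lv <- array(t(le$y), c(ncol(le$y), 1, B))
      hh <- hh + lv[, rep(1, Lh), , drop = FALSE]
      st$le <- le
    }
    ac <- .fwdSiLU(hh)
    st$ac <- ac
    ca$enc[[i]] <- st
    h <- ac$y
  }
  if (cfg$bottleneck == "bimamba") {
    ip <- .fwdLinear(p, "binproj", h)
    bs <- .fwdBiMambaStack(p, "bs", ip$y, cfg$backbone)
    op <- .fwdLinear(p, "boutproj", bs$y)
    h <- op$y
    ca$bneck <- list(ip = ip, bs = bs, op = op)
  } else {
    bn <- list()
    for (j in 1:2) {
      cv <- .fwdConv1d(p, sprintf("cb%d", j), h)
      nb <- .fwdBatchNorm(p, sprintf("cbn%d", j), cv$y, model$state, train)
      lr <- .fwdLeakyReLU(nb$y)
      dp <- .fwdDropout(lr$y, cfg$dropout, train)
      bn[[j]] <- list(cv = cv, nb = nb, lr = lr, dp = dp)
      h <- dp$y
    }
    ca$bneck <- bn
  }
  ca$dec <- vector("list", cfg$depth)
  for (i in seq(cfg$depth, 1)) {
    zs <- .fwdZeroStuff(h, 2)
    cv <- .fwdConv1d(p, sprintf("dec%d", i), zs$y)
    ac <- .fwdSiLU(cv$y)
    ca$dec[[i]] <- list(zs = zs, cv = cv, ac = ac)
    h <- ac$y
  }
  hd <- .fwdConv1d(p, "head", h)
  ca$head <- hd
  list(y = hd$y, cache = ca)
}

.bwdModel <- function(model, cache, dy) {
  cfg <- model$cfg
  p <- model$params
  g <- list()
  bh <- .bwdConv1d(p, "head", cache$head$cache, dy)
  g <- .addGrads(g, bh$g)
  dh <- bh$dx
  for (i in seq_len(cfg$depth)) {       # decoder was filled depth..1
    st <- cache$dec[[i]]
    da <- .bwdSiLU(st$ac$cache, dh)
    bc <- .bwdConv1d(p, sprintf("dec%d", i), st$cv$cache, da)
    g <- .addGrads(g, bc$g)
    dh <- .bwdZeroStuff(st$zs$cache, bc$dx)
  }
  if (cfg$bottleneck == "bimamba") {
    bo <- .bwdLinear(p, "boutproj", cache$bneck$op$cache, dh)
    g <- .addGrads(g, bo$g)
    bs <- .bwdBiMambaStack(p, "bs", cache$bneck$bs$cache, bo$dx,
                           cfg$backbone)
    g <- .addGrads(g, bs$g)
    bi <- .bwdLinear(p, "binproj", cache$bneck$ip$cache, bs$dx)
    g <- .addGrads(g, bi$g)
    dh <- bi$dx
  } else {
    for (j in 2:1) {
      st <- cache$bneck[[j]]
      dd <- .bwdDropout(st$dp$cache, dh)
      dl <- .bwdLeakyReLU(st$lr$cache, dd)
      bn <- .bwdBatchNorm(p, sprintf("cbn%d", j), st$nb$cache, dl)
      g <- .addGrads(g, bn$g)
      bc <- .bwdConv1d(p, sprintf("cb%d", j), st$cv$cache, bn$dx)
      g <- .addGrads(g, bc$g)
      dh <- bc$dx
    }
  }
  dtEmbAct <- NULL
  for (i in seq(cfg$depth, 1)) {
    st <- cache$enc[[i]]
    da <- .bwdSiLU(st$ac$cache, dh)
    if (!is.null(st$ts)) {
      dts <- apply(da, c(1, 3), sum)     # sum over time (broadcast adjoint)
      bts <- .bwdLinear(p, sprintf("ts%d", i), st$ts$cache,
                        array(dts, c(nrow(dts), 1, ncol(dts))))
      g <- .addGrads(g, bts$g)
      dtEmbAct <- if (is.null(dtEmbAct)) bts$dx else dtEmbAct + bts$dx
    }
    if (!is.null(st$le)) {
      dle <- t(apply(da, c(1, 3), sum))  # B x width
      ble <- .bwdEmbedding(p, "lab", st$le$cache, dle)
      g <- .addGrads(g, ble$g)
    }
    bc <- .bwdConv1d(p, sprintf("enc%d", i), st$cv$cache, da)
    g <- .addGrads(g, bc$g)
    dh <- bc$dx
  }
  if (!is.null(dtEmbAct)) {
    dtm <- .bwdSiLU(cache$tAct$cache, dtEmbAct)
    btm <- .bwdLinear(p, "tmap", cache$tm$cache, dtm)
    g <- .addGrads(g, btm$g)
  }
  if (!is.null(cache$posBias)) {
    ngrp <- dim(dh)[1] %/% cfg$hrChannels
    dpb <- rowSums(matrix(dh, dim(dh)[1]))
    dpb <- rowSums(matrix(dpb, cfg$hrChannels, ngrp))
    # bias_c = posW . (E[rank_c, ] + coords_c posC^T)
    gW <- matrix(dpb, 1) %*% (p[["pos.E"]] +
      cache$montagePositions %*% t(p[["posC.W"]]))
    g <- .addGrads(g, stats::setNames(list(gW), "posW.W"))
    dEmb <- matrix(dpb, ncol = 1) %*% p[["posW.W"]]
    g <- .addGrads(g, stats::setNames(list(dEmb), "pos.E"))
    g <- .addGrads(g, stats::setNames(
      list(t(dEmb) %*% cache$montagePositions), "posC.W"))
  }
  list(dx = dh, g = g)
}

# ---- user-facing forwards --------------------------------------------------

#' Regression (non-diffusion) forward pass
#'
#' Maps an HR-shaped upsampled-LR input to an HR reconstruction. When LR
#' conditioning is on (the default for regression), a global residual adds
#' the input back to the trunk output, so the network learns a correction.
#'
#' @param model from [initModel()] with \code{diffusion = FALSE}.
#' @param lrUp HR-shaped matrix (channels x samples) or array
#'   \code{(channels, samples, batch)}.
#' @param montage montage for position conditioning (when enabled).
#' @param labels 0-based class ids, length batch (when label conditioning is
#'   enabled).
#' @param train training mode (dropout/batch-norm statistics).
#' @return HR-shaped array matching the input batch shape.
#' @export
bimaForward <- function(model, lrUp, montage = NULL, labels = NULL,
                        train = FALSE) {
  stopifnot(!model$cfg$diffusion)
  x <- .as3d(lrUp)
  fw <- .fwdModel(model, x, labels = labels, montage = montage,
                  train = train)
  y <- fw$y + if (model$cfg$conditioning$lr && model$cfg$residual) x else 0
  if (length(dim(lrUp)) == 2) y <- y[, , 1]
  y
}

#' Diffusion denoiser forward pass
#'
#' Predicts (per the schedule's prediction type) the clean signal or noise
#' from the noisy HR input at diffusion timestep \code{t}, conditioned on
#' the upsampled LR signal, electrode positions and labels according to the
#' model flags.
#'
#' @param model from [initModel()] with \code{diffusion = TRUE}.
#' @param xt noisy HR-shaped matrix or \code{(channels, samples, batch)}
#'   array.
#' @param t integer timestep in \code{[0, T-1]} (scalar or per-batch).
#' @param lrUp upsampled LR signal (same shape as \code{xt}); ignored when
#'   LR conditioning is off.
#' @inheritParams bimaForward
#' @export
dibimaForward <- function(model, xt, t, lrUp = NULL, montage = NULL,
                          labels = NULL, train = FALSE) {
  stopifnot(model$cfg$diffusion)
  if (missing(t) || is.null(t)) stop("diffusion forward needs a timestep")
  x <- .as3d(xt)
  B <- dim(x)[3]
  if (model$cfg$conditioning$lr) {
    if (is.null(lrUp)) stop("lr conditioning needs lrUp")
    lu <- .as3d(lrUp)
    xin <- array(0, c(2 * dim(x)[1], dim(x)[2], B))
    xin[seq_len(dim(x)[1]), , ] <- x
    xin[dim(x)[1] + seq_len(dim(x)[1]), , ] <- lu
  } else xin <- x
  tEmb <- embedTimestep(rep_len(t, B), model$cfg$tDim)
  .bumpDenoiser(t[1])
  fw <- .fwdModel(model, xin, tEmb = tEmb, labels = labels,
                  montage = montage, train = train)
  y <- fw$y +
    if (model$cfg$conditioning$lr && model$cfg$residual) .as3d(lrUp) else 0
  if (length(dim(xt)) == 2) y <- y[, , 1]
  y
}
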