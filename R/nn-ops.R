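# Minimal reverse-mode neural-network primitives on (channels, length, batch)
# arrays. Every primitive has init*/ fwd* / bwd* functions; forward returns
# list(y, cache), backward returns list(dx, g) where g is a named gradient
# list aligned with the parameter names. Parameters live in one flat named
# list; composite modules namespace them with a prefix.

.rnormMat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

.addGrads <- function(a, b) {
  for (nm in names(b)) {
    if (is.null(a[[nm]])) a[[nm]] <- b[[nm]] else a[[nm]] <- a[[nm]] + b[[nm]]
  }
  a
}

.as3d <- function(x) {
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1)
  x
}

# ---- linear over the channel dimension -------------------------------------

.initLinear <- function(prefix, cin, cout, scale = sqrt(2 / cin),
                        bias = TRUE) {
  p <- list()
  p[[paste0(prefix, ".W")]] <- .rnormMat(cout, cin, scale)
  if (bias) p[[paste0(prefix, ".b")]] <- numeric(cout)
  p
}

.fwdLinear <- function(params, prefix, x) {
  d <- dim(x)
  W <- params[[paste0(prefix, ".W")]]
  b <- params[[paste0(prefix, ".b")]]
  xm <- matrix(x, d[1], d[2] * d[3])
  y <- W %*% xm
  if (!is.null(b)) y <- y + b
  dim(y) <- c(nrow(W), d[2], d[3])
  list(y = y, cache = list(xm = xm, d = d))
}

.bwdLinear <- function(params, prefix, cache, dy) {
  W <- params[[paste0(prefix, ".W")]]
  dym <- matrix(dy, nrow(W), cache$d[2] * cache$d[3])
  g <- list()
  g[[paste0(prefix, ".W")]] <- tcrossprod(dym, cache$xm)
  if (!is.null(params[[paste0(prefix, ".b")]]))
    g[[paste0(prefix, ".b")]] <- rowSums(dym)
  dx <- crossprod(W, dym)
  dim(dx) <- cache$d
  list(dx = dx, g = g)
}

# ---- 1-D convolution (full, via im2col) ------------------------------------

.initConv1d <- function(prefix, cin, cout, K,
                        scale = sqrt(2 / (cin * K))) {
  p <- list()
  p[[paste0(prefix, ".W")]] <- array(stats::rnorm(cout * cin * K, sd = scale),
                                     c(cout, cin, K))
  p[[paste0(prefix, ".b")]] <- numeric(cout)
  p
}

.padTime <- function(x, pl, pr) {
  if (pl == 0 && pr == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + pl + pr, d[3]))
  xp[, pl + seq_len(d[2]), ] <- x
  xp
}

.fwdConv1d <- function(params, prefix, x, stride = 1, pad = NULL) {
  W <- params[[paste0(prefix, ".W")]]
  b <- params[[paste0(prefix, ".b")]]
  K <- dim(W)[3]
  if (is.null(pad)) {                      # same padding (stride 1, odd K)
    pad <- c((K - 1) %/% 2, K %/% 2)
  }
  d0 <- dim(x)
  xp <- .padTime(x, pad[1], pad[2])
  d <- dim(xp)
  Lo <- (d[2] - K) %/% stride + 1
  idx <- outer(seq_len(K), stride * (seq_len(Lo) - 1), `+`)   # K x Lo
  xcol <- xp[, as.vector(idx), , drop = FALSE]                 # Ci x K*Lo x B
  dim(xcol) <- c(d[1] * K, Lo * d[3])
  W2 <- matrix(W, dim(W)[1])
  y <- W2 %*% xcol + b
  dim(y) <- c(dim(W)[1], Lo, d[3])
  list(y = y, cache = list(xcol = xcol, d0 = d0, dp = d, Lo = Lo, idx = idx,
                           stride = stride, pad = pad, K = K))
}

.bwdConv1d <- function(params, prefix, cache, dy) {
  W <- params[[paste0(prefix, ".W")]]
  Co <- dim(W)[1]; Ci <- dim(W)[2]; K <- dim(W)[3]
  dym <- matrix(dy, Co, cache$Lo * cache$dp[3])
  g <- list()
  gW <- tcrossprod(dym, cache$xcol)
  dim(gW) <- dim(W)
  g[[paste0(prefix, ".W")]] <- gW
  g[[paste0(prefix, ".b")]] <- rowSums(dym)
  dxcol <- crossprod(matrix(W, Co), dym)          # Ci*K x Lo*B
  dim(dxcol) <- c(Ci, K * cache$Lo, cache$dp[3])
  dxp <- array(0, cache$dp)
  for (k in seq_len(K)) {
    sel <- seq(k, K * cache$Lo, by = K)
    pos <- cache$idx[k, ]
    dxp[, pos, ] <- dxp[, pos, , drop = FALSE] + dxcol[, sel, , drop = FALSE]
  }
  dx <- dxp[, cache$pad[1] + seq_len(cache$d0[2]), , drop = FALSE]
  list(dx = dx, g = g)
}

# ---- depthwise causal conv (kernel K, pads K-1 on the left) ----------------

.initDepthConv <- function(prefix, c, K, scale = sqrt(1 / K)) {
  p <- list()
  p[[paste0(prefix, ".W")]] <- .rnormMat(c, K, scale)
  p[[paste0(prefix, ".b")]] <- numeric(c)
  p
}

.fwdDepthConv <- function(params, prefix, x) {
  W <- params[[paste0(prefix, ".W")]]
  b <- params[[paste0(prefix, ".b")]]
  K <- ncol(W)
  d <- dim(x)
  xp <- .padTime(x, K - 1, 0)
  y <- array(0, d)
  for (k in seq_len(K))
    y <- y + W[, k] * xp[, (k - 1) + seq_len(d[2]), , drop = FALSE]
  y <- y + b
  list(y = y, cache = list(xp = xp, d = d, K = K))
}

.bwdDepthConv <- function(params, prefix, cache, dy) {
  W <- params[[paste0(prefix, ".W")]]
  K <- cache$K; d <- cache$d
  g <- list()
  gW <- matrix(0, nrow(W), K)
  dxp <- array(0, dim(cache$xp))
  for (k in seq_len(K)) {
    xs <- cache$xp[, (k - 1) + seq_len(d[2]), , drop = FALSE]
    gW[, k] <- rowSums(matrix(dy * xs, d[1]))
    dxp[, (k - 1) + seq_len(d[2]), ] <-
      dxp[, (k - 1) + seq_len(d[2]), , drop = FALSE] + W[, k] * dy
  }
  g[[paste0(prefix, ".W")]] <- gW
  g[[paste0(prefix, ".b")]] <- rowSums(matrix(dy, d[1]))
  dx <- dxp[, (K - 1) + seq_len(d[2]), , drop = FALSE]
  list(dx = dx, g = g)
}

# ---- activations -----------------------------------------------------------

.sigmoid <- function(x) 1 / (1 + exp(-x))

.fwdSiLU <- function(x) {
  s <- .sigmoid(x)
  list(y = x * s, cache = list(x = x, s = s))
}
.bwdSiLU <- function(cache, dy) dy * (cache$s * (1 + cache$x * (1 - cache$s)))

.fwdLeakyReLU <- function(x, alpha = 0.2) {
  m <- x > 0
  list(y = ifelse(m, x, alpha * x), cache = list(m = m, alpha = alpha))
}
.bwdLeakyReLU <- function(cache, dy) ifelse(cache$m, dy, cache$alpha * dy)

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

# ---- zero-stuffing temporal upsampling (for transposed conv) ---------------

.fwdZeroStuff <- function(x, s) {
  d <- dim(x)
  y <- array(0, c(d[1], d[2] * s, d[3]))
  pos <- (seq_len(d[2]) - 1) * s + 1
  y[, pos, ] <- x
  list(y = y, cache = list(pos = pos))
}
.bwdZeroStuff <- function(cache, dy) dy[, cache$pos, , drop = FALSE]

# ---- batch normalization over (length, batch) per channel ------------------

.initBatchNorm <- function(prefix, c) {
  p <- list()
  p[[paste0(prefix, ".gamma")]] <- rep(1, c)
  p[[paste0(prefix, ".beta")]] <- numeric(c)
  p
}

.fwdBatchNorm <- function(params, prefix, x, state, train, eps = 1e-5,
                          momentum = 0.1) {
  d <- dim(x)
  xm <- matrix(x, d[1])
  gamma <- params[[paste0(prefix, ".gamma")]]
  beta <- params[[paste0(prefix, ".beta")]]
  key <- paste0(prefix, ".run")
  if (train) {
    mu <- rowMeans(xm)
    vr <- rowMeans((xm - mu)^2)
    run <- state[[key]]
    if (is.null(run)) run <- list(mu = mu * 0, vr = mu * 0 + 1)
    state[[key]] <- list(mu = (1 - momentum) * run$mu + momentum * mu,
                         vr = (1 - momentum) * run$vr + momentum * vr)
  } else {
    run <- state[[key]]
    if (is.null(run)) run <- list(mu = numeric(d[1]), vr = rep(1, d[1]))
    mu <- run$mu; vr <- run$vr
  }
  istd <- 1 / sqrt(vr + eps)
  xhat <- (xm - mu) * istd
  y <- gamma * xhat + beta
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, istd = istd, d = d, train = train))
}

.bwdBatchNorm <- function(params, prefix, cache, dy) {
  d <- cache$d
  gamma <- params[[paste0(prefix, ".gamma")]]
  dym <- matrix(dy, d[1])
  g <- list()
  g[[paste0(prefix, ".gamma")]] <- rowSums(dym * cache$xhat)
  g[[paste0(prefix, ".beta")]] <- rowSums(dym)
  dxhat <- gamma * dym
  if (cache$train) {
    N <- ncol(dym)
    dx <- cache$istd * (dxhat - rowMeans(dxhat) -
                        cache$xhat * rowMeans(dxhat * cache$xhat))
  } else {
    dx <- cache$istd * dxhat
  }
  dim(dx) <- d
  list(dx = dx, g = g)
}

# ---- layer normalization over the channel dimension ------------------------

.initLayerNorm <- function(prefix, c) {
  p <- list()
  p[[paste0(prefix, ".gamma")]] <- rep(1, c)
  p[[paste0(prefix, ".beta")]] <- numeric(c)
  p
}

.fwdLayerNorm <- function(params, prefix, x, eps = 1e-5) {
  d <- dim(x)
  xm <- matrix(x, d[1])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  vr <- colMeans(xc^2)
  istd <- 1 / sqrt(vr + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  gamma <- params[[paste0(prefix, ".gamma")]]
  beta <- params[[paste0(prefix, ".beta")]]
  y <- gamma * xhat + beta
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, istd = istd, d = d))
}

.bwdLayerNorm <- function(params, prefix, cache, dy) {
  d <- cache$d
  gamma <- params[[paste0(prefix, ".gamma")]]
  dym <- matrix(dy, d[1])
  g <- list()
  g[[paste0(prefix, ".gamma")]] <- rowSums(dym * cache$xhat)
  g[[paste0(prefix, ".beta")]] <- rowSums(dym)
  dxhat <- gamma * dym
  C <- d[1]
  dx <- sweep(dxhat, 2, colMeans(dxhat)) -
        sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), `*`)
  dx <- sweep(dx, 2, cache$istd, `*`)
  dim(dx) <- d
  list(dx = dx, g = g)
}

# ---- dropout ---------------------------------------------------------------

.fwdDropout <- function(x, p, train) {
  if (!train || p <= 0) return(list(y = x, cache = NULL))
  mask <- array(stats::rbinom(length(x), 1, 1 - p) / (1 - p), dim(x))
  list(y = x * mask, cache = list(mask = mask))
}
.bwdDropout <- function(cache, dy) {
  if (is.null(cache)) dy else dy * cache$mask
}

# ---- embedding table -------------------------------------------------------

.initEmbedding <- function(prefix, n, d, scale = 0.1) {
  p <- list()
  p[[paste0(prefix, ".E")]] <- .rnormMat(n, d, scale)
  p
}

.fwdEmbedding <- function(params, prefix, ids) {
  E <- params[[paste0(prefix, ".E")]]
  list(y = E[ids + 1L, , drop = FALSE], cache = list(ids = ids, dims = dim(E)))
}

.bwdEmbedding <- function(params, prefix, cache, dy) {
  gE <- matrix(0, cache$dims[1], cache$dims[2])
  for (i in seq_along(cache$ids))
    gE[cache$ids[i] + 1L, ] <- gE[cache$ids[i] + 1L, ] + dy[i, ]
  g <- list()
  g[[paste0(prefix, ".E")]] <- gE
  list(g = g)
}

# ---- parameter utilities ---------------------------------------------------

#' Count trainable parameters of a model
#'
#' @param model a model object from [initModel()] (or any flat named list of
#'   numeric arrays under \code{$params}).
#' @return named list with total and a per-module breakdown.
#' @export
countParams <- function(model) {
  params <- if (!is.null(model$params)) model$params else model
  sizes <- vapply(params, length, integer(1))
  top <- sub("\\..*$", "", names(sizes))
  list(total = sum(sizes),
       byModule = sort(tapply(sizes, top, sum), decreasing = TRUE))
}
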