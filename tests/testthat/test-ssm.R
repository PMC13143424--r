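test_that("selective scan matches the brute-force recurrence", {
  set.seed(10)
  for (r in 1:10) {
    inst <- randomScanInstance(L = sample(4:16, 1), din = sample(2:4, 1),
                               N = sample(2:4, 1), scalarA = r %% 2 == 0)
    y <- selectiveScan(inst$u, inst$delta, inst$A, inst$B, inst$C, inst$D)
    expect_lt(max(abs(y[, , 1] - do.call(naiveScan, inst))), 1e-6)
  }
})

test_that("scan degenerate cases: zero input, cumulative-sum reduction", {
  set.seed(11)
  inst <- randomScanInstance(8, 3, 2)
  y0 <- selectiveScan(inst$u * 0, inst$delta, inst$A, inst$B, inst$C, inst$D)
  expect_identical(max(abs(y0)), 0)
  # scalar channel/state, A = 0, D = 0: y_t = C_t * cumsum(delta * B * u)
  L <- 4
  u <- matrix(c(1, -2, 0.5, 3), 1)
  delta <- matrix(c(0.1, 0.2, 0.3, 0.4), 1)
  B <- matrix(c(2, 1, -1, 0.5), 1)
  C <- matrix(c(1, 0.5, 2, -1), 1)
  y <- selectiveScan(u, delta, matrix(0, 1, 1), B, C, 0)
  expect_equal(as.numeric(y), C[1, ] * cumsum(delta[1, ] * B[1, ] * u[1, ]),
               tolerance = 1e-12)
  # positivity precondition
  expect_error(selectiveScan(u, -delta, matrix(0, 1, 1), B, C, 0),
               "positive")
})

test_that("mamba blocks preserve shape, are causal and deterministic", {
  for (v in 1:2) {
    cfg <- mambaBlockConfig(version = v, dModel = 8, dState = 3, nHeads = 4)
    blk <- mambaBlock(cfg, seed = 2)
    set.seed(5)
    x <- array(rnorm(8 * 20 * 2), c(8, 20, 2))
    y <- mambaBlockApply(blk, x)
    expect_identical(dim(y), dim(x))
    expect_identical(y, mambaBlockApply(mambaBlock(cfg, seed = 2), x))
    # causality: a perturbation at time t cannot affect outputs before t
    for (t in c(5, 10, 15)) {
      x2 <- x
      x2[, t, 1] <- x2[, t, 1] + 1
      y2 <- mambaBlockApply(blk, x2)
      expect_lt(max(abs(y2[, seq_len(t - 1), 1] - y[, seq_len(t - 1), 1])),
                1e-12)
      expect_gt(max(abs(y2[, t:20, 1] - y[, t:20, 1])), 0)
    }
  }
})

test_that("bidirectional layer: shape, additive fusion, reversal equivariance", {
  cfg <- bimambaStackConfig(mambaBlockConfig(1, dModel = 6, dState = 2),
                            nLayers = 1, nBlocks = 1)
  ly <- bimambaLayer(cfg, seed = 3)
  set.seed(6)
  x <- array(rnorm(6 * 16), c(6, 16, 1))
  y <- bimambaLayerApply(ly, x)
  expect_identical(dim(y), dim(x))
  # additive fusion: output = forward-stream + reversed backward-stream
  fwd <- eegsr:::.fwdDirStream(ly$params, "bl.f", x, cfg)$y
  bwd <- eegsr:::.revTime(
    eegsr:::.fwdDirStream(ly$params, "bl.r", eegsr:::.revTime(x), cfg)$y)
  expect_equal(y, fwd + bwd, tolerance = 1e-12)
  # tied directional weights commute with time reversal
  cfgT <- bimambaStackConfig(mambaBlockConfig(1, dModel = 6, dState = 2),
                             nLayers = 1, nBlocks = 1, tieDirections = TRUE)
  lyT <- bimambaLayer(cfgT, seed = 3)
  yT <- bimambaLayerApply(lyT, x)
  yR <- bimambaLayerApply(lyT, eegsr:::.revTime(x))
  expect_equal(eegsr:::.revTime(yR), yT, tolerance = 1e-6)
})

test_that("the stack reduces to layer + residual conv and scales linearly", {
  blkCfg <- mambaBlockConfig(1, dModel = 6, dState = 2)
  cfg1 <- bimambaStackConfig(blkCfg, nLayers = 1, nBlocks = 1)
  st <- bimambaStack(cfg1, seed = 4)
  set.seed(7)
  x <- array(rnorm(6 * 12), c(6, 12, 1))
  y <- bimambaStackApply(st, x)
  ly <- eegsr:::.fwdBiMambaLayer(st$params, "bs.l1", x, cfg1)$y
  pj <- eegsr:::.fwdConv1d(st$params, "bs.p1", x)$y
  expect_equal(y, ly + pj, tolerance = 1e-12)
  # zeroing the block output projections leaves only the conv paths
  p0 <- st$params
  for (nm in grep("\\.out\\.W$", names(p0), value = TRUE)) p0[[nm]][] <- 0
  for (nm in grep("\\.out\\.b$", names(p0), value = TRUE)) p0[[nm]][] <- 0
  st0 <- st; st0$params <- p0
  y0 <- bimambaStackApply(st0, x)
  convOnly <- eegsr:::.fwdConv1d(p0, "bs.p1", x)$y +
    eegsr:::.fwdDepthConv(p0, "bs.l1.f.conv", x)$y +
    eegsr:::.revTime(eegsr:::.fwdDepthConv(p0, "bs.l1.r.conv",
                                           eegsr:::.revTime(x))$y)
  expect_equal(y0, convOnly, tolerance = 1e-12)
  # recurrence steps grow linearly in L
  resetCounters()
  invisible(bimambaStackApply(st, array(rnorm(6 * 32), c(6, 32, 1))))
  s32 <- getCounters()$scanSteps
  resetCounters()
  invisible(bimambaStackApply(st, array(rnorm(6 * 64), c(6, 64, 1))))
  s64 <- getCounters()$scanSteps
  expect_identical(s64, 2L * s32)
})

test_that("the same parameters run at any sequence length", {
  st <- bimambaStack(bimambaStackConfig(mambaBlockConfig(1, 6, 2),
                                        nLayers = 1, nBlocks = 1), seed = 8)
  set.seed(9)
  for (L in c(64, 1600)) {
    y <- bimambaStackApply(st, array(rnorm(6 * L), c(6, L, 1)))
    expect_identical(dim(y)[2], as.integer(L))
    expect_true(all(is.finite(y)))
  }
})

test_that("bidirectional receptive field covers past and future (L = 32)", {
  st <- bimambaStack(bimambaStackConfig(mambaBlockConfig(1, 6, 2),
                                        nLayers = 1, nBlocks = 1), seed = 1)
  set.seed(2)
  x <- array(rnorm(6 * 32), c(6, 32, 1))
  y <- bimambaStackApply(st, x)
  t0 <- 16
  for (tp in c(4, 28)) {                       # one before, one after t0
    x2 <- x
    x2[, tp, 1] <- x2[, tp, 1] + 0.5
    y2 <- bimambaStackApply(st, x2)
    expect_gt(max(abs(y2[, t0, 1] - y[, t0, 1])), 1e-10)
  }
})

test_that("block gradients agree with finite differences", {
  cfg <- mambaBlockConfig(2, dModel = 4, dState = 2, nHeads = 2, dtRank = 2)
  set.seed(12)
  params <- eegsr:::.initMambaBlock("mb", cfg)
  x <- array(rnorm(4 * 6 * 2), c(4, 6, 2))
  tgt <- array(rnorm(4 * 6 * 2), c(4, 6, 2))
  lossOf <- function(p) {
    y <- eegsr:::.fwdMambaBlock(p, "mb", x, cfg)$y
    mean((y - tgt)^2)
  }
  fw <- eegsr:::.fwdMambaBlock(params, "mb", x, cfg)
  bw <- eegsr:::.bwdMambaBlock(params, "mb", fw$cache,
                               2 * (fw$y - tgt) / length(tgt), cfg)
  eps <- 1e-5
  for (nm in names(bw$g)) {
    i <- 1
    pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
    num <- (lossOf(pp) - lossOf(pm)) / (2 * eps)
    expect_equal(bw$g[[nm]][i], num, tolerance = 1e-3,
                 label = paste("grad", nm))
  }
})
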