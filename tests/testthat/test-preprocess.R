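mkWindow <- function(X, rate = 32, montage = buildStandardMontage(nrow(X))) {
  new("EEGWindow", data = X, rate = rate, duration = ncol(X) / rate,
      label = 0L, montage = montage)
}

test_that("bad-channel rules: flatline, saturation, good", {
  set.seed(1)
  n <- 10000
  X <- matrix(rnorm(4 * n), 4)
  X[2, ] <- 0                                   # flatline (variance rule)
  # constant 5.0 plus a sub-1e-8 per-sample drift: enough variance to escape
  # the flatline rule, but consecutive differences below the saturation one
  X[3, ] <- 5 + cumsum(rep(9e-9, n))
  flags <- detectBadChannels(X)
  expect_identical(flags[2], "flatline")
  expect_identical(flags[3], "saturation")
  expect_identical(flags[1], "good")
  expect_identical(flags[4], "good")
})

test_that("windows with >30% bad channels are rejected, else spline-repaired", {
  mon <- buildStandardMontage(64)
  set.seed(2)
  X <- matrix(rnorm(64 * 32), 64)
  w <- mkWindow(X, montage = mon)
  # 20 of 64 = 31.25% -> rejected
  Xbad <- X; Xbad[1:20, ] <- 0
  expect_null(rejectOrRepair(mkWindow(Xbad, montage = mon)))
  # no bad channels -> unchanged object
  expect_identical(windowData(rejectOrRepair(w)), X)
  # one bad channel -> only that row changes
  X1 <- X; X1[5, ] <- 0
  rep1 <- rejectOrRepair(mkWindow(X1, montage = mon))
  diff <- windowData(rep1) != X1
  expect_true(all(rowSums(diff)[-5] == 0))
  expect_gt(sum(diff[5, ]), 0)
  # all channels bad -> rejected, not an error
  expect_null(rejectOrRepair(mkWindow(matrix(0, 64, 32), montage = mon)))
})

test_that("z-scoring matches the stabilized population formula", {
  X <- matrix(rnorm(4 * 100), 4)
  Z <- zscoreWindow(X)
  expect_lt(max(abs(rowMeans(Z))), 1e-10)
  expect_equal(unname(apply(Z, 1, function(r) sqrt(mean((r - mean(r))^2)))),
               rep(1, 4), tolerance = 1e-6)
  expect_equal(as.numeric(zscoreWindow(matrix(c(1, 2, 3), 1))),
               c(-1.2247448, 0, 1.2247448), tolerance = 1e-6)
  expect_identical(as.numeric(zscoreWindow(matrix(7, 1, 5))), rep(0, 5))
  # common average reference subtracts the instantaneous mean first
  Zc <- zscoreWindow(X, commonAverage = TRUE)
  expect_false(isTRUE(all.equal(Z, Zc)))
})

test_that("notch + bandpass filtering attenuates and preserves as specified", {
  rate <- 160
  tt <- seq_len(1600) / rate
  sp <- filterSpec(notchHz = 50, bandLo = 0.5, bandHi = 40)
  rms <- function(x) sqrt(mean(x^2))
  o50 <- applyFilters(matrix(sin(2 * pi * 50 * tt), 1), sp, rate)
  expect_lt(rms(o50), 0.05 * rms(sin(2 * pi * 50 * tt)))
  o10 <- applyFilters(matrix(sin(2 * pi * 10 * tt), 1), sp, rate)
  expect_equal(rms(o10), rms(sin(2 * pi * 10 * tt)), tolerance = 0.1)
  expect_identical(as.numeric(applyFilters(matrix(0, 1, 1600), sp, rate)),
                   rep(0, 1600))
  expect_error(applyFilters(matrix(0, 1, 100), filterSpec(bandHi = 90),
                            rate), "infeasible")
})

test_that("filtering is linear", {
  rate <- 160
  set.seed(3)
  x <- matrix(rnorm(1600), 1); y <- matrix(rnorm(1600), 1)
  sp <- filterSpec()
  lhs <- applyFilters(2 * x + 3 * y, sp, rate)
  rhs <- 2 * applyFilters(x, sp, rate) + 3 * applyFilters(y, sp, rate)
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("segmentation arithmetic, exact fractions and determinism", {
  mon <- buildStandardMontage(8)
  set.seed(4)
  rec <- matrix(rnorm(8 * 1600), 8)
  sp <- segmentAndSplit(rec, 160, mon, duration = 2, split = splitSpec())
  expect_length(c(sp$train, sp$val, sp$test), 5)
  expect_equal(ncol(windowData(sp$train[[1]])), 320)
  rec100 <- matrix(rnorm(8 * 64 * 100), 8)
  sp100 <- segmentAndSplit(rec100, 32, mon, duration = 2,
                           split = splitSpec(0.8, 0.1, 0.1, seed = 7))
  expect_equal(lengths(sp100[c("train", "val", "test")]),
               c(train = 80, val = 10, test = 10))
  sp100b <- segmentAndSplit(rec100, 32, mon, duration = 2,
                            split = splitSpec(0.8, 0.1, 0.1, seed = 7))
  expect_identical(lapply(sp100$train, windowData),
                   lapply(sp100b$train, windowData))
  expect_error(segmentAndSplit(rec[, 1:100, drop = FALSE], 160, mon),
               "fewer than 3")
})

test_that("spatial degradation keeps rows; temporal keeps every factor-th sample", {
  mon <- buildStandardMontage(64)
  set.seed(5)
  w <- mkWindow(matrix(rnorm(64 * 320), 64), rate = 160, montage = mon)
  task <- spatialTask(mon, 8)
  lr <- degradeSpatial(w, task)
  expect_equal(dim(windowData(lr)), c(8, 320))
  expect_identical(windowData(lr), windowData(w)[task@lrChannels, ])
  expect_identical(degradeWindow(w, spatialTask(mon, 1)), w)
  # temporal: closed-form sinusoid decimation
  tt <- seq_len(320) / 160
  tone <- mkWindow(matrix(sin(2 * pi * 5 * tt), 1), rate = 160,
                   montage = buildStandardMontage(1))
  tTask <- temporalTask(160, 4)
  dec <- degradeTemporal(tone, tTask)
  expect_equal(samplingRate(dec), 40)
  expect_equal(as.numeric(windowData(dec)),
               sin(2 * pi * 5 * seq(0, by = 1 / 40,
                                    length.out = 80) + 2 * pi * 5 / 160),
               tolerance = 1e-12)
  expect_equal(ncol(windowData(degradeTemporal(
    mkWindow(matrix(rnorm(1600), 1), 160, buildStandardMontage(1)),
    temporalTask(160, 8)))), 200)
})

test_that("naive upsampling follows the zero-pad / linear-interp contracts", {
  mon <- buildStandardMontage(16)
  set.seed(6)
  w <- mkWindow(matrix(rnorm(16 * 64), 16), montage = mon)
  task <- spatialTask(mon, 2)
  lr <- degradeWindow(w, task)
  up <- upsampleToHrShape(lr, task, mon)
  expect_equal(up[task@lrChannels, ], windowData(lr))
  expect_true(all(up[-task@lrChannels, ] == 0))
  # linear ramp is reproduced exactly by linear interpolation
  ramp <- mkWindow(matrix(seq(0, 1, length.out = 16), 1), rate = 8,
                   montage = buildStandardMontage(1))
  tT <- temporalTask(32, 4)
  lrR <- new("EEGWindow", data = ramp@data, rate = 8, duration = 2,
             label = 0L, montage = ramp@montage)
  upR <- upsampleToHrShape(lrR, tT, buildStandardMontage(1))
  expect_equal(ncol(upR), 64)
  expect_equal(diff(upR[1, 1:61]), rep(diff(upR[1, 1:2]), 60),
               tolerance = 1e-12)
  # hand-computed x2 with hold-last endpoint
  lr3 <- new("EEGWindow", data = matrix(c(0, 1, 0), 1), rate = 1.5,
             duration = 2, label = 0L, montage = buildStandardMontage(1))
  up3 <- upsampleToHrShape(lr3, temporalTask(3, 2), buildStandardMontage(1))
  expect_equal(as.numeric(up3), c(0, 0.5, 1, 0.5, 0, 0))
})

test_that("degrade-upsample-degrade is idempotent in both modes", {
  mon <- buildStandardMontage(16)
  set.seed(7)
  w <- mkWindow(matrix(rnorm(16 * 64), 16), montage = mon)
  sTask <- spatialTask(mon, 4)
  lr <- degradeWindow(w, sTask)
  up <- upsampleToHrShape(lr, sTask, mon)
  wUp <- mkWindow(up, montage = mon)
  expect_identical(windowData(degradeWindow(wUp, sTask)), windowData(lr))
  tTask <- temporalTask(32, 4)
  lrT <- degradeWindow(w, tTask)
  upT <- upsampleToHrShape(lrT, tTask, mon)
  wUpT <- new("EEGWindow", data = upT, rate = 32, duration = 2, label = 0L,
              montage = mon)
  expect_equal(windowData(degradeWindow(wUpT, tTask)), windowData(lrT),
               tolerance = 1e-12)
})

test_that("spline baseline copies LR rows, is exact on constants, beats zero-pad", {
  mon <- buildStandardMontage(16)
  task <- spatialTask(mon, 2)
  # one source with a smooth leadfield at high SNR: the field is spatially
  # coherent everywhere, the regime spherical splines are built for
  cfg <- syntheticConfig(nChannels = 16, nSources = 1, nClasses = 1,
                         snrDb = 25, leadfieldDecay = 1.5, nWindows = 1,
                         seed = 9)
  w <- generateSyntheticDataset(cfg, montage = mon)[[1]]
  lr <- degradeWindow(w, task)
  rec <- splineUpsampleBaseline(lr, task, mon)
  expect_equal(rec[task@lrChannels, ], windowData(lr), ignore_attr = TRUE)
  expect_lt(nmse(rec, windowData(w)),
            nmse(upsampleToHrShape(lr, task, mon), windowData(w)))
  # constant-in-space field is reproduced exactly
  cw <- mkWindow(matrix(rep(1:8, each = 16), 16, 8), montage = mon)
  lrC <- degradeWindow(cw, task)
  expect_equal(splineUpsampleBaseline(lrC, task, mon), windowData(cw),
               tolerance = 1e-8)
})

test_that("text recordings round-trip through the reader", {
  set.seed(8)
  X <- matrix(rnorm(3 * 10), 10, 3,
              dimnames = list(NULL, c("C3", "Cz", "C4")))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(X), f, row.names = FALSE)
  rec <- readRecordingText(f, rate = 100)
  expect_equal(rec$data, t(X), tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(rownames(rec$data), c("C3", "Cz", "C4"))
})
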