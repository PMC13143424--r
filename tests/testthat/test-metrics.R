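refPair <- function(C = 4, L = 64, seed = 40) {
  set.seed(seed)
  list(x = matrix(rnorm(C * L), C), xhat = matrix(rnorm(C * L), C))
}

test_that("nmse: ideal, worst-case and hand-computed values", {
  p <- refPair()
  expect_identical(nmse(p$x, p$x), 0)
  expect_identical(nmse(p$x * 0, p$x), 1)
  expect_equal(nmse(matrix(c(1, 1), 1), matrix(c(1, 2), 1)), 0.2)
  expect_error(nmse(p$x, p$x * 0), "zero-energy")
})

test_that("pcc: affine invariance, sign, covariance-formula oracle", {
  p <- refPair()
  expect_equal(pcc(2 * p$x + 3, p$x), 1)
  expect_equal(pcc(-p$x, p$x), -1)
  oracle <- mean(vapply(1:4, function(c) {
    a <- p$xhat[c, ]; b <- p$x[c, ]
    mean((a - mean(a)) * (b - mean(b))) /
      (sqrt(mean((a - mean(a))^2)) * sqrt(mean((b - mean(b))^2)))
  }, numeric(1)))
  expect_equal(pcc(p$xhat, p$x), oracle, tolerance = 1e-10)
  expect_warning(pcc(rbind(p$x[1, ] * 0, p$x[2, ]), p$x[1:2, ]), "constant")
})

test_that("ssim: ideal value, mean-shift penalty, naive-loop oracle", {
  p <- refPair(C = 2, L = 48)
  expect_equal(ssimMetric(p$x, p$x), 1, tolerance = 1e-12)
  expect_lt(ssimMetric(p$x + 10, p$x), 1)
  # independent naive implementation: explicit loop over window positions
  R <- diff(range(p$x))                      # global dynamic range
  naiveSsim <- function(a, b) {
    c1 <- (0.01 * R)^2; c2 <- (0.03 * R)^2
    g <- exp(-((1:11 - 6)^2) / (2 * 1.5^2)); g <- g / sum(g)
    vals <- sapply(seq_len(length(a) - 10), function(s) {
      wa <- a[s:(s + 10)]; wb <- b[s:(s + 10)]
      mua <- sum(g * wa); mub <- sum(g * wb)
      va <- sum(g * wa^2) - mua^2; vb <- sum(g * wb^2) - mub^2
      cab <- sum(g * wa * wb) - mua * mub
      ((2 * mua * mub + c1) * (2 * cab + c2)) /
        ((mua^2 + mub^2 + c1) * (va + vb + c2))
    })
    mean(vals)
  }
  oracle <- (naiveSsim(p$xhat[1, ], p$x[1, ]) +
             naiveSsim(p$xhat[2, ], p$x[2, ])) / 2
  expect_equal(ssimMetric(p$xhat, p$x), oracle, tolerance = 1e-6)
  # shorter-than-window signals fall back to one global window
  expect_equal(ssimMetric(p$x[, 1:8], p$x[, 1:8]), 1, tolerance = 1e-12)
})

test_that("psnr: exact dB values and the exact-match sentinel", {
  x <- matrix(0, 1, 100)
  expect_equal(psnr(x + 0.1, x), 20)
  expect_equal(psnr(x + 1, x), 0)
  expect_identical(psnr(x, x), Inf)
})

test_that("snr: zero-estimate and direct-formula cases, nmse identity", {
  p <- refPair()
  expect_equal(snr(p$x * 0, p$x), 0)
  expect_equal(snr(p$xhat, p$x),
               10 * log10(sum(p$x^2) / sum((p$xhat - p$x)^2)))
  expect_equal(snr(p$xhat, p$x), -10 * log10(nmse(p$xhat, p$x)))
})

test_that("topographic smoothness: constants, shuffling, quadratic scaling", {
  mon <- buildStandardMontage(32)
  const <- matrix(5, 32, 10)
  expect_equal(topoSmoothness(const, mon), 0)
  f <- matrix(mon@positions[, 3], 32, 10)
  set.seed(41)
  fShuf <- f[sample(32), ]
  expect_lt(topoSmoothness(f, mon), topoSmoothness(fShuf, mon))
  expect_equal(topoSmoothness(2 * f, mon), 4 * topoSmoothness(f, mon))
  expect_error(topoSmoothness(matrix(1, 3, 4), buildStandardMontage(3)),
               "neighbours")
})

test_that("band-power MAE: ideal, amplitude doubling, tone separation", {
  set.seed(42)
  x <- matrix(rnorm(2 * 512), 2)
  bp <- bandpowerMae(x, x, rate = 64)
  expect_true(all(bp == 0))
  bp2 <- bandpowerMae(2 * x, x, rate = 64)
  expect_equal(unname(bp2), rep(log(4), length(bp2)), tolerance = 1e-10)
  tt <- seq_len(512) / 64
  tone10 <- matrix(sin(2 * pi * 10 * tt), 1)
  tone20 <- matrix(sin(2 * pi * 20 * tt), 1)
  bpT <- bandpowerMae(tone10, tone20, rate = 64)
  expect_gt(bpT["alpha"], bpT["delta"] * 5)
  expect_error(bandpowerMae(x, x, rate = 64,
                            bands = list(bad = c(63, 64))), "empty band|band")
})

test_that("imaginary coherence: zero-lag null, quadrature tones, scale invariance", {
  set.seed(43)
  v <- rnorm(512)
  expect_lt(imagCoherence(rbind(v, v), rate = 64), 1e-12)
  tt <- seq_len(512) / 64
  quad <- rbind(sin(2 * pi * 10 * tt), cos(2 * pi * 10 * tt))
  ic <- imagCoherence(quad + 0.01 * matrix(rnorm(1024), 2), rate = 64,
                      band = c(9.95, 10.05))   # the tone's own Welch bin
  expect_gt(ic, 0.9)
  X <- matrix(rnorm(3 * 512), 3)
  expect_equal(imagCoherence(X, rate = 64), imagCoherence(5 * X, rate = 64),
               tolerance = 1e-12)
})

test_that("Frechet distance: closed forms and eigendecomposition oracle", {
  expect_equal(frechetDistance(c(1, 2), diag(2), c(1, 2), diag(2)), 0,
               tolerance = 1e-12)
  # 1-D closed form (mu1-mu2)^2 + (s1-s2)^2
  expect_equal(frechetDistance(0, matrix(4), 3, matrix(9)), 9 + (2 - 3)^2)
  # 5-D oracle via the symmetric square root of S2^(1/2) S1 S2^(1/2)
  set.seed(44)
  A1 <- matrix(rnorm(25), 5); S1 <- crossprod(A1) + diag(0.1, 5)
  A2 <- matrix(rnorm(25), 5); S2 <- crossprod(A2) + diag(0.1, 5)
  mu1 <- rnorm(5); mu2 <- rnorm(5)
  sqrtm <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
  }
  R2 <- sqrtm(S2)
  oracle <- sum((mu1 - mu2)^2) + sum(diag(S1 + S2)) -
            2 * sum(diag(sqrtm(R2 %*% S1 %*% R2)))
  expect_equal(frechetDistance(mu1, S1, mu2, S2), oracle, tolerance = 1e-8)
  expect_error(frechetDistance(mu1, A1, mu2, S2), "symmetric")
})

test_that("feature-space Frechet distance behaves like a divergence", {
  set.seed(45)
  ws <- lapply(1:30, function(i) matrix(rnorm(4 * 64), 4))
  expect_lt(abs(eegFid(ws, ws)), 1e-8)
  jit <- function(s) lapply(ws, function(w) w + s * matrix(rnorm(256), 4))
  d <- vapply(c(0.1, 0.5, 1), function(s) eegFid(ws, jit(s)), numeric(1))
  expect_true(all(d > 0))
  expect_true(all(diff(d) > 0))                # monotone in jitter scale
  expect_equal(eegFid(ws, rev(ws)), 0, tolerance = 1e-8)
  expect_error(eegFid(ws[1], ws), "at least 2")
})

test_that("metrics are invariant to consistent channel permutations", {
  mon <- buildStandardMontage(16)
  cfg <- syntheticConfig(nWindows = 1, seed = 46)
  x <- windowData(generateSyntheticDataset(cfg, montage = mon)[[1]])
  set.seed(47)
  xhat <- x + 0.3 * matrix(rnorm(length(x)), nrow(x))
  perm <- sample(16)
  monP <- montageSubset(mon, perm)
  expect_equal(nmse(xhat[perm, ], x[perm, ]), nmse(xhat, x))
  expect_equal(pcc(xhat[perm, ], x[perm, ]), pcc(xhat, x))
  expect_equal(ssimMetric(xhat[perm, ], x[perm, ]), ssimMetric(xhat, x))
  expect_equal(topoSmoothness(xhat[perm, ], monP), topoSmoothness(xhat, mon))
  expect_equal(imagCoherence(xhat[perm, ], rate = 32),
               imagCoherence(xhat, rate = 32))
})

test_that("the metric report is complete and JSON round-trips", {
  mon <- buildStandardMontage(16)
  cfg <- syntheticConfig(nWindows = 1, seed = 48)
  w <- generateSyntheticDataset(cfg, montage = mon)[[1]]
  set.seed(49)
  xhat <- windowData(w) + 0.1 * matrix(rnorm(16 * 64), 16)
  rep <- metricReport(xhat, w)
  expect_true(all(c("nmse", "pcc", "ssim", "psnr_db", "snr_db", "mse",
                    "rmse", "topo_smoothness", "bandpower_mae",
                    "imag_coherence") %in% names(rep)))
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, null = "null")
  back <- jsonlite::fromJSON(js)
  expect_equal(back$nmse, rep$nmse, tolerance = 1e-12)
  expect_equal(back$bandpower_mae$alpha, rep$bandpower_mae$alpha,
               tolerance = 1e-12)
})
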