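test_that("noise estimator recovers white-noise sigma and ignores slow waves", {
  set.seed(11)
  expect_equal(estimateNoise(rep(0, 64)), 0)
  x <- rnorm(1e4)
  expect_gt(estimateNoise(x), 0.9)
  expect_lt(estimateNoise(x), 1.1)
  slow <- 10 * sin(2 * pi * (1:1e4) / 100) + rnorm(1e4)
  s <- estimateNoise(slow)
  expect_gt(s, 0.8)
  expect_lt(s, 1.3)  # band excludes the period-100 oscillation
  expect_error(estimateNoise(rnorm(10)), "32 frames")
})

test_that("AR(1) coefficient recovery from autocovariance ratios", {
  set.seed(12)
  ar <- as.numeric(stats::filter(rnorm(1e4), 0.8, method = "recursive"))
  expect_lt(abs(estimateAR(ar, 0) - 0.8), 0.02)
  expect_lt(abs(estimateAR(rnorm(1e4), 1)), 0.05)
  expect_warning(g <- estimateAR(rep(3, 200), 0), "zero-variance")
  expect_equal(g, 0)
  # sparse spike drive plus measurement noise
  spk <- rbinom(1e4, 1, 0.02) * 0.8
  y <- as.numeric(stats::filter(spk, 0.9, method = "recursive")) +
    rnorm(1e4, sd = 0.05)
  expect_lt(abs(estimateAR(y, 0.05) - 0.9), 0.05)
})

test_that("OASIS handles the analytic fixtures", {
  f <- oasisDeconvolve(c(1, -1), gamma = 0, lambda = 0)
  expect_equal(f$denoised, c(1, 0))
  expect_equal(f$spikes, c(1, 0))
  # a feasible input is its own solution
  y <- c(0, 1, 0.5, 0.25)
  f2 <- oasisDeconvolve(y, gamma = 0.5, lambda = 0)
  expect_equal(f2$denoised, y)
  expect_equal(f2$spikes, c(0, 1, 0, 0))
  expect_error(oasisDeconvolve(c(1, NA), 0.5), "non-finite")
  expect_error(oasisDeconvolve(1:3, 1.0), "gamma")
})

test_that("OASIS equals the exhaustive QP oracle on random short traces", {
  set.seed(13)
  maxdev <- 0
  for (g in c(0, 0.3, 0.9)) for (lam in c(0, 0.1)) {
    for (i in 1:36) {
      T <- sample(4:8, 1)
      y <- rnorm(T)
      fit <- oasisDeconvolve(y, g, lam)
      expect_gte(min(fit$spikes), -1e-9)  # feasibility
      orc <- qp_oasis_oracle(y, g, lam)
      maxdev <- max(maxdev, max(abs(fit$denoised - orc)))
      # solution is never worse than other feasible points
      obj <- function(cc) {
        s <- c(cc[1], cc[-1] - g * cc[-T])
        0.5 * sum((cc - y)^2) + lam * sum(s)
      }
      expect_lte(obj(fit$denoised), obj(numeric(T)) + 1e-9)
      sy <- c(y[1], y[-1] - g * y[-T])
      if (all(sy >= 0))  # y itself feasible: projection is identity
        expect_lte(obj(fit$denoised), obj(y) + 1e-9)
    }
  }
  expect_lt(maxdev, 1e-6)
})

test_that("noiseless AR(1) kernels deconvolve to the exact spike train", {
  set.seed(14)
  for (g in c(0.5, 0.905)) {
    spk <- numeric(120)
    spk[c(5, 30, 31, 80, 118)] <- c(1, 0.5, 0.7, 2, 1)
    y <- as.numeric(stats::filter(spk, g, method = "recursive"))
    f <- oasisDeconvolve(y, g, 0)
    expect_equal(f$spikes, spk, tolerance = 1e-9)
    expect_equal(f$denoised, y, tolerance = 1e-9)
  }
})

test_that("noise-constrained lambda mode reaches the target residual", {
  set.seed(15)
  spk <- rbinom(500, 1, 0.02)
  y <- as.numeric(stats::filter(spk, 0.9, method = "recursive")) +
    rnorm(500, sd = 0.2)
  f <- oasisDeconvolve(y, 0.9, lambda = "auto", sigma = 0.2)
  expect_gt(f$lambda, 0)
  rss <- sqrt(sum((f$denoised - y)^2))
  expect_equal(rss, 0.2 * sqrt(500), tolerance = 0.05)
})

test_that("FOV-level deconvolution carries exclusions and pooled gamma", {
  set.seed(16)
  n <- 4; T <- 400
  spk <- matrix(rbinom(n * T, 1, 0.02) * 0.5, n)
  dffm <- t(apply(spk, 1, function(r)
    as.numeric(stats::filter(r, 0.85, method = "recursive")))) +
    matrix(rnorm(n * T, sd = 0.03), n)
  ts <- new("RoiTraceSet", roi_ids = 1:4 + 0L,
            raw = dffm, f0 = dffm * 0 + 1, dff = dffm,
            roi_areas_px = rep(5L, 4), frame_rate_hz = 10,
            excluded = integer())
  ts@dff[2, ] <- NA_real_; ts@excluded <- 2L
  dec <- deconvolveTraces(ts)
  expect_s4_class(dec, "FovDeconv")
  expect_true(all(is.na(denoised(dec)[2, ])))
  expect_length(unique(dec@gamma[-2]), 1L)  # pooled
  expect_lt(abs(dec@gamma[1] - 0.85), 0.1)
})
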