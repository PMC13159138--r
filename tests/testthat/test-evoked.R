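test_that("ROI classification uses a strict 10% overlap rule", {
  lab <- matrix(0L, 20, 20)
  lab[1:10, 1:10] <- 1L              # 100 px
  lab[15:18, 15:18] <- 2L            # fully outside
  stim <- matrix(0L, 20, 20)
  stim[1:10, 1] <- 1L                # exactly 10 px of ROI 1
  cls <- classifyRois(lab, stim)
  expect_equal(cls$non_stimulated, c(1L, 2L))   # 0.10 is not > 0.10
  stim[1, 2] <- 1L                   # 11 px -> 0.11 > 0.10
  cls2 <- classifyRois(lab, stim)
  expect_equal(cls2$stimulated, 1L)
  # full containment
  stim2 <- matrix(1L, 20, 20)
  expect_setequal(classifyRois(lab, stim2)$stimulated, c(1L, 2L))
  # partition property
  expect_length(intersect(cls2$stimulated, cls2$non_stimulated), 0L)
  expect_setequal(c(cls2$stimulated, cls2$non_stimulated), c(1L, 2L))
  expect_error(classifyRois(lab, matrix(0L, 5, 5)), "shapes differ")
})

test_that("pulse matching follows the five-frame window convention", {
  m <- matchPeaksToPulses(c(49L, 54L, 55L), 50L, 5L)
  expect_equal(m$evoked, c(FALSE, TRUE, FALSE))
  expect_equal(m$pulse_index, c(NA_integer_, 1L, NA_integer_))
  # overlapping windows attribute to the later pulse
  m2 <- matchPeaksToPulses(12L, c(10L, 12L), 5L)
  expect_equal(m2$pulse_index, 2L)
})

test_that("binary-search matching equals the linear-scan oracle", {
  set.seed(41)
  for (i in 1:200) {
    n_p <- sample(1:20, 1)
    onsets <- sort(sample(1:500, n_p))
    w <- sample(1:8, 1)
    frames <- sort(sample(1:520, sample(1:30, 1)))
    got <- matchPeaksToPulses(frames, onsets, w)
    want <- scan_match(frames, onsets, w)
    expect_equal(got$evoked, as.logical(want[, 1]))
    expect_equal(got$pulse_index, as.integer(want[, 2]))
  }
})

test_that("all five calibration forms recover exact generating curves", {
  x <- c(1, 2, 4, 6, 8, 10)
  cases <- list(
    linear      = list(y = 10 * x, want = c(a = 10, b = 0)),
    quadratic   = list(y = 0.8 * x^2 + 2 * x + 1,
                       want = c(a = 0.8, b = 2, c = 1)),
    exponential = list(y = 2 * exp(0.3 * x) + 1,
                       want = c(a = 2, b = 0.3, c = 1)),
    power_law   = list(y = 2 * x^1.5, want = c(a = 2, b = 1.5)),
    logarithmic = list(y = 3 * log(x) + 0.5, want = c(a = 3, b = 0.5)))
  for (form in names(cases)) {
    fit <- fitLedCalibration(x, cases[[form]]$y, form)
    expect_lt(max(abs(fit@coefficients - cases[[form]]$want)), 1e-6)
    expect_lt(fit@fit_residual, 1e-8)
    expect_equal(predict(fit, x), cases[[form]]$y, tolerance = 1e-7)
  }
  expect_error(fitLedCalibration(c(1, 2), 1:2, "quadratic"), "distinct")
  expect_error(fitLedCalibration(c(-1, 2, 3), 1:3, "power_law"), "positive")
})

test_that("power-response table reports n, mean and SEM per group", {
  prot <- stimProtocol(c(10L, 60L, 110L), 100, led_power_pct = c(5, 5, 5),
                       irradiance_mw_cm2 = c(50, 50, 50))
  ev <- data.frame(roi = c(1, 1, 2, 3), frame = c(11, 61, 111, 200),
                   amplitude = c(1, 2, 3, 9),
                   evoked = c(TRUE, TRUE, TRUE, FALSE),
                   pulse_index = c(1L, 2L, 3L, NA))
  pr <- powerResponse(ev, prot, stimulated_ids = c(1L, 2L))
  s <- pr[pr$class == "stimulated", ]
  expect_equal(s$n, 3L)
  expect_equal(s$mean_amplitude, 2)
  expect_equal(s$sem_amplitude, sd(1:3) / sqrt(3))
  expect_false("non_stimulated" %in% pr$class)  # no evoked peaks there
})

test_that("stimulation-field area is pi r squared", {
  expect_equal(stimFieldArea(80), pi * 40^2)
  expect_lt(abs(stimFieldArea(80) - 5e3), 50)   # ~5 x 10^3 um^2
  expect_equal(stimFieldArea(2), pi)
  expect_error(stimFieldArea(0), "positive")
})

test_that("synthetic evoked recordings satisfy the evoked contracts", {
  sim <- simulateFov(evoked_sim_params(2))
  res <- analyzeFov(sim$recording,
                    analysisConfig(peak = peakParams("global", 0.05, 2, 3)))
  cls <- res$roi_classes
  # exact recovery of the generatively stimulated cells
  expect_setequal(cls$stimulated, sim$stimulated_truth)
  # stimulation epochs carry higher median correlation than quiet periods
  expect_gte(res$correlation_stim$median_all,
             res$correlation_nonstim$median_all)
  # stimulated-class evoked amplitudes dominate at every shared drive level
  pr <- res$power_response
  for (l in intersect(pr$level[pr$class == "stimulated"],
                      pr$level[pr$class == "non_stimulated"]))
    expect_gte(pr$mean_amplitude[pr$class == "stimulated" & pr$level == l],
               pr$mean_amplitude[pr$class == "non_stimulated" &
                                 pr$level == l])
  # evoked-peak rate is higher among stimulated ROIs
  ev <- res$events
  expect_gt(mean(ev$evoked[ev$roi %in% cls$stimulated]),
            mean(ev$evoked[!ev$roi %in% cls$stimulated]))
})
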