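test_that("identical parameters and seed give bit-identical output", {
  p <- simParams(n_cells = 6, duration_s = 10, noise_sigma_counts = 15,
                 seed = 77)
  a <- simulateFov(p)
  b <- simulateFov(p)
  expect_identical(video(a$recording), video(b$recording))
  expect_identical(labelMask(a$recording), labelMask(b$recording))
  expect_identical(a$spikes, b$spikes)
})

test_that("generator geometry: disjoint disks, labels match truth", {
  p <- simParams(n_cells = 10, duration_s = 5, seed = 8)
  sim <- simulateFov(p)
  lab <- labelMask(sim$recording)
  expect_equal(sort(unique(as.integer(lab[lab > 0]))), 1:10)
  # all disks have the full radius-3 pixel count (no clipping, no overlap)
  expect_true(all(tabulate(as.integer(lab[lab > 0])) == 29L))
  expect_error(simulateFov(simParams(grid = c(16L, 16L), n_cells = 50)),
               "could not place")
})

test_that("realized spike counts are Poisson-calibrated", {
  tot <- vapply(1:10, function(s)
    nrow(simulateFov(simParams(n_cells = 20, duration_s = 150,
                               spike_rate_hz = 0.1, grid = c(72L, 72L),
                               noise_sigma_counts = 0,
                               seed = 1000 + s))$spikes), 0L)
  mu <- 20 * 150 * 0.1  # 300 expected per FOV
  expect_lt(abs(mean(tot) - mu), 3 * sqrt(mu / 10))
})

test_that("noise-free traces reproduce the AR(1) calcium truth", {
  p <- simParams(n_cells = 5, duration_s = 60, noise_sigma_counts = 0,
                 drift_amplitude_counts = 0, spike_rate_hz = 0.1, seed = 31)
  sim <- simulateFov(p)
  ts <- extractTraces(sim$recording)
  tsn <- normalizeTraces(ts)
  # dF/F0 equals the generated calcium up to count quantization and the
  # small positive floor the 10th percentile picks up from decay tails
  expect_lt(max(abs(dff(tsn) - sim$calcium)), 6e-3)
})

test_that("simulated plates load back with conditions and truth attached", {
  td <- withr::local_tempdir()
  pl <- simulatePlate(list(ctl = list(spike_rate_hz = 0.05)), td,
                      base_params = simParams(grid = c(32L, 32L),
                                              n_cells = 5, duration_s = 20),
                      seed = 3)
  expect_true(file.exists(file.path(td, "layout.yaml")))
  recs <- loadExperiment(td)
  expect_length(recs, 1L)
  expect_false(is.null(labelMask(recs[[1]])))
  expect_equal(pl$plate_map$condition, "ctl")
  expect_true(all(pl$truth$condition == "ctl"))
  grp <- applyPlateMap(recs, pl$plate_map)
  expect_named(grp, "ctl")
})
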