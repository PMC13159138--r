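test_that("experiment write/load round trip preserves videos and masks", {
  td <- withr::local_tempdir()
  pl <- simulatePlate(list(ctrl = list()), td,
                      wells_per_condition = 2,
                      base_params = simParams(grid = c(24L, 24L), n_cells = 3,
                                              duration_s = 2, seed = 9),
                      seed = 5)
  recs <- loadExperiment(td)
  expect_length(recs, 2L)
  # regenerate the first FOV from its derived seed and compare bit-for-bit
  p1 <- simParams(grid = c(24L, 24L), n_cells = 3, duration_s = 2,
                  seed = (5L * 7919L + 1L * 131L) %% 2147483647L)
  sim <- simulateFov(p1)
  expect_identical(video(recs[[1]]), video(sim$recording))
  expect_identical(labelMask(recs[[1]]), labelMask(sim$recording))
  expect_equal(frameRate(recs[[1]]), 10)
})

test_that("loader rejects mismatched masks and unknown layouts", {
  td <- withr::local_tempdir()
  dir.create(file.path(td, "B02"))
  v <- array(round(runif(10 * 8 * 8, 0, 100)), dim = c(10, 8, 8))
  wellcal:::.write_video_tiff(v, file.path(td, "B02", "B02_f000.tif"))
  wellcal:::.write_mask_tiff(matrix(1L, 16, 16),
                             file.path(td, "B02", "B02_f000_mask.tif"))
  layout <- list(dialect = "tiff", frame_rate_hz = 10)
  expect_error(loadExperiment(td, layout), "mask shape")
  expect_error(loadExperiment(td, modifyList(layout, list(dialect = "zarr"))),
               "unsupported storage dialect")
  dir.create(file.path(td, "ZZ"))
  expect_error(loadExperiment(td, layout), "well label")
})

test_that("plate-map grouping is a partition with unassigned fallback", {
  recs <- lapply(c("B02", "B03", "B04", "B05", "E11"), function(w)
    fovRecording(array(1, dim = c(1, 2, 2)), 10, well_id = w))
  pm <- data.frame(well_id = c("B02", "B03", "B04", "B05"),
                   genotype = c("wt", "wt", "mut", "mut"),
                   treatment = "", dose = NA,
                   condition = c("control", "control", "treated", "treated"))
  grp <- applyPlateMap(recs, pm)
  expect_setequal(names(grp), c("control", "treated", "unassigned"))
  expect_length(grp$control, 2L)
  expect_length(grp$treated, 2L)
  expect_equal(wellId(grp$unassigned[[1]]), "E11")
  expect_equal(sum(lengths(grp)), length(recs))  # partition
  # empty map: everything unassigned
  grp0 <- applyPlateMap(recs, NULL)
  expect_length(grp0$unassigned, 5L)
  # duplicate well entries are a config error
  expect_error(applyPlateMap(recs, rbind(pm, pm[1, ])), "more than once")
})

test_that("plate-map files parse from YAML and CSV and reject duplicates", {
  td <- withr::local_tempdir()
  yml <- file.path(td, "pm.yaml")
  writeLines(c("wells:",
               "  B07: {genotype: WT, treatment: vehicle}",
               "  B08: {genotype: KO, treatment: drug, dose: 10uM}"), yml)
  pm <- readPlateMap(yml)
  expect_equal(pm$condition, c("WT_vehicle", "KO_drug_10uM"))
  csv <- file.path(td, "pm.csv")
  writeLines(c("well,genotype,treatment", "B07,WT,vehicle", "B07,KO,drug"),
             csv)
  expect_error(readPlateMap(csv), "more than once")
})

test_that("feature export writes one CSV per parameter and round trips", {
  td <- withr::local_tempdir()
  feats <- data.frame(well_id = c("B02", "B02", "B03"),
                      fov_index = 0L, roi_id = 1:3,
                      condition = c("a", "a", "b"),
                      frequency_hz = c(0.1, 0.2, 0.30000001),
                      amplitude_mean = c(1.5, NA, 2.25))
  paths <- exportFeatureTables(feats, td)
  expect_setequal(basename(paths),
                  c("frequency_hz.csv", "amplitude_mean.csv",
                    "features_combined.csv"))
  back <- utils::read.csv(file.path(td, "features_combined.csv"))
  expect_equal(back$frequency_hz, feats$frequency_hz)
  expect_equal(back$amplitude_mean, feats$amplitude_mean)
  long <- utils::read.csv(file.path(td, "frequency_hz.csv"))
  expect_named(long, c("well_id", "fov_index", "roi_id", "condition",
                       "value"))
  # empty table: header-only files, no crash
  p0 <- exportFeatureTables(feats[0, ], file.path(td, "empty"))
  expect_true(all(file.exists(p0)))
  expect_equal(nrow(utils::read.csv(p0[1])), 0L)
})
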