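# Experiment layout on disk:
#   <root>/layout.yaml                 dialect, frame_rate_hz, pixel_size_um
#   <root>/<well>/<well>_f<k>.tif      multi-page 16-bit video (T pages)
#   <root>/<well>/<well>_f<k>_mask.tif 16-bit instance label mask
#   <root>/<well>/<well>_f<k>_stim.csv pulse log (onset_frame, duration_ms,
#                                      power_pct[, irradiance_mw_cm2])
#   <root>/<well>/<well>_f<k>_stimmask.tif binary stimulation mask

.TIFF_MAX <- 65535

.write_video_tiff <- function(video, path) {
  if (any(video < 0) || any(video > .TIFF_MAX) ||
      any(video != round(video)))
    stop("video must contain integer counts in [0, ", .TIFF_MAX,
         "] for 16-bit TIFF storage")
  frames <- lapply(seq_len(dim(video)[1]),
                   function(t) video[t, , , drop = TRUE] / .TIFF_MAX)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

.read_video_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  d <- dim(frames[[1L]])
  video <- array(0, dim = c(length(frames), d[1L], d[2L]))
  for (t in seq_along(frames)) {
    if (!identical(dim(frames[[t]]), d))
      stop("inconsistent frame shapes in ", path)
    video[t, , ] <- frames[[t]]
  }
  video
}

.write_mask_tiff <- function(mask, path) {
  if (any(mask < 0) || any(mask > .TIFF_MAX))
    stop("label mask values must fit 16-bit unsigned range")
  tiff::writeTIFF(mask / .TIFF_MAX, path, bits.per.sample = 16L)
  invisible(path)
}

.read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

.valid_well_id <- function(w) {
  ok <- grepl("^[A-P][0-9]{2}$", w)
  col <- suppressWarnings(as.integer(substring(w, 2L)))
  ok & !is.na(col) & col >= 1L & col <= 24L
}

.read_stim_csv <- function(path, shape, mask_path = NULL) {
  log <- utils::read.csv(path)
  need <- c("onset_frame", "duration_ms", "power_pct")
  if (!all(need %in% names(log)))
    stop("stimulation log ", path, " must have columns: ",
         paste(need, collapse = ", "))
  smask <- NULL
  if (!is.null(mask_path) && file.exists(mask_path)) {
    smask <- .read_mask_tiff(mask_path)
    if (!identical(dim(smask), shape))
      stop("stimulation mask ", mask_path, " does not match video shape")
  }
  irr <- if ("irradiance_mw_cm2" %in% names(log))
    log$irradiance_mw_cm2 else NA_real_
  stimProtocol(log$onset_frame,
               pulse_duration_ms = log$duration_ms[1L],
               led_power_pct = log$power_pct,
               irradiance_mw_cm2 = irr,
               stim_mask = smask)
}

#' Load a multi-well imaging experiment from disk
#'
#' Discovers one [FovRecording-class] per field of view under `root`. Each
#' well is a sub-directory named by its plate coordinate (row letter +
#' zero-padded column, e.g. `"B07"`); each FOV is a multi-page TIFF
#' `"<well>_f<k>.tif"` with optional `_mask`, `_stim` and `_stimmask`
#' side-car files. The layout config (YAML) declares the storage dialect and
#' acquisition metadata.
#'
#' @param root experiment directory.
#' @param layout path to a layout YAML, or an equivalent named list with
#'   elements `dialect` (currently `"tiff"`), `frame_rate_hz` and optionally
#'   `pixel_size_um`. Defaults to `<root>/layout.yaml`.
#' @return list of [FovRecording-class] objects, ordered by well then FOV.
#' @export
loadExperiment <- function(root, layout = file.path(root, "layout.yaml")) {
  if (!dir.exists(root)) stop("experiment directory not found: ", root)
  if (is.character(layout)) {
    if (!file.exists(layout)) stop("layout config not found: ", layout)
    layout <- yaml::read_yaml(layout)
  }
  dialect <- layout$dialect %||% "tiff"
  if (!identical(dialect, "tiff"))
    stop("unsupported storage dialect '", dialect, "' (supported: tiff)")
  fr <- layout$frame_rate_hz
  if (is.null(fr) || fr <= 0)
    stop("layout must declare a positive frame_rate_hz")
  px <- layout$pixel_size_um %||% NA_real_

  wells <- sort(basename(Filter(dir.exists,
                  list.dirs(root, recursive = FALSE))))
  bad <- wells[!.valid_well_id(wells)]
  if (length(bad))
    stop("unknown well label(s) in layout: ", paste(bad, collapse = ", "))

  recs <- list()
  for (w in wells) {
    vids <- sort(list.files(file.path(root, w),
                            pattern = paste0("^", w, "_f[0-9]+\\.tif$"),
                            full.names = TRUE))
    for (v in vids) {
      k <- as.integer(sub(".*_f([0-9]+)\\.tif$", "\\1", v))
      video <- tryCatch(.read_video_tiff(v), error = function(e)
        stop("failed to read FOV ", w, "/f", k, ": ",
             conditionMessage(e), call. = FALSE))
      stem <- sub("\\.tif$", "", v)
      mask <- NULL
      if (file.exists(paste0(stem, "_mask.tif"))) {
        mask <- .read_mask_tiff(paste0(stem, "_mask.tif"))
        if (!identical(dim(mask), dim(video)[2:3]))
          stop("mask shape ", paste(dim(mask), collapse = "x"),
               " does not match video ",
               paste(dim(video)[2:3], collapse = "x"),
               " for FOV ", w, "/f", k)
      }
      stim <- NULL
      if (file.exists(paste0(stem, "_stim.csv")))
        stim <- .read_stim_csv(paste0(stem, "_stim.csv"), dim(video)[2:3],
                               paste0(stem, "_stimmask.tif"))
      recs[[length(recs) + 1L]] <- fovRecording(
        video, fr, well_id = w, fov_index = k, label_mask = mask,
        pixel_size_um = px, stim = stim)
    }
  }
  recs
}

#' Read a plate map
#'
#' A plate map assigns experimental conditions (genotype, treatment,
#' optional dose) to wells. Two formats are accepted: YAML with a `wells`
#' section (`B07: {genotype: ..., treatment: ..., dose: ...}`) or CSV with
#' columns `well, genotype, treatment[, dose]`.
#'
#' @param path plate-map file (`.yaml`/`.yml` or `.csv`).
#' @return data.frame with columns `well_id`, `genotype`, `treatment`,
#'   `dose`, `condition` (the condition label used for grouping).
#' @export
readPlateMap <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    y <- yaml::read_yaml(path)
    wells <- y$wells %||% y
    pm <- data.frame(
      well_id   = names(wells),
      genotype  = vapply(wells, function(x) as.character(x$genotype %||% ""),
                         ""),
      treatment = vapply(wells, function(x) as.character(x$treatment %||% ""),
                         ""),
      dose      = vapply(wells, function(x) as.character(x$dose %||% NA), ""),
      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    pm <- utils::read.csv(path, stringsAsFactors = FALSE)
    names(pm)[names(pm) == "well"] <- "well_id"
    if (!all(c("well_id", "genotype") %in% names(pm)))
      stop("plate-map CSV must have columns well (or well_id) and genotype")
    if (is.null(pm$treatment)) pm$treatment <- ""
    if (is.null(pm$dose)) pm$dose <- NA_character_
    pm <- pm[c("well_id", "genotype", "treatment", "dose")]
  }
  if (anyDuplicated(pm$well_id)) {
    d <- unique(pm$well_id[duplicated(pm$well_id)])
    stop("plate map lists well(s) more than once: ", paste(d, collapse = ", "))
  }
  bad <- pm$well_id[!.valid_well_id(pm$well_id)]
  if (length(bad))
    stop("plate map has invalid well label(s): ", paste(bad, collapse = ", "))
  parts <- cbind(pm$genotype, pm$treatment,
                 ifelse(is.na(pm$dose), "", pm$dose))
  pm$condition <- apply(parts, 1L, function(p)
    paste(p[nzchar(p)], collapse = "_"))
  pm$condition[!nzchar(pm$condition)] <- "unassigned"
  pm
}

#' Group recordings by plate-map condition
#'
#' Partitions a collection of recordings by the condition their well is
#' assigned to. Wells absent from the map are collected under the reserved
#' `"unassigned"` group; every recording lands in exactly one group.
#'
#' @param recordings list of [FovRecording-class].
#' @param plate_map data.frame from [readPlateMap()], or `NULL`/empty for no
#'   annotation.
#' @return named list: condition label -> list of recordings.
#' @export
applyPlateMap <- function(recordings, plate_map = NULL) {
  wells <- vapply(recordings, wellId, "")
  cond <- rep("unassigned", length(recordings))
  if (!is.null(plate_map) && nrow(plate_map)) {
    if (anyDuplicated(plate_map$well_id))
      stop("plate map lists well(s) more than once")
    idx <- match(wells, plate_map$well_id)
    cond[!is.na(idx)] <- plate_map$condition[idx[!is.na(idx)]]
  }
  split(recordings, factor(cond, levels = unique(cond)))
}

#' Export feature tables as per-parameter CSV files
#'
#' Writes one long-format CSV per feature column (`well, fov, roi,
#' condition, value`) plus a combined wide CSV, mirroring the per-parameter
#' summaries a plate-level analysis produces.
#'
#' @param features data.frame keyed by `well_id`, `fov_index`, `roi_id` with
#'   a `condition` column and one column per scalar feature (see
#'   [buildFeatureTable()]).
#' @param out_dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
exportFeatureTables <- function(features, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  keys <- c("well_id", "fov_index", "roi_id", "condition", "genotype",
            "treatment", "dose")
  feat_cols <- setdiff(names(features), keys)
  have_keys <- intersect(c("well_id", "fov_index", "roi_id", "condition"),
                         names(features))
  paths <- character()
  for (fc in feat_cols) {
    out <- features[c(have_keys, fc)]
    names(out)[ncol(out)] <- "value"
    p <- file.path(out_dir, paste0(fc, ".csv"))
    utils::write.csv(out, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "features_combined.csv")
  utils::write.csv(features, p, row.names = FALSE)
  invisible(c(paths, p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
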