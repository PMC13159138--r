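#' Default analysis configuration
#'
#' @param baseline_window_s sliding-window length for F0, seconds.
#' @param baseline_percentile F0 percentile.
#' @param gamma fixed AR(1) coefficient or `NULL` to estimate.
#' @param lambda OASIS sparsity penalty (0, or `"auto"`).
#' @param pool_gamma pool gamma per field of view.
#' @param peak a [peakParams()] list.
#' @param evoked_window_frames evoked-peak window after a pulse onset.
#' @param epoch_window_ms half-window of stimulation epochs for the
#'   epoch-restricted correlations.
#' @return configuration list.
#' @export
analysisConfig <- function(baseline_window_s = 30, baseline_percentile = 10,
                           gamma = NULL, lambda = 0, pool_gamma = TRUE,
                           peak = peakParams(min_distance_frames = 3L),
                           evoked_window_frames = 5L,
                           epoch_window_ms = 250) {
  list(baseline_window_s = baseline_window_s,
       baseline_percentile = baseline_percentile,
       gamma = gamma, lambda = lambda, pool_gamma = pool_gamma,
       peak = peak, evoked_window_frames = evoked_window_frames,
       epoch_window_ms = epoch_window_ms)
}

#' Analyze one field of view end to end
#'
#' Trace extraction, dF/F0 normalization, OASIS deconvolution, event
#' detection, single-cell features, pairwise correlation and — when a
#' stimulation protocol is attached — evoked labeling, stimulated/
#' non-stimulated classification and epoch-restricted correlations.
#'
#' @param rec a [FovRecording-class] with a label mask.
#' @param config an [analysisConfig()] list.
#' @return list: `traces` ([RoiTraceSet-class]), `deconv`
#'   ([FovDeconv-class]), `events` (data.frame), `features` (data.frame, one
#'   row per ROI), `correlation`, and in evoked mode `roi_classes`,
#'   `correlation_stim`, `correlation_nonstim`, `power_response`.
#' @export
analyzeFov <- function(rec, config = analysisConfig()) {
  stopifnot(is(rec, "FovRecording"))
  if (is.null(rec@label_mask)) stop("recording has no label mask")
  traces <- extractTraces(rec)
  traces <- normalizeTraces(traces, config$baseline_window_s,
                            config$baseline_percentile)
  dec <- deconvolveTraces(traces, gamma = config$gamma,
                          lambda = config$lambda,
                          pool_gamma = config$pool_gamma)
  events <- detectEvents(dec, config$peak)
  T <- ncol(traces@raw)
  feats <- do.call(rbind, lapply(seq_along(traces@roi_ids), function(i) {
    id <- traces@roi_ids[i]
    if (id %in% traces@excluded) return(NULL)
    ev <- events[events$roi == id, , drop = FALSE]
    cbind(data.frame(well_id = rec@well_id, fov_index = rec@fov_index,
                     roi_id = id),
          computeFeatures(ev$frame, ev$amplitude, traces@roi_areas_px[i],
                          T, rec@frame_rate_hz, rec@pixel_size_um))
  }))
  out <- list(traces = traces, deconv = dec, events = events,
              features = feats)
  ok <- rowSums(is.na(dec@denoised)) == 0L
  if (sum(ok) >= 2L)
    out$correlation <- correlationMatrix(dec@denoised[ok, , drop = FALSE],
                                         roi_ids = dec@roi_ids[ok])
  stim <- rec@stim
  if (!is.null(stim) && length(stim@pulse_onset_frames)) {
    out$events <- matchPeaksToPulses(events, stim,
                                     config$evoked_window_frames)
    if (!is.null(stim@stim_mask)) {
      cls <- classifyRois(rec@label_mask, stim@stim_mask)
      out$roi_classes <- cls
      grp <- dec@roi_ids[ok] %in% cls$stimulated
      if (sum(ok) >= 2L) {
        smask <- buildStimFrameMask(stim@pulse_onset_frames,
                                    config$epoch_window_ms,
                                    rec@frame_rate_hz, T)
        out$correlation <- correlationMatrix(
          dec@denoised[ok, , drop = FALSE], roi_groups = grp,
          roi_ids = dec@roi_ids[ok])
        if (sum(smask) >= 10L)
          out$correlation_stim <- correlationMatrix(
            dec@denoised[ok, , drop = FALSE], frame_mask = smask,
            roi_groups = grp, roi_ids = dec@roi_ids[ok])
        if (sum(!smask) >= 10L)
          out$correlation_nonstim <- correlationMatrix(
            dec@denoised[ok, , drop = FALSE], frame_mask = !smask,
            roi_groups = grp, roi_ids = dec@roi_ids[ok])
      }
      if (any(out$events$evoked %in% TRUE))
        out$power_response <- powerResponse(out$events, stim,
                                            cls$stimulated)
    }
  }
  out
}

#' Analyze a whole experiment
#'
#' Runs [analyzeFov()] on every recording, annotates the pooled feature
#' table with plate-map conditions, and summarizes per condition (mean event
#' frequency and amplitude, percentage of active cells). Optionally exports
#' the per-parameter CSVs.
#'
#' @param recordings list of [FovRecording-class], e.g. from
#'   [loadExperiment()].
#' @param plate_map data.frame from [readPlateMap()], or `NULL`.
#' @param config an [analysisConfig()] list.
#' @param out_dir optional directory for [exportFeatureTables()].
#' @return list: `features` (pooled table with condition columns),
#'   `condition_summary` (data.frame), `fov_results` (per-FOV lists).
#' @export
analyzeExperiment <- function(recordings, plate_map = NULL,
                              config = analysisConfig(), out_dir = NULL) {
  res <- lapply(recordings, analyzeFov, config = config)
  features <- do.call(rbind, lapply(res, `[[`, "features"))
  if (!is.null(plate_map)) {
    idx <- match(features$well_id, plate_map$well_id)
    features$condition <- ifelse(is.na(idx), "unassigned",
                                 plate_map$condition[idx])
    features$genotype <- ifelse(is.na(idx), NA, plate_map$genotype[idx])
    features$treatment <- ifelse(is.na(idx), NA, plate_map$treatment[idx])
  } else {
    features$condition <- "unassigned"
  }
  cs <- do.call(rbind, lapply(split(features, features$condition),
    function(g) data.frame(
      condition = g$condition[1L], n_rois = nrow(g),
      mean_frequency_hz = mean(g$event_frequency_hz),
      mean_amplitude = mean(g$amplitude_mean, na.rm = TRUE),
      percent_active = percentActive(g$active))))
  rownames(cs) <- NULL
  if (!is.null(out_dir)) exportFeatureTables(features, out_dir)
  list(features = features, condition_summary = cs, fov_results = res)
}
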