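#' Construct a stimulation protocol
#'
#' @param pulse_onset_frames integer vector of 1-based pulse onset frames,
#'   strictly increasing.
#' @param pulse_duration_ms pulse duration in milliseconds.
#' @param led_power_pct LED power in percent; recycled to one value per pulse.
#' @param irradiance_mw_cm2 irradiance in mW/cm^2 per pulse; defaults to `NA`
#'   until a calibration is applied.
#' @param stim_mask optional binary matrix (Y x X) marking the illuminated
#'   region.
#' @return a [StimProtocol-class] object.
#' @export
stimProtocol <- function(pulse_onset_frames, pulse_duration_ms = 100,
                         led_power_pct = NA_real_,
                         irradiance_mw_cm2 = NA_real_,
                         stim_mask = NULL) {
  n <- length(pulse_onset_frames)
  if (!is.null(stim_mask)) {
    stim_mask <- matrix(as.integer(stim_mask != 0), nrow = nrow(stim_mask))
  }
  new("StimProtocol",
      pulse_onset_frames = as.integer(pulse_onset_frames),
      pulse_duration_ms  = as.numeric(pulse_duration_ms),
      led_power_pct      = rep_len(as.numeric(led_power_pct), n),
      irradiance_mw_cm2  = rep_len(as.numeric(irradiance_mw_cm2), n),
      stim_mask          = stim_mask)
}

#' Construct a field-of-view recording
#'
#' @param video numeric array `T x Y x X` of non-negative fluorescence counts.
#' @param frame_rate_hz acquisition rate in Hz.
#' @param well_id well label such as `"B07"`.
#' @param fov_index non-negative integer position index within the well.
#' @param label_mask optional integer matrix `Y x X`, 0 = background.
#' @param pixel_size_um optional pixel size in micrometres.
#' @param stim optional [StimProtocol-class].
#' @return a [FovRecording-class] object.
#' @export
fovRecording <- function(video, frame_rate_hz, well_id = "A01",
                         fov_index = 0L, label_mask = NULL,
                         pixel_size_um = NA_real_, stim = NULL) {
  if (!is.null(label_mask)) storage.mode(label_mask) <- "integer"
  new("FovRecording",
      well_id = as.character(well_id), fov_index = as.integer(fov_index),
      video = video, frame_rate_hz = as.numeric(frame_rate_hz),
      pixel_size_um = as.numeric(pixel_size_um),
      label_mask = label_mask, stim = stim)
}
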