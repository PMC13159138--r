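#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Optogenetic stimulation protocol
#'
#' Describes a train of LED stimulation pulses delivered during a recording:
#' pulse onset frames (1-based), pulse duration, per-pulse LED power and
#' (once calibrated) irradiance at the sample, plus an optional binary
#' stimulation mask marking the illuminated region of the field of view.
#'
#' @slot pulse_onset_frames strictly increasing integer vector of 1-based
#'   onset frames.
#' @slot pulse_duration_ms positive scalar, pulse duration in milliseconds.
#' @slot led_power_pct numeric vector of LED power (percent), one per pulse.
#' @slot irradiance_mw_cm2 numeric vector of irradiance (mW/cm^2), one per
#'   pulse; may be `NA` until a calibration is applied.
#' @slot stim_mask binary integer/logical matrix (Y x X) marking the
#'   illuminated region, or `NULL`.
#'
#' @seealso [stimProtocol()], [classifyRois()], [matchPeaksToPulses()]
#' @export
setClass("StimProtocol",
  slots = c(
    pulse_onset_frames = "integer",
    pulse_duration_ms  = "numeric",
    led_power_pct      = "numeric",
    irradiance_mw_cm2  = "numeric",
    stim_mask          = "matrixOrNULL"
  )
)

setValidity("StimProtocol", function(object) {
  o <- object@pulse_onset_frames
  msg <- character()
  if (length(o) && any(diff(o) <= 0))
    msg <- c(msg, "pulse_onset_frames must be strictly increasing")
  if (length(o) && any(o < 1L))
    msg <- c(msg, "pulse_onset_frames must be >= 1 (frames are 1-based)")
  if (length(object@pulse_duration_ms) != 1L || object@pulse_duration_ms <= 0)
    msg <- c(msg, "pulse_duration_ms must be a positive scalar")
  if (length(object@led_power_pct) != length(o))
    msg <- c(msg, "led_power_pct must have one entry per pulse")
  if (length(object@irradiance_mw_cm2) != length(o))
    msg <- c(msg, "irradiance_mw_cm2 must have one entry per pulse")
  if (any(object@irradiance_mw_cm2 < 0, na.rm = TRUE))
    msg <- c(msg, "irradiance must be non-negative")
  if (length(msg)) msg else TRUE
})

setClassUnion("StimProtocolOrNULL", c("StimProtocol", "NULL"))

#' One field of view of a multi-well recording
#'
#' Container for a single acquired position: the fluorescence video
#' (frames x rows x columns), acquisition frame rate, optional pixel size,
#' optional instance label mask delineating the somata and optional
#' stimulation protocol.
#'
#' @slot well_id well label, e.g. `"B07"` (row letter + zero-padded column).
#' @slot fov_index non-negative integer index of the position within the well.
#' @slot video numeric array `T x Y x X` of non-negative fluorescence counts.
#' @slot frame_rate_hz positive scalar acquisition rate.
#' @slot pixel_size_um pixel size in micrometres, or `NA_real_` if unknown.
#' @slot label_mask integer matrix `Y x X` with 0 = background and labels
#'   1..N marking ROIs, or `NULL`.
#' @slot stim a [StimProtocol-class] or `NULL`.
#'
#' @seealso [fovRecording()], [loadExperiment()], [extractTraces()]
#' @export
setClass("FovRecording",
  slots = c(
    well_id       = "character",
    fov_index     = "integer",
    video         = "array",
    frame_rate_hz = "numeric",
    pixel_size_um = "numeric",
    label_mask    = "matrixOrNULL",
    stim          = "StimProtocolOrNULL"
  )
)

setValidity("FovRecording", function(object) {
  msg <- character()
  d <- dim(object@video)
  if (length(d) != 3L)
    msg <- c(msg, "video must be a 3-D array (T x Y x X)")
  else {
    if (d[1L] < 1L) msg <- c(msg, "video must have at least one frame")
    if (!is.null(object@label_mask) &&
        !identical(dim(object@label_mask), d[2:3]))
      msg <- c(msg, sprintf(
        "label_mask (%s) does not match video frame shape (%s)",
        paste(dim(object@label_mask), collapse = "x"),
        paste(d[2:3], collapse = "x")))
    if (!is.null(object@stim) && !is.null(object@stim@stim_mask) &&
        !identical(dim(object@stim@stim_mask), d[2:3]))
      msg <- c(msg, "stim_mask does not match video frame shape")
  }
  if (length(object@frame_rate_hz) != 1L || object@frame_rate_hz <= 0)
    msg <- c(msg, "frame_rate_hz must be a positive scalar")
  if (length(object@fov_index) != 1L || object@fov_index < 0L)
    msg <- c(msg, "fov_index must be a non-negative integer")
  if (length(msg)) msg else TRUE
})

#' Per-ROI fluorescence traces for one field of view
#'
#' Holds, row per ROI, the raw mean-fluorescence traces F, the
#' sliding-window percentile baseline F0 and the normalized dF/F0 traces,
#' together with ROI pixel areas. ROIs whose baseline fell below the
#' positive floor are recorded in `excluded` and carry `NA` rows in
#' `f0`/`dff`.
#'
#' @slot roi_ids integer vector of mask labels, ascending.
#' @slot raw N x T matrix of mean fluorescence per ROI (counts).
#' @slot f0 N x T baseline matrix (counts), or 0 x 0 before normalization.
#' @slot dff N x T dF/F0 matrix, dimensionless.
#' @slot roi_areas_px integer vector of ROI pixel counts.
#' @slot frame_rate_hz acquisition rate carried from the recording.
#' @slot excluded integer vector of roi_ids excluded by the baseline floor.
#'
#' @seealso [extractTraces()], [normalizeTraces()], [deconvolveTraces()]
#' @export
setClass("RoiTraceSet",
  slots = c(
    roi_ids       = "integer",
    raw           = "matrix",
    f0            = "matrix",
    dff           = "matrix",
    roi_areas_px  = "integer",
    frame_rate_hz = "numeric",
    excluded      = "integer"
  )
)

setValidity("RoiTraceSet", function(object) {
  msg <- character()
  n <- length(object@roi_ids)
  if (nrow(object@raw) != n)
    msg <- c(msg, "raw must have one row per roi_id")
  if (length(object@roi_areas_px) != n)
    msg <- c(msg, "roi_areas_px must have one entry per roi_id")
  if (n && any(object@roi_areas_px < 1L))
    msg <- c(msg, "ROI areas must be positive")
  for (s in c("f0", "dff")) {
    m <- slot(object, s)
    if (nrow(m) && !identical(dim(m), dim(object@raw)))
      msg <- c(msg, sprintf("%s must match the shape of raw", s))
  }
  if (is.unsorted(object@roi_ids, strictly = TRUE))
    msg <- c(msg, "roi_ids must be strictly ascending")
  if (length(msg)) msg else TRUE
})

#' Deconvolution results for one field of view
#'
#' Output of non-negative AR(1) deconvolution (OASIS) applied to each dF/F0
#' trace: the denoised calcium trace c, the deconvolved activity s with
#' s[t] = c[t] - gamma * c[t-1] >= 0, and the per-ROI model parameters.
#'
#' @slot roi_ids integer ROI labels (rows of the matrices).
#' @slot denoised N x T matrix of denoised dF/F0.
#' @slot spikes N x T matrix of deconvolved activity, non-negative.
#' @slot gamma per-ROI AR(1) coefficient in [0, 1).
#' @slot sigma per-ROI noise scale (dF/F0 units).
#' @slot lambda per-ROI sparsity penalty used.
#' @slot frame_rate_hz acquisition rate carried through the pipeline.
#'
#' @seealso [oasisDeconvolve()], [deconvolveTraces()], [detectEvents()]
#' @export
setClass("FovDeconv",
  slots = c(
    roi_ids       = "integer",
    denoised      = "matrix",
    spikes        = "matrix",
    gamma         = "numeric",
    sigma         = "numeric",
    lambda        = "numeric",
    frame_rate_hz = "numeric"
  )
)

setValidity("FovDeconv", function(object) {
  msg <- character()
  n <- length(object@roi_ids)
  if (nrow(object@denoised) != n || nrow(object@spikes) != n)
    msg <- c(msg, "denoised and spikes must have one row per roi_id")
  if (!identical(dim(object@denoised), dim(object@spikes)))
    msg <- c(msg, "denoised and spikes must have the same shape")
  for (s in c("gamma", "sigma", "lambda"))
    if (length(slot(object, s)) != n)
      msg <- c(msg, sprintf("%s must have one entry per roi_id", s))
  if (any(object@gamma < 0 | object@gamma >= 1))
    msg <- c(msg, "gamma must lie in [0, 1)")
  if (any(object@sigma < 0)) msg <- c(msg, "sigma must be non-negative")
  if (any(object@lambda < 0)) msg <- c(msg, "lambda must be non-negative")
  if (length(msg)) msg else TRUE
})

#' LED power calibration curve
#'
#' Least-squares fit mapping LED power (percent) to irradiance at the sample
#' (mW/cm^2) under one of five functional forms: linear `a*x + b`, quadratic
#' `a*x^2 + b*x + c`, exponential `a*exp(b*x) + c`, power-law `a*x^b`,
#' logarithmic `a*log(x) + b`.
#'
#' @slot form one of `"linear"`, `"quadratic"`, `"exponential"`,
#'   `"power_law"`, `"logarithmic"`.
#' @slot coefficients named numeric vector of fitted coefficients.
#' @slot fit_residual root-mean-square residual of the fit.
#'
#' @seealso [fitLedCalibration()], [predict,LedCalibration-method]
#' @export
setClass("LedCalibration",
  slots = c(
    form         = "character",
    coefficients = "numeric",
    fit_residual = "numeric"
  )
)

.led_forms <- c(linear = 2L, quadratic = 3L, exponential = 3L,
                power_law = 2L, logarithmic = 2L)

setValidity("LedCalibration", function(object) {
  msg <- character()
  if (!object@form %in% names(.led_forms))
    msg <- c(msg, sprintf("unknown calibration form '%s'", object@form))
  else if (length(object@coefficients) != .led_forms[[object@form]])
    msg <- c(msg, sprintf("form '%s' requires %d coefficients",
                          object@form, .led_forms[[object@form]]))
  if (object@fit_residual < 0) msg <- c(msg, "fit_residual must be >= 0")
  if (length(msg)) msg else TRUE
})
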