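#' Peak-detection parameters
#'
#' Two height modes are supported, mirroring common practice for
#' noise-adaptive transient detection: `"noise_multiplier"`, where the
#' minimum peak height is `height_value * sigma` per ROI (sigma from the
#' deconvolution noise estimate), and `"global"`, where `height_value` is an
#' absolute dF/F0 threshold applied to all ROIs. The prominence threshold is
#' always adaptive: `prominence_multiplier * sigma`.
#'
#' @param height_mode `"noise_multiplier"` or `"global"`.
#' @param height_value multiplier k_h (default 3) or absolute height.
#' @param prominence_multiplier k_p applied to sigma; default 2.
#' @param min_distance_frames minimum spacing between retained peaks; when
#'   two candidates are closer, the higher one is kept (ties: earlier frame).
#' @return a list of class `"PeakParams"`.
#' @export
peakParams <- function(height_mode = c("noise_multiplier", "global"),
                       height_value = 3, prominence_multiplier = 2,
                       min_distance_frames = 1L) {
  height_mode <- match.arg(height_mode)
  if (height_value <= 0) stop("height_value must be > 0")
  if (prominence_multiplier < 0) stop("prominence_multiplier must be >= 0")
  if (min_distance_frames < 1L) stop("min_distance_frames must be >= 1")
  structure(list(height_mode = height_mode, height_value = height_value,
                 prominence_multiplier = prominence_multiplier,
                 min_distance_frames = as.integer(min_distance_frames)),
            class = "PeakParams")
}

# local maxima with plateaus collapsed to their first frame; trace edges are
# never peaks
.local_maxima <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3L) return(integer())
  i <- 2:(k - 1L)
  starts[i][r$values[i] > r$values[i - 1L] & r$values[i] > r$values[i + 1L]]
}

# topographic prominence with unlimited window: on each side, scan to the
# nearest strictly higher sample (or the edge) and take the minimum; the
# prominence is peak height minus the larger of the two side minima
.prominence <- function(x, peak) {
  h <- x[peak]
  left <- if (peak == 1L) h else {
    seg <- x[(peak - 1L):1L]
    stopi <- which(seg > h)
    if (length(stopi)) min(seg[seq_len(stopi[1L] - 1L)], h) else min(seg)
  }
  right <- if (peak == length(x)) h else {
    seg <- x[(peak + 1L):length(x)]
    stopi <- which(seg > h)
    if (length(stopi)) min(seg[seq_len(stopi[1L] - 1L)], h) else min(seg)
  }
  h - max(left, right)
}

#' Detect calcium transients on a denoised dF/F0 trace
#'
#' Finds local maxima that (i) reach the effective minimum height (per-ROI
#' `k_h * sigma` in noise-multiplier mode, an absolute value in global mode),
#' (ii) have topographic prominence >= `k_p * sigma`, and (iii) are at least
#' `min_distance_frames` apart. Distance conflicts are resolved by keeping
#' the higher peak (exact ties: the earlier frame). Plateau maxima are placed
#' at the first frame of the plateau. Amplitudes are read directly off the
#' denoised trace at the peak frame.
#'
#' @param denoised numeric trace (denoised dF/F0).
#' @param sigma per-ROI noise scale.
#' @param params a [peakParams()] list.
#' @return data.frame with columns `frame` (1-based, strictly increasing) and
#'   `amplitude`; zero rows when nothing qualifies.
#' @export
detectPeaks <- function(denoised, sigma, params = peakParams()) {
  stopifnot(inherits(params, "PeakParams"), sigma >= 0)
  x <- as.numeric(denoised)
  if (any(!is.finite(x))) stop("non-finite values in trace")
  empty <- data.frame(frame = integer(), amplitude = numeric())
  cand <- .local_maxima(x)
  if (!length(cand)) return(empty)
  h_min <- if (params$height_mode == "noise_multiplier")
    params$height_value * sigma else params$height_value
  cand <- cand[x[cand] >= h_min]
  if (!length(cand)) return(empty)
  p_min <- params$prominence_multiplier * sigma
  if (p_min > 0) {
    prom <- vapply(cand, function(p) .prominence(x, p), 0)
    cand <- cand[prom >= p_min]
    if (!length(cand)) return(empty)
  }
  d <- params$min_distance_frames
  if (d > 1L && length(cand) > 1L) {
    ord <- cand[order(-x[cand], cand)]
    kept <- integer()
    for (p in ord)
      if (!length(kept) || all(abs(kept - p) >= d)) kept <- c(kept, p)
    cand <- sort(kept)
  }
  data.frame(frame = cand, amplitude = x[cand])
}

#' Detect events for every ROI of a field of view
#'
#' @param deconv a [FovDeconv-class].
#' @param params a [peakParams()] list.
#' @return data.frame (one row per peak): `roi`, `frame`, `time_s`
#'   (`(frame - 1) / frame_rate`), `amplitude`, `evoked` (`NA` until
#'   [matchPeaksToPulses()] labels it), `pulse_index`.
#' @export
detectEvents <- function(deconv, params = peakParams()) {
  stopifnot(is(deconv, "FovDeconv"))
  out <- list()
  for (i in seq_along(deconv@roi_ids)) {
    tr <- deconv@denoised[i, ]
    if (anyNA(tr)) next  # ROI excluded upstream
    pk <- detectPeaks(tr, deconv@sigma[i], params)
    if (nrow(pk))
      out[[length(out) + 1L]] <- data.frame(
        roi = deconv@roi_ids[i], frame = pk$frame,
        time_s = (pk$frame - 1) / deconv@frame_rate_hz,
        amplitude = pk$amplitude, evoked = NA, pulse_index = NA_integer_)
  }
  if (!length(out))
    return(data.frame(roi = integer(), frame = integer(), time_s = numeric(),
                      amplitude = numeric(), evoked = logical(),
                      pulse_index = integer()))
  do.call(rbind, out)
}

#' Single-ROI activity features
#'
#' Event frequency (peaks per second of recording), inter-event intervals,
#' amplitude statistics, cell size, and the active flag (>= 1 detected
#' event).
#'
#' @param peak_frames integer vector of peak frames for one ROI (1-based).
#' @param peak_amplitudes matching amplitudes.
#' @param roi_area_px ROI area in pixels.
#' @param T recording length in frames.
#' @param frame_rate_hz acquisition rate.
#' @param pixel_size_um pixel size; cell_size_um2 is `NA` when unknown.
#' @return one-row data.frame of features.
#' @export
computeFeatures <- function(peak_frames, peak_amplitudes, roi_area_px,
                            T, frame_rate_hz, pixel_size_um = NA_real_) {
  stopifnot(T >= 1, frame_rate_hz > 0)
  n <- length(peak_frames)
  iei <- if (n >= 2L) diff(sort(peak_frames)) / frame_rate_hz else numeric()
  data.frame(
    n_events = n,
    event_frequency_hz = n / (T / frame_rate_hz),
    mean_iei_s = if (length(iei)) mean(iei) else NA_real_,
    amplitude_mean = if (n) mean(peak_amplitudes) else NA_real_,
    amplitude_median = if (n) stats::median(peak_amplitudes) else NA_real_,
    cell_size_px = roi_area_px,
    cell_size_um2 = if (is.na(pixel_size_um)) NA_real_ else
      roi_area_px * pixel_size_um^2,
    active = n >= 1L)
}

#' Percentage of active cells
#'
#' @param active logical vector of per-ROI active flags, or a feature table
#'   with an `active` column.
#' @return 100 * active / total; `NA` with a message for an empty input.
#' @export
percentActive <- function(active) {
  if (is.data.frame(active)) active <- active$active
  if (!length(active)) {
    message("percentActive: no ROIs; returning NA")
    return(NA_real_)
  }
  100 * sum(active) / length(active)
}
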