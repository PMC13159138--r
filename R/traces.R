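#' Extract per-ROI mean fluorescence traces
#'
#' Averages the video over the pixels of each labelled ROI, frame by frame.
#' The pixel statistic is the arithmetic mean, the standard choice for soma
#' ROIs. ROI order is ascending label; absent labels (gaps in the label
#' sequence) simply do not produce a trace.
#'
#' @param video numeric array `T x Y x X`, or a [FovRecording-class] (whose
#'   mask is then used by default).
#' @param label_mask integer matrix `Y x X`, 0 = background.
#' @param frame_rate_hz acquisition rate, required when `video` is an array.
#' @return a [RoiTraceSet-class] with `raw` and `roi_areas_px` filled;
#'   baseline and dF/F0 are added by [normalizeTraces()].
#' @export
extractTraces <- function(video, label_mask = NULL, frame_rate_hz = NULL) {
  if (is(video, "FovRecording")) {
    rec <- video
    video <- rec@video
    label_mask <- label_mask %||% rec@label_mask
    frame_rate_hz <- frame_rate_hz %||% rec@frame_rate_hz
  }
  if (is.null(label_mask)) stop("a label mask is required")
  if (is.null(frame_rate_hz)) stop("frame_rate_hz is required")
  d <- dim(video)
  if (length(d) != 3L) stop("video must be a T x Y x X array")
  if (!identical(dim(label_mask), d[2:3]))
    stop("label mask shape (", paste(dim(label_mask), collapse = "x"),
         ") does not match video frames (", paste(d[2:3], collapse = "x"), ")")
  lab <- as.integer(label_mask)
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) stop("label mask contains no ROIs")
  m <- matrix(video, nrow = d[1L])  # T x (Y*X), pixel-major like the mask
  raw <- matrix(0, length(ids), d[1L])
  areas <- integer(length(ids))
  for (i in seq_along(ids)) {
    pix <- which(lab == ids[i])
    areas[i] <- length(pix)
    raw[i, ] <- if (length(pix) == 1L) m[, pix] else rowMeans(m[, pix])
  }
  new("RoiTraceSet", roi_ids = ids, raw = raw,
      f0 = matrix(0, 0, 0), dff = matrix(0, 0, 0),
      roi_areas_px = areas, frame_rate_hz = as.numeric(frame_rate_hz),
      excluded = integer())
}

# Percentile by linear interpolation between order statistics at rank
# p/100 * (n-1) (same rule as stats::quantile type 7); inlined for the
# hot loop.
.window_percentile <- function(sorted, p) {
  n <- length(sorted)
  if (n == 1L) return(sorted)
  h <- p / 100 * (n - 1)
  lo <- floor(h)
  if (lo >= n - 1) return(sorted[n])
  sorted[lo + 1L] + (h - lo) * (sorted[lo + 2L] - sorted[lo + 1L])
}

#' Sliding-window percentile baseline
#'
#' For each frame t the baseline F0\[t\] is the given percentile (default
#' 10th) of the raw fluorescence within a window of `window_frames` frames
#' centred on t (for even lengths the extra frame falls on the left), clipped
#' to the recording so edge windows shrink. Percentiles interpolate linearly
#' between order statistics at rank `p/100 * (n-1)`.
#'
#' @param raw numeric trace, or an N x T matrix (row-wise traces).
#' @param window_frames window length in frames (>= 1).
#' @param percentile percentile in (0, 100); default 10.
#' @return baseline of the same shape as `raw`.
#' @export
computeBaseline <- function(raw, window_frames, percentile = 10) {
  if (is.matrix(raw)) {
    out <- raw
    for (i in seq_len(nrow(raw)))
      out[i, ] <- computeBaseline(raw[i, ], window_frames, percentile)
    return(out)
  }
  if (window_frames < 1L) stop("window_frames must be >= 1")
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must lie in (0, 100)")
  if (any(!is.finite(raw)))
    stop("non-finite values in trace at frame(s): ",
         paste(utils::head(which(!is.finite(raw)), 10L), collapse = ", "))
  T <- length(raw)
  w <- as.integer(window_frames)
  half_lo <- w %/% 2L
  half_hi <- (w - 1L) %/% 2L
  f0 <- numeric(T)
  for (t in seq_len(T)) {
    lo <- max(1L, t - half_lo)
    hi <- min(T, t + half_hi)
    f0[t] <- .window_percentile(sort.int(raw[lo:hi], method = "quick"),
                                percentile)
  }
  f0
}

#' Compute dF/F0 against a sliding-window percentile baseline
#'
#' dF/F0 = (F - F0) / F0 elementwise, with F0 from [computeBaseline()]. The
#' baseline must stay above a positive floor `eps` everywhere; a violation
#' raises an error (at the trace level) so that callers can exclude the ROI
#' rather than abort the field of view (see [normalizeTraces()]).
#'
#' @inheritParams computeBaseline
#' @param eps positive floor for F0; default `1e-6 * median(raw)`.
#' @return dF/F0 trace of the same length.
#' @export
computeDff <- function(raw, window_frames, percentile = 10, eps = NULL) {
  f0 <- computeBaseline(raw, window_frames, percentile)
  eps <- eps %||% (1e-6 * stats::median(raw))
  if (any(f0 <= max(eps, 0)))
    stop("baseline fell below the positive floor at frame(s): ",
         paste(utils::head(which(f0 <= max(eps, 0)), 10L), collapse = ", "))
  (raw - f0) / f0
}

#' Normalize an ROI trace set to dF/F0
#'
#' Fills the `f0` and `dff` slots of a [RoiTraceSet-class]. ROIs whose
#' baseline falls below the positive floor (10^-6 of the set's global median
#' intensity by default) are excluded — their `f0`/`dff` rows are `NA` and
#' their ids recorded in the `excluded` slot — rather than failing the whole
#' field of view.
#'
#' @param traces a [RoiTraceSet-class] from [extractTraces()].
#' @param window_s baseline window length in seconds; default 30 s
#'   (converted to frames with the set's frame rate).
#' @param percentile baseline percentile; default 10.
#' @param eps positive floor for F0.
#' @return the trace set with baseline and dF/F0 matrices filled.
#' @export
normalizeTraces <- function(traces, window_s = 30, percentile = 10,
                            eps = NULL) {
  stopifnot(is(traces, "RoiTraceSet"))
  w <- max(1L, as.integer(round(window_s * traces@frame_rate_hz)))
  eps <- eps %||% (1e-6 * stats::median(traces@raw))
  n <- nrow(traces@raw); T <- ncol(traces@raw)
  f0 <- matrix(NA_real_, n, T)
  dff <- matrix(NA_real_, n, T)
  excl <- integer()
  for (i in seq_len(n)) {
    b <- computeBaseline(traces@raw[i, ], w, percentile)
    if (any(b <= max(eps, 0))) {
      excl <- c(excl, traces@roi_ids[i])
      next
    }
    f0[i, ] <- b
    dff[i, ] <- (traces@raw[i, ] - b) / b
  }
  if (length(excl))
    warning("ROI(s) excluded by baseline floor: ",
            paste(excl, collapse = ", "))
  traces@f0 <- f0
  traces@dff <- dff
  traces@excluded <- excl
  traces
}
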