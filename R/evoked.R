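#' Classify ROIs as stimulated or non-stimulated
#'
#' An ROI is "stimulated" when strictly more than `threshold` (default 10%)
#' of its pixel area overlaps the binary stimulation mask; every ROI falls in
#' exactly one class. The ROI pixel sets are used exactly as segmented, with
#' no morphological preprocessing.
#'
#' @param label_mask integer label image (0 = background).
#' @param stim_mask binary image of the illuminated region, same shape.
#' @param threshold overlap fraction that must be exceeded; default 0.10.
#' @return list with `stimulated` and `non_stimulated` (integer ROI ids) and
#'   `overlap_fraction` (named numeric vector over all ROIs).
#' @export
classifyRois <- function(label_mask, stim_mask, threshold = 0.10) {
  if (!identical(dim(label_mask), dim(stim_mask)))
    stop("label mask (", paste(dim(label_mask), collapse = "x"),
         ") and stimulation mask (", paste(dim(stim_mask), collapse = "x"),
         ") shapes differ")
  lab <- as.integer(label_mask)
  inside <- as.integer(stim_mask) != 0L
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) stop("label mask contains no ROIs")
  area <- tabulate(lab, nbins = max(ids))
  hit <- tabulate(lab[inside], nbins = max(ids))
  frac <- hit[ids] / area[ids]
  names(frac) <- ids
  list(stimulated = ids[frac > threshold],
       non_stimulated = ids[frac <= threshold],
       overlap_fraction = frac)
}

#' Label detected peaks as evoked by stimulation pulses
#'
#' A peak at frame f is evoked when it falls within a `window_frames`-long
#' window starting at some pulse onset p, i.e. p <= f <= p + window_frames -
#' 1 (the onset frame counts as the first of the window). The preceding
#' pulse is located by binary search over the sorted onsets; a peak
#' qualifying under overlapping windows is attributed to the latest pulse.
#'
#' @param events event data.frame from [detectEvents()] (needs a `frame`
#'   column), or an integer vector of peak frames.
#' @param pulse_onset_frames sorted 1-based pulse onsets, or a
#'   [StimProtocol-class].
#' @param window_frames window length in frames; default 5.
#' @return the events with `evoked` (logical) and `pulse_index` (index of the
#'   attributed pulse, `NA` when not evoked) filled; for a vector input, a
#'   data.frame with `frame`, `evoked`, `pulse_index`.
#' @export
matchPeaksToPulses <- function(events, pulse_onset_frames,
                               window_frames = 5L) {
  if (is(pulse_onset_frames, "StimProtocol"))
    pulse_onset_frames <- pulse_onset_frames@pulse_onset_frames
  onsets <- as.integer(pulse_onset_frames)
  if (is.unsorted(onsets, strictly = TRUE))
    stop("pulse onsets must be strictly increasing")
  vec_in <- !is.data.frame(events)
  if (vec_in) events <- data.frame(frame = as.integer(events))
  f <- events$frame
  if (length(onsets)) {
    idx <- findInterval(f, onsets)  # latest onset <= f: binary search
    evoked <- idx >= 1L & (f - onsets[pmax(idx, 1L)]) <= window_frames - 1L
    idx[!evoked] <- NA_integer_
  } else {
    evoked <- rep(FALSE, length(f))
    idx <- rep(NA_integer_, length(f))
  }
  events$evoked <- evoked
  events$pulse_index <- idx
  events
}

#' Fit an LED power-to-irradiance calibration
#'
#' Least-squares fit of one of five forms mapping LED power (percent) to
#' irradiance at the sample (mW/cm^2): linear `a*x + b`, quadratic
#' `a*x^2 + b*x + c`, exponential `a*exp(b*x) + c`, power-law `a*x^b`
#' (log-log regression), logarithmic `a*log(x) + b`. Power-law and
#' logarithmic forms require positive powers (power-law additionally positive
#' irradiances).
#'
#' @param power_pct LED power values.
#' @param irradiance matching irradiance values.
#' @param form calibration form.
#' @return a [LedCalibration-class]; use `predict(fit, power)` to map power
#'   to irradiance.
#' @export
fitLedCalibration <- function(power_pct, irradiance,
                              form = c("linear", "quadratic", "exponential",
                                       "power_law", "logarithmic")) {
  form <- match.arg(form)
  x <- as.numeric(power_pct); y <- as.numeric(irradiance)
  if (length(x) != length(y)) stop("power and irradiance lengths differ")
  need <- .led_forms[[form]]
  if (length(unique(x)) < need)
    stop("form '", form, "' needs at least ", need, " distinct points")
  if (form %in% c("power_law", "logarithmic") && any(x <= 0))
    stop("form '", form, "' requires strictly positive power values")
  coefs <- switch(form,
    linear = {
      fit <- stats::lm(y ~ x)
      c(a = unname(stats::coef(fit)[2L]), b = unname(stats::coef(fit)[1L]))
    },
    quadratic = {
      fit <- stats::lm(y ~ x + I(x^2))
      co <- stats::coef(fit)
      c(a = unname(co[3L]), b = unname(co[2L]), c = unname(co[1L]))
    },
    logarithmic = {
      fit <- stats::lm(y ~ log(x))
      c(a = unname(stats::coef(fit)[2L]), b = unname(stats::coef(fit)[1L]))
    },
    power_law = {
      if (any(y <= 0))
        stop("power_law form requires strictly positive irradiances")
      fit <- stats::lm(log(y) ~ log(x))
      c(a = exp(unname(stats::coef(fit)[1L])),
        b = unname(stats::coef(fit)[2L]))
    },
    exponential = .fit_exponential(x, y))
  pred <- .predict_calibration(form, coefs, x)
  resid <- sqrt(mean((y - pred)^2))
  new("LedCalibration", form = form, coefficients = coefs,
      fit_residual = resid)
}

# a*exp(b*x) + c by Levenberg-Marquardt; the offset start is profiled just
# below the smallest irradiance (physically: irradiance rises from a small
# dark offset), then both orientations of the exponential are tried.
.fit_exponential <- function(x, y) {
  spread <- max(diff(range(y)), 1e-8)
  starts <- list()
  for (c0 in c(min(y) - 0.05 * spread, min(y) - 0.5 * spread, 0)) {
    z <- y - c0
    if (all(z > 0)) {
      lf <- stats::lm(log(z) ~ x)
      starts[[length(starts) + 1L]] <-
        c(a = exp(unname(stats::coef(lf)[1L])),
          b = unname(stats::coef(lf)[2L]), c = c0)
    }
    z <- c0 + spread + max(y) - y  # mirrored: decaying toward an asymptote
    if (all(z > 0)) {
      lf <- stats::lm(log(z) ~ x)
      starts[[length(starts) + 1L]] <-
        c(a = -exp(unname(stats::coef(lf)[1L])),
          b = unname(stats::coef(lf)[2L]), c = max(y) + c0 + spread)
    }
  }
  best <- NULL; best_rss <- Inf
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(b * x) + c,
                        start = as.list(st),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (rss < best_rss) { best <- fit; best_rss <- rss }
    }
  }
  if (is.null(best)) stop("exponential calibration fit failed to converge")
  co <- stats::coef(best)
  c(a = unname(co["a"]), b = unname(co["b"]), c = unname(co["c"]))
}

.predict_calibration <- function(form, co, x) {
  switch(form,
    linear      = co["a"] * x + co["b"],
    quadratic   = co["a"] * x^2 + co["b"] * x + co["c"],
    exponential = co["a"] * exp(co["b"] * x) + co["c"],
    power_law   = co["a"] * x^co["b"],
    logarithmic = co["a"] * log(x) + co["b"])
}

#' Predict irradiance from LED power
#'
#' @param object a [LedCalibration-class].
#' @param newdata numeric vector of LED power values.
#' @param ... ignored.
#' @return predicted irradiance (mW/cm^2).
#' @export
setMethod("predict", "LedCalibration", function(object, newdata, ...) {
  unname(.predict_calibration(object@form, object@coefficients,
                              as.numeric(newdata)))
})

#' Irradiance-response table of evoked amplitudes
#'
#' Groups evoked peak amplitudes by the irradiance (or LED power, when no
#' calibration is attached) of their attributed pulse and by ROI class, and
#' reports n, mean and SEM per group; empty groups are omitted.
#'
#' @param events labeled event data.frame from [matchPeaksToPulses()] with a
#'   `roi` column.
#' @param protocol the [StimProtocol-class] of the recording.
#' @param stimulated_ids ROI ids classified as stimulated (from
#'   [classifyRois()]).
#' @return data.frame: `class` (`"stimulated"`/`"non_stimulated"`), `level`
#'   (irradiance or power), `n`, `mean_amplitude`, `sem_amplitude`.
#' @export
powerResponse <- function(events, protocol, stimulated_ids = integer()) {
  stopifnot(is(protocol, "StimProtocol"))
  ev <- events[!is.na(events$evoked) & events$evoked, , drop = FALSE]
  if (!nrow(ev)) stop("no evoked peaks to summarize")
  lev <- protocol@irradiance_mw_cm2
  if (all(is.na(lev))) lev <- protocol@led_power_pct
  ev$level <- lev[ev$pulse_index]
  ev$class <- ifelse(ev$roi %in% stimulated_ids, "stimulated",
                     "non_stimulated")
  agg <- do.call(rbind, lapply(
    split(ev, list(ev$class, ev$level), drop = TRUE),
    function(g) data.frame(
      class = g$class[1L], level = g$level[1L], n = nrow(g),
      mean_amplitude = mean(g$amplitude),
      sem_amplitude = if (nrow(g) > 1L)
        stats::sd(g$amplitude) / sqrt(nrow(g)) else NA_real_)))
  rownames(agg) <- NULL
  agg[order(agg$class, agg$level), , drop = FALSE]
}

#' Area of a circular stimulation field
#'
#' @param diameter_um field diameter in micrometres (e.g. the iris-limited
#'   minimal field of ~80 um corresponds to ~5e3 um^2).
#' @return area in um^2, `pi * (d/2)^2`.
#' @export
stimFieldArea <- function(diameter_um) {
  if (!is.numeric(diameter_um) || any(diameter_um <= 0))
    stop("diameter must be positive")
  pi * (diameter_um / 2)^2
}
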