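#' @rdname FovRecording-class
#' @param object,x an object.
#' @export
setGeneric("wellId", function(x) standardGeneric("wellId"))

#' @rdname FovRecording-class
#' @export
setGeneric("fovIndex", function(x) standardGeneric("fovIndex"))

#' @rdname FovRecording-class
#' @export
setGeneric("video", function(x) standardGeneric("video"))

#' @rdname FovRecording-class
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname FovRecording-class
#' @export
setGeneric("labelMask", function(x) standardGeneric("labelMask"))

#' @rdname FovRecording-class
#' @export
setGeneric("stimProtocolOf", function(x) standardGeneric("stimProtocolOf"))

#' @rdname RoiTraceSet-class
#' @param x an object.
#' @export
setGeneric("roiIds", function(x) standardGeneric("roiIds"))

#' @rdname RoiTraceSet-class
#' @export
setGeneric("rawTraces", function(x) standardGeneric("rawTraces"))

#' @rdname RoiTraceSet-class
#' @export
setGeneric("baseline", function(x) standardGeneric("baseline"))

#' @rdname RoiTraceSet-class
#' @export
setGeneric("dff", function(x) standardGeneric("dff"))

#' @rdname RoiTraceSet-class
#' @export
setGeneric("roiAreas", function(x) standardGeneric("roiAreas"))

#' @rdname FovDeconv-class
#' @param x an object.
#' @export
setGeneric("denoised", function(x) standardGeneric("denoised"))

#' @rdname FovDeconv-class
#' @export
setGeneric("spikes", function(x) standardGeneric("spikes"))

# ---- accessor methods ----

#' @rdname FovRecording-class
setMethod("wellId", "FovRecording", function(x) x@well_id)
#' @rdname FovRecording-class
setMethod("fovIndex", "FovRecording", function(x) x@fov_index)
#' @rdname FovRecording-class
setMethod("video", "FovRecording", function(x) x@video)
#' @rdname FovRecording-class
setMethod("frameRate", "FovRecording", function(x) x@frame_rate_hz)
#' @rdname FovRecording-class
setMethod("labelMask", "FovRecording", function(x) x@label_mask)
#' @rdname FovRecording-class
setMethod("stimProtocolOf", "FovRecording", function(x) x@stim)

#' @rdname RoiTraceSet-class
setMethod("roiIds", "RoiTraceSet", function(x) x@roi_ids)
#' @rdname RoiTraceSet-class
setMethod("rawTraces", "RoiTraceSet", function(x) x@raw)
#' @rdname RoiTraceSet-class
setMethod("baseline", "RoiTraceSet", function(x) x@f0)
#' @rdname RoiTraceSet-class
setMethod("dff", "RoiTraceSet", function(x) x@dff)
#' @rdname RoiTraceSet-class
setMethod("roiAreas", "RoiTraceSet", function(x) x@roi_areas_px)
#' @rdname FovRecording-class
setMethod("frameRate", "RoiTraceSet", function(x) x@frame_rate_hz)

#' @rdname FovDeconv-class
setMethod("roiIds", "FovDeconv", function(x) x@roi_ids)
#' @rdname FovDeconv-class
setMethod("denoised", "FovDeconv", function(x) x@denoised)
#' @rdname FovDeconv-class
setMethod("spikes", "FovDeconv", function(x) x@spikes)
#' @rdname FovRecording-class
setMethod("frameRate", "FovDeconv", function(x) x@frame_rate_hz)

# ---- show methods ----

setMethod("show", "FovRecording", function(object) {
  d <- dim(object@video)
  cat(sprintf("FovRecording well %s fov %d: %d frames of %dx%d @ %.3g Hz\n",
              object@well_id, object@fov_index, d[1], d[2], d[3],
              object@frame_rate_hz))
  if (!is.null(object@label_mask))
    cat(sprintf("  label mask: %d ROIs\n",
                length(setdiff(unique(as.integer(object@label_mask)), 0L))))
  if (!is.null(object@stim))
    cat(sprintf("  stimulation: %d pulses of %g ms\n",
                length(object@stim@pulse_onset_frames),
                object@stim@pulse_duration_ms))
  invisible(NULL)
})

setMethod("show", "RoiTraceSet", function(object) {
  cat(sprintf("RoiTraceSet: %d ROIs x %d frames @ %.3g Hz (%s normalized)\n",
              length(object@roi_ids), ncol(object@raw), object@frame_rate_hz,
              if (nrow(object@dff)) "dF/F0" else "not yet"))
  if (length(object@excluded))
    cat(sprintf("  excluded by baseline floor: %s\n",
                paste(object@excluded, collapse = ", ")))
  invisible(NULL)
})

setMethod("show", "FovDeconv", function(object) {
  cat(sprintf(
    "FovDeconv: %d ROIs x %d frames; gamma median %.3f, sigma median %.4f\n",
    length(object@roi_ids), ncol(object@denoised),
    stats::median(object@gamma), stats::median(object@sigma)))
  invisible(NULL)
})

setMethod("show", "StimProtocol", function(object) {
  cat(sprintf("StimProtocol: %d pulses of %g ms, power %s%%\n",
              length(object@pulse_onset_frames), object@pulse_duration_ms,
              paste(format(unique(object@led_power_pct)), collapse = "/")))
  invisible(NULL)
})

setMethod("show", "LedCalibration", function(object) {
  cat(sprintf("LedCalibration (%s): %s; rms residual %.3g\n", object@form,
              paste(names(object@coefficients),
                    format(object@coefficients, digits = 4),
                    sep = "=", collapse = ", "),
              object@fit_residual))
  invisible(NULL)
})
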