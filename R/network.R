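#' Pairwise Pearson correlation between ROIs of one field of view
#'
#' Computes the N x N Pearson correlation matrix of the denoised dF/F0
#' traces over a frame selection (full recording, stimulation epochs, or
#' their complement), excluding ROIs with zero variance over the selection.
#' Medians are taken over the upper-triangle off-diagonal entries; when a
#' stimulated/non-stimulated grouping is given, rows are ordered
#' stimulated-first and the group medians are computed over the within-group
#' blocks.
#'
#' @param denoised N x T matrix (rows = ROIs), or a [FovDeconv-class].
#' @param frame_mask optional logical T-vector selecting frames (e.g. from
#'   [buildStimFrameMask()]).
#' @param roi_groups optional logical vector, `TRUE` for stimulated ROIs.
#' @param roi_ids optional ROI labels; taken from the [FovDeconv-class] when
#'   one is passed.
#' @param min_frames minimum number of selected frames (default 10); fewer
#'   raises an epoch error.
#' @return list of class `"CorrelationResult"`: `matrix` (stimulated-first
#'   when grouped; `NULL` when fewer than two usable ROIs remain, reported as
#'   missing), `roi_order`, `stimulated`, `median_all`, `median_stim`,
#'   `median_nonstim`, `frames_used`, `excluded`.
#' @export
correlationMatrix <- function(denoised, frame_mask = NULL, roi_groups = NULL,
                              roi_ids = NULL, min_frames = 10L) {
  if (is(denoised, "FovDeconv")) {
    roi_ids <- roi_ids %||% denoised@roi_ids
    denoised <- denoised@denoised
  }
  stopifnot(is.matrix(denoised))
  n <- nrow(denoised); T <- ncol(denoised)
  if (n < 2L) stop("need at least 2 ROIs")
  roi_ids <- roi_ids %||% seq_len(n)
  if (is.null(frame_mask)) frame_mask <- rep(TRUE, T)
  if (length(frame_mask) != T) stop("frame_mask length must equal T")
  used <- sum(frame_mask)
  if (used < min_frames)
    stop("epoch too short: ", used, " frames selected, need >= ", min_frames)
  X <- denoised[, frame_mask, drop = FALSE]
  sds <- apply(X, 1L, stats::sd)
  keep <- is.finite(sds) & sds > 0
  excluded <- roi_ids[!keep]
  if (length(excluded))
    message("ROI(s) with zero variance over the selection excluded: ",
            paste(excluded, collapse = ", "))
  res <- list(matrix = NULL, roi_order = integer(), stimulated = logical(),
              median_all = NA_real_, median_stim = NA_real_,
              median_nonstim = NA_real_, frames_used = used,
              excluded = excluded)
  class(res) <- "CorrelationResult"
  if (sum(keep) < 2L) {
    message("fewer than 2 usable ROIs; correlation undefined")
    return(res)
  }
  ids <- roi_ids[keep]
  grp <- if (is.null(roi_groups)) rep(FALSE, sum(keep)) else roi_groups[keep]
  ord <- order(!grp)  # stimulated first, stable
  M <- stats::cor(t(X[keep, , drop = FALSE][ord, , drop = FALSE]))
  dimnames(M) <- list(ids[ord], ids[ord])
  upper <- function(m) m[upper.tri(m)]
  res$matrix <- M
  res$roi_order <- ids[ord]
  res$stimulated <- grp[ord]
  res$median_all <- stats::median(upper(M))
  if (!is.null(roi_groups)) {
    s <- which(res$stimulated)
    ns <- which(!res$stimulated)
    if (length(s) >= 2L)
      res$median_stim <- stats::median(upper(M[s, s, drop = FALSE]))
    if (length(ns) >= 2L)
      res$median_nonstim <- stats::median(upper(M[ns, ns, drop = FALSE]))
  }
  res
}

#' @export
print.CorrelationResult <- function(x, ...) {
  cat(sprintf("CorrelationResult: %d ROIs over %d frames; median %.3f",
              length(x$roi_order), x$frames_used, x$median_all))
  if (!is.na(x$median_stim) || !is.na(x$median_nonstim))
    cat(sprintf(" (stim %.3f / non-stim %.3f)", x$median_stim,
                x$median_nonstim))
  cat("\n")
  invisible(x)
}

#' Frame mask of stimulation epochs
#'
#' Marks frames within +/- `window_ms` of any pulse onset, converting the
#' window to frames by ceiling (`ceil(window_ms/1000 * frame_rate)`) so a
#' stimulus-adjacent frame is never dropped; overlapping windows merge. The
#' logical complement of the result is the non-stimulation-period mask.
#'
#' @param pulse_frames sorted 1-based pulse onset frames within \[1, T\].
#' @param window_ms half-window in milliseconds (default 250).
#' @param frame_rate_hz acquisition rate.
#' @param T recording length in frames.
#' @return logical vector of length T.
#' @export
buildStimFrameMask <- function(pulse_frames, window_ms = 250,
                               frame_rate_hz, T) {
  stopifnot(window_ms >= 0, frame_rate_hz > 0, T >= 1)
  if (length(pulse_frames) && (min(pulse_frames) < 1 || max(pulse_frames) > T))
    stop("pulse frames must lie within [1, T]")
  w <- ceiling(window_ms / 1000 * frame_rate_hz)
  mask <- rep(FALSE, T)
  for (p in pulse_frames)
    mask[max(1L, p - w):min(T, p + w)] <- TRUE
  mask
}

#' Plot a correlation matrix as a heatmap
#'
#' Simple static heatmap of a [correlationMatrix()] result, with ROIs in the
#' stored (stimulated-first) order.
#'
#' @param cr a `"CorrelationResult"`.
#' @param file optional PNG path; plots to the active device when `NULL`.
#' @return invisibly, `cr`.
#' @export
plotCorrelationMatrix <- function(cr, file = NULL) {
  if (is.null(cr$matrix)) stop("no correlation matrix to plot")
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 600)
    on.exit(grDevices::dev.off())
  }
  n <- nrow(cr$matrix)
  graphics::image(seq_len(n), seq_len(n), t(cr$matrix[n:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = grDevices::hcl.colors(64, "RdBu",
                                                               rev = TRUE),
                  xlab = "ROI", ylab = "ROI",
                  main = sprintf("Pairwise Pearson correlation (median %.3f)",
                                 cr$median_all))
  invisible(cr)
}
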