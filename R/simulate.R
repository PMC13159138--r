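#' Parameters for the synthetic field-of-view generator
#'
#' The generator emulates the recordings the analysis pipeline targets:
#' disk-shaped somata on a dimmer background, Poisson spike trains driving
#' AR(1) (exponential-decay) calcium transients, an optional shared network
#' drive producing correlated activity, an optional optogenetic protocol
#' with pulse-locked evoked spikes inside a stimulation region, and
#' fluorescence F = baseline * (1 + calcium) + drift * sin + Gaussian noise,
#' quantized to integer camera counts.
#'
#' @param grid `c(Y, X)` image size in pixels.
#' @param n_cells number of somata.
#' @param cell_radius_px soma disk radius.
#' @param frame_rate_hz acquisition rate; default 10 Hz.
#' @param duration_s recording length in seconds.
#' @param spike_rate_hz mean spontaneous spike rate per cell.
#' @param gamma AR(1) kernel coefficient; default `exp(-1 / (tau_s *
#'   frame_rate_hz))` with a 1-s indicator decay constant.
#' @param transient_amplitude dF/F jump caused by one spike.
#' @param baseline_counts soma resting intensity (camera counts).
#' @param bg_level background intensity as a fraction of baseline.
#' @param drift_amplitude_counts amplitude of the slow sinusoidal drift.
#' @param drift_period_s drift period (>= 60 s keeps it below the baseline
#'   window's passband).
#' @param noise_sigma_counts Gaussian camera noise SD (counts).
#' @param shared_drive_weight in \[0, 1\]: fraction of each cell's rate drawn
#'   from a population-wide event train (0 = independent cells).
#' @param refractory_frames minimum gap between spikes of one cell.
#' @param evoked `NULL`, or a list describing the optogenetic protocol:
#'   `mask_rect` (`c(y0, y1, x0, x1)` in pixels), `pulse_onset_frames`,
#'   `pulse_duration_ms` (default 100), `power_pct` (per pulse),
#'   `direct_drive_prob`, `propagated_drive_prob`, `irradiance_per_pct`
#'   (linear calibration slope, default 10), `half_sat_mw_cm2` (irradiance
#'   of half-maximal evoked gain, default 24).
#' @param seed integer RNG seed; identical parameters and seed give
#'   bit-identical output.
#' @return a list of class `"SimParams"`.
#' @export
simParams <- function(grid = c(64L, 64L), n_cells = 20L, cell_radius_px = 3L,
                      frame_rate_hz = 10, duration_s = 120,
                      spike_rate_hz = 0.1, gamma = NULL,
                      transient_amplitude = 0.5, baseline_counts = 1000,
                      bg_level = 0.3, drift_amplitude_counts = 30,
                      drift_period_s = 90, noise_sigma_counts = 20,
                      shared_drive_weight = 0, refractory_frames = 8L,
                      evoked = NULL, seed = 1L) {
  gamma <- gamma %||% exp(-1 / (1.0 * frame_rate_hz))
  if (!is.null(evoked)) {
    evoked$pulse_duration_ms <- evoked$pulse_duration_ms %||% 100
    evoked$power_pct <- rep_len(evoked$power_pct %||% 10,
                                length(evoked$pulse_onset_frames))
    evoked$direct_drive_prob <- evoked$direct_drive_prob %||% 0.9
    evoked$propagated_drive_prob <- evoked$propagated_drive_prob %||% 0.2
    evoked$irradiance_per_pct <- evoked$irradiance_per_pct %||% 10
    evoked$half_sat_mw_cm2 <- evoked$half_sat_mw_cm2 %||% 24
  }
  p <- list(grid = as.integer(grid), n_cells = as.integer(n_cells),
            cell_radius_px = as.integer(cell_radius_px),
            frame_rate_hz = frame_rate_hz, duration_s = duration_s,
            spike_rate_hz = spike_rate_hz, gamma = gamma,
            transient_amplitude = transient_amplitude,
            baseline_counts = baseline_counts, bg_level = bg_level,
            drift_amplitude_counts = drift_amplitude_counts,
            drift_period_s = drift_period_s,
            noise_sigma_counts = noise_sigma_counts,
            shared_drive_weight = shared_drive_weight,
            refractory_frames = as.integer(refractory_frames),
            evoked = evoked, seed = as.integer(seed))
  stopifnot(p$n_cells >= 1L, p$cell_radius_px >= 1L, p$frame_rate_hz > 0,
            p$duration_s > 0, p$spike_rate_hz >= 0,
            p$gamma >= 0, p$gamma < 1, p$transient_amplitude >= 0,
            p$shared_drive_weight >= 0, p$shared_drive_weight <= 1)
  class(p) <- "SimParams"
  p
}

# disk pixel offsets around a centre
.disk_pixels <- function(cy, cx, r, Y, X) {
  ys <- max(1L, cy - r):min(Y, cy + r)
  xs <- max(1L, cx - r):min(X, cx + r)
  g <- expand.grid(y = ys, x = xs)
  g <- g[(g$y - cy)^2 + (g$x - cx)^2 <= r^2, , drop = FALSE]
  g$y + (g$x - 1L) * Y
}

# rejection-sampled jittered-grid placement; in evoked mode, disks straddling
# the stimulation-mask boundary are rejected so "stimulated" is unambiguous
.place_cells <- function(p, stim_inside) {
  Y <- p$grid[1L]; X <- p$grid[2L]
  r <- p$cell_radius_px
  s <- 2L * r + 3L
  cy0 <- seq(r + 2L, Y - r - 1L, by = s)
  cx0 <- seq(r + 2L, X - r - 1L, by = s)
  cand <- expand.grid(y = cy0, x = cx0)
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  jit <- max(0L, (s - 2L * r - 2L) %/% 2L)
  centers <- matrix(0L, 0L, 2L)
  for (i in seq_len(nrow(cand))) {
    if (nrow(centers) == p$n_cells) break
    cy <- cand$y[i] + sample.int(2L * jit + 1L, 1L) - jit - 1L
    cx <- cand$x[i] + sample.int(2L * jit + 1L, 1L) - jit - 1L
    if (cy - r < 1L || cy + r > Y || cx - r < 1L || cx + r > X) next
    if (nrow(centers) &&
        any((centers[, 1L] - cy)^2 + (centers[, 2L] - cx)^2 <=
            (2L * r + 1L)^2)) next
    if (!is.null(stim_inside)) {
      pix <- .disk_pixels(cy, cx, r, Y, X)
      ins <- stim_inside[pix]
      if (any(ins) && !all(ins)) next
    }
    centers <- rbind(centers, c(cy, cx))
  }
  if (nrow(centers) < p$n_cells)
    stop("could not place ", p$n_cells, " non-overlapping cells on a ",
         Y, "x", X, " grid")
  centers
}

#' Simulate one field of view with ground truth
#'
#' @param params a [simParams()] list.
#' @return list: `recording` (a [FovRecording-class] with label mask and,
#'   in evoked mode, the stimulation protocol attached), `centers` (n x 2,
#'   row/col), `spikes` (data.frame `roi`, `frame`, `amplitude`, `evoked`,
#'   `pulse_index`), `calcium` (noise-free dF/F truth matrix N x T), and
#'   `params`.
#' @export
simulateFov <- function(params) {
  stopifnot(inherits(params, "SimParams"))
  p <- params
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(p$seed)

  Y <- p$grid[1L]; X <- p$grid[2L]
  T <- as.integer(round(p$duration_s * p$frame_rate_hz))
  stim_inside <- NULL
  protocol <- NULL
  if (!is.null(p$evoked)) {
    m <- matrix(0L, Y, X)
    rc <- p$evoked$mask_rect
    m[rc[1L]:rc[2L], rc[3L]:rc[4L]] <- 1L
    stim_inside <- as.vector(m) != 0L
    irr <- p$evoked$irradiance_per_pct * p$evoked$power_pct
    protocol <- stimProtocol(p$evoked$pulse_onset_frames,
                             pulse_duration_ms = p$evoked$pulse_duration_ms,
                             led_power_pct = p$evoked$power_pct,
                             irradiance_mw_cm2 = irr, stim_mask = m)
  }
  centers <- .place_cells(p, stim_inside)
  r <- p$cell_radius_px
  pix <- lapply(seq_len(p$n_cells), function(i)
    .disk_pixels(centers[i, 1L], centers[i, 2L], r, Y, X))
  label <- matrix(0L, Y, X)
  for (i in seq_len(p$n_cells)) label[pix[[i]]] <- i

  # spontaneous spikes: independent Poisson + thinned shared drive. The
  # per-frame probability is dead-time compensated so the realized rate
  # after the refractory filter equals the nominal rate in expectation
  # (renewal argument: mean interval = refractory - 1 + 1/p').
  w <- p$shared_drive_weight
  pr_frame <- p$spike_rate_hz / p$frame_rate_hz
  dt_corr <- 1 - pr_frame * (p$refractory_frames - 1L)
  if (dt_corr <= 0.5)
    stop("spike rate too high for the refractory period")
  pr_frame <- pr_frame / dt_corr
  shared <- stats::runif(T) < pr_frame
  spike_amp <- vector("list", p$n_cells)
  spike_frm <- vector("list", p$n_cells)
  spike_evk <- vector("list", p$n_cells)
  spike_pls <- vector("list", p$n_cells)
  in_mask <- if (is.null(stim_inside)) rep(FALSE, p$n_cells) else
    vapply(pix, function(px) all(stim_inside[px]), TRUE)
  for (i in seq_len(p$n_cells)) {
    own <- stats::runif(T) < (1 - w) * pr_frame
    adopt <- shared & (stats::runif(T) < w)
    frm <- which(own | adopt)
    # the first and last frame cannot host a resolvable transient peak
    frm <- frm[frm > 1L & frm < T]
    amp <- rep(p$transient_amplitude, length(frm))
    evk <- rep(FALSE, length(frm))
    pls <- rep(NA_integer_, length(frm))
    if (!is.null(p$evoked)) {
      onsets <- p$evoked$pulse_onset_frames
      irr <- protocol@irradiance_mw_cm2
      gain <- irr / (irr + p$evoked$half_sat_mw_cm2)
      for (j in seq_along(onsets)) {
        if (in_mask[i]) {
          if (stats::runif(1) < p$evoked$direct_drive_prob) {
            frm <- c(frm, min(onsets[j] + 1L, T))
            amp <- c(amp, p$transient_amplitude * 1.5 * gain[j])
            evk <- c(evk, TRUE); pls <- c(pls, j)
          }
        } else if (stats::runif(1) < p$evoked$propagated_drive_prob) {
          frm <- c(frm, min(onsets[j] + 2L, T))
          amp <- c(amp, p$transient_amplitude * 0.75 * gain[j])
          evk <- c(evk, TRUE); pls <- c(pls, j)
        }
      }
    }
    o <- order(frm, -amp)
    frm <- frm[o]; amp <- amp[o]; evk <- evk[o]; pls <- pls[o]
    # refractory: greedy ascending, keep first of any too-close pair
    keep <- logical(length(frm))
    last <- -p$refractory_frames
    for (k in seq_along(frm)) {
      if (frm[k] - last >= p$refractory_frames) {
        keep[k] <- TRUE
        last <- frm[k]
      }
    }
    spike_frm[[i]] <- frm[keep]; spike_amp[[i]] <- amp[keep]
    spike_evk[[i]] <- evk[keep]; spike_pls[[i]] <- pls[keep]
  }

  # calcium: AR(1) impulse response on the spike amplitudes
  calcium <- matrix(0, p$n_cells, T)
  for (i in seq_len(p$n_cells)) {
    imp <- numeric(T)
    imp[spike_frm[[i]]] <- spike_amp[[i]]
    calcium[i, ] <- as.numeric(stats::filter(imp, p$gamma,
                                             method = "recursive"))
  }

  # fluorescence video
  drift <- p$drift_amplitude_counts *
    sin(2 * pi * (seq_len(T) - 1) / (p$drift_period_s * p$frame_rate_hz))
  base <- matrix(p$bg_level * p$baseline_counts, Y, X)
  for (i in seq_len(p$n_cells)) base[pix[[i]]] <- p$baseline_counts
  M <- matrix(rep(as.numeric(base), each = T), nrow = T) + drift
  if (p$noise_sigma_counts > 0)
    M <- M + matrix(stats::rnorm(T * Y * X, 0, p$noise_sigma_counts),
                    nrow = T)
  for (i in seq_len(p$n_cells))
    M[, pix[[i]]] <- M[, pix[[i]]] + p$baseline_counts * calcium[i, ]
  M <- round(pmin(pmax(M, 0), .TIFF_MAX))
  videoArr <- array(M, dim = c(T, Y, X))

  spikes <- do.call(rbind, lapply(seq_len(p$n_cells), function(i)
    if (length(spike_frm[[i]]))
      data.frame(roi = i, frame = spike_frm[[i]],
                 amplitude = spike_amp[[i]], evoked = spike_evk[[i]],
                 pulse_index = spike_pls[[i]])
    else NULL))
  if (is.null(spikes))
    spikes <- data.frame(roi = integer(), frame = integer(),
                         amplitude = numeric(), evoked = logical(),
                         pulse_index = integer())

  rec <- fovRecording(videoArr, p$frame_rate_hz, label_mask = label,
                      stim = protocol)
  list(recording = rec, centers = centers, spikes = spikes,
       calcium = calcium, params = p,
       stimulated_truth = which(in_mask))
}

#' Simulate a multi-condition plate experiment on disk
#'
#' Writes a directory tree loadable by [loadExperiment()] (layout config,
#' plate map, per-FOV videos/masks/stimulation logs) plus ground-truth spike
#' tables. Per-FOV seeds are derived deterministically from the master seed.
#'
#' @param conditions named list: condition label -> list of [simParams()]
#'   overrides (e.g. `list(low = list(spike_rate_hz = 0.05))`).
#' @param out_dir output directory.
#' @param wells_per_condition,fovs_per_well experiment geometry.
#' @param base_params shared [simParams()] defaults.
#' @param seed master seed.
#' @return list: `root`, `plate_map` (data.frame), `truth` (spike table with
#'   `well_id`, `fov_index` columns), `params_by_condition`.
#' @export
simulatePlate <- function(conditions, out_dir, wells_per_condition = 1L,
                          fovs_per_well = 1L, base_params = simParams(),
                          seed = 1L) {
  stopifnot(length(conditions) >= 1L, !is.null(names(conditions)))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  yaml::write_yaml(list(dialect = "tiff",
                        frame_rate_hz = base_params$frame_rate_hz),
                   file.path(out_dir, "layout.yaml"))
  pm_rows <- list(); truth <- list(); params_by <- list()
  well_i <- 0L
  for (ci in seq_along(conditions)) {
    cname <- names(conditions)[ci]
    pars <- utils::modifyList(unclass(base_params),
                              conditions[[ci]] %||% list())
    for (wi in seq_len(wells_per_condition)) {
      well_i <- well_i + 1L
      well <- sprintf("%s%02d", LETTERS[(well_i - 1L) %/% 12L + 2L],
                      (well_i - 1L) %% 12L + 3L)
      dir.create(file.path(out_dir, well), showWarnings = FALSE)
      pm_rows[[well_i]] <- data.frame(well_id = well, genotype = cname,
                                      treatment = "", dose = NA_character_)
      for (fv in seq_len(fovs_per_well) - 1L) {
        pars$seed <- (seed * 7919L + well_i * 131L + fv) %% 2147483647L
        sp <- do.call(simParams, pars[setdiff(names(pars), character())])
        sim <- simulateFov(sp)
        params_by[[cname]] <- sp
        stem <- file.path(out_dir, well, sprintf("%s_f%03d", well, fv))
        .write_video_tiff(video(sim$recording), paste0(stem, ".tif"))
        .write_mask_tiff(labelMask(sim$recording), paste0(stem, "_mask.tif"))
        st <- stimProtocolOf(sim$recording)
        if (!is.null(st)) {
          utils::write.csv(data.frame(
            onset_frame = st@pulse_onset_frames,
            duration_ms = st@pulse_duration_ms,
            power_pct = st@led_power_pct,
            irradiance_mw_cm2 = st@irradiance_mw_cm2),
            paste0(stem, "_stim.csv"), row.names = FALSE)
          if (!is.null(st@stim_mask))
            .write_mask_tiff(st@stim_mask, paste0(stem, "_stimmask.tif"))
        }
        if (nrow(sim$spikes)) {
          tr <- sim$spikes
          tr$well_id <- well; tr$fov_index <- fv; tr$condition <- cname
          truth[[length(truth) + 1L]] <- tr
        }
      }
    }
  }
  pm <- do.call(rbind, pm_rows)
  yaml::write_yaml(list(wells = stats::setNames(lapply(seq_len(nrow(pm)),
    function(i) list(genotype = pm$genotype[i], treatment = pm$treatment[i])),
    pm$well_id)), file.path(out_dir, "plate_map.yaml"))
  truth <- if (length(truth)) do.call(rbind, truth) else NULL
  if (!is.null(truth))
    utils::write.csv(truth, file.path(out_dir, "truth_spikes.csv"),
                     row.names = FALSE)
  list(root = out_dir, plate_map = readPlateMap(
         file.path(out_dir, "plate_map.yaml")),
       truth = truth, params_by_condition = params_by)
}
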