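# Independent reference implementations used as oracles. These deliberately
# take the slow, exhaustive route so they share no code path with the
# package.

# exhaustive active-set solver for the OASIS quadratic program:
# min 1/2 ||c - y||^2 + lambda * sum(s), s = c_t - gamma c_{t-1} >= 0.
# Enumerates every pattern of active (s = 0) constraints, solves the
# equality-constrained least squares, and keeps the feasible solution with
# the smallest objective (unique by strict convexity).
qp_oasis_oracle <- function(y, gamma, lambda) {
  T <- length(y)
  K <- outer(seq_len(T), seq_len(T),
             function(t, tau) ifelse(t >= tau, gamma^(t - tau), 0))
  best <- NULL; bestobj <- Inf
  for (pat in 0:(2^T - 1)) {
    act <- as.logical(bitwAnd(pat, 2^(0:(T - 1))))
    free <- which(!act)
    s <- numeric(T)
    if (length(free)) {
      Kf <- K[, free, drop = FALSE]
      sol <- tryCatch(solve(crossprod(Kf), crossprod(Kf, y) - lambda),
                      error = function(e) NULL)
      if (is.null(sol)) next
      s[free] <- sol
    }
    if (any(s < -1e-9)) next
    cc <- as.numeric(K %*% s)
    obj <- 0.5 * sum((cc - y)^2) + lambda * sum(s)
    if (obj < bestobj) { bestobj <- obj; best <- cc }
  }
  best
}

# per-frame sort-and-interpolate percentile baseline (rank p/100 * (n-1),
# linear interpolation = stats::quantile type 7)
naive_baseline <- function(raw, w, p = 10) {
  T <- length(raw)
  half_lo <- w %/% 2L
  half_hi <- (w - 1L) %/% 2L
  vapply(seq_len(T), function(t) {
    win <- raw[max(1L, t - half_lo):min(T, t + half_hi)]
    stats::quantile(win, p / 100, type = 7, names = FALSE)
  }, 0)
}

# exhaustive reference peak detector: test every frame for the local-max,
# height and prominence conditions, then greedy removal by descending height
# (ties: earlier frame) for the distance constraint
brute_peaks <- function(x, h_min, p_min, d) {
  T <- length(x)
  is_cand <- function(t) {
    if (t == 1L || x[t - 1L] == x[t]) return(FALSE)  # not a plateau start
    il <- t - 1L
    while (il >= 1L && x[il] == x[t]) il <- il - 1L
    ir <- t + 1L
    while (ir <= T && x[ir] == x[t]) ir <- ir + 1L
    if (il < 1L || ir > T) return(FALSE)
    x[il] < x[t] && x[ir] < x[t]
  }
  prom <- function(t) {
    h <- x[t]
    side <- function(idx) {
      if (!length(idx)) return(h)
      m <- h
      for (i in idx) {
        if (x[i] > h) return(m)
        m <- min(m, x[i])
      }
      m
    }
    h - max(side(rev(seq_len(t - 1L))), side(seq(t + 1L, length.out = T - t)))
  }
  cand <- Filter(is_cand, seq_len(T))
  cand <- cand[x[cand] >= h_min]
  if (p_min > 0) cand <- cand[vapply(cand, prom, 0) >= p_min]
  if (length(cand) > 1L && d > 1L) {
    ord <- cand[order(-x[cand], cand)]
    kept <- integer()
    for (p in ord) if (!length(kept) || all(abs(kept - p) >= d))
      kept <- c(kept, p)
    cand <- sort(kept)
  }
  cand
}

# linear-scan evoked labeling: peak evoked iff some onset p satisfies
# p <= f <= p + w - 1; attribution to the latest qualifying pulse
scan_match <- function(frames, onsets, w) {
  t(vapply(frames, function(f) {
    q <- which(onsets <= f & f <= onsets + w - 1L)
    if (length(q)) c(TRUE, max(q)) else c(FALSE, NA)
  }, c(0, 0)))
}

# matching F1 with optional frame tolerance
f1_score <- function(tru, det, tol = 0) {
  if (!length(tru) && !length(det)) return(1)
  tp <- 0; used <- rep(FALSE, length(det))
  for (tf in tru) {
    j <- which(!used & abs(det - tf) <= tol)
    if (length(j)) { tp <- tp + 1; used[j[1L]] <- TRUE }
  }
  2 * tp / (2 * tp + sum(!used) + (length(tru) - tp))
}

# small random label-mask pair with controllable overlap structure
random_mask_pair <- function(ny = 20, nx = 20, n_obj = 3) {
  ref <- matrix(0L, ny, nx); pred <- matrix(0L, ny, nx)
  for (k in seq_len(n_obj)) {
    y0 <- sample(1:(ny - 5), 1); x0 <- sample(1:(nx - 5), 1)
    ref[y0:(y0 + 3), x0:(x0 + 3)] <- k
    dy <- sample(-2:2, 1); dx <- sample(-2:2, 1)
    yy <- pmin(pmax(y0 + dy, 1), ny - 3); xx <- pmin(pmax(x0 + dx, 1), nx - 3)
    pred[yy:(yy + 3), xx:(xx + 3)] <- k
  }
  list(pred = pred, ref = ref)
}

# standard evoked simulation used across evoked tests: 3 pulses per
# intensity step, 10 s spacing, desynchronized spontaneous background
evoked_sim_params <- function(seed) {
  onsets <- as.integer(seq(101, by = 100, length.out = 30))
  simParams(grid = c(64L, 64L), n_cells = 20, duration_s = 310,
            spike_rate_hz = 0.05, noise_sigma_counts = 20,
            evoked = list(mask_rect = c(1L, 64L, 1L, 30L),
                          pulse_onset_frames = onsets,
                          power_pct = rep(1:10 * 10, each = 3),
                          direct_drive_prob = 0.95,
                          propagated_drive_prob = 0.3),
            seed = seed)
}
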