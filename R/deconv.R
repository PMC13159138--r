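#' Estimate the noise scale of a dF/F0 trace from its high-frequency power
#'
#' The noise standard deviation sigma is estimated as the square root of the
#' mean periodogram power over a high-frequency band where calcium-transient
#' power is negligible — the PSD-based estimator conventional to AR-model
#' deconvolution. The trace is split into non-overlapping segments of length
#' `min(256, T)`, each segment is de-meaned, its periodogram `|FFT|^2 / L` is
#' taken, and the power is averaged over segments and over frequencies in
#' `freq_band` (as fractions of the sampling rate).
#'
#' @param dff numeric trace (dF/F0 units), length >= 32.
#' @param freq_band two fractions of the sampling frequency in (0, 0.5];
#'   default `c(0.25, 0.5)`.
#' @return sigma >= 0, in the units of the trace.
#' @export
estimateNoise <- function(dff, freq_band = c(0.25, 0.5)) {
  T <- length(dff)
  if (T < 32L)
    stop("trace too short for noise estimation (need >= 32 frames, got ",
         T, ")")
  if (any(!is.finite(dff))) stop("non-finite values in trace")
  if (freq_band[1] <= 0 || freq_band[2] > 0.5 ||
      freq_band[1] >= freq_band[2])
    stop("freq_band must lie within (0, 0.5] of the sampling frequency")
  L <- min(256L, T)
  nseg <- T %/% L
  k <- 0:(L - 1L)
  sel <- (k / L) >= freq_band[1] & (k / L) <= freq_band[2]
  pow <- 0
  for (s in seq_len(nseg)) {
    seg <- dff[((s - 1L) * L + 1L):(s * L)]
    seg <- seg - mean(seg)
    pow <- pow + mean(Mod(stats::fft(seg))[sel]^2 / L)
  }
  sqrt(pow / nseg)
}

#' Estimate the AR(1) coefficient of a calcium trace
#'
#' Under the AR(1) model c\[t\] = gamma c\[t-1\] + s\[t\] observed with
#' additive white noise, white noise inflates only the lag-0 autocovariance,
#' so the lag-2 / lag-1 autocovariance ratio recovers gamma free of the noise
#' term. When the lag-1 autocovariance is not distinguishable from the
#' sampling noise floor (pure noise, or a degenerate constant trace) the
#' estimate is 0, with a warning for the degenerate case.
#'
#' @param dff numeric trace, length >= 100.
#' @param sigma noise scale from [estimateNoise()]; used for the
#'   signal-variance fallback `acov(1) / (acov(0) - sigma^2)` when the lag-2
#'   estimate is unusable.
#' @return gamma in \[0, 0.99\].
#' @export
estimateAR <- function(dff, sigma = 0) {
  T <- length(dff)
  if (T < 100L)
    stop("trace too short for AR estimation (need >= 100 frames, got ",
         T, ")")
  x <- dff - mean(dff)
  v0 <- sum(x^2) / T
  if (v0 <= .Machine$double.eps) {
    warning("zero-variance trace; returning gamma = 0")
    return(0)
  }
  v1 <- sum(x[-1L] * x[-T]) / T
  v2 <- sum(x[-(1:2)] * x[-((T - 1L):T)]) / T
  # sampling noise floor for autocovariance estimates
  floor1 <- 2 * v0 / sqrt(T)
  if (v1 <= floor1) return(0)
  g <- v2 / v1
  if (!is.finite(g) || g < 0) {
    den <- v0 - sigma^2
    g <- if (den > 0.1 * v0) v1 / den else 0
  }
  min(max(g, 0), 0.99)
}

#' Non-negative AR(1) deconvolution (OASIS)
#'
#' Solves the constrained quadratic program
#' \deqn{\min_c \tfrac12 \sum_t (c_t - y_t)^2 + \lambda \sum_t s_t
#'   \quad s.t.\quad s_t = c_t - \gamma c_{t-1} \ge 0,\; s_1 = c_1 \ge 0}
#' by the pool-adjacent-violators scheme: a single forward pass that opens a
#' pool per frame and merges backwards whenever the non-negativity constraint
#' at a pool boundary is violated. Within a pool the solution decays
#' geometrically from the pool value. The sparsity penalty is absorbed by
#' shifting the data (`y - lambda (1 - gamma)`, last frame `y - lambda`).
#' The minimizer is unique (strictly convex objective).
#'
#' @param dff numeric dF/F0 trace.
#' @param gamma AR(1) coefficient in \[0, 1).
#' @param lambda sparsity penalty >= 0, or `"auto"` for the noise-constrained
#'   mode that scales lambda until the residual norm reaches
#'   `sigma * sqrt(T)`.
#' @param sigma noise scale; required for `lambda = "auto"`.
#' @return list with `denoised` (c), `spikes` (s, non-negative), `gamma`,
#'   `lambda`, `sigma`.
#' @export
oasisDeconvolve <- function(dff, gamma, lambda = 0, sigma = NA_real_) {
  y <- as.numeric(dff)
  if (any(!is.finite(y))) stop("non-finite values in trace")
  if (gamma < 0 || gamma >= 1) stop("gamma must lie in [0, 1)")
  if (identical(lambda, "auto")) {
    if (!is.finite(sigma)) stop("lambda = \"auto\" requires sigma")
    return(.oasis_auto_lambda(y, gamma, sigma))
  }
  if (lambda < 0) stop("lambda must be >= 0")
  T <- length(y)
  ytil <- y - lambda * (1 - gamma)
  ytil[T] <- y[T] - lambda

  # pools: value v, weight w, length l; pool 1 is a zero-floor sentinel
  # (v = 0, infinite weight) enforcing c >= 0 at the start of the trace
  pv <- numeric(T + 1L); pw <- numeric(T + 1L); pl <- integer(T + 1L)
  pv[1L] <- 0; pw[1L] <- Inf; pl[1L] <- 0L
  np <- 1L
  for (t in seq_len(T)) {
    np <- np + 1L
    pv[np] <- ytil[t]; pw[np] <- 1; pl[np] <- 1L
    while (np > 1L && pv[np] < gamma^pl[np - 1L] * pv[np - 1L]) {
      g <- gamma^pl[np - 1L]
      if (is.infinite(pw[np - 1L])) {
        pv[np - 1L] <- 0
      } else {
        wn <- pw[np - 1L] + g^2 * pw[np]
        pv[np - 1L] <- (pw[np - 1L] * pv[np - 1L] + g * pw[np] * pv[np]) / wn
        pw[np - 1L] <- wn
      }
      pl[np - 1L] <- pl[np - 1L] + pl[np]
      np <- np - 1L
    }
  }
  cc <- numeric(T)
  pos <- 1L
  for (i in seq_len(np)) {
    if (pl[i] == 0L) next
    k <- 0:(pl[i] - 1L)
    cc[pos + k] <- pv[i] * gamma^k
    pos <- pos + pl[i]
  }
  s <- c(cc[1L], cc[-1L] - gamma * cc[-T])
  list(denoised = cc, spikes = s, gamma = gamma, lambda = lambda,
       sigma = sigma)
}

# noise-constrained mode: bisect lambda until ||c - y|| ~ sigma * sqrt(T)
.oasis_auto_lambda <- function(y, gamma, sigma) {
  T <- length(y)
  target <- sigma * sqrt(T)
  rss <- function(lam) {
    fit <- oasisDeconvolve(y, gamma, lam)
    sqrt(sum((fit$denoised - y)^2))
  }
  if (rss(0) >= target) {
    fit <- oasisDeconvolve(y, gamma, 0)
    fit$sigma <- sigma
    return(fit)
  }
  hi <- max(abs(y), 1)
  while (rss(hi) < target && hi < 1e6) hi <- hi * 2
  lo <- 0
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (rss(mid) < target) lo <- mid else hi <- mid
  }
  fit <- oasisDeconvolve(y, gamma, hi)
  fit$sigma <- sigma
  fit
}

#' Deconvolve all traces of a field of view
#'
#' Runs [estimateNoise()], [estimateAR()] and [oasisDeconvolve()] on every
#' dF/F0 trace of a normalized [RoiTraceSet-class]. Excluded ROIs keep `NA`
#' rows. gamma can be pooled across the field of view (median of per-ROI
#' estimates) for stability on short or sparse traces.
#'
#' @param traces a normalized [RoiTraceSet-class].
#' @param gamma fixed AR(1) coefficient, or `NULL` to estimate per ROI.
#' @param lambda sparsity penalty (>= 0 or `"auto"`); default 0 — downstream
#'   peak detection does the thresholding.
#' @param pool_gamma if `TRUE` (default), replace per-ROI gamma estimates by
#'   their median across the field of view.
#' @param freq_band band for [estimateNoise()].
#' @return a [FovDeconv-class].
#' @export
deconvolveTraces <- function(traces, gamma = NULL, lambda = 0,
                             pool_gamma = TRUE, freq_band = c(0.25, 0.5)) {
  stopifnot(is(traces, "RoiTraceSet"))
  if (!nrow(traces@dff)) stop("trace set is not normalized; run normalizeTraces()")
  n <- nrow(traces@dff); T <- ncol(traces@dff)
  ok <- !is.na(traces@dff[, 1L])
  sig <- rep(NA_real_, n)
  gam <- rep(NA_real_, n)
  for (i in which(ok)) {
    sig[i] <- estimateNoise(traces@dff[i, ], freq_band)
    gam[i] <- if (is.null(gamma)) {
      if (T >= 100L) estimateAR(traces@dff[i, ], sig[i]) else 0
    } else gamma
  }
  if (is.null(gamma) && pool_gamma && any(ok))
    gam[ok] <- stats::median(gam[ok])
  den <- matrix(NA_real_, n, T)
  spk <- matrix(NA_real_, n, T)
  lam <- rep(NA_real_, n)
  for (i in which(ok)) {
    fit <- oasisDeconvolve(traces@dff[i, ], gam[i], lambda, sig[i])
    den[i, ] <- fit$denoised
    spk[i, ] <- fit$spikes
    lam[i] <- fit$lambda
  }
  gam[!ok] <- 0; sig[!ok] <- 0; lam[!ok] <- 0
  new("FovDeconv", roi_ids = traces@roi_ids, denoised = den, spikes = spk,
      gamma = gam, sigma = sig, lambda = lam,
      frame_rate_hz = traces@frame_rate_hz)
}
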