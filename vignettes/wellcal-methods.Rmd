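---
title: "Methods: from multi-well calcium videos to events, networks and evoked responses"
author: "wellcal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from multi-well calcium videos to events, networks and evoked responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wellcal)
```

# Scope and data model

`wellcal` analyses time-lapse fluorescence recordings of neuronal cultures
expressing genetically encoded calcium indicators (GCaMP6s, jRCaMP1b),
acquired at 10–20 Hz across multi-well plates. The unit of analysis is one
field of view (FOV): a `T x Y x X` video of camera counts together with an
integer label mask delineating each soma (one ROI per label). Segmentation
itself is *not* performed here — masks are an input, typically produced by a
deep-learning segmenter; the package evaluates such masks (see
"Segmentation evaluation") and consumes them.

Frame indices are 1-based everywhere, and times in seconds are
`(frame - 1) / frame_rate_hz`. This convention is fixed once and used by
every module (stimulation logs, event tables, epoch masks).

On disk, an experiment is a directory of well subdirectories
(`B07/B07_f000.tif`, ...) holding 16-bit multi-page TIFF videos with
side-car label masks, stimulation logs and stimulation masks, plus a layout
config and an optional plate map (YAML or CSV) assigning conditions
(genotype, treatment, dose) to wells. `loadExperiment()` reads this layout;
`applyPlateMap()` partitions recordings by condition, with unannotated wells
collected under `"unassigned"` so that grouping is always a partition.

# Trace extraction and dF/F0

Each ROI's raw trace is the arithmetic mean of the video over the ROI's
pixels, frame by frame — the standard statistic for somatic ROIs (medians
are more robust to segmentation bleed-through but bias amplitudes down;
sums confound size with brightness).

The baseline F0 at frame t is the 10th percentile of the raw trace within a
sliding window centred on t:

* **Window**: `window_frames` long, centred, shrinking at the recording
  edges (a trailing window would bias the first half-minute of these short
  in-vitro recordings). For even lengths the extra frame falls on the left.
  The default is 30 s worth of frames — long relative to the ~1 s indicator
  decay, so transients do not drag the percentile up, and short relative to
  slow drift.
* **Percentile rule**: linear interpolation between order statistics at
  rank `p/100 * (n - 1)` (the same rule as `quantile(type = 7)`); pinned so
  results are bit-reproducible and the test oracle is well defined.
* **Floor**: dF/F0 = (F - F0)/F0 requires F0 > 0. ROIs whose baseline falls
  below `1e-6` times the set's median intensity are excluded and reported,
  rather than aborting the FOV — a dark ROI is a segmentation artefact, not
  a reason to lose the plate.

A limitation worth knowing: a percentile baseline tracks slow drift only up
to a residual of roughly `drift slope x window/2`. With the synthetic
defaults (3% sinusoidal drift, 90 s period) that residual is ~0.025 dF/F,
an order of magnitude above the camera-noise floor of a 29-pixel soma. This
matters for threshold choice below.

# Deconvolution (OASIS)

Calcium kinetics are modelled as AR(1): `c[t] = gamma c[t-1] + s[t]` with
non-negative activity `s`. Denoising/deconvolution solves

$$\min_c \tfrac12\sum_t (c_t - y_t)^2 + \lambda \sum_t s_t,
  \qquad s_t = c_t - \gamma c_{t-1} \ge 0,$$

by a single forward pass with backtracking pool merges (the online
active-set / pool-adjacent-violators scheme). A zero-floor sentinel pool
enforces `c >= 0` at the start of the trace, which makes the pass return
the exact minimizer of the constrained quadratic program — the test suite
checks this against an exhaustive active-set enumeration on short traces.

* **gamma** defaults to a per-FOV pooled estimate (median across ROIs) of
  the lag-2/lag-1 autocovariance ratio, which is immune to additive white
  measurement noise (noise only inflates lag 0). Estimates whose lag-1
  autocovariance is inside the sampling noise floor return 0 — a trace with
  no autocorrelated signal should not be smoothed. Pooling is on by default
  because sparse 2-minute traces give unstable individual estimates.
* **sigma** is the square root of mean periodogram power over the
  0.25–0.5 x sampling-rate band (Welch-style segments of length
  `min(256, T)`, de-meaned). On quiet traces this estimates the camera
  noise; on active traces the AR(1) tail adds a small amount of high-band
  power, so sigma is mildly conservative — a desirable bias for
  thresholding.
* **lambda** defaults to 0: downstream peak detection does the
  thresholding, and an un-penalized projection preserves amplitudes. A
  noise-constrained mode (`lambda = "auto"`, residual norm driven to
  `sigma * sqrt(T)` by bisection) is available when sparse output is wanted
  directly.

AR order is fixed at 1; at 10 Hz the sub-100 ms rise of these indicators is
sub-frame, so an AR(2) rise model adds parameters without signal.

# Event detection and features

Transients are detected on the *denoised* trace as local maxima passing
three user-controlled filters: minimum height, topographic prominence
(>= `k_p x sigma`, default `k_p = 2`), and minimum spacing (higher peak
wins; exact ties keep the earlier frame; plateaus collapse to their first
frame — all tie-breaks are pinned for determinism). Height has two modes:

* `noise_multiplier` (default, `k_h = 3`): threshold `k_h x sigma` per ROI,
  adapting across a plate with heterogeneous expression;
* `global`: one absolute dF/F0 value for all ROIs — the right choice when
  the amplitude scale is known, and the mode used by the synthetic recovery
  experiments below (at a 3% drift residual, a 3-sigma threshold on a
  near-silent ROI sits *below* the residual and would admit drift-crest
  noise bumps).

Peak amplitude is the denoised dF/F0 value at the peak frame (prominence is
only a filter). Per-ROI features follow directly: event frequency
(count / duration), inter-event intervals, amplitude mean/median, cell size
(pixels, and um^2 when the pixel size is known), and the active flag
(>= 1 event). "Percent active" is the percentage of ROIs with at least one
detected event — the simplest reading consistent with per-FOV reporting.

# Network correlation

Population synchrony is summarized by pairwise Pearson correlation between
denoised dF/F0 traces of one FOV, with medians over the upper-triangle
off-diagonal entries. Zero-variance ROIs are excluded and listed.
Epoch-restricted variants use a frame mask: `buildStimFrameMask()` marks
+/-250 ms (converted to frames by ceiling, so a stimulus-adjacent frame is
never dropped) around each pulse onset; the complement gives the
non-stimulation periods. Windows are anchored on pulse *onset* (the rise
begins within the 100 ms pulse); this is configurable. Epoch correlations
require at least 10 selected frames — Pearson on fewer is noise. When a
stimulated/non-stimulated grouping is available, rows sort
stimulated-first and group medians are computed within the group blocks,
matching the block structure of sorted correlation heatmaps.

# Evoked-response analysis

* **Classification**: an ROI is stimulated when *strictly more than 10%* of
  its pixels fall inside the binary stimulation mask; masks are used
  exactly as segmented.
* **Peak-pulse matching**: a peak at frame f is evoked when
  `p <= f <= p + 4` for some pulse onset p (the onset frame counts as the
  first of the five-frame window, configurable); the preceding onset is
  found by binary search (`findInterval`), and overlapping windows
  attribute the peak to the *later* pulse — the nearest preceding cause.
* **Calibration**: LED power maps to irradiance through one of five
  least-squares forms (linear, quadratic, exponential `a e^{bx} + c`,
  power-law via log-log regression, logarithmic). The exponential is fitted
  by Levenberg-Marquardt from a profiled start; all forms recover exact
  generating curves to machine precision in the tests.
* **Irradiance-response**: evoked amplitudes group by the attributed
  pulse's irradiance (exact discrete levels; binning is available for
  continuous calibrations) and ROI class, reported as n / mean / SEM.
* **Geometry**: `stimFieldArea(d)` is just `pi (d/2)^2`; an 80 um
  iris-limited field covers ~5 x 10^3 um^2.

# Segmentation evaluation

Four metrics compare a predicted label mask against a reference:
binary-foreground Dice; Panoptic Quality
`PQ = sum(TP IoU) / (TP + FP/2 + FN/2)` at the IoU > 0.5 matching level
(provably one-to-one); SoftPQ; and mAP as the mean of the score-free
`TP/(TP+FP+FN)` form over IoU thresholds 0.50:0.05:0.95 (label masks carry
no confidences, so ranked AP is not defined). Empty-vs-empty pairs score
1.0 by convention; all conventions are tested explicitly.

SoftPQ extends PQ with partial credit: pairs are greedily matched by
descending IoU above a low threshold (default 0.05); pairs above the high
threshold (default 0.5) are full TPs, while partial pairs contribute
`sqrt(IoU/high) x IoU` to the numerator and keep unit mass in the
denominator. The published description pins only two properties — reduction
to PQ at `low = high = 0.5` (bit-exact here by construction) and a score
increase over PQ under mild under-segmentation — and both are enforced by
tests; the sublinear weight is this package's documented parameterization.

# The synthetic generator

`simulateFov()` builds recordings with known ground truth: disk somata
(radius 3 px) rejection-sampled on a jittered grid; per-cell Bernoulli
spike trains at `spike_rate_hz` with a refractory gap (8 frames) and
dead-time-compensated probability so the realized rate equals the nominal
one; an optional shared drive (a population event train thinned per cell)
for correlated activity; AR(1) calcium with `gamma = exp(-1/(1 s x rate))`
matching the deconvolution model so noiseless recovery is exact; and
fluorescence `F = B(1 + c) + drift sin + N(0, sigma)` quantized to 16-bit
camera counts, background at 30% of the soma baseline. Spikes never land on
the first or last frame, where no detector can resolve a peak.

In evoked mode a rectangular stimulation mask and pulse schedule are added;
cells are placed so no disk straddles the mask boundary (making
"stimulated" generatively unambiguous), direct drive fires inside the mask
at onset+1 with high probability and weaker propagated drive outside at
onset+2, and evoked amplitudes scale with a saturating function of
irradiance, stronger for directly driven cells — so the expected
irradiance-response ordering is true by construction.

What the generator does *not* emulate: photobleaching, neuropil and
neurite morphology, motion, astrocyte signals, shot-noise scaling with
intensity. Passing the recovery tests therefore demonstrates correctness of
the analysis chain under the stated model, not robustness to every artefact
of real recordings.

## Study designs used by the tests and acceptance script

Sizes are chosen to exercise every stage at desk scale:

* **Noiseless recovery**: 15 cells, 120 s at 10 Hz, 0.1 Hz spikes, no
  noise/drift; detection in global mode (height 0.2) recovers every spike
  frame exactly (F1 = 1).
* **SNR 5**: camera noise set so trace noise is A/5 (A = 0.5, 29-px
  somata); noise-multiplier mode (`k_h = 3, k_p = 2`, spacing 5) reaches
  F1 >= 0.9 at +/-2 frames.
* **Rate contrast**: two conditions (0.05 vs 0.15 Hz), 3 wells x 15 cells,
  150 s; the recovered group-mean frequency ratio lands within 20% of 3x.
* **Evoked**: 20 cells, 30 pulses (3 per intensity step, 10 steps) spaced
  10 s, 0.05 Hz spontaneous background. The inter-pulse gap (10 decay
  constants) and the desynchronized background matter: without them the
  non-stimulation periods contain only the synchronized decay tails of
  evoked transients and the stim-epoch vs non-stim correlation contrast
  inverts. This is a property of the science, not of the implementation —
  epoch contrasts presuppose that something uncorrelated happens between
  stimuli.

# Numerical choices and degenerate inputs

Tie-breaks (plateau starts, equal-height distance conflicts, greedy IoU
ties by ascending id) are all deterministic. Degenerate inputs have defined
behaviour: empty event tables produce zero frequencies and `active =
FALSE`; empty ROI collections make percent-active `NA` with a message;
constant traces give gamma 0 with a warning; correlation with fewer than
two usable ROIs is reported as missing rather than fabricated; empty mask
pairs score 1.0. The generator is bit-reproducible: identical parameters
and seed give identical arrays, and plate seeds derive deterministically
from the master seed.
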