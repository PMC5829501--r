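---
title: "Quantifying PCM disassembly: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying PCM disassembly: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcmhalo)
```

## The measurement problem

In the one-cell *C. elegans* embryo, pericentriolar material (PCM) around
each of the two centrioles grows through mitosis, peaks around anaphase
(roughly 275 s after nuclear envelope breakdown, NEBD), and is then
dismantled within minutes — partly dissolving in place, partly fragmenting
as cortical pulling forces tear at it. The observable is a time-lapse movie
of a GFP-tagged scaffold protein: two bright foci on a fluorescent
cytoplasmic background. The quantity of interest is each centrosome's
*integrated* fluorescence above local background — a proxy for PCM mass —
tracked over time, and the kinetic summaries derived from it: when
disassembly starts, how fast it proceeds, and how much material persists
into the next cell cycle under different genetic perturbations.

Two properties of the data shape the method. First, the cytoplasmic
background varies between embryos and drifts with depth, so background must
be estimated *locally*, next to the centrosome, not globally. Second, the
PCM is not a point source: it is an extended, irregular object whose area
changes several-fold, so a fixed-size measurement aperture would conflate
area and intensity. The annulus method addresses both: background statistics
come from a band-shaped ring just outside the PCM, and the measurement
region adapts per frame as the connected set of pixels above an adaptive
threshold.

## The quantification chain

For a projected, NEBD-cropped, per-centrosome movie, `quantify_movie()`
performs:

1. **Seed detection** (`detect_seed`). The first frame is blurred with a
   Gaussian of `blur_sigma = 1` px and the maximum-intensity pixel taken as
   the centrosome centre. The blur exists only to keep a single hot pixel
   from hijacking the argmax; all statistics and masses are computed on the
   *unblurred* frame.
2. **Background** (`estimate_background`). Pixels whose centre lies strictly
   outside the inner circle (`inner_radius = 7` px, chosen to encompass the
   largest extent of PCM signal) and inside or on the outer circle
   (`outer_radius = 10` px) form the annulus; `mean_bg` and `stdev_bg`
   (population, ddof = 0) are computed over it. An annulus clipped by the
   image border is flagged; an empty one is an error.
3. **Threshold** (`compute_threshold`). `mean_bg + k_sigma * stdev_bg` with
   `k_sigma = 3`, computed **once on the first frame** and held fixed for
   the whole movie. Re-estimating per frame would make late, dim frames
   self-referential (the threshold would chase the disappearing signal);
   fixing it anchors all frames to a common baseline.
4. **Segmentation** (`segment_roi`). The ROI is the 8-connected component of
   pixels strictly above the threshold that contains the seed — not all
   suprathreshold pixels, so unrelated debris elsewhere in the crop cannot
   inflate the mass. A sub-threshold seed yields an empty, flagged ROI and
   mass 0: the centrosome is "no longer detectable", which is a data point,
   not an error.
5. **Mass** (`integrated_mass`). `(mean_ROI − threshold) · area_ROI`, which
   is identically `Σ_ROI (pixel − threshold)`. Subtracting the threshold
   (rather than `mean_bg`) under every ROI pixel makes the measure robust to
   the exact ROI boundary: pixels near the cut contribute almost nothing.
6. **Tracking.** The posterior centrosome moves towards the cortex, so by
   default the seed is re-detected each frame within a
   `(2·search_radius+1)`-px window (`search_radius = 10`) around the
   previous seed. This is configurable (`track_seed_per_frame = FALSE`
   reproduces a strictly static first-frame seed).

**Merged mode.** When the two centrosomes sit too close to resolve (the
double-depletion phenotype with a collapsed spindle), the pair is quantified
as one object with bigger annulus radii and every integrated mass divided by
two. The bigger radii default to twice the singles (14/20 px) — the original
macro's value is not recorded anywhere, so the factor is configurable; two
unresolvable foci of combined extent ~2× a single one make 2× a natural
default.

### Numerical conventions

* Coordinates are 1-based `(row = y, col = x)` matrix indices, the native R
  convention; crops are inclusive index ranges. Hemisphere split at boundary
  `b` keeps columns `1..b` (anterior) and `b+1..end` (posterior), a
  partition of the frame; each crop carries its origin so coordinates map
  back.
* The annulus membership test is strict inner / inclusive outer
  (`inner < d <= outer`) on pixel centres; the exact pixel set is pinned by
  an exhaustive per-pixel loop oracle in the test suite.
* Threshold comparison is strict (`pixel > threshold`), so an exactly
  uniform frame — whose standard deviation is 0 and whose threshold
  therefore equals its value — yields zero mass rather than segmenting the
  entire image.
* Seed argmax ties break towards the smallest y, then smallest x; an
  all-constant frame returns a flagged low-confidence seed instead of
  failing.
* "Frames after NEBD" includes the NEBD frame itself (t = 0 exists), so
  NEBD-aligned ensembles share an anchor sample.
* The +3σ threshold controls segmentation-stage false positives: with the
  chain run at a given centre on an i.i.d.-background frame, a nonzero mass
  requires that pixel to exceed mean + 3σ (~0.1% per trial). Note this
  guarantee is about the chain below seed detection: the global argmax of a
  blurred pure-noise frame is itself an extreme-value statistic and exceeds
  +3σ far more often, which is why seeds on late empty frames are only
  searched near the last known position.

## Kinetics

`normalize_curve()` divides each frame's mass by the stack maximum
(normalization is per centrosome; each curve's own peak defines 1).

**Onset** (`detect_onset`) anchors the anaphase peak: the normalized curve
is smoothed with a centred moving average (window `2·smooth_window+1`,
default 5 samples, truncated at the edges), the global maximum located (ties
earliest), and the estimate refined to the raw-curve maximum within the
smoothing half-window around that point. The refinement matters: on an
asymmetric peak (slow rise, fast decay) a plain smoothed argmax lands
systematically one to two samples early, because the window ahead of the
peak averages in the steep decay. Smoothing provides noise rejection;
refinement removes the bias.

**Rate** (`disassembly_rate`) is the least-squares slope of normalized mass
versus time from the raw-curve maximum at/after the onset anchor down to the
first sample below `fit_fraction` (default 0.5) of the starting value —
peak to half-maximum. Starting at the raw peak keeps pre-peak rising samples
out of the fit; including them penalises fast decays (short windows) much
more than slow ones and distorts percent-reduction comparisons by over ten
points at the effect sizes studied here. For a pure exponential the window
scales as `1/k`, so the fitted linear slope scales as `k` and ratios of
slopes estimate ratios of decay constants. A flat post-onset curve never
crosses the fraction; the window then runs to the last sample and the rate
is 0. Fewer than three samples in the window is an explicit error naming
the window. `method = "exponential"` instead fits `log(norm_mass)` over the
same window, returning minus the decay constant (1/s).

**Reduction** (`rate_reduction`) is `100·(1 − |treated|/|reference|)`.

**Persistence** (`persistence_fraction`) is the median normalized mass over
the trailing `eval_window_s` (default 60 s) of the curve — a median so that
single-frame noise or a transient tracking excursion cannot move it.

**Alignment** (`align_curves`) shifts each curve so its anchor (NEBD or
detected onset) sits at t = 0 and reports the pointwise ensemble mean with a
normal-approximation band `mean ± 1.96·SE` wherever at least two curves
contribute. The sample sizes here are small ensembles of continuous
measurements; a t-quantile band would differ only marginally and the normal
approximation is the conventional presentation for these overlays.

## Ratiometric immunofluorescence

For fixed two-channel images (modification-specific antibody in channel A,
total-scaffold antibody in channel B), `measure_ratio()` segments the ROI on
channel B only and integrates *both* channels over that pixel set, each
above its own annulus threshold. Using one shared ROI controls for PCM size:
a ratio of integrated signals over the same region is insensitive to how
much PCM there is, and multiplying both channels by any constant (exposure,
illumination) leaves it unchanged. Ratios are normalized to the mean
interphase ratio (`normalize_to_interphase()`, making the interphase group
mean exactly 1) and stages are compared with Welch's unequal-variance
unpaired t-test (`compare_stages()`); Welch is the safer default when group
sizes and variances differ across stages, and the choice is recorded in the
output. Degenerate zero-variance comparisons return p = 1 (identical) or
p = 0 (constant but different), flagged.

One bias is worth knowing: because each channel subtracts its own threshold
pedestal over the shared ROI, a channel with k-fold more signal loses a
slightly smaller *fraction* of it to the pedestal, so large ratios are
overestimated by a few percent at typical noise levels. The noiseless
recovery tests bound this at <2%; at the default noise level the staged
profile's ordering and approximate values survive intact.

## What the simulator emulates — and what it does not

`render_movie()` produces the statistical structure the quantifier assumes:

* two isotropic Gaussian foci (`sigma_psf = 2` px) whose total
  above-background counts equal the analytic `mass_profile()` exactly
  (pixel values are integrals of the Gaussian over each pixel, so painted-in
  mass is conserved to <0.5% truncation);
* an ellipsoidal embryo of uniform cytoplasmic autofluorescence
  (`background_level = 200` counts) on a camera with offset 100 counts,
  Poisson photon noise (`photon_scale = 1` count/photon) and Gaussian read
  noise (3 counts) — a standard CCD model; the source study reports no
  acquisition noise statistics, so these are stated defaults, not inferred
  values;
* linear cortex-directed drift of each centrosome along the long axis;
* optionally, `n_z` z-slices with a Gaussian axial profile whose SUM
  projection reproduces the 2D render, to exercise the ingest path.

The kinetic profile is a logistic rise (rate `k_grow = 0.015`/s, midpoint
200 s post-NEBD) rescaled to reach `m_peak` exactly at onset
(`t_onset_s = 275` s), then exponential decay to a residual plateau
`f_residual`. The midpoint choice makes the curve still rise steeply into
the peak — disassembly onset is the moment removal outpaces growth, not a
saturation — which matches the observed rapid anaphase expansion followed
by abrupt disintegration. With a saturated logistic the peak would be
flat over many frames and "onset" would be ill-defined even in principle.

Preset kinetics encode the study's effect sizes as ground truth: wild-type
decay constants 0.018/s (anterior) and 0.024/s (posterior; pulling forces
are stronger on the posterior side), phosphatase depletion scaling them by
0.46/0.35 with a small residual (0.10), force depletion scaling only the
posterior by 0.73, and the double depletion scaling by 0.41/0.28 with
`f_residual = 0.25` and merged, motionless centrosomes. Peak mass is 1e5
counts — a bright SUM-projected GFP signal; peak spot amplitude ≈ 4,000
counts against a background noise σ ≈ 14.5, i.e. SNR in the hundreds, with
the early post-NEBD frames (~6% of peak mass) still comfortably detectable.

Not modelled, deliberately: PCM fragmentation geometry and packet shedding,
microtubule asters, spindle oscillations (drift is linear), photobleaching,
multi-cell embryos, and any spatial structure in the background. Passing
tests therefore demonstrate that the *pipeline arithmetic and estimators*
are correct and well-calibrated on data obeying the stated model — not that
the model captures every feature of real embryos. In particular, real PCM
at anaphase is an expanding, tearing network, so real integrated-intensity
curves are noisier around the peak than the simulator's, and rate estimates
on real data carry additional variance the recovery tests do not measure.

## Test and simulation sizes

The property suite checks every arithmetic step (annulus statistics,
threshold, seed-connected ROI, integrated mass) against exhaustive per-pixel
loop implementations on 200+ random frames up to 64×64 px, and the full
pipeline on ensembles of 20 simulated embryos per condition (100×180 px, 90
frames at 10 s — 900 s of movie, enough for a 275 s peak plus six decay time
constants of the slowest preset). Recovery checks at these sizes: mean
percent rate reduction within ±10 points of the programmed k-ratio, mean
persistence within ±0.05 of `f_residual`, onsets within ±2 frames of truth
in ≥90% of replicates, merged-mode masses within 15% of single-spot truth,
and the staged ratio profile recovered in order at the study's group sizes
(19/48/17/33). `scripts/acceptance.R` re-runs the same ensembles end to end
and reports the summary numbers as JSON.

## Known limitations

* The threshold pedestal makes integrated mass a *biased* estimator at low
  signal: relative underestimation grows as the spot dims (the plateau of a
  double-depletion curve is measured a little below its true fraction).
  Normalized curves inherit a mild distortion from the same effect.
* Onset is only defined to the frame grid; with 10 s sampling all onset
  statements carry ±1 frame granularity.
* The hemisphere split is a fixed boundary; an embryo whose centrosomes
  cross the midline would need a manual boundary (or merged mode).
* Empty-ROI frames keep mass 0 rather than missing; downstream medians are
  robust to this, but means over many empty frames are floored at 0.
* No sub-pixel centroiding, no registration/drift correction of the stage,
  no photobleaching correction.
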