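---
title: "Methods: quantitative time-lapse analysis of coral tissue response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative time-lapse analysis of coral tissue response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coraldyn)
```

## The problem

When a coral colony is stressed, its tissue pales (loss of symbiotic algae),
detaches, and is eventually overgrown by macroalgae. Start/end-point
photography misses the dynamics of this process. With a fixed camera taking
a frame every few minutes over weeks to months, three quantitative analyses
become possible, and this package implements all three plus the simulation
machinery needed to test them:

1. **Dominant-color staging.** Per frame, the colony ROI's pixels are
   clustered in RGB space (k-means, k = 3) into dark/medium/light shades;
   the evolution of their percentage shares is segmented into stages.
2. **Polyp morphology tracking.** Per polyp crop, the Pearson correlation
   $r_t$ between the green channel of frame $t$ and the reference frame
   measures morphological similarity; a sharp sustained drop marks the
   "drastic morphology change" (polyp death).
3. **Recurrence analysis.** The scalar series $r_t$ is turned into a
   recurrence plot $R_{ij} = \Theta(\varepsilon - |r_i - r_j|)$ and
   summarized by the six standard RQA measures (RR, DET, LMAX, ENT, LAM,
   TT), compared before vs after the change point.

## Models and conventions

### Recurrence quantification

States are the scalar correlation values themselves (no delay embedding; an
embedding would be a departure from the defining formula, so it is not even
exposed). The threshold is $\varepsilon = 0.02$ in $r$ units by default.
Conventions the literature leaves open, fixed here:

* **Boundary rule**: distance exactly $\varepsilon$ *is* recurrent
  ($\Theta(0) = 1$), the common convention; needed for bit-exact tests.
* **Theiler window 1** for diagonal measures (DET, ENT, LMAX): the main
  diagonal is excluded, both triangles are counted. RR keeps the full
  double sum (its defining formula sums all $i, j$), and vertical lines
  include the main diagonal.
* $l_{\min} = v_{\min} = 2$; the DET and LAM denominators sum from length 1.
* ENT uses the natural logarithm over $p(l)$ for $l \ge l_{\min}$.
* When no vertical line reaches $v_{\min}$, TT is reported as 0 with a
  `tt_defined = FALSE` flag rather than NA, so downstream summaries stay
  numeric.

One consequence worth knowing: DET cannot reach 1 even for the all-ones
matrix, because the two corner diagonals always have length 1 — for an
$N \times N$ all-ones plot, $\mathrm{DET} = (N(N-1)-2)/(N(N-1))$. The test
suite asserts this closed form as the $\varepsilon \to \infty$ limit.

Windowed before/after statistics (`segmented_rqa()`) use sliding windows of
one day of frames by default with stride = half window; the mean and
standard deviation across windows provide the error bars. The windowing
scheme behind such published summaries is typically unstated; ours is a
convention and is recorded in every output.

### Pearson correlation and the intensity plot

$r_t$ is computed exactly from the centered cross-product formula over the
ROI pixels of one channel (green by default: it is the most stable channel
across the three shades, so it tracks morphology rather than lighting).
Each frame's ROI intensities are z-scored first. This leaves $r$
mathematically unchanged (Pearson is affine-invariant) but standardizes the
joint intensity histograms and documents the intent of suppressing the slow
brightness increase that falling water levels cause; the normalization tag
is stored in the result. Zero variance in either frame raises an error
rather than propagating NaN. Joint histograms use 64 equal-width bins on
[0, 255] (bin count unstated in the source analyses; 64 is a round default
that keeps 8-bit quantization visible).

The change point is the index maximizing (mean of $r$ over the window
before) − (mean over the window after), window defaulting to one day of
frames. A visual judgement in the original workflow, replaced here by the
simplest reproducible surrogate; a drop below `min_magnitude` (default 0)
sets a `no_change` flag.

### Dominant colors and staging

k-means (Euclidean, k = 3) runs per frame on the unique-color table with
pixel counts as weights — identical to clustering the raw pixels, but
faster and, because the table is sorted before seeded k-means++ sampling,
invariant to pixel order. Ten restarts are kept. k is fixed at 3 for
physical interpretability (dark/medium/light), not chosen by any cost
criterion.

Cluster identity across frames is by **luminance rank**
($0.2126R + 0.7152G + 0.0722B$, ties by G, R, B), not percentage rank and
not centroid tracking: percentage ranks swap between stages (the medium
shade overtakes the dark one mid-process), while the centroids stay in a
narrow region of RGB space, so the luminance ordering is stable and
stateless. Percentage rank is kept as metadata.

Smoothing is a centered moving average with edge truncation, renormalized
to sum to 100 (the published figures say "after smoothing" without details;
window defaults to about one day of analyzed frames). Extraction may run on
a decimated series (default every 30th frame, i.e. hourly at 2-minute
cadence) — downsampling is explicitly viable for these statistics and the
factor is logged.

Stage boundaries: the published analysis "detected four inflection points"
visually. The reproducible surrogate here is segmented least squares —
independent linear fits per segment, joint SSE over the three shade series,
solved exactly by dynamic programming. The spec'd alternative of a
*continuous* piecewise-linear fit does not decompose over segments (no
Bellman recursion exists with a continuity constraint), and its own
exhaustive-search equivalence property only holds for the separable cost,
so the discontinuous segmented model is used. Because segments are fit
independently, a steep smoothed transition ramp could attract *two*
breakpoints; `min_days` (default 6; every documented stage lasts at least
8 days) enforces a minimum stage duration so each transition receives one.
A `no_strong_inflections` flag is set when five segments improve the SSE of
a single linear fit by less than 25 %.

The ternary trajectory is the per-frame (dark, medium, light) composition
on the 2-simplex; the **convergence center** is the mean composition over
the terminal stage. How the original "approximate center of the ring" was
computed is unstated; terminal-stage mean is this package's convention and
is not claimed to be equivalent.

### White-balance correction

The upstream method in the source workflow is a learned kNN color mapping
trained on 65,000 image pairs; reproducing it requires that dataset.
Because the pipeline contract is simply "neutralize the blue cast", the
module substitutes classical statistics-based estimators behind a pluggable
interface: gray world (default), white patch (99th percentile to 255), and
fixed gains for exact reproducibility. Gray world inverts a multiplicative
cast exactly *in expectation and up to one global brightness factor* — it
rescales each channel to the mean of channel means. Gains are refit per
frame by default (robust to brightness drift); fit-once is available and
the choice is recorded in output metadata.

## The synthetic world

`generate_series()` renders the stated world every test runs against:

* **Colony composition.** Inside the colony ROI each pixel takes one of
  three base colors (dark/medium/light coral-browns ~(60,45,35),
  (130,105,80), (205,190,170)). The per-frame allocation is *exact*:
  largest-remainder rounding of the scheduled fractions, assigned along a
  fixed seeded pixel permutation. Exactness is the point — it makes
  expected shares testable to one pixel, and the fixed permutation keeps
  frames temporally coherent (a constant schedule yields bit-identical
  frames). An iid multinomial draw would bury the 1-pixel tolerance under
  sampling noise.
* **Stage schedule.** Five stages with boundaries at days 9, 46, 56, 70 by
  default and mixtures (0.52,0.34,0.14) → (0.37,0.33,0.30) →
  (0.33,0.43,0.24) → (0.41,0.39,0.20) → (0.39,0.40,0.21): a
  dark-dominated healthy stage; paling with the light share peaking near
  30 % at the second boundary; a medium-dominated pale stage; re-darkening
  under algal overgrowth; a stable terminal composition near
  (39, 40, 21) %. Mixtures ramp linearly over `transition_width` days
  (default 2) at each boundary.
* **Polyps.** Disks with a radial brightness profile. Before `change_day`
  the radius and brightness oscillate sinusoidally (quasi-periodic regime).
  At the change day the tissue collapses onto a skeleton-colored random
  texture (sd 45), which then drifts as a reflected Gaussian random walk
  with an erratic per-frame component on top — detached tissue swinging in
  the flow. The erratic component matters: a *slow* walk alone produces
  filled recurrence blocks and high DET, the opposite of the disrupted
  plots seen after polyp death.
* **Illumination.** A per-channel multiplicative blue cast (default gains
  0.85/1.0/1.35), a slow linear brightness drift (default +10 % across the
  series), and additive Gaussian sensor noise, then clipping to [0, 255].
  The cast is exactly the model gray world inverts, by construction.

Ground truth records the scheduled fractions, stage labels, per-polyp
change days, base colors, and two masks: the full colony ROI and
`color_mask`, the colony minus the polyp boxes. Compositional analysis uses
`color_mask` — the polyp crops are analyzed by the correlation stage, and
a post-change polyp wandering through RGB space would otherwise contaminate
the colony composition with dynamics the schedule does not describe.

Polyp analysis crops are **inscribed in the disk** (side ≈ 0.9 × radius)
rather than bounding it. A bounding crop is half static colony background,
whose perfect self-correlation sets a floor of $r \approx 0.5$ that masks
both regimes; an all-tissue crop starts at $r \approx 0.95$ and collapses
toward 0 at the change day, which is the published phenomenology.

What the generator does **not** emulate: real coral texture and its spatial
correlation, macroalgae appearance, optical refraction, registration error,
lighting flicker, dropped frames. A green test therefore establishes that
the *algorithms* recover a known forward model's parameters — not that the
forward model is photorealistic.

### Noise levels and the ε = 0.02 threshold

Sensor noise propagates into the correlation series with standard deviation
roughly $(1 - r^2)/\sqrt{N_{\text{pix}}}$. With desk-scale 13×13 crops and
`noise_sd = 4`, that floor is ≈ 0.02 — exactly the recurrence threshold —
and recurrence structure of either regime is erased. The dynamics-contrast
acceptance scene therefore uses `noise_sd = 2`, the level at which a
quasi-periodic regime is expressible at all under the fixed ε; the
parameter-recovery scene keeps the default `noise_sd = 4` (boundary and
change-day detection do not depend on sub-ε recurrence structure). At the
original study's scale (megapixel frames, large crops) the floor is orders
of magnitude below ε, so this is purely a desk-scale consideration.

## Pipeline and reproducibility

`run_pipeline()` executes simulate/load → correct → colors → correlate →
rqa and writes CSV/JSON outputs plus a self-contained JSON report embedding
the resolved config and a config hash; a rerun with the same config and
seed reproduces the report payload byte-for-byte, and an existing report
with a matching hash is reused (`resume = FALSE` forces recomputation;
stage-level resumption was deliberately not implemented — the report-level
hash check covers the realistic use case at far lower complexity). A single
global seed derives per-stage seeds by stage-name hashing. Configs are JSON
(`jsonlite`) rather than YAML — no YAML parser is guaranteed in the target
environment, and the nesting is identical.

On-disk image format is lossless NetPBM (PPM, P6/P3) with a
`filename,day` manifest: PPM round-trips 8-bit RGB bit-exactly and needs no
external codec, which the deployment environment cannot guarantee for
PNG/TIFF. Time gaps larger than three times the median spacing produce a
warning; dynamics operations use index spacing throughout (the recurrence
formulation is index-based).

## Worked example

```{r example, eval = FALSE}
library(coraldyn)

# a 20-day scene with one polyp dying at day 10
p <- polyp_config(center = c(48, 48), radius = 14, oscillation_period = 48,
                  oscillation_amplitude = 0.3, change_day = 10,
                  post_change_drift = 4)
sc <- scene_config(96, 96, n_frames = 241, minutes_per_frame = 120,
                   schedule = stage_schedule(c(4, 8, 12, 16),
                                             default_shade_fractions(), 1),
                   noise_sd = 2, polyps = list(p), seed = 1)
cfg <- pipeline_config(simulate = sc,
                       colors = list(decimate = 2L, smooth_window = 3L),
                       out_dir = tempfile("run_"), seed = 1)
rep <- run_pipeline(cfg, verbose = TRUE)
rep$stage_boundaries_days
rep$polyps$polyp_1$change_day
```

## Known limitations

* The stage-boundary detector assumes roughly piecewise-linear shade
  dynamics with stages of at least `min_days`; fast oscillatory composition
  changes would be mis-segmented.
* Polyp ROIs are fixed in pixel coordinates (no tracking/registration),
  matching the fixed-camera design; camera motion violates the model.
* Gray world assumes the scene is neutral on average; a strongly colored
  scene biases the correction (white patch or fixed gains are the fallback).
* TT = 0 reporting (with flag) for segments without laminar structure is a
  convention; comparisons across segments should check `tt_defined`.
* The real-data benchmark (stage days, day-46 light-share peak, terminal
  ternary center) requires the original 105-day image series and is out of
  desk-scale scope; nothing in this package asserts those numbers.
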