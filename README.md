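# coraldyn

Quantitative analysis of high-frequency coral time-lapse imagery.

When a coral colony is stressed, its tissue pales, detaches, and is
eventually overgrown by macroalgae. A fixed camera taking a frame every few
minutes turns that process into data, and `coraldyn` provides the full
analysis chain for it — aimed at coral biologists and biophysicists running
long time-lapse experiments, and at anyone who needs a tested recurrence
quantification implementation for scalar similarity series.

## What it computes

**Dominant-color staging.** Per frame, the colony ROI's pixels are clustered
in RGB space (k-means, k = 3, Euclidean distance) into dark/medium/light
shades with percentage shares. The smoothed share series is segmented into
five stages by segmented least squares (exact dynamic program), and the
composition is traced on the ternary simplex with a terminal-stage
convergence center.

**Polyp morphology tracking.** Per polyp crop, the Pearson correlation
between the green channel of frame *t* and the reference frame,

    r_t = Σ (I^r − Ī^r)(I_t − Ī_t) / sqrt( Σ(I^r − Ī^r)² · Σ(I_t − Ī_t)² ),

summed over ROI pixels, measures morphological similarity; a two-window scan
detects the drastic morphology change (the sharp sustained drop in r_t).
Joint intensity histograms (reference vs current intensity) visualize the
same information.

**Recurrence analysis.** The series r_t becomes a recurrence plot
R_ij = Θ(ε − |r_i − r_j|) with ε = 0.02, summarized by the six standard RQA
measures — recurrence rate (RR), determinism (DET), longest diagonal line
(LMAX), diagonal-length entropy (ENT), laminarity (LAM), trapping time
(TT) — whole-series and on sliding windows before vs after the change point
(mean ± sd per segment).

**Synthetic ground truth.** A forward model (`generate_series()`) renders a
coral scene with an exact staged shade mixture, oscillating-then-collapsing
polyp disks, blue illumination cast, brightness drift, and sensor noise, so
every stage of the pipeline is testable without a multi-month recording.
Frames are stored as lossless PPM with a `filename,day` manifest.

## Worked example

A 20-day synthetic scene (96×96 px, one frame per 2 h) with stage boundaries
planted at days 4, 8, 12, 16 and one polyp dying at day 10:

```r
library(coraldyn)

p  <- polyp_config(center = c(48, 48), radius = 14, oscillation_period = 48,
                   oscillation_amplitude = 0.3, change_day = 10,
                   post_change_drift = 4)
sc <- scene_config(96, 96, n_frames = 241, minutes_per_frame = 120,
                   schedule = stage_schedule(c(4, 8, 12, 16),
                                             default_shade_fractions(), 1),
                   noise_sd = 2, polyps = list(p), seed = 1)
cfg <- pipeline_config(simulate = sc,
                       colors = list(decimate = 2L, smooth_window = 3L),
                       out_dir = tempfile("run_"), seed = 1)
rep <- run_pipeline(cfg)
```

Output (printed by the code above on this machine):

```
boundaries: 4.08 8.08 11.92 15.75        # planted: 4, 8, 12, 16
change day: 10.17                        # planted: 10
DET before/after: 0.916 0.669            # quasi-periodic vs nonstationary
center: 40.14 39.39 20.46                # terminal stage mean (dark/medium/light %)
```

The four recovered stage boundaries sit within 0.25 days of the planted
schedule, the detected morphology change is within 0.17 days of the planted
death day, and determinism drops after the change — the quasi-periodic →
nonstationary transition. The classic closed-form check:

```r
rqa(matrix(1L, 4, 4))
#> RR 1.0000  DET 0.8333  LMAX 3  ENT 0.6931  LAM 1.0000  TT 4.0000
```

## Command line

```sh
coral-dyn simulate  --config scene.json --out frames --seed 1
coral-dyn colors    --in frames --roi colony.json --smooth-window 25 --out colors.csv
coral-dyn correlate --in frames --roi polypA.json --out r.csv
coral-dyn rqa       --series r.csv --epsilon 0.02 --out rqa.json
coral-dyn run       --config pipeline.json --out results --seed 1
```

(`coral-dyn` is installed under `exec/` in the package library; equivalently
`Rscript -e 'coraldyn::coraldyn_main()' -- ...` or call `run_pipeline()`
from R.)

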