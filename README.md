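# MTdyn

Automated detection, tracking and dynamic-instability analysis of
microtubules in TIRF time-lapse movies.

In the standard in vitro reconstitution assay, stabilized microtubule
seeds are immobilized on a coverglass and dynamic microtubules grow from
the seed ends in a second fluorescence channel. Extracting the four
parameters of dynamic instability — growth velocity *v<sub>g</sub>*
(nm/s), shrinkage velocity *v<sub>s</sub>* (nm/s), catastrophe frequency
*f<sub>c</sub>* (1/s) and rescue frequency *f<sub>r</sub>* (1/s) — is
usually done by drawing and reading kymographs by hand. MTdyn automates
the whole chain for experimentalists running such assays:

1. **Seed detection** — maximally stable extremal regions (MSER) on the
   image component tree segment the seeds; each region's ellipse major
   axis (slope `m = (r − p + dr)/(2q)` from the second moments
   `p, q, r`, `dr = sqrt(p² + 4q² − 2pr + r²)`) initializes a
   sum-of-Gaussians (SoG) line model
   `F_i = A (G_start,i + Σ_j G_j,i + G_end,i) + Bg`
   fitted by Levenberg–Marquardt with analytic derivatives; both seed
   ends are then refined to subpixel precision by an iterative
   Gaussian-mask fit.
2. **Tracking** — per frame, each microtubule is re-detected by MSER,
   initialized from its fixed seed end and the projected growth
   direction, and fitted with the SoG model along a third-order
   polynomial path `y = I x³ + b x² + m x + c` (bending and crossing
   filaments); implausible steps (tip direction change > 20°, coefficient
   jumps) become gaps, collisions are resolved by proximity, and the
   contour length from seed end to refined tip is reported per frame.
3. **Analysis** — each length-versus-time track is segmented into growth
   and shrinkage events by iterative RANSAC (near-linear growth model,
   fast-decline shrinkage model, tolerance ε); `v_g`/`v_s` are the mean
   event slopes, `f_c`/`f_r` are events over time, transitions are
   classified into rescues and total catastrophes against the seed
   baseline, and the faster end is labeled plus.

A calibrated simulator (Gaussian-chain filament rendering at PSF width,
Poisson noise at a target SNR, two-state telegraph length dynamics)
generates ground-truthed images and movies; the whole validation suite
runs on it. See the vignette `vignettes/microtubule-dynamics.Rmd` for the
models, parameter meanings, defaults and design decisions.

## Worked example

Simulate a movie of two dynamic microtubules at SNR 8, run the full
pipeline, and read off the pooled dynamics:

```r
library(MTdyn)

cfg_sim <- sim_config(width_px = 256, height_px = 256, pixel_size_nm = 156,
                      psf_fwhm_nm = 199, target_snr = 8, rng_seed = 42)
mov <- simulate_movie(cfg_sim, n_frames = 150, frame_interval = 2,
                      dynamics = list(vg = 30, vs = 100, fc = 0.015,
                                      fr = 0.03, l0 = 800),
                      n_filaments = 2)

res <- run_pipeline(mov$seed_image, mov$frames,
                    pipeline_config(pixel_size_nm = 156,
                                    frame_interval_s = 2),
                    out_dir = "results")
#> detected 2 seeds
#> tracked 2 track(s), 159 points
#> pooled: vg = 25.96 nm/s, vs = 100.58 nm/s, fc = 0.04348 1/s, fr = 0.05 1/s
```

The pooled velocities recover the simulated values well (shrinkage
100.6 nm/s against a simulated 100; growth 26.0 against 30, pulled down
by one short post-catastrophe event out of the four this movie
contains). The frequencies rest on just two observed catastrophes and
two rescues in a five-minute demo movie, so their uncertainty is on the
order of the values themselves — frequencies should always be pooled
over many microtubules (the validation suite recovers the simulated
rates within sampling error from 100 tracks). `results/` now holds
`seeds.csv` (one row per
seed with subpixel endpoints), `tracks.csv` (per frame and track: tip
position and contour length in nm), `events.csv` (growth/shrink segments
with slopes) and `summary.json` (the pooled numbers above). Each stage is
also callable on its own (`detect_seeds()`, `track_movie()`,
`analyze_track()`), and `inst/scripts/mt` exposes the same stages as a
command line (`mt simulate | detect-seeds | track | analyze | run`).

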