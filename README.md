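# smkymo

Single-molecule kymograph analysis of plasma-membrane protein dynamics from
VA-TIRFM time-lapse movies, for cell biologists quantifying how long
membrane proteins reside at the cell surface — e.g. receptor internalisation
under a treatment versus control — and how strongly they cluster or
colocalize with a second labeled protein.

## The method

A kymograph is a `T × L` space–time image: intensity sampled at `L`
unit-spaced points along a scan line in each of `T` frames. A
membrane-resident particle is a horizontal streak; its dwell time is

```
dwell = (end_frame − start_frame + 1) × Δt
```

with `Δt` the frame interval (inclusive frame count: one visible frame means
at least one exposure of residence). Raw streak reading fails in two known
ways, and `smkymo` handles both explicitly:

- **Censoring.** Streaks touching frame 0 or frame T−1 ("overlength"
  traces) have unknown duration. They are flagged `censored_left` /
  `censored_right`, contribute no dwell value, and their fraction is
  reported. Stable proteins whose residence far exceeds the ~30 s recording
  window are thereby reported as unmeasurable rather than given a bogus
  dwell.
- **Merged-trace rejection.** Every segment is cross-validated against
  2D+t trajectories built independently by Laplacian-of-Gaussian spot
  detection and nearest-neighbour linking. Exactly one supporting
  trajectory whose endpoints agree within ±2 frames → `validated`; two or
  more distinct supporters → `rejected(merged)` (two particles fused into
  one streak); none → `rejected(unsupported)`. This automates, and makes
  reproducible, the manual practice of rotating the 2D+t volume in a 3D
  viewer to spot composite traces.

The package also computes the spatial clustering index

```
SCI = mean(top 5% of pixel intensities) / mean(bottom 5%)
```

(1 for a uniform image, larger with clustering), sub-pixel two-channel
registration by phase correlation with upsampled cross-correlation
refinement, and an A-conditional colocalization degree: the fraction of
channel-A trajectories that co-move with a channel-B trajectory within 2 px
for ≥ 3 frames. A synthetic VA-TIRFM movie generator with complete
per-particle ground truth (Poisson arrivals, exponential dwell with
censoring at the movie end, Brownian motion, integrated Gaussian PSF,
Poisson + read noise, photobleaching, two channels with a known chromatic
shift and controllable colocalized fraction) backs every claim with
parameter-recovery tests.

## Worked example

Simulate a 30 s acquisition (200 frames, 150 ms) of particles with a 3.8 s
mean membrane dwell, then run the full chain — detection, linking,
per-trajectory scan lines, kymographs, segment validation:

```r
library(smkymo)

res <- run_pipeline(list(seed = 42, outdir = "out",
  simulate = list(n_frames = 200, fov = c(96, 96), arrival_rate = 0.5)))
#> pipeline: 4504 localizations, 1228 trajectories, 125 scan lines,
#>   297 segments (76 validated, 78 censored, 36 merged, 107 unsupported)

v <- res$dwell[res$dwell$status == "validated", ]
mean(v$dwell_s)   # 3.52 s over 76 measurable segments
```

The stage counts are the audit trail: 78 segments touched the recording
boundaries (no dwell value), 36 were composite streaks of two particles
(the artifact that inflates naive estimates), 107 had no trajectory
support, and 76 survived validation. Their mean, 3.52 s, is a conditional
mean over measurable dwells — dwells longer than the window are censored,
which is why it sits below a naive expectation for the 3.8 s simulation
law.

```r
compute_sci(read_stack("movie.tif", frame_interval_s = 0.15, pixel_size_um = 0.1))
#> SCI = 4.069 +/- 0.214 SD (top/bottom 460 of 9216 pixels, 200 frame(s))

compare_groups(dwells_control, dwells_treated, flavor = "student")
#> Group A: n=30, 3.87 +/- 0.83 s | Group B: n=30, 2.81 +/- 0.64 s
#> Student t = 5.586 (df 58.0), p = 6.49e-07
```

A thin CLI wrapping the same functions is installed at
`inst/cli/smkymo` (`smkymo simulate|track|kymo|sci|coloc|run`).

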