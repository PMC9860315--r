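# wormforage

Quantification of *C. elegans* foraging behavioral states and of
ligand-gated ion channel pharmacology in *Xenopus* oocytes, with seeded
synthetic-data generators for every input so the whole analysis chain can be
validated against known ground truth.

The package is aimed at behavioral neuroscientists and electrophysiologists
who work with (a) centroid worm-tracking output, (b) plate-level foraging
assays (dispersal, food leaving, chemotaxis), and (c) two-electrode
voltage-clamp (TEVC) recordings from oocytes expressing ligand-gated
channels.

## What it computes

**Reorientation detection from trajectories.** Centroid tracks
(`worm_id, frame, x_mm, y_mm` at a known frame rate) are filtered (tracks ≥
30 s), holes shorter than 5 s are linearly interpolated (longer holes split
the track), positions are smoothed with a 50-frame centered rolling mean to
cancel the ~1 s sinusoidal body wave, and per-frame path curvature

κ(t) = |Δ heading(t)|,  heading(t) = atan2(y(t+1) − y(t−1), x(t+1) − x(t−1))

is thresholded (default κ\* = 0.25 rad/frame); maximal supra-threshold runs
are *reorientation events*, summarized as reorientations per worm per
minute. This separates the turn-rich *local search* state from the
run-dominated *global search* state.

**Plate assays.** The dispersal statistic on a thresholded plate image is

zone density ratio = (IntDen_zone / zone area) / (IntDen_plate / plate area),

food-leaving probability is `events / worms at start / video minutes`,
the quadrant chemotaxis index is `CI = (Test − Control) / Total`, and
repellent-induced patch leaving is reported as percent of worms remaining
per minute.

**TEVC analysis.** Peak currents per agonist application (median baseline
over the 2 s before onset), per-oocyte normalization to the maximum
response, and Hill fits

response = bottom + (top − bottom) / (1 + (EC50 / c)^n)

in three-parameter (bottom = 0, or top fixed at the control response for
inhibition) and four-parameter form, selected by small-sample-corrected AIC.
Ion selectivity is assessed from −80..+60 mV ramps: the reversal potential
is the zero-current crossing, and ΔErev between ND96 and an ion-substituted
solution (paired per oocyte) diagnoses the conducting ion. A monoisotopic
m/z utility covers exact-mass checks (e.g. protonated betaine C5H12NO2+,
118.0863).

**Synthetic data.** Every analysis input has a generator with known ground
truth: a two-state run-and-reorient trajectory model (Poisson turn events,
heading noise, sinusoidal wobble, tracking gaps, reflecting arena), plate
images with controllable central blob density, Hill-model dose–response
data, linear I–V ramps, and pulse-train current traces.

## Worked example

```r
library(wormforage)

cfg_local  <- foraging_config(n_worms = 10, state = "local",  seed = 1)
cfg_global <- foraging_config(n_worms = 10, state = "global", seed = 2)
sim_l <- simulate_foraging_tracks(cfg_local)
sim_g <- simulate_foraging_tracks(cfg_global)
res_l <- analyze_trajectories(sim_l$tracks)
res_g <- analyze_trajectories(sim_g$tracks)

summarize_groups(list(
  local  = res_l$summary$reorientations_per_minute,
  global = res_g$summary$reorientations_per_minute), seed = 1)
#>    group  n median ci_lo ci_hi  q1   q3
#> 1  local 10    3.4   3.1   4.6 3.2 4.35
#> 2 global 10    0.8   0.6   0.8 0.6 0.80

m <- event_match_stats(sim_l$truth$planted_events, res_l$events, fps = 25)
#> sensitivity 0.995, precision 1.000
```

The two cohorts were simulated at 4 and 1 reorientations per minute; the
recovered per-worm rates separate cleanly (local median 3.4/min vs global
0.8/min; detected rates sit slightly below the planted rate because
back-to-back turns merge on the smoothed path) and the planted events are
recovered with near-perfect sensitivity and precision.

```r
conc <- 211 * 10^seq(-1, 1, length.out = 8)
dr <- simulate_dose_response(211, 1.5, concentrations_uM = conc,
                             n_oocytes = 6, noise_sd = 0.05, seed = 3)
fit_hill_activation(dr)
#> 3-parameter Hill fit (activation): EC50 = 223 uM, n = 1.38, top = 1.02,
#>   bottom = 0, R^2 = 0.9862
```

A dose–response dataset generated at EC50 = 211 uM with 5% per-oocyte noise
is fitted back to 223 uM (≈6% off, within the sampling error of six
oocytes); noiseless data recover the planted value to numerical precision.

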