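---
title: "Methods: models, parameters and design choices in wormforage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in wormforage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormforage)
```

wormforage couples two analysis chains — behavioral-state quantification
from worm centroid trajectories, and oocyte voltage-clamp pharmacology —
with synthetic-data generators that plant known ground truth for every
input. This vignette explains the underlying models, why the defaults are
what they are, and where the genuinely open design decisions were made.

## The trajectory model and its analysis

### Generative model

`simulate_foraging_tracks()` implements a two-state run-and-reorient random
walk, the minimal structure the downstream detector assumes. Each worm:

* runs at constant speed `run_speed` (default 0.1 mm/s, a typical off-food
  crawl) with per-frame Gaussian heading noise (`heading_noise`, default
  0.03 rad/frame);
* executes reorientation events at Poisson rate `reorientation_rate`
  (defaults: 4/min for `"local"` search, 1/min for `"global"` search — the
  two off-food behavioral states differ only in this rate). During an event
  the heading swings by `turn_magnitude` (default 3.05 rad ≈ 175°, an
  omega-turn-like near-reversal) over `turn_duration_frames` (default 8)
  frames, with random rotation sign;
* carries a sinusoidal lateral wobble (`wobble_amplitude` 0.15 mm,
  `wobble_period_s` 1 s) — the body-wave signature a centroid tracker sees;
* reflects specularly off the arena wall (`arena_radius` 40 mm, an 8-cm
  plate) and starts within 2 mm of the plate center, as in assays where
  animals are deposited centrally;
* loses frames in Poisson tracking gaps (`gap_rate` 0.5/min ×
  `gap_length_s` 2 s).

The local/global rate defaults are deliberate placeholders: published
figures report the rates graphically, not numerically, so the defaults were
chosen once to represent the two regimes and are exposed as a single knob.
All randomness flows through one explicit `seed` per call; the global RNG
stream of the session is left untouched.

Two default choices deserve justification because they interact with the
detector:

* **Turn sharpness.** A turn of total angle Δθ smeared by a `w`-frame
  rolling mean produces a peak per-frame curvature of roughly
  (2/w)·tan(Δθ/2). With the standard w = 50 and threshold 0.25 rad/frame,
  only turns sharper than ≈165° are detectable at all. The default
  `turn_magnitude` of 3.05 rad places planted events safely above the
  threshold (measured peak ≈ 0.37) while staying in the biologically
  sensible omega-turn/reversal range. Shallow course corrections are, by
  construction of the published procedure, not "reorientations".
* **Speed vs arena.** At 0.1 mm/s a worm travels at most 30 mm in a 5-min
  video, so it cannot reach the wall of an 8-cm plate from a central start;
  wall reflections (sharp heading changes that are real path features but
  not planted events) therefore do not contaminate rate estimates at the
  default settings. Reflection is still implemented and tested for
  configurations that do reach the wall.

### Analysis pipeline

`analyze_trajectories()` chains five operations, each exported separately:

1. **`filter_and_segment()`** — per worm, the frame sequence splits wherever
   ≥ `max_gap_s` (5 s) of frames are missing; contiguous pieces shorter than
   `min_track_s` (30 s) are dropped. A hole of *exactly* 5 s splits (only
   strictly shorter holes are interpolable), and a piece of exactly 30 s is
   kept.
2. **`interpolate_gaps()`** — remaining holes are filled on the straight
   line between flanking observations; interpolation adds no curvature, so
   it can hide but never fabricate a turn.
3. **`rolling_mean_smooth()`** — a centered 50-frame rolling mean. An even
   window cannot be centered on a frame, so interior frames use the
   classical even-order centered average (half weight on the two outermost
   samples): this preserves straight lines exactly and retains the exact
   null of the 50-term average at the 25-frame wobble period (the window
   spans two full periods). Near segment edges the largest centered odd
   window is used instead of padding; no positions are fabricated.
4. **`compute_curvature()`** — heading from the centered displacement,
   curvature as the absolute wrapped per-frame heading change (rad/frame).
   Two numerical guards: (a) frames whose centered displacement falls below
   `stillness_floor_mm` get zero curvature, because heading is undefined
   when stationary; (b) the half-window margins of a smoothed segment are
   excluded, because partially-smoothed positions retain unattenuated
   wobble whose residual curvature would masquerade as turning.
5. **`detect_reorientations()`** — maximal supra-threshold runs become
   events; runs separated by less than `min_event_separation_s` (1 s) merge,
   so one omega turn whose smoothed curvature dips briefly below threshold
   is not double-counted.

**The stillness floor is small on purpose.** On a rolling-mean path the
product of per-frame curvature and squared centered displacement is bounded
by step²/window, so any supra-threshold (κ > 0.25) turn necessarily passes
through sub-micron per-frame displacements near its apex. A floor at the
raw-tracker-noise scale (several µm) would therefore veto *every* real
reorientation; the default of 0.1 µm sits below the apex displacement of a
175° turn at default speed while still suppressing atan2 noise at true
standstill. If raw (unsmoothed) centroid jitter is analyzed directly, the
floor should be raised to the jitter scale.

**Curvature at an instantaneous corner.** With heading defined on centered
displacements, a one-frame 90° corner yields two adjacent curvature values
of π/4 rather than a single π/2: the centered stencil sees the corner from
both sides. Total turning is preserved; per-frame peaks of very sharp
unsmoothed corners are halved. On smoothed tracks (the intended input) the
distinction is immaterial because every turn is already spread over many
frames.

**Event scoring.** `event_match_stats()` matches planted to detected events
by interval overlap after dilating both by a ±2 s tolerance, many-to-one:
smoothing smears each turn over about two seconds, so one detection may
legitimately cover two back-to-back planted turns. A strict one-to-one count
comparison would misread merging as failure. Two genuine blind spots remain
and are visible in the tests: events in the first/last ~1.1 s of a track
fall in the excluded smoothing margin, and two opposite-sign near-reversals
within one smoothing window cancel on the smoothed path and are invisible
to any curvature detector operating at this smoothing scale.

### What the generator does not emulate

No body posture (the 49-point skeleton), no pirouette sub-structure, no
speed modulation between states, no centroid measurement noise, and no
density-dependent interactions between worms. Passing the recovery tests
therefore shows that the pipeline implements its stated transformation
correctly and recovers Poisson event statistics under wobble, heading
noise and tracking gaps — not that it is robust to every artifact of real
tracker output (collisions, identity swaps, posture-dependent centroid
shifts).

## Plate assays

`zone_density_ratio()` thresholds the image (Otsu on the in-plate pixels by
default — a reproducible, parameter-free stand-in for interactive
thresholding; a fixed numeric threshold can be supplied), zeroes
sub-threshold pixels, and computes
(IntDen_zone/zone area)/(IntDen_plate/plate area) over pixel-center disk
masks. A uniform plate gives exactly 1; a fully concentrated plate gives
plate_area/zone_area. Degenerate cases: a constant image keeps all pixels
(thresholding a blank field should not delete it); zero supra-threshold
signal reports a missing ratio with a warning. The central-zone radius is a
required geometry input, not a default. One known bias: with heavily
overlapping bright objects, thresholding removes proportionally less mass
where objects crowd, inflating the ratio by a few percent — the simulator
oracle test quantifies this at moderate densities.

`food_leaving_probability()` uses the only observable proxy for "the full
body left the patch" available at centroid resolution: the centroid passing
`radius + body_length/2` (body length default 1 mm, configurable). The
detector re-arms only when the worm returns fully inside the patch radius,
so an excursion that lingers in the annulus cannot fire twice. The
probability is events / worms-at-start / video minutes.

`chemotaxis_index()` computes (Test − Control)/Total. Assay write-ups
sometimes misprint this formula with the Test terms repeated (which would be
identically zero); the contrast form is the only meaningful reading and is
what is implemented. Center-stranded worms are excluded from the total and
plates under 50 counted worms are flagged invalid but still scored.

## TEVC analysis

**Peaks and normalization.** `extract_peak_currents()` subtracts a baseline
(median over the 2 s before application onset; the window is clamped at the
trace start) and takes the signed in-window extremum. Inward currents are
negative throughout; `normalize_responses()` divides each oocyte's peak
magnitudes by that oocyte's maximum magnitude, so normalization is
idempotent and polarity-free. The simulated traces low-pass their
instrument noise at 10 Hz, as an acquisition chain does; peak extraction
assumes filtered traces and applies no further smoothing.

**Hill fits and model selection.** Both fitters run Levenberg–Marquardt
least squares (via minpack.lm) on the log-concentration scale with
log-parameterized EC50, which makes convergence insensitive to the
concentration units. The three-parameter form fixes bottom = 0 (activation)
or top = control response (inhibition); the four-parameter form frees both
asymptotes. Selection uses AICc, with the extra parameter retained only if
it improves AICc by more than the conventional margin of 2: on data
generated from the three-parameter model, the unpenalized criterion accepts
the spurious fourth parameter in roughly one replicate in ten (the expected
chi-square(1) fluctuation of the residual improvement), while the margin
rule keeps the nested model in the large majority of replicates, as the
property test verifies. On exactly noiseless data both residual sums vanish
and the criteria degenerate, so parsimony picks the nested model outright.
Degenerate inputs: essentially flat responses (range < 2% of the maximum)
are reported as an unidentifiable fit (missing EC50) with a warning rather
than a spurious number; an EC50 outside the tested concentration range is
flagged as extrapolated.

**Reversal potentials.** `extract_reversal_potential()` smooths the ramp
current with a 5-point running median (a light guard against single-sample
spikes that cannot move the crossing), finds sign changes, and — if several
survive the smoothing — keeps the one nearest the median crossing voltage
(a tie-break that ignores noise-induced outlier crossings). A local
straight-line fit within ±5 mV of the crossing gives the root, making the
estimate invariant to uniform current scaling and to leak conductances
sharing the same reversal. `delta_erev()` reports the per-oocyte paired
shift, signed as substituted-minus-reference so that a chloride channel
assayed in low chloride with a planted reversal below the reference yields
a negative mean shift, with SEM over oocytes (0 for a single pair).

## Reporting utilities

`summarize_groups()` reports medians with quartiles and a seeded percentile
bootstrap CI of the median (default 2000 replicates) — the right summary
for per-worm rates, which are small counts divided by time and markedly
skewed. Hypothesis tests between groups are deliberately left to standard R
(`kruskal.test`, `aov` + `TukeyHSD`, `p.adjust`): the package's
contribution is the metrics, not the inferential machinery.
`monoisotopic_mz()` sums monoisotopic atomic masses, subtracts the electron
mass per positive charge, divides by |charge| and rounds to 4 decimals (the
HRMS reporting convention).

## Problem sizes and determinism

The shipped tests simulate cohorts of up to 50 worms × 5 min × 25 fps
(750k trajectory rows for the two-cohort recovery check) and 100-replicate
noise ensembles for the dose–response properties; these sizes give the
Poisson and bootstrap checks enough resolution while keeping a full test
run under a minute on one core. Every generator is bit-reproducible given
(config, seed), and `run_pipeline()` writes a results file that is
byte-identical across reruns with the same seed (timestamps go to the log
only).

## Known limitations

* The curvature threshold of 0.25 rad/frame is treated as a dimensionless
  per-frame angle on the smoothed centroid path; trackers that define
  curvature per unit path length will need a rescaled threshold.
* Whether the original analyses used a centered or trailing rolling mean is
  not documented; centered was chosen because it introduces no phase lag
  into event positions.
* The HDF5 trajectory container used by some trackers is not read; the CSV
  dialect (with a YAML metadata sidecar) is the interchange format.
* Detection sensitivity is defined for near-reversal maneuvers; gradual arc
  turns are below threshold by design of the published procedure.
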