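---
title: "Cumulative Achilles tendon load from insole forces: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cumulative Achilles tendon load from insole forces: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tendonload)
```

This vignette is the package's account of its science: the tendon-load
model and its assumptions, the quality-control and biomarker definitions,
the reliability and association analyses, what the synthetic cohort
generator does and does not emulate, and the numerical and design choices
that were genuinely open.

## The moment-arm model

A force-sensing insole measures plantar contact force under three pads
(heel, midfoot, forefoot) at 20 Hz. Treating each force as perpendicular
to the sole and applied at a fixed per-pad center of pressure, the net
ankle plantarflexion moment is the sum of force-by-moment-arm products,
and dividing by the Achilles tendon moment arm gives a proxy tendon
force, normalized by body weight:

$$M_{PF} = \sum_i F_i\, r_i, \qquad
  F_{AT} = \frac{\max(0, M_{PF}/r_{AT})}{BW}.$$

Assumptions worth stating explicitly:

* the Achilles tendon is taken as the dominant transmitter of the
  plantarflexion moment; small plantar flexors are ignored, which biases
  the estimate slightly upward;
* $r_{AT}$ = 0.05 m is a standardized value; its inter-individual
  variation is reported to be under 10% and is not subject-specific here;
* pad moment arms are *signed* anterior distances — the heel pad may sit
  posterior to the ankle axis, so `r_heel` is allowed to be negative. The
  defaults (−0.02, 0.05, 0.12 m) are this package's own calibration such
  that synthetic walking reproduces ≈3×BW peak tendon loads; real
  deployments should substitute per-insole-size arms via
  `sensor_geometry()`;
* negative net moments map to zero tendon load. The tendon cannot push,
  and without the clamp nonphysical "negative impulse" would leak into
  the cumulative metrics.

## Quality control

Contact force must read zero whenever the insole is unloaded; offsets and
drifts there are sensor artifacts. The pipeline:

1. **Unloaded-epoch detection** (`detect_unloaded_epochs()`): 10-s
   epochs; an epoch is unloaded iff the within-epoch *range* of total
   force is below 20 N. A range (not level) criterion recognises a quiet
   epoch sitting on an 800 N offset as unloaded — exactly the case drift
   correction needs to find.
2. **Drift correction** (`correct_baseline_drift()`): per channel, the
   *lower median* within each unloaded epoch becomes a baseline anchor;
   anchors are held piecewise-constant between unloaded epochs,
   subtracted, and the result is clipped at 0 N (contact force is
   non-negative). Piecewise-constant interpolation was chosen over linear
   because anchors can be sparse and a held level is the simplest model
   that cannot overshoot during long loaded stretches. The lower median
   (always an actual sample value) makes the correction idempotent to
   machine precision even though clipping truncates the noise
   distribution. A consequence to keep in mind: a step drift that begins
   mid-activity remains uncorrected until the next quiet anchor.
3. **Screening** (`screen_recording()`): a session is excluded when it is
   essentially never unloaded despite being long (initialization-failure
   signature: < 2% unloaded epochs over > 10 min), when any 1-s mean of
   total force exceeds 10×BW, or when more than 1% of samples were below
   −5 N before clipping. Field practice screens such recordings
   numerically *and* graphically without a published algorithm, so these
   thresholds are this package's documented defaults, all exposed in
   `qc_rules()`.

## Cumulative biomarkers

Two thresholds stratify the load trace: 0.3×BW (the load of seated heel
raises, the lowest-loading tendon exercise — a clinically meaningful
baseline) and 3.0×BW (≈ peak walking tendon load, so supra-threshold
loading is predominantly dynamic exercise). For a set of days,
`summarize_load()` reports time at or above each threshold, the
cumulative impulse above each, and per-hour normalized values.

Numerical choices:

* **Full-magnitude integration.** The impulse above a threshold
  integrates the whole load magnitude (area down to zero) over
  supra-threshold samples, not the excess above the threshold line. The
  alternative reading exists, but only the full-magnitude reading is
  consistent with a normalized overall load near 1×BW on
  walking-dominated data (the excess reading would hover near the
  average *exceedance*, far below the threshold), so it is adopted; the
  excess reading would be a one-line change for sensitivity analysis.
* **Trapezoidal rule at the native 20 Hz**, with threshold crossings
  resolved at sample resolution. The error is bounded by one sample
  period per crossing; for constant traces the integral spans $n-1$
  intervals so printed round numbers are reproduced to ~1e-4 of the
  continuous value.
* **Both normalized values share the overall loading time as
  denominator** — the high-level per-hour load is high-level impulse per
  hour of *any* loading, not per hour above 3×BW. A zero loading time
  flags the normalized values as undefined (`NA` with a warning), never
  0 or infinity.
* Sessions are concatenated without bridging gaps; inter-session time
  contributes nothing.

## Day-subsampling reliability

`reliability_analysis()` asks how well k monitoring days (k = 1..6,
drawn from each participant's first six recorded days) reproduce the
full-dataset biomarkers. All $\binom{6}{k}$ day combinations are used:
the leave-one-out (k = 5) and single-day (k = 1) designs generalise
naturally and even k = 3 costs only 20 subsets. Agreement is described
by the mean absolute percent error across participants and subsets, the
Pearson correlation of per-participant subset means against the
reference, and the intraclass correlation across same-size subsets
(columns aligned in day order). Participants with fewer than six
recorded days are excluded with a warning; the reference is always *all*
recorded valid days.

The ICC form is fixed to ICC(2,1) — two-way random effects, absolute
agreement, single measures — because the scientific question is whether
one day's estimate *agrees in value* with another's, not merely ranks
participants consistently. It is computed from the standard mean-squares
decomposition and cross-checked in the test suite against an independent
`aov()`-based oracle. Only descriptive statistics are reported; no
inferential testing is layered on the reliability curves.

## Associations

`correlation_table()` correlates the two normalized biomarkers with
functional and survey measures: Pearson r, a two-sided p from the t
transform with n − 2 df, and the a-priori strength classes
|r| ≥ 0.6 strong, 0.4 ≤ |r| < 0.6 moderate, |r| < 0.4 weak. Both
boundaries are closed from below, matching the class definitions.
Significance at α = 0.05 is an ancillary flag only — with a dozen
uncorrected tests on a small cohort, the descriptive strength class is
the primary result, and no multiplicity correction is applied by design.
Capacity utilities normalize dynamometer traces to %H×W (peak moment),
%H×W×rad/s (peak power) and %H×W×rad (work per contraction, averaged
across repetitions), and jump/heel-raise heights to %BH.

## The synthetic cohort generator

`generate_cohort()` exists so every stage is testable without access to
any real deposit. Waveform realism is deliberately secondary to analytic
tractability: days are assembled from segments whose supra-threshold time
and impulse have closed forms, so each participant carries *exact* ground
truth.

* **Walking**: raised-cosine stance pulses (stance fraction 0.58 of a
  1.17-s per-foot cycle), peaks drawn per step from N(2.8, 0.06) ×BW
  truncated at ±2.5 SD. Placing ordinary walking just *below* the 3×BW
  threshold reflects that threshold's definition (it bounds walking from
  above) and avoids the knife edge of a peak exactly at the threshold,
  where sample-resolution crossing decisions would be dominated by
  sensor noise.
* **Standing**: 0.5×BW with ±0.12×BW sinusoidal sway (4-s period,
  durations rounded to whole periods so the closed forms are
  phase-free). Sway keeps standing epochs from being misread as
  unloaded by the range criterion — as real postural sway does.
* **Exercise**: on exercise days, a run (5×BW peaks, 20 min by default)
  plus a heel-raise set (4×BW). The default run volume puts the cohort's
  normalized high-level load near 0.1×BW per hour and its high-level
  time share near 2–3% of loading time, the magnitudes reported for
  real cohorts.
* **Heterogeneity**: persistent per-participant habit multipliers for
  walking, standing and running volume, and a wide Beta(1.2, 1.8)
  exercise propensity, on top of ~20% day-to-day variation. Profiles
  draw anthropometrics from the published cohort ranges.
* **Artifacts** (`inject_artifacts()`): white sensor noise (1.5 N),
  whole-session constant offsets (≤ 40 N, fully recoverable from quiet
  anchors), mid-session step drifts (≤ 15 N — kept within the band the
  anchor-held correction can absorb without flipping a threshold
  classification, since a mid-activity step is uncorrected until the
  next anchor), and rare initialization failures (a wandering baseline
  that never reads quiet, which screening must exclude; these sessions
  are also excluded from ground truth, as they are unrecoverable by
  construction).
* **Outcomes**: each measure is a target-correlation mix of the
  standardized ground-truth high-level load with noise orthogonalized
  against it, so the realized Pearson correlation equals the target
  exactly before discretization; ordinal and count measures
  (PAS, repetitions, ages) are rounded and clamped to their scales,
  which attenuates their correlations by a few hundredths. A pure
  rank-copula construction was considered and rejected: it preserves
  rank but attenuates raw-scale Pearson correlations noticeably on
  skewed load distributions.
* **Determinism**: one global seed fans out to fixed per-participant
  substreams, so a cohort can be extended without perturbing existing
  participants, and identical configs yield byte-identical datasets.

What passing tests on this generator *do* show: the pipeline recovers
known loading truth through QC, model inversion, integration and
summarisation (within 2% per participant on clean data, 5% with
artifacts enabled), and the reliability machinery reproduces the
expected qualitative structure (single-day estimates are far less
reliable for the exercise-driven high-level biomarker than for the
habitual overall one, with error shrinking monotonically as days are
added). What they do *not* show: performance on real gait, where load
waveforms are not raised cosines, center of pressure travels
continuously, drifts are not steps, days are not conditionally
independent given habits — one visible consequence is that the synthetic
cohort's single-day ICCs (≈0.4 overall, ≈0.3 high at default settings)
sit below values reported for real cohorts — and where exclusion
decisions were partly graphical judgement.

## Problem sizes and degenerate inputs

The test suite exercises cohort-scale recovery at 20 participants × 10
days and the reliability-shape scenario at 12 participants × 6 days with
reduced bout volumes; the acceptance script simulates the default
15-participant, 6–14-day scenario. These sizes are the package's chosen
validation scale — large enough for aggregate discretization errors to
average out, small enough to re-run routinely.

Degenerate inputs are handled explicitly: empty recordings are an error;
recordings shorter than one epoch fall back to a single epoch with a
warning; sessions with no quiet anchor pass through uncorrected with a
warning; zero loading time flags normalized biomarkers as undefined;
zero-variance or sub-3-pair correlation cells are flagged, not silently
dropped; MAPE drops participants with a zero reference with a warning.

## Known limitations

* The tendon-load proxy inherits the moment-arm model's assumptions:
  fixed centers of pressure, a standardized tendon moment arm and
  tendon-dominant moment transmission.
* QC thresholds are package defaults, not a published standard; exact
  reproduction of any particular study's manual exclusions is out of
  scope.
* Total loading time excludes all sub-0.3×BW wear (including swing
  phases), so it is not a wear-time or active-time measure.
* The generator's waveforms are pulse-parametric idealisations;
  conclusions about real-data performance require real data — the
  pipeline can be pointed at any dataset directory in the package
  dialect via `reanalyze_dataset()`.
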