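---
title: "Detecting chest-compression periods from defibrillator accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chest-compression periods from defibrillator accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccperiods)
library(dplyr)
```

## The problem

During cardiopulmonary resuscitation (CPR), defibrillators with a sternal
accelerometry pad record the chest's acceleration continuously, in the
vendor's uncalibrated internal units. Knowing *when* compressions were being
delivered — the start and stop markers of each chest-compression (CC)
period — is the basis of every standard CPR quality metric, above all the
chest compression fraction (CCF): the fraction of the arrest interval
covered by compressions. Annotating these periods by hand is slow;
`ccperiods` computes them directly from the accelerometer channel.

The package detects *periods*, not individual compressions: the unit of
output is a `(start_s, stop_s)` interval, and everything in between two
periods is a pause (ventilation, rhythm check, shock — the detector does
not classify why).

## Signal model and processing chain

During compressions the acceleration oscillates at roughly the compression
rate (about 100–120 per minute, i.e. near 2 Hz) with an approximately
steady amplitude; during pauses it is close to zero, apart from residual
motion, sensor noise, slow baseline drift and the constant gravity
component. The detector works on a quantity that makes this dichotomy
explicit:

1. **Band-pass filter** (`bandpass()`): a fourth-order Butterworth filter
   with critical frequencies 0.2 Hz and 50 Hz removes drift and the
   gravity offset below the band and broadband noise above it. The filter
   is applied forward–backward (zero phase) so that the markers derived
   later are not phase-delayed; a causal single pass is available via
   `detector_config(zero_phase = FALSE)`.
2. **Envelope** (`sliding_abs_mean()`): the centered sliding mean, over a
   1 s window, of the absolute filtered acceleration. For a sinusoid of
   amplitude $A$ this converges to $2A/\pi$; it is nearly constant and
   non-vanishing while compressions are present and approximately zero in
   pauses.
3. **Smoothed derivative** (`smooth_derivative()`): the finite-difference
   derivative of the envelope (central differences, one-sided at the two
   edge samples), smoothed with the same 1 s sliding mean. Envelope
   plateaus map to ≈ 0, compression onsets to positive lobes, offsets to
   negative lobes.
4. **Soft shrinkage** (`soft_shrink()`): $x \mapsto \operatorname{sign}(x)\,
   \max(|x| - \lambda, 0)$ zeroes small, non-significant extrema of the
   derivative.
5. **Alternating extrema** (`alternating_extrema()`): the candidate start
   markers are the maxima and the candidate stop markers the minima of the
   shrunk derivative, searched *alternately* — between two extrema of one
   kind, the absolutely largest extremum of the other kind is taken.
6. **Candidate filtering** (`filter_candidates()`): three acceptance rules,
   below.
7. **Marker refinement** (`refine_marker()`): a derivative-weighted mean
   resolves the case of two similarly large derivative maxima, below.

`detect_compressions()` runs the whole chain and returns the segmentation,
a pause audit log, and all intermediate series (plot them with
`autoplot()`).

## The three acceptance rules

Candidate markers pair into potential compression periods with pauses in
between. A pause bounded by two periods is accepted only if

* its envelope mean is **less than 35 %** of the average of the envelope
  means of the two flanking compression periods (`pause_ratio = 0.35`),
  and
* it lasts **at least 1.6 s** (`min_pause_s = 1.6`).

In addition, a compression period's envelope mean must not fall below a
floor (`cc_min_level`). Rejected pauses are merged into their neighbouring
periods; a rejected period is absorbed into the surrounding pause. Either
operation changes the neighbouring intervals, so the rules are re-applied
until nothing changes. This fixpoint iteration is a deliberate design
choice: the three rules are stated as conditions, not as a sequence, and
iterating to a fixpoint makes the result independent of the order in which
they are applied. It terminates because every change removes at least one
period or pause. Every verdict of every iteration is logged in the
`gaps` table (`verdict` ∈ accepted / `rejected_short` / `rejected_ratio`),
which makes the two pause rules directly auditable.

The ratio rule is evaluated on the 1 s envelope rather than on the raw
absolute acceleration; over intervals much longer than the window the two
differ only by edge effects, and using the envelope keeps a single
smoothed quantity throughout the chain.

## Marker refinement

Because the acceleration is oscillatory, the transition at a period
boundary can produce two similarly large maxima of the absolute
derivative instead of one. When a second local maximum with at least
`similar_max_ratio` (default 0.5 — "similar" is not quantified by the
method's description, so it is a parameter) of the anchor's strength lies
within the 1 s refinement window centered on the marker, the marker is
replaced by the $|d|$-weighted mean time over that window,

$$t^\ast = \frac{\sum_i t_i\,|d(t_i)|}{\sum_i |d(t_i)|},$$

which lands between the two maxima. Both start and stop markers are
refined by default; `refine_starts` / `refine_stops` switch either off.
Markers synthesized at record edges (below) are never refined. The
pre-refinement boundaries are kept alongside the refined ones
(`start_raw_s`, `stop_raw_s` in `tidy()`), and the pause log always refers
to the pre-refinement candidate boundaries.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `band_low`, `band_high` | 0.2, 50 | Hz | Butterworth band edges |
| `filter_order` | 4 | – | Butterworth order |
| `window_s` | 1.0 | s | envelope and derivative smoothing window |
| `pause_ratio` | 0.35 | – | pause/flank envelope ceiling |
| `min_pause_s` | 1.6 | s | pause duration floor |
| `shrink_lambda` | adaptive | units/s | soft-shrinkage threshold |
| `cc_min_level` | adaptive | units | compression envelope floor |
| `refine_window_s` | 1.0 | s | refinement window |
| `similar_max_ratio` | 0.5 | – | "similarly large" second maximum |

The band, order, window, ratio, floor-duration and refinement-window
values are the method's published constants. The two absolute thresholds
are not published — and cannot be, in fixed form, because the
accelerometer's internal units are uncalibrated — so both default to
adaptive, scale-free fractions chosen once here: $\lambda$ is 10 % of the
95th percentile of $|d|$ (`shrink_frac`), and the compression floor is
20 % of the 90th percentile of the envelope over the candidate compression
periods (`cc_min_frac`). Either can be overridden by an absolute value in
internal units. A consequence of the adaptive defaults is exact amplitude
equivariance: rescaling a record leaves the segmentation unchanged, which
the test suite asserts to within one sample.

## Numerical choices and degenerate inputs

* **Window parity.** The window length is `round(window_s * fs)` samples —
  250 at the native 250 Hz, an *even* number, so the "centered" window is
  offset by half a sample (2 ms, negligible against the 0.5 s matching
  tolerance). This keeps an integer number of samples per window and, for
  periodic test signals with an integer number of cycles per window, makes
  the envelope match its analytic value to better than $10^{-4}$.
* **Edge truncation.** Centered windows are truncated and renormalized at
  the record edges rather than padded: padding would fabricate data
  exactly where compressions may already be ongoing.
* **Filter edge handling.** The record is demeaned and odd-extended around
  its endpoints before `filtfilt`; without this, the 0.2 Hz high-pass edge
  rings for several seconds into the record when the filter's zero initial
  state meets the gravity offset.
* **Record edges.** Envelope and derivative values inside the first and
  last window are computed from truncated windows and are not trusted for
  marker placement. If a record begins mid-compression the candidate list
  starts with a stop marker; a synthetic start is pinned to the first
  sample (symmetrically at the end). If the envelope at a record edge
  clears the compression floor and the adjacent boundary falls within one
  window of that edge, the boundary is likewise pinned to the edge. A
  record with no surviving derivative extremum at all is a single
  full-record period if its mean envelope clears the floor, and empty
  otherwise.
* **Ties.** Equal extrema are resolved to the earliest time, so output is
  deterministic on adversarially flat inputs.
* **Too-short records.** Records shorter than twice the window are
  refused.

## The synthetic generator

Real registry recordings cannot be redistributed with the package, so
validation runs on seeded synthetic cases (`scenario()`,
`generate_case()`) with exact ground truth. A scenario is a schedule of
compression and pause segments; the generator renders each compression
segment as a sinusoid at the compression rate (default 1.833 Hz ≈ 110
min⁻¹, amplitude 1 internal unit) with smooth 0.3 s raised-cosine ramps
centered on the segment boundaries — so the ground-truth boundary is the
ramp midpoint, which makes the 0.5 s recovery tolerance well defined —
plus residual pause motion, a gravity offset (5 units), a slow drift
sinusoid (0.1 units at 0.01 Hz) and seeded Gaussian noise (σ = 0.02 by
default, 0.15 in the `noisy` preset). Sample rates and the companion
channels follow the published case layout: accelerometer and shock-pad ECG
at 250 Hz, capnography at 125 Hz, Arrest/ROSC timepoints bracketing the
record.

The generator reproduces exactly the phenomenology the detector relies
on — a near-constant, non-vanishing envelope during compressions and a
near-zero envelope during pauses — and deliberately nothing more. It does
not model per-compression biomechanics (leaning, incomplete recoil,
rate variability), rescuer swaps, pad repositioning artefacts, or
physiological ECG/capnography; the placeholder channels only satisfy the
file format. Passing the recovery tests therefore demonstrates that the
algorithm is implemented correctly under its own signal model, not that it
reaches any particular accuracy on clinical registry data.

Five presets (`preset_scenario()`) each exercise one behaviour: `clean`
(baseline boundary recovery), `noisy` (σ = 0.15 broadband noise),
`residual_motion` (pauses at 20 % and 50 % residual amplitude, straddling
the 35 % ratio rule), `short_pauses` (pauses of 1.0 s and 3.0 s,
straddling the 1.6 s floor) and `edge_truncated` (record starting and
ending mid-compression).

Validation problem sizes: the bundled checks sweep 46 gap durations
(0.5–5.0 s) and 17 residual amplitudes (0–0.8), verify the
alternating-extrema search against an independent oracle on 200 random
series, and measure boundary recovery on 50 seeded `clean` cases
(53 s records at 250 Hz), where at least 95 % of ground-truth boundaries
must match within 0.5 s — the same tolerance beyond which two human
annotators' markers were considered discrepant and reset in consensus.

## Quality metrics and agreement

`ccf(seg, t_arrest, t_end)` computes the chest compression fraction over
an explicit window, clipping (not dropping) periods that straddle the
window; the window defaults in practice to the Arrest → ROSC/Termination
pair from `PhysioStatus.csv`. `compare_segmentations(alg, ann)` matches
like-kind boundaries one-to-one, greedily by ascending absolute deviation
(ties to the earlier annotation), within a tolerance defaulting to the
0.5 s consensus bound, reports signed deviations (algorithm − annotation),
and the Jaccard overlap of compression time. The matching procedure is
this package's own construction — the method description defines none —
and is deliberately simple and symmetric-free of tuning.

## Worked example

```{r example}
sim <- generate_case(preset_scenario("clean"))
det <- detect_compressions(sim$case)
tidy(det)
glance(det)
compare_segmentations(tidy(det)[, c("start_s", "stop_s")],
                      sim$truth$periods)
```

```{r plot, fig.width = 7, fig.height = 3.5}
autoplot(det)
```

## Known limitations

* The detector assumes the envelope dichotomy; sustained strong artefacts
  during a pause (transport, vigorous handling) that mimic compression
  amplitude will defeat the 35 % ratio rule by construction.
* Pauses shorter than 1.6 s are invisible by design — that is the duration
  floor, not a failure mode.
* The adaptive thresholds assume each record contains *some* compressions;
  a record consisting purely of noise can yield a spurious period, since
  the floor is relative to the record's own envelope. Supplying an
  absolute `cc_min_level` calibrated for a device removes this.
* No per-compression rate or depth estimation, no pause-purpose
  classification, no rhythm or ROSC analysis: the output is the period
  segmentation and metrics derived from it.
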