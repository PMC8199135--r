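---
title: "Quantifying gait asymmetry with DTW on fused gyroscope and pressure signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gait asymmetry with DTW on fused gyroscope and pressure signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitdtw)
```

## The problem and the signals

Hemiplegic gait — typically after stroke — is asymmetric: the affected
leg swings longer, rotates less, and loads the ground with different
timing than the sound leg. Classical assessments reduce each foot's
movement to a scalar spatiotemporal parameter (stride time, swing time,
peak angular velocity) and compare the two feet with a symmetry index.
Those scalars discard the waveform: two gaits can share identical stride
times yet move through the cycle very differently.

`gaitdtw` instead compares the *whole* per-foot gait waveform. Each foot
contributes two synchronized channels:

- **gyro**: the sagittal-plane (x-axis) angular velocity of the shank in
  deg/s. One gait cycle shows a near-zero flat during mid-stance (MS,
  foot flat), a negative trough at toe-off (TO), a large positive peak at
  mid-swing (MSW), and a negative trough at heel-strike (HS).
- **pressure**: a *single* channel from two force-sensing resistors
  (heel and forefoot) wired as a voltage divider. With a supply of 5 V
  the unloaded output sits at 2.5 V; after removing that offset, heel
  load is negative, forefoot load positive, and swing exactly zero. Only
  the heel/forefoot *balance over time* matters, not calibrated force.

## The pipeline

For each foot:

1. **Filter** — the gyro channel is low-pass filtered with a 4th-order
   Butterworth at 10 Hz, applied forward-backward (`lowpass_filter()`).
   Event detection relies on extrema *locations*, so the filter must be
   zero-phase; the order/cutoff are package choices (the method itself
   does not fix them) and are configurable. The implementation pads the
   signal by odd reflection before `signal::filtfilt()` so that records
   that do not start at zero have no start-up transient.
2. **Detect events** (`detect_events()`) — rule-based, on the filtered
   gyro only:
   - MSW: the maximum between an upward and the paired downward crossing
     of a 5 deg/s threshold;
   - MS: the first sample after an MSW with |gyro| ≤ 1.5 deg/s whose
     backward difference is < 0.25 deg/s;
   - HS: the minimum between an MSW and its MS;
   - TO: the minimum between an MS and the next MSW.
   The three thresholds (5, 1.5, 0.25 deg/s) are the method's published
   values and live in `pipeline_config()`. Ties go to the earliest
   index, the MS search also runs from the final MSW to the record end
   (so the last stride can be closed), and incomplete cycles at the
   record boundaries are dropped; these are deterministic tie-break and
   boundary choices the rules leave open.
3. **Extract and normalize strides** — strides are HS-to-HS segments
   (half-open at the sample level so neighbors share no samples, with
   the closing HS kept as the right interpolation endpoint). Each stride
   of each channel is resampled onto a common 0–100% gait-cycle grid
   (101 points, i.e. 1% steps) with shape-preserving PCHIP
   interpolation, which cannot overshoot the data's local extrema.
   Pressure strides are cut with the gyro-derived events: one event
   stream per foot.
4. **Average, standardize, superpose** — resampled strides are averaged
   pointwise per channel, each mean channel is z-standardized
   (`Z = (X − μ)/σ`, population σ), and the two standardized channels
   are summed into one fused waveform (`build_fused_stride()`).
   Standardizing *after* averaging keeps each channel's own stride-to-
   stride amplitude structure inside the mean; standardization rather
   than min–max normalization preserves relative amplitude information
   between conditions while making deg/s and arbitrary pressure units
   commensurable.

The asymmetry of a walk is then the **DTW distance** between the left
and right fused waveforms (`dtw_distance()`): the terminal entry of the
accumulated cost matrix

`D(i,j) = Dist(i,j) + min{D(i−1,j), D(i,j−1), D(i−1,j−1)}`

with squared sample difference as the default local cost (an absolute
cost is available), first row/column accumulated along their single
predecessor, and *no* path-length normalization or warping window: the
inputs are standardized and equal length (101 points), so raw terminal
costs are comparable across walks. Identical sequences give exactly 0.
The backtraced warp path (`dtw_align()`) prefers the diagonal on ties,
which makes paths deterministic; the distance itself is tie-independent.

For benchmarking, `walk_metrics()` also reports the three classical
symmetry indices, each `100·ln(left/right)` of a per-foot mean (stride
duration, swing duration, per-stride maximum angular velocity). The
log-ratio form is zero at perfect symmetry and antisymmetric under a
left/right swap; which side sits in the numerator is a configuration
choice, not a claim. `compare_groups()` applies a two-sided
Mann–Whitney test per metric across two groups of walks — exact
enumeration whenever both groups have ≤ 10 untied values (so small-study
p-values are reproducible bit for bit), normal approximation with tie
correction otherwise, and p = 1 by convention when all values are tied.

```{r}
walk_sym  <- synth_walk(gait_params(n_strides = 8, seed = 1))
walk_asym <- synth_walk(gait_params(n_strides = 8, seed = 1),
                        asymmetry_preset(severity = 1, side = "right"))
walk_metrics(walk_sym)
walk_metrics(walk_asym)
```

## The synthetic gait generator

No public recordings of this sensor setup exist, so the package carries
a first-class generator (`synth_foot()`, `synth_walk()`,
`synth_cohort()`) that emulates the *morphology* of the signals and
returns ground-truth event times. Each gait-phase landmark is a
raised-cosine (Hann) lobe: C¹-smooth, with controllable extrema, and —
critically — an exactly flat mid-stance, which the MS rule requires.
Defaults describe a normal adult walk and are fixed once: 1.1 s strides
at 100 Hz, a 60/40 stance/swing split, a 250 deg/s mid-swing peak with
100 and 60 deg/s HS/TO troughs (typical shank-gyro magnitudes; the
method publishes no amplitudes), unit pressure lobes confined to the
stance interval, 2% stride-duration jitter, 5% per-stride amplitude
jitter, and 0.5 deg/s additive gyro noise. A lead-in swing peak precedes
the first heel strike and a landing flat follows the last one, so an
n-stride record yields exactly n detectable HS-to-HS strides.

The hemiplegia preset (`asymmetry_preset()`) scales three effects
continuously with a severity in [0, 1], at full severity: the affected
side's swing duration × 1.3 with the stride period unchanged (so the
stride-duration index stays near zero while the swing-duration index
does not — the signature that makes stride time an insensitive marker),
its swing peak × 0.6 (restricted ankle/knee rotation), and a 60 ms
pressure-onset *lead* relative to the gyro HS trough (the foot meets
the ground before the shank finishes rotating). Stride durations and
per-stride amplitude factors are drawn once per walk and shared by both
feet — cadence is common to both legs — so left/right differences come
only from measurement noise and the preset.

What the generator does **not** emulate: inter-subject variability,
gradual fatigue or speed drift, double-support force transfer between
feet, sensor drift/saturation, or any musculoskeletal dynamics. Passing
tests therefore show that the pipeline's rules and metrics behave as
designed on signals with the documented morphology — not that the
detector is robust to every artifact of real hardware.

## Numerical choices and degenerate inputs

- Population (divide-by-N) standard deviation in the z-transform; a
  constant channel cannot be standardized and raises a
  degenerate-signal error rather than propagating NaN.
- Recording CSVs are written with 17 significant digits, so
  write-then-read round-trips are bit-exact.
- Sampling must be uniform to within 1 ns per step; the rate is inferred
  from the time column.
- Records in which fewer than two complete heel strikes survive the
  order checks raise a no-strides error.
- Exact Mann–Whitney enumeration is limited to ≤ 10 per group (the
  intended study size); larger or tied samples use the corrected normal
  approximation.

## Validation scale

The bundled tests exercise the full pipeline at desk scale: cohorts of
10 walks of 8–10 strides per condition, a 459-stride randomized
detection ensemble (27 records × 17 strides with varied speed,
amplitudes and noise), 1000 random sequence pairs (every m·n ≤ 64)
checked against an exhaustive warp-path enumeration oracle, and 200
Monte-Carlo null repeats for the Mann–Whitney calibration; these sizes
give stable statistics while keeping the default suite to a couple of
minutes. Detection on default synthetic gait recovers a mean stance
fraction within a fraction of a percentage point of the canonical 60%,
and 10-vs-10 synthetic cohorts separate on the DTW metric at the exact
two-sided minimum p = 2/C(20,10) ≈ 1.1 × 10⁻⁵.

## Known limitations

- The rule set assumes sagittal shank rotation with a clear positive
  swing peak; gaits without one (severe shuffling, stairs) will not
  segment.
- DTW distances are comparable only at a fixed grid length and local
  cost; changing `resample_points` or the cost kind rescales them.
- The symmetry-index sign convention depends on the configured numerator
  side; only magnitudes are side-agnostic.
- Single-channel pressure deliberately confounds heel and forefoot load;
  it encodes their balance and timing, not force magnitude.
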