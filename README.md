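# gaitdtw

Asymmetric gait analysis from a per-foot wearable sensor pair: a shank
gyroscope (sagittal-plane angular velocity, deg/s) and a single
heel/forefoot pressure channel (two force-sensing resistors in a voltage
divider, offset-removed so heel load is negative, forefoot load positive
and swing exactly zero).

Clinicians and gait researchers usually quantify asymmetry — e.g. in
post-stroke hemiplegic gait — with scalar spatiotemporal parameters
(stride time, swing time, peak angular velocity) compared between feet
by a symmetry index. Those scalars ignore the waveform. `gaitdtw`
compares the whole cycle instead:

1. zero-phase Butterworth low-pass of the gyro channel;
2. rule-based detection of mid-swing (MSW, max between crossings of a
   5 deg/s threshold), mid-stance (MS, first sample in a ±1.5 deg/s band
   whose backward difference is < 0.25 deg/s), heel-strike (HS, min
   between MSW and MS) and toe-off (TO, min between MS and next MSW);
3. HS-to-HS stride extraction, shape-preserving PCHIP resampling to a
   0–100% gait-cycle grid (101 points), pointwise averaging;
4. z-standardization `Z = (X − μ)/σ` of the mean gyro and mean pressure
   stride and their superposition into one fused waveform per foot;
5. the **Dynamic Time Warping distance** between the left and right
   fused waveforms,

   `D(i,j) = Dist(i,j) + min{D(i−1,j), D(i,j−1), D(i−1,j−1)}`,
   `DTW(X,Y) = D(m,n)`,

   with squared sample difference as local cost, no window and no
   path-length normalization. Identical waveforms give exactly 0.

The classical indices (`100·ln(left/right)` of stride duration, swing
duration and maximum angular velocity) and a Mann–Whitney group test are
included for benchmarking, and a parametric synthetic gait generator
(normal plus a graded hemiplegic preset, with ground-truth event times)
makes the whole pipeline testable without recorded data.

## Worked example

```r
library(gaitdtw)

walk_sym  <- synth_walk(gait_params(seed = 1))
walk_asym <- synth_walk(gait_params(seed = 1),
                        asymmetry_preset(severity = 1, side = "right"))
walk_metrics(walk_sym)
#> <walk_metrics>
#>   stride duration SI            0.000
#>   swing duration SI            -0.224
#>   max angular velocity SI       0.090
#>   DTW distance                  0.008
walk_metrics(walk_asym)
#> <walk_metrics>
#>   stride duration SI            0.000
#>   swing duration SI           -25.630
#>   max angular velocity SI      51.270
#>   DTW distance                 27.954
```

The symmetric walk scores near zero on every metric. The hemiplegic
preset (right ankle restricted) leaves the stride-duration index at zero
— both feet share the stride period, which is exactly why stride time is
an insensitive asymmetry marker — while the prolonged right swing drives
the swing index negative, the attenuated right swing peak drives the
peak-velocity index positive, and the DTW distance between the fused
waveforms grows by three orders of magnitude.

Group comparison over two cohorts of 10 walks:

```r
sym  <- synth_cohort(10, gait_params(), seed = 100)
asym <- synth_cohort(10, gait_params(),
                     asymmetry_preset(severity = 1, side = "right"),
                     seed = 200)
for (cmp in compare_groups(sym, asym)) print(cmp)
#> stride_duration_si           0.01 +/- 0.07         0.03 +/- 0.06     U=37     p=0.327
#> swing_duration_si           -0.22 +/- 0.78       -25.38 +/- 0.32     U=100    p=1.083e-05
#> max_angular_velocity_si     -0.00 +/- 0.06        51.11 +/- 0.06     U=0      p=1.083e-05
#> dtw_distance                 0.09 +/- 0.13        28.24 +/- 0.24     U=0      p=1.083e-05
```

Columns are mean ± sd for each condition, the Mann–Whitney U and its
exact two-sided p-value (2/C(20,10) at complete separation of 10 vs 10).
Stride duration does not separate the groups; swing duration, peak
angular velocity and the DTW distance all do.

## Command line

```sh
Rscript exec/gaitdtw simulate --out cohort_sym/  --n-walks 10 --severity 0 --seed 1
Rscript exec/gaitdtw simulate --out cohort_hemi/ --n-walks 10 --severity 1 --seed 2
Rscript exec/gaitdtw detect   --input cohort_sym/walk01/left.csv --out events.json
Rscript exec/gaitdtw analyze  --left cohort_sym/walk01/left.csv \
                              --right cohort_sym/walk01/right.csv --out metrics.json
Rscript exec/gaitdtw compare  --group-a cohort_sym/ --group-b cohort_hemi/ --out table.json
```

Every output directory gets a `run_manifest.json` (config, seed, package
version) so runs reproduce bit-for-bit. A YAML config with any subset of
`pipeline_config()` fields can be passed via `--config`.

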