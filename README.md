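# gaitrod

Drift-free estimation of leg-segment and joint angles during gait from
**dual-accelerometer arrays**: two biaxial accelerometers mounted 55 mm
apart on a rigid rod strapped along each leg segment (thigh, shank, foot),
sampled at 100 Hz. The package is aimed at movement-analysis researchers
and engineers who want sagittal-plane knee and ankle kinematics from
accelerometers alone — no gyroscopes, no magnetometers, no camera lab —
plus a rigid-body gait simulator that makes the whole pipeline testable
with exact ground truth.

## The method

With sensors at `r_1,2 = r_0 ∓ l/2` on a rigid rod, the difference of the
two equivalent accelerations cancels gravity and centroid translation
exactly:

```
a_2 − a_1 = l̈ = l·α·i_x − l·ω²·i_y
```

so `Δa_x/l` measures the segment's angular acceleration `α = φ̈` and
`Δa_y/l` measures `−ω²`. Instead of double-integrating `α` (whose bias
drifts as `b·t²/2`), the angle is reconstructed in the frequency domain:
double integration is multiplication by `−1/ω²`, and in the roll-off
region a low-pass filter's response is proportional to `ω₀²/ω²`. A
first-order Butterworth low-pass applied forward and backward in time
(zero phase, magnitude `1/(1+(ω/ω₀)²)`), cascaded with a steep 8th-order
high-pass and divided by `−ω₀²`, double-integrates every gait harmonic
above the cutoff while *suppressing* drift instead of accumulating it. The
static offset removed by filtering is restored by using the sensors as
inclinometers during ≥ 2 s of quiet standing. Joint angles are
reconstructed by filtering the difference of the two adjacent segments'
`α` estimates (knee: thigh − shank; ankle: shank − foot).

The cutoff adapts to cadence: for knee angles `f0 ∈ [f_gc/3, f_gc/2]`
(geometric midpoint `f_gc/√6` by default), for ankle angles about twice
that, where `f_gc = 1/T` is the gait-cycle frequency — estimated, if
unknown, from the angular-acceleration spectrum.

## Worked example

```r
library(gaitrod)

cfg   <- gait_config(stride_period = 1, n_strides = 10, seed = 1)  # f_gc = 1 Hz
trial <- simulate_trial(cfg)          # 3 instrumented segments + ground truth

spec <- design_pseudo_integrator(select_cutoff(1, "knee"), fs = 100)
knee <- joint_angle(trial$streams$thigh, trial$streams$shank, "knee", spec)
ref  <- data.frame(time_s = trial$truth$time_s, angle_deg = trial$truth$knee_deg)
agreement(knee, ref, trial$stride_bounds)
#> agreement: RMSE 2.46 deg, PCC 0.9986 (800 samples, 2 strides excluded)
```

The reconstructed knee angle tracks the (noisy, 12-bit-quantized) synthetic
trial's ground truth to 2.5° RMSE with correlation 0.999, evaluated on the
interior strides only (the first and last stride of every trial are
excluded by protocol). The residual is dominated by the known
`1/(1+(ω₀/ω)²)` roll-off attenuation of the fundamental, not by drift: the
same trial pushed through plain cumulative double integration
(`naive_double_integration()`) diverges parabolically within seconds.

The same functions drive a shell pipeline:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/gaitrod.R", package = "gaitrod"))')
Rscript $CLI simulate --out sim
Rscript $CLI estimate --thigh sim/thigh.csv --shank sim/shank.csv \
                      --foot sim/foot.csv --f0 auto --out angles.csv
#> estimate: f_gc = 1.001 Hz, f0(knee) = 0.409 Hz, f0(ankle) = 0.817 Hz
Rscript $CLI evaluate --est angles.csv --ref sim/truth.csv \
                      --strides sim/strides.json --out report.json
#> evaluate: knee RMSE 2.46 deg, PCC 0.9986
#> evaluate: ankle RMSE 1.11 deg, PCC 0.9964
```

Sensor streams are plain CSV (`time_s,a1x,a1y,a2x,a2y`, m/s²) with a JSON
sidecar (sampling rate, inter-sensor distance, standing windows), so real
recordings in the same format drop straight into `read_stream()` /
`estimate`.

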