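# radarhr

Multi-target heart-rate estimation from FMCW MIMO radar data cubes, in R.

Non-contact vital-sign monitoring with a 77 GHz frequency-modulated
continuous-wave (FMCW) radar works because the intermediate-frequency beat
signal carries a subject's distance in its frequency,
`f_IF = 2 S d0 / c`, and sub-millimetre chest motion in its phase,
`phi(t) = 4 pi f_c (d0 + s(t)) / c`. With several people in the scene the
problem becomes: detect everyone in range, separate co-range subjects in
azimuth with a virtual MIMO array, and then pull a ~0.5 rad heartbeat
component out from under a ~13 rad respiration swing — per person, once a
second. This package is for signal-processing researchers and engineers who
want a tested, scriptable reference implementation of that chain.

The stages, each usable on its own:

* **Scene simulator** (`radar_config`, `vital_profile`, `radar_scene`,
  `simulate_cube`, `two_tone`, `add_awgn`) — seeded synthetic IF data cubes
  (fast time x slow time x channel) with respiration + heartbeat phase
  modulation, static clutter and white noise.
* **Range processing** (`range_fft`, `remove_clutter`,
  `two_stage_accumulate`, `os_cfar`, `hdbs`, `detect_ranges`) — range-time
  maps, zero-Doppler clutter removal, channel/chirp accumulation, and
  range-bin detection by ordered-statistics CFAR plus DBSCAN clustering
  with per-cluster slow-time energy argmax.
* **Angle processing** (`doppler_accumulate`, `root_music`,
  `mvdr_separate`) — Doppler-domain snapshot accumulation, Root-MUSIC
  direction finding on the virtual 8-element array, and MVDR (Capon)
  beamforming separation of subjects sharing a range bin.
* **Heartbeat extraction** (`extract_phase`, `vmd_decompose`,
  `select_heartbeat_mode`, `lmd_decompose`, `correlation_select`,
  `wavelet_denoise`, `vlw_pipeline`) — phase unwrapping and the cascaded
  VMD -> LMD -> wavelet-threshold denoiser.
* **Frequency estimation** (`fiib`, `fiib_real`, `fft_peak`, `music_freq`,
  `crb_frequency`, `pick_heart_rate`) — fast iterative interpolated
  beamforming: super-resolution multi-tone estimation by iterative
  Dirichlet-kernel leakage subtraction and two-point interpolated-DFT
  refinement. The real-valued variant works only in the positive half-band,
  reconstructs the conjugate components analytically, and halves the
  fine-stage leakage evaluations (18 vs 36 per iteration at L = 4).
* **Orchestration** (`run_pipeline`, `track_heart_rate`, `sliding_windows`,
  `hr_metrics`, `bland_altman`, `mc_benchmark`) — cube to per-target
  heart-rate series in 25.6 s windows hopped by 1 s, evaluation metrics
  (MAE, RMSE, relative range error, Bland-Altman), and the seeded
  Monte-Carlo estimator benchmark against the Cramér-Rao bound.

A thin command-line interface (`exec/radarhr`) exposes `simulate`,
`detect`, `estimate-hr`, `benchmark` and `vlw-demo` over text scene/cube
containers and CSV outputs.

## Worked example

Two subjects on boresight, 0.8 m and 1.5 m from the radar (the rear one
occluded), heart rates 74.0 and 87.0 bpm, 40 s at 20 dB SNR:

```r
library(radarhr)

scene <- radar_scene(
  targets = list(
    radar_target(0.8, 0, vital_profile(heartbeat_frequency = 1.233)),
    radar_target(1.5, 0, vital_profile(respiration_frequency = 0.25,
                                       heartbeat_frequency = 1.45,
                                       respiration_phase = 1.1))),
  snr_db = 20, duration = 40, seed = 42)

fit <- run_pipeline(simulate_cube(scene))
fit
#> radar HR fit: 2 target(s) from 6 segment(s)
#>   target 1: 0.81 m (bin 19), -0.0 deg, median HR 74.0 bpm
#>   target 2: 1.50 m (bin 35), +0.0 deg, median HR 87.0 bpm
```

Both subjects are found within one range bin (4.3 cm) and both tracked
heart rates land on the ground truth; `summary(fit)` returns the per-target
table and `fit$targets[[i]]$hr` the 1 Hz time series.

The estimator core on the classic two-tone test (1.05 and 1.25 Hz, 10 s at
20 Hz — only two FFT bins apart) at 25 dB SNR:

```r
est <- fiib_real(add_awgn(two_tone(), 25, seed = 1), L = 4, fs = 20)
est
#> FIIB estimate (fiib_real, L = 4, 10 fine iteration(s))
#>  frequency_hz amplitude phase_rad
#>          1.05    0.4969    -1.564
#>          1.25    0.3990    -1.584
#>         18.75    0.3990     1.584
#>         18.95    0.4969     1.564
```

The two tones are resolved off-grid to sub-millihertz error (a sine of
amplitude A appears as a conjugate pair of amplitude A/2; the mirrored
18.75/18.95 Hz rows are the reconstructed negative frequencies).

## Acceptance script

`scripts/acceptance.R` re-runs the Monte-Carlo frequency-estimation study
from scratch — 1000 seeded two-tone trials per operating point through the
package's own estimators — and writes the resulting error statistics
(improved-FIIB and FFT-baseline MSE at 25 dB SNR, and the improved-FIIB
per-component RMSE at 0.6x-resolution tone spacing at 20 dB) as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Further reading

`vignettes/fmcw-heart-rate.Rmd` documents the signal model, every tunable
parameter with units and defaults, the synthetic world's assumptions, and
the numerical design choices (CFAR constants, VMD initialization, the
correlation-gate reference, wavelet thresholding depth, FIIB update
formulas) with their rationale.
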