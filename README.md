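# pulsechain

Pulse rate variability (PRV) from wrist-worn photoplethysmography, with an
ECG-derived heart rate variability (HRV) reference chain and the metrics to
compare the two.

Wearable PPG is cheap and comfortable, but lighting changes, taps on the
watch, arm movement and breathing all corrupt the waveform, and every
mis-detected pulse corrupts the interval series derived from it. This
package implements a processing chain that reduces those artifacts using the
PPG alone, while preserving the frequency content (LF 0.04–0.15 Hz,
HF 0.15–0.4 Hz) that makes PRV diagnostically useful:

1. **Wavelet band filtering** — maximal-overlap discrete wavelet transform
   (undecimated, shift-invariant, perfect reconstruction). PPG: coif1, keep
   the 0.78–3.12 Hz detail bands (pulse rates 47–187 bpm). ECG: sym4, drop
   the 16.25–65 Hz details and the sub-0.064 Hz approximation.
2. **Amplitude demodulation** — divide the PPG by its analytic (Hilbert)
   envelope, flattening motion-induced amplitude modulation without touching
   beat timing; sliding-window standardization and an extrema-average method
   are provided as alternatives.
3. **Beat detection** — Pan–Tompkins for ECG R peaks; PDA (gated local
   maxima), AMPD (local-maxima scalogram) and SSF (slope sum function,
   Eq. `SSF_i = Σ_{k=i-w..i} max(Δx_k, 0)` with `w = 128 ms`) for PPG
   systolic peaks.
4. **Interval post-processing** — physiological screening to 0.3–1.5 s
   (merge false beats, split missed ones, conserving total duration), a
   25-sample moving mean ± 3 SD repair for PRV, cubic-spline resampling to
   10 Hz with a zero-phase 0.5 Hz low-pass and decimation to 1 Hz, and an
   AR(8), 25-sample-window one-step plausibility check that replaces samples
   deviating by more than one forecast SD.
5. **Evaluation** — dynamic time warping and aligned Pearson correlation on
   the raw (unequal-length) interval sequences; relative RMSE
   `RRMSE = 100·‖PRV − HRV‖₂/‖HRV‖₂` (%) on the uniform series, RMS-combined
   across recordings (`mrrmse`); Welch power spectral density (30 s windows,
   25-sample overlap).

A seeded synthetic module generates paired PPG/ECG recordings from an
integral-pulse-frequency-modulated beat process with LF/HF rate modulation,
plus five laboratory artifact regimes (`none`, `light`, `tap`, `arm`,
`breath`), so the whole chain is testable against known ground truth.

## Worked example

Simulate a 300 s recording with the arm-movement artifact regime, run both
chains, and compare:

```r
library(pulsechain)

res <- run_pipeline(pipeline_config(seed = 1, simulate = list(regime = "arm")))
res$report
#> comparison_report: RRMSE = 4.75%, DTW = 11.248 s, r = 0.510 (n_test = 352, n_ref = 350)
cat(res$events, sep = "\n")
#> simulated 300 s, regime arm, severity 1, seed 1
#> HRV screening: 0 merged, 0 split, 0 residual
#> PRV screening: 0 merged, 0 split, 0 residual
#> PRV local-statistics correction: 10 merged, 2 split
#> PRV AR correction: 51 samples replaced (0 skipped)
```

The report reads: after post-processing, the PRV series from the corrupted
PPG differs from the ECG-derived HRV by 4.75% relative RMSE; the DTW
distance sums 11.2 s of absolute interval mismatch along the optimal
alignment of the 352 detected pulse intervals against the 350 reference R-R
intervals. The event log shows what the corrections did: the deep
amplitude-modulation artifact produced 12 implausible intervals that the
3-sigma rule repaired. Disabling post-processing
(`post = list(screen = FALSE, outlier = FALSE, ar = FALSE)`) on the same
recording yields RRMSE = 9.38% and DTW = 13.5 s — the repairs halve the
error. On a clean recording (`regime = "none"`) the same toggles change
RRMSE by under 0.3 points: the corrections only matter when the signal is
actually corrupted.

Individual stages are ordinary functions on plain containers:

```r
sim  <- simulate_recording(beat_process_params(duration = 300, seed = 7))
ppg  <- hilbert_demodulate(filter_ppg(sim$ppg))   # filter + demodulate
beats <- pda(resample_cubic(ppg, 250))            # systolic peaks
prv  <- to_uniform(beats_to_intervals(beats))     # 1 Hz PRV series
welch_psd(prv)                                    # spectrum
band_edges(25, 4)                                 # $f_lo 0.78125, $f_hi 1.5625
```

A command-line wrapper with subcommands `simulate`, `filter`, `demod`,
`detect`, `prv`, `sync-envelope`, `evaluate`, `run` is installed at
`inst/cli/pulsechain.R`:

```sh
Rscript inst/cli/pulsechain.R run --regime tap --seed 7 --out-dir out/
```

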