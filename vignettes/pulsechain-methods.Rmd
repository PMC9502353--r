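---
title: "Extracting pulse rate variability from wrist PPG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting pulse rate variability from wrist PPG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsechain)
```

## The problem

Wrist-worn devices measure a photoplethysmogram (PPG): an optical
blood-volume waveform with one pulse per heartbeat. The series of
pulse-to-pulse durations — pulse rate variability (PRV) — is the wearable
surrogate for heart rate variability (HRV) computed from ECG R-R intervals.
What makes PRV valuable is its frequency content: the low-frequency band
(0.04–0.15 Hz) and high-frequency band (0.15–0.4 Hz) reflect autonomic
regulation. What makes it fragile is the PPG itself: ambient-light changes,
sensor taps, arm movement and breathing all distort the waveform, and any
beat mis-detection corrupts the derived intervals.

`pulsechain` implements a complete chain from raw PPG to a post-processed
PRV series, the parallel ECG reference chain, and the metrics used to score
one against the other. Because suitable raw recordings are rarely shareable,
the package also contains a first-class synthetic generator that produces
paired PPG/ECG recordings from a common beat process with known ground
truth, plus the five laboratory artifact regimes; every stage of the chain
is tested against that ground truth.

## The processing chains

**ECG reference chain.** The ECG (nominally 130 Hz) is band-filtered with a
maximal-overlap discrete wavelet transform using the sym4 wavelet, whose
shape resembles a QRS complex. Ten decomposition levels put the
approximation below 130/2^11 ≈ 0.064 Hz; the approximation (baseline wander)
and the two finest detail levels (16.25–65 Hz noise) are discarded and the
signal is rebuilt from the remaining levels. R peaks are then found with the
Pan–Tompkins detector (`pan_tompkins()`): derivative, squaring, 150 ms
moving-window integration, dual adaptive thresholds with search-back, a
200 ms refractory period and a T-wave slope test. The usual Pan–Tompkins
band-pass stage is omitted — the wavelet filter already did that work.

**PPG chain.** The PPG (nominally 25 Hz) is filtered the same way with the
coif1 wavelet, keeping only detail levels 3 and 4, i.e. the dyadic bands
0.78–1.56 and 1.56–3.12 Hz. Together they bracket the physiological pulse
range (47–187 bpm); everything slower (baseline wander, lighting drift) or
faster (sensor noise) is dropped. Because motion also modulates the pulse
*amplitude*, the filtered signal is amplitude-demodulated before detection.
Three methods are provided: division by a sliding-window standard deviation
(`adaptive_standardize()`), a sliding-window extrema-average method with an
adjustable gate `P` (`online_demodulate()`), and division by the magnitude
of the analytic (Hilbert) extension (`hilbert_demodulate()`). The analytic
envelope is the default: it is parameter-free and leaves zero crossings and
peak timing untouched, which is all that matters for interval extraction.

Systolic peaks are detected by one of three detectors: a gated local-maximum
search (`pda()`, accepting maxima above 0.8 of the surrounding 2 s maximum),
automatic multiscale peak detection (`ampd()`, choosing the dominant
periodicity scale from a local-maxima scalogram computed per ~30-pulse
segment with 50% overlap), or the slope sum function (`ssf_detect()`, a
128 ms trailing sum of positive first differences with an adaptive
threshold: initialized to the mean SSF over the first 10 s and reset to 40%
of each pulse's SSF maximum). SSF marks pulse onsets; each onset is refined
to the systolic maximum within the following 0.3 s (with a half-window
look-back for late crossings) so that all three detectors emit comparable
fiducials. For devices that record the PPG upside-down, `reflect = TRUE`
flips the signal before both the SSF and the peak search; the synthetic
waveforms are generated peak-up, so the pipeline default is `FALSE`.

**Post-processing.** Intervals outside 0.3–1.5 s (200–40 bpm) are screened
in one left-to-right pass: a too-short interval marks its ending beat as an
artifact and is folded into the following interval, a too-long interval
(missed beat) is split in half; total duration is conserved and residual
violations are logged rather than silently re-processed. PRV intervals are
additionally checked against a 25-sample moving mean ± 3 SD and repaired by
the same merge/split rules (the two-sided Gaussian 3-sigma tail is 0.0027,
so under clean conditions fewer than 0.3% of valid samples are touched; a
zero-SD window treats every sample as inside the band). Both series are then
resampled: cubic-spline interpolation onto a 10 Hz grid, zero-phase FIR
low-pass at 0.5 Hz (151 taps at 10 Hz, DC gain normalized to exactly 1,
reflection padding against end transients; the order shrinks automatically
for short series), and decimation to 1 Hz. Finally the PRV series gets an
autoregressive plausibility check: an AR(8) model is fitted by Burg's method
to each 25-sample window and the next sample is replaced by its one-step
prediction when it deviates by more than one forecast SD.

Two AR details deserve emphasis because they are where a naive
implementation goes wrong. First, the in-sample innovation variance of an
order-8 fit on 25 points is optimistic; the gate uses the forecast SE
inflated for estimation uncertainty, `sqrt(var_pred * (1 + p/w) * w/(w - p -
1))`. Second, predictions are always formed from the *observed* history, not
from previously replaced values: feeding replacements back makes each window
smoother, shrinks the apparent innovation variance, and cascades until
essentially every sample is "corrected" (~98% on a clean AR(2) realization
in our experiments). With both details in place, a clean AR(2) process sees
~35% of samples touched (each by less than one innovation SD, harmless by
construction) while isolated 10-SD spikes are all caught and replaced to
within 3 innovation SD of the uncontaminated values.

**Evaluation.** Raw PRV and HRV interval sequences generally differ in
length, so they are compared by dynamic time warping (unit-weight symmetric
steps, no window constraint, cost `|a_i − b_j|`) and by the Pearson
correlation of the DTW-matched pairs. The uniform 1 Hz series are compared
by relative RMSE, `100 · ‖PRV − HRV‖₂ / ‖HRV‖₂` (%), aggregated across
recordings as the RMS (`mrrmse()`). Spectra come from Welch's method: 30 s
Hamming-tapered segments, 25-sample overlap, per-segment taper-weighted
demeaning (which zeroes the DC bin exactly), one-sided density
normalization.

## The synthetic generator

`simulate_beats()` draws beats from an integral pulse frequency modulation
model: the instantaneous rate is `mean_hr + lf_amp·sin(2π·lf_freq·t) +
hf_amp·sin(2π·hf_freq·t)` and a beat fires at each integer crossing of its
integral. Defaults — 300 s, 70 bpm, LF 2 bpm at 0.1 Hz, HF 3 bpm at 0.25 Hz,
2 ms timing jitter — describe a resting adult with both autonomic bands
populated (respiratory modulation slightly dominant, as at rest). The PPG is
a superposition of a gamma-shaped systolic lobe with a diastolic bump at
0.35 of its amplitude, the peak landing 0.25 s after each beat (a constant
pulse transit offset); the ECG is a biphasic QRS-like template (~90 ms wide,
so its energy sits in the 5–15 Hz band) with small P and T lobes, centered
exactly on the beats.

`inject_artifacts()` reproduces the five laboratory regimes. `light` adds a
square wave with 10 s half-period. `tap` models a finger tap every second
for the first half and every two seconds for the second half; each tap is a
biphasic motion transient (derivative-of-Gaussian, σ = 80 ms, so its energy
lies inside the pulse band) of four signal-SDs *plus* a ±0.25 s
sensor-contact loss, because a physical tap briefly decouples the sensor —
it is the contact loss, not the spike alone, that produces the erroneous and
missed peaks characteristic of tap recordings. `arm` applies a 20 s-period
amplitude modulation deep enough to extinguish the pulse at its trough
(raised arm, drained wrist) plus slow 0.05 Hz baseline wander. `breath` adds
a mild baseline at the guided breathing rates (5 then 30 breaths/min); the
physiological effect of breathing on the beat process itself belongs in
`simulate_beats()` via the HF modulator, not in the waveform. All regimes
add severity-scaled Gaussian sensor noise (SD 5% of signal SD at severity
1), and severity 0 is the identity.

What the generator does *not* emulate: morphological beat-to-beat pulse
shape variation, pulse-transit-time modulation (the offset is constant),
drifting sensor gain, ectopic beats, and the device-specific quantization of
real smartwatches. Passing tests therefore demonstrate that the chain
recovers intervals correctly under controlled, artifact-typed corruption —
not that it is validated on real wrist recordings.

## Numerical choices

- **Wavelet boundary.** The maximal-overlap transform uses circular
  extension, which keeps perfect reconstruction exact (observed ≤ 1e-12
  relative error); edge-adjacent samples are boundary-affected, which is why
  waveform-level tests evaluate drift rejection on windows long enough to
  hold at least one cycle of the slowest component.
- **Coefficient handling.** Levels are kept or dropped wholesale; no
  thresholding. Band filters are exactly linear.
- **Detection rates.** Detectors run on cubic-spline upsampled signals: PPG
  at 250 Hz (4 ms quantization, the commonly accepted resolution floor for
  HRV frequency analysis) and ECG at 260 Hz. `resample_cubic()` itself
  defaults to 1000 Hz for standalone use; the pipeline uses the lower rates
  because AMPD's scalogram cost grows quadratically with the rate.
- **Printing of band edges.** Two-decimal truncation, not rounding (3.125
  prints as 3.12); the bpm range is reported with inner rounding
  (ceiling of the lower edge, floor of the upper: 46.875 → 47, 187.5 → 187).
- **Ties and degenerate cases.** A zero-SD moving window counts every sample
  as inside the 3-sigma band; constant AR windows skip correction; zero-SD
  demodulation windows fall back to an epsilon guard (1e-12 of the global
  SD) and are logged; DTW backtracking prefers the diagonal on ties.
- **SSF threshold referent.** The initial threshold is the mean of the *SSF*
  over the first 10 s (a threshold must live on the SSF scale), applied from
  the start of the record so no leading beats are lost.
- **PDA threshold referent.** The 0.8 gate is interpreted relative to the
  rolling 2 s maximum of the demodulated signal, which is meaningful because
  demodulation gives a near-unit envelope.
- **AMPD segmentation.** Segment duration is `expected_peaks / dominant
  rate`, the rate estimated from the periodogram peak in 0.5–3 Hz; segments
  overlap 50% and duplicates within 0.1 s keep the earlier detection.

## Design choices on open questions

- The physiological screening bounds are 0.3–1.5 **seconds**; their bpm
  equivalents (200 and 40) fix the unit.
- Out-of-band outliers map onto the interval rules by direction: above the
  band → split (a missed beat), below → merge into the successor (a false
  beat); a trailing short interval merges into its predecessor so duration
  is conserved.
- The 3-sigma correction operates on beat-indexed durations *before*
  resampling, matching the order of the post-processing stages.
- The AR window is 25 samples; a 25-parameter model cannot be fitted stably
  on 25 points, so the order is 8 — wide enough for the two spectral peaks
  plus colored detection noise, small enough to leave 16 residual degrees of
  freedom.
- DTW uses raw interval durations in seconds, unnormalized; every matched
  path pair contributes once to the aligned correlation.
- Welch tapering uses a Hamming window with constant (taper-weighted)
  detrending per segment.

## What the tests exercise, and known limitations

The test suite (seeded throughout; recordings of 300 s, ten replicate seeds
where medians are asserted) verifies, among others: perfect reconstruction
over random signals for both wavelets; exact agreement of the DTW distance
with brute-force path enumeration on 200 small instances; recovery of the
ground-truth variability series by the full chain with each detector at
RRMSE < 3% on clean recordings; strictly smaller median DTW with
post-processing enabled under the tap and arm regimes, with a sub-1-point
RRMSE change on clean recordings; and identical Welch peak bins for
recovered PRV and ground truth under LF-dominant modulation.

Limitations worth knowing:

- **HF attenuation.** The PPG chain attenuates 0.25 Hz interval modulation
  by roughly 30% in power relative to the ECG chain: the band-filtered pulse
  shape interacts with the local rate, so the detected peak wanders slightly
  with the modulation itself. All three detectors agree with each other
  (≥ 99% within one sample) — the wander is common mode — but spectral
  comparisons near the top of the HF band should be interpreted with care.
  This is why the spectral-fidelity check is defined on the LF-dominated
  simulation.
- **Structurally dead merge rule on detector output.** Every detector
  enforces a refractory separation of at least 0.3 s, so detector output can
  never contain sub-0.3 s intervals; the screening merge rule only fires on
  externally supplied interval series. Repair of tap corruption consequently
  comes from the split rule and the 3-sigma correction, and is modest —
  consistent with tap being the hardest regime.
- **The online demodulation method** retains a small residual envelope
  (ratio ~1.24 from a 3:1 input on the reference AM tone): its P gate
  excludes sub-threshold extrema near amplitude troughs, biasing the divisor
  upward. The analytic-envelope method does not share this bias and is the
  default.
- **AR correction on clean data** still touches ~15–35% of samples (each by
  less than one forecast SD). Its net RRMSE effect on clean recordings is
  below 0.3 points in our conditions, but like the source method it should
  be reserved for visibly corrupted recordings.

## Reproducing the headline numbers

`scripts/acceptance.R` re-runs the whole chain from scratch — band-edge
arithmetic, reconstruction and DTW oracles, clean-chain recovery per
detector, the artifact-regime contrast over ten seeds, and the spectral
check — and writes one JSON object of plain numbers:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
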