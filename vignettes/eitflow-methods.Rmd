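---
title: "Deriving regional respiratory gas flow from EIT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving regional respiratory gas flow from EIT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eitflow)
```

## The measurement model

Electrical impedance tomography reconstructs a cross-sectional image of
relative impedance change at high temporal resolution (13 tomograms/s for
the reference device). Regional impedance change is proportional to
regional air content, so after partitioning the 32 × 32 pixel matrix into
ventral, middle and dorsal 8 × 32 strips (the dorsal-most strip holds no
lung in a supine pig and is excluded), the ROI pixel sum `Z_ROI(t)` is an
uncalibrated regional gas-content curve. Calibration uses the only
absolute volume available at the bedside, the ventilator tidal volume
`V_T`:

$$V_{ROI}(t) = Z_{ROI}(t)\cdot V_T / Z_T,$$

with `Z_T` the tidal amplitude of the *global* signal. A single global
`Z_T` calibrates all ROIs so that regional volumes express the regional
share of the tidal volume and stay additive. Gas flow is the backward
difference of the volume curve, defined at every sample except the first.

Four summary metrics describe the respiratory cycle per ROI and breath:
the cycle's flow maximum (PIF, early inspiration) and minimum (PEF, early
expiration), and the average slope of `V(t)` over a 3.0 s window starting
0.5 s after each peak (LIF, LEF — late inspiration/expiration). The
windowed average exists to reject the cardiac-frequency oscillation that
thoracic blood movement superimposes on the aeration signal.

## Parameters that matter

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `fs_eit` | 13 | frames/s | reference device frame rate |
| `fs_spiro` | 100 | Hz | reference spirometer rate |
| `rr`, `ie_ratio` | 8, 1:1 | /min, – | reference ventilator mode: 7.5 s cycle, 3.75 s per phase |
| `v_t` | 345 | ml | 15 ml/kg for a 23 kg animal |
| `delay`, `window` | 0.5, 3.0 | s | late-flow window placement after the peak |
| `estimator` | `"ols"` | – | late-flow slope estimator (see below) |

## Numerical choices

**Late-flow estimator.** "Average slope of the volume curve" admits two
readings: the endpoint difference quotient (equal to the mean of the
backward differences) and the least-squares slope over all window
samples. The OLS slope is the default because it is markedly more robust
to a cardiac sinusoid that does not complete an integer number of periods
inside the window: on a 12 ml/s ramp carrying a 5 ml, 1.5 Hz oscillation
the OLS estimate errs by 0.27 ml/s, the endpoint estimator by 3.1 ml/s.
The endpoint variant remains available (`estimator = "endpoint"`) for
sensitivity analysis, and is also the natural counterpart of the
spirometric late metrics, which are computed as the plain mean of the
measured flow samples in the window.

**Window snapping.** Window boundaries snap to the nearest sample with
half-up rounding. At 13 Hz the 0.5 s delay is 6.5 frames, i.e. the target
falls exactly between samples; a small relative tolerance in the snap
makes such half-grid cases resolve identically regardless of how the peak
time was accumulated in floating point. If less than 80 % of the nominal
window falls inside the record and breath, the estimate is computed on
the truncated window and flagged. With the reference timing (peak near
the phase onset, 0.5 + 3.0 s < 3.75 s) windows never truncate.

**Breath segmentation.** Inspiration onsets are upward zero-crossings of
the raw backward-difference global flow. Raw crossings alone are
unusable on noisy records, because late-expiratory flow decays to a few
ml/s — far below the pixel-noise floor of the differentiated signal. The
detector therefore (1) finds candidate inspirations as runs where a
centred ~0.4 s moving average exceeds 30 % of its maximum, (2) anchors
each run with a *trailing* (causal) ~0.7 s moving average, which cannot
leak the coming inspiratory rise backwards in time and whose width spans
about one cardiac period, and (3) places the onset at the first positive
raw-flow sample at or after the anchor. On noise-free records this
reduces exactly to the first positive backward difference; with 5 %
pixel noise onsets stay within about ±2 frames. Only the detection uses
smoothing — analysed signals are never filtered. A refractory period of
half the expected cycle (from the respiratory-rate hint) suppresses
double triggers; cycles bounded by onsets count as complete within ±50 %
of the expected duration, a trailing cycle needs ≥90 % of it, and leading
partial segments are flagged incomplete.

**Tidal amplitude.** `Z_T` is the mean over complete breaths of the
per-cycle max-minus-min of `Z_global` — not the difference of the
end-inspiratory and end-expiratory boundary samples. Max-minus-min is
immune to one-sample jitter of the detected cycle boundaries; on the
strictly periodic simulations both conventions coincide to numerical
precision.

**Peak search.** PIF/PEF are searched over the whole cycle rather than
within ventilator phase halves; ties break to the earliest sample. A
regional flow sample opposing the phase of the regional volume curve
(e.g. pendelluft-like behaviour, or simply noise) sets a quality flag;
values are reported signed and never clipped.

## The synthetic world

`simulate_record()` generates what a PCV experiment would record: three
lung compartments (mapped to the ventral/middle/dorsal strips) fill
exponentially with time constants `tau_insp` toward their share
`f_r · V_T` of the tidal volume, and empty with `tau_exp`. Inspiratory
and expiratory exponentials are normalised so each breath returns exactly
to baseline — a deliberate trade of physiological realism for exact
periodic ground truth. Defaults: fractions (0.15, 0.50, 0.35) matching a
healthy supine distribution; time constants 0.5–0.7 s (compliance around
38 ml/mbar times sub-mbar·s/ml airway resistance); cardiac sinusoid at
1.5 Hz (≈90/min) with amplitude 2 % of `V_T`, added to the middle-ROI
pixels where the heart sits; Gaussian pixel noise with sd 5 % of the
individual pixel's tidal amplitude (reconstruction noise scales with
local signal; a global-amplitude-relative convention would drown the
differentiated signal entirely); spirometer noise 1 % of peak flow. The
`lavage_preset()` rescales the dorsal fraction by 11/36 and renormalises,
emulating the loss of dependent-lung ventilation after surfactant
depletion — a generative preset, not a reproduction of animal values.

`analytic_ground_truth()` evaluates the closed-form volumes on the
discrete EIT grid and the continuous flows on the spirometry grid and
applies the *same definitions* (onset convention, calibration, window
snapping) to them, giving the exact value every pipeline stage must
recover on a noise-free record; the test suite checks this to 1e-6
relative, and pins the continuous values against a dense-grid (10 kHz)
finite-difference oracle. Note a subtlety: because the 13 Hz grid rarely
samples the exact end-inspiratory peak, the measured tidal amplitude is
slightly below `V_T`, and calibration rescales all EIT-side truths by
`V_T / amplitude` — the ground truth includes that factor.

What the simulator does **not** model: regional phase lags (compartments
start filling synchronously, so regional tidal percentages sum to
exactly 100 % rather than the >100 % sums real asynchronous lungs
produce), spontaneous breathing efforts, nonlinear compliance,
perfusion, and electrode/reconstruction physics. A green end-to-end test
therefore establishes correctness of the signal processing, not realism
of the waveforms.

**Tissue inertance option.** A first-order low-pass (`lowpass_tau`,
default off) on the EIT signal path emulates the inert reaction of lung
tissue to airway flow. Enabled at 0.1 s it acts on the peak-flow
timescale (the 77 ms frame interval) while leaving the ~0.6 s late-flow
timescale comparatively untouched, which reproduces the characteristic
proportional Bland–Altman error of the peak metrics. The late metrics
retain a smaller proportional component (roughly a third of the peak
effect) because their window still contains fast early decay; a strict
zero effect is unattainable in this world.

## Method comparison design

Per-breath pairing within one record is statistically degenerate on
clean simulations (every breath is identical), so condition-level
comparison uses `simulate_paired_metrics()`: 7 subjects of 20–26 kg with
lognormal (sd 0.4) inter-individual time-constant spread, each under
`V_T` ∈ {15, 20} ml/kg × PEEP ∈ {0, 5, 10} mbar — 42 condition pairs.
The spread matches the between-animal and between-setting variability of
the reference experiment (compliance CV ≈ 30 %) and is what makes a
slope-recovery criterion of r² ≥ 0.95 achievable at 5 % metric noise:
with equal noise on both arms, r² ≈ (CV²/(CV²+σ²))², which demands a
truth CV above ~31 %.

**Lag alignment.** EIT and spirometry are assumed to share a trigger;
`estimate_lag()` offers cross-correlation alignment (linear
interpolation to 100 Hz, no smoothing, search ±1 cycle). Periodic
signals make the lag identifiable only up to the cycle, so near-tied
correlation maxima resolve to the smallest absolute lag, and a maximum
on the search boundary raises an "unalignable records" error. The
backward-difference EIT flow intrinsically trails the continuous flow by
about half a frame; estimates below one frame are expected even for
perfectly synchronised records.

## Known limitations

- Calibration inherits any error in the ventilator-reported `V_T` and
  assumes impedance–volume linearity over the tidal range.
- The spirometry-vs-EIT late-flow equivalence (volume slope vs mean flow)
  holds to ~2 % only where late flow is genuinely slowly varying (time
  constants well above the window misalignment of ≤1 EIT frame); with
  fast time constants the two arms can differ by 10 % and more. This is
  a property of the definitions, not an implementation artifact.
- With the cardiac oscillation enabled, onset detection can jitter by a
  few frames around the true onset (the late-expiratory flow is smaller
  than the cardiac flow component); phase metrics are insensitive
  because peaks and windows live well inside the cycle.
- Regional metrics have no independent reference — only the global
  metrics are validated against spirometry; regional values rest on the
  validity of regional gas-content measurement by EIT.
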