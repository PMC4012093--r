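# eitflow

Regional respiratory gas flow from electrical impedance tomography (EIT)
during mechanical ventilation.

EIT monitors regional lung aeration as a time series of reconstructed
tomograms (here 32 × 32 pixel matrices of relative impedance change at 13
frames/s). Because the regional impedance signal tracks regional gas
content, its **first time derivative is regional gas flow** — a quantity no
other bedside method resolves regionally. `eitflow` implements that
derivation end to end, for clinicians and researchers who want to
characterise how fast different lung regions fill and empty under
pressure-controlled ventilation (PCV), and how that pattern changes with
ventilator settings or lung injury.

## Method

For ROIs ventral, middle, dorsal (8 × 32 pixel strips; the dorsal-most
strip of the matrix contains no lung in the supine pig and is excluded)
and their union (global):

1. **Regional impedance** — `Z_ROI(t)` is the sum of pixel values over the
   ROI, so `Z_global = Z_ventral + Z_middle + Z_dorsal`.
2. **Volume calibration** — `V_ROI(t) = Z_ROI(t) · V_T / Z_T`, where `V_T`
   is the ventilator tidal volume and `Z_T` the mean per-breath
   peak-to-trough amplitude of `Z_global`.
3. **Gas flow** — backward difference
   `V'_ROI(t_n) = (V_ROI(t_n) − V_ROI(t_{n−1})) / (t_n − t_{n−1})`.
4. **Four phases per breath** — peak inspiratory/expiratory flow
   (PIF = cycle maximum of `V'`, PEF = minimum) for early inspiration and
   expiration, and late inspiratory/expiratory flow (LIF, LEF) as the
   average slope of `V(t)` over a 3.0 s window starting 0.5 s after the
   respective peak (the window averages away the cardiac oscillation).

Method comparison against simultaneous 100 Hz spirometry uses per-metric
ordinary least squares (`EIT = a · spiro + b`, r²) and Bland–Altman
statistics (bias, 95 % limits of agreement, proportional slope). Regional
ventilation distribution is reported as per-breath regional tidal
amplitude percentages.

A multi-compartment PCV simulator (`simulate_record()`) with exponential
filling/emptying, cardiac artifact, pixel noise, and closed-form ground
truth (`analytic_ground_truth()`) makes every stage testable without
animal data.

## Worked example

```r
library(eitflow)
sim <- simulate_record(vent = ventilator_settings(v_t = 345),
                       model = lung_model_config(), seed = 1)
ana <- analyze_record(sim$frames, v_t = 345, rr = 8)
print(ana)
```

```
<eit_analysis> 8 complete breaths, Z_T = 3.579
  global PIF:   536.75 +/- 53.90 ml/s
  global LIF:    26.34 +/- 0.94 ml/s
  global PEF:  -517.48 +/- 54.42 ml/s
  global LEF:   -25.74 +/- 1.37 ml/s
tidal volume distribution over 8 breaths:
  ventral 14.5%  middle 51.9%  dorsal 34.0%
```

The 60 s record at respiratory rate 8/min contains 8 breaths. Peak flows
around ±530 ml/s dwarf the late flows around ±26 ml/s: most filling and
emptying happens early in each phase. The tidal volume distributes
according to the configured regional amplitude fractions (15/50/35 %),
recovered here from the noisy pixel data.

Condition-level method comparison (7 simulated subjects × 6 ventilator
settings, 5 % noise, EIT arm on the 13 Hz grid):

```r
pairs <- simulate_paired_metrics(n_subjects = 7, noise_rel = 0.05,
                                 seed = 1, arm = "grid")
for (met in c("pif", "lif", "pef", "lef")) {
  d <- pairs[pairs$metric == met, ]
  print(linear_regression(d$spiro, d$eit))
}
```

```
PIF: EIT = 0.838 * spiro +48.1, r^2 = 0.962 | bias -71.9 ml/s, LoA [-185.0, 41.1]
LIF: EIT = 0.912 * spiro -16.4, r^2 = 0.922 | bias -21.2 ml/s, LoA [-31.6, -10.9]
PEF: EIT = 0.839 * spiro -32.8, r^2 = 0.955 | bias 86.0 ml/s, LoA [-26.3, 198.3]
LEF: EIT = 0.913 * spiro +17.7, r^2 = 0.904 | bias 22.6 ml/s, LoA [11.4, 33.8]
```

EIT-derived absolute flow runs smaller than spirometry (slopes < 1,
peak metrics more so than late metrics): the 13 Hz backward difference
averages the fast early-phase flow transient that 100 Hz spirometry
resolves.

## Command line

```sh
exec/eitflow simulate --out run1 --seed 1
exec/eitflow analyze  --eit run1/eit_frames.txt --out run1 --vt 345 --rr 8
exec/eitflow compare  --eit run1/eit_frames.txt --spiro run1/spiro.txt --out run1
```

Every run writes the resolved configuration next to its outputs. File
formats are plain text (see `?write_eit_frames`, `?write_spiro`).

## Units

Volumes in ml, times in s, flows in ml/s, throughout.
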