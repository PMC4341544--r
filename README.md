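# erpperm

Simulation and permutation-based inference for ERP priming experiments:
a complete, tested pipeline for the overt-priming lexical-decision design
in which each verb target (e.g. *ziehen*) is preceded by an unrelated (U),
semantically related (S), morphologically related transparent (T),
morphologically related opaque (O), or form-related (F) prime, and the
question is whether semantic transparency modulates morphological priming
in the N250/P325/N400 range.

The package is written for cognitive electrophysiologists who want the
*statistical procedure* — not a particular dataset — as executable,
verifiable code:

- **Design generator**: Latin-square rotation of the five primes per target
  over ten blocks (targets in every second block, once per condition), 540
  fillers dealt evenly, within-block randomization under a
  lexicality-run-of-four constraint. A default session has 720 trials, 72
  per block, 180 critical pairs (25%).
- **Epoch simulator**: Gaussian component templates (N250, P325, N400,
  frontal form positivity) × scalp topography × per-condition amplitude,
  log-normal subject gains, AR(1) band-limited trial noise, injectable
  step/drift artifacts, response-error flags; fully seed-deterministic.
- **Preprocessing**: drift correction (linear stand-in), artifact rejection
  (voltage step > 50 µV or peak-to-peak > 100 µV), baseline correction to
  the half-open [−100, 0) ms window, pooling of 61 recording electrodes to
  the 19 standard 10–20 sites (3 per pool), per-condition averaging of
  correct trials.
- **Inference**: pointwise paired t statistics; running-t ROI detection
  (|t| above the two-tailed 5% Student bound for ≥ 50 ms); sign-flip
  **max-t permutation**: each draw flips every subject's whole difference
  array by ±1, the maximum |t| over all ROI points is recorded, the
  nearest-rank 95th percentile is the critical value, p = (1 + #{null ≥
  observed}) / (1 + B). The T−O test is restricted to the S−U ROI; the
  double difference (O−F)−(T−S) contrasts form against meaning.
- **Calibration**: `calibrate_fwer()` measures the family-wise error of the
  whole chain on null simulations — and demonstrates why testing a
  contrast inside a ROI selected from *that same contrast* is only
  descriptive.

The core statistic, for subject differences $d_i(k,t)$ at channel $k$ and
sample $t$:

$$t(k,t) = \frac{\bar d(k,t)}{s_d(k,t)/\sqrt{n}}, \qquad
t_{\max} = \max_{(k,t)\,\in\,\mathrm{ROI}} |t(k,t)|$$

with the null distribution of $t_{\max}$ generated by $d_i \mapsto \pm d_i$
per subject (whole array, preserving spatio-temporal correlation).

## Worked example

```r
library(erpperm)

cfg <- run_config(
  sim = simulation_params(n_subjects = 17, channels = standard_channels(),
                          fs = 250, epoch_window = c(-100, 800),
                          noise_sd = 10, noise_ar1 = 0.9, lowpass_hz = NA,
                          artifact_step_rate = 0.03, error_rate = 0.05,
                          seed = 2026),
  analysis = analysis_config(n_perm = 2000, seed = 2026),
  design_args = list(filler_spec = c()),   # critical pairs only
  pool = FALSE,                            # simulate the 19 pooled channels
  roi_time_window = c(0, 800))

report <- run_pipeline(cfg)
```

The seven contrasts of the suite (output of `analysis/03_contrasts.R`,
which runs exactly this configuration):

```
     contrast  roi_source roi_points observed_tmax critical_t p_value n_sig_points
1         S-U         S-U        207          9.00       4.27  0.0005           16
2         T-U         T-U        404          6.93       4.58  0.0025           40
3         O-U         O-U        588          7.45       4.65  0.0010           91
4         F-U         F-U         37          4.49       3.29  0.0065           15
5         T-O         S-U        207          2.78       4.35  0.6532            0
6         O-F         O-F        236          6.51       4.21  0.0030           31
7 (O-F)-(T-S) (O-F)-(T-S)        105          6.03       3.80  0.0020           25
```

Read: every priming condition differs reliably from the unrelated baseline
(S−U, T−U, O−U, F−U significant after max-t correction), the form and
double-difference controls come out (O−F, (O−F)−(T−S)), but T−O — tested
inside the semantic-priming ROI — stays null: transparent and opaque
derivations prime their base alike, which is the generator's injected
ground truth (equal T and O amplitudes). Grand-average 400–600 ms
centro-parietal means reproduce the injected negativity rank order
T ≈ O < S < F < U.

The numbered drivers under `analysis/` narrate the stages and write their
tables to `results/`: `01_design.R` (session structure and letter-overlap
statistics), `02_simulate_preprocess.R` (rejection audit, condition means),
`03_contrasts.R` (the table above, significance tables, full JSON report),
`04_fwer_calibration.R` (null calibration, confirmatory vs self-test
layout).

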