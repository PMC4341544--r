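---
title: "Simulating and testing ERP priming effects with sign-flip max-t permutation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and testing ERP priming effects with sign-flip max-t permutation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Overt-priming lexical-decision experiments measure how the event-related
potential (ERP) to a target word changes with its relation to a preceding
prime. The design this package implements has five within-subject prime
conditions on each critical verb target — unrelated (U), purely semantically
related (S), morphologically related and semantically transparent (T),
morphologically related but opaque (O), and form-related (F) — and asks
whether transparency changes morphological priming: does T differ from O?

The electrophysiological signatures are deflections of the ERP: an N250 and
a strong centro-parietal N400 whose amplitude attenuates with prime
relatedness (rank order of negativity T ≈ O < S < F < U), a P325 enhanced by
morphological primes, and an early right-frontal positivity for form-related
primes.

Because multichannel ERP time series yield thousands of correlated
(electrode, time point) tests, the inferential machinery is the interesting
part: a running-t region-of-interest (ROI) rule plus a sign-flip maximum-t
permutation test that controls the family-wise error rate (FWER). The raw
EEG of the original study is not available, so every stage runs on a
synthetic generator whose structure matches the study design; all claims the
package makes are therefore claims about the *procedure*, demonstrated on
simulated data, not about real brains.

## Experimental design generator

`build_session()` rotates the five primes of each of 36 targets over ten
blocks by a Latin-square scheme: a target appears in every second block
(five blocks of one parity), once per condition, with the condition order
cyclically shifted by target index and participant. This yields the exact
all-ones target × condition incidence and guarantees that a target never
occurs in adjacent blocks. 540 filler pairs (180 word targets, 180 unrelated
pseudoword targets, 180 pseudoword targets form-related to the critical
verbs) are dealt evenly over blocks so each block holds 72 trials, half with
word targets; critical pairs are 25% of the material. Within a block, order
is randomized by rejection sampling (cap 1,000 retries) under the constraint
of at most four adjacent targets of equal lexicality; the constraint is
skipped for degenerate single-lexicality blocks, where it is unsatisfiable
and meaningless.

The geometry requires `n_blocks = 2 × n_conditions` and an even number of
targets — this is the "every second block" scheme itself, stated as a
precondition rather than silently relaxed.

The synthetic lexicon (`make_stimulus_set()`) emulates only *structural*
properties: pseudo-German infinitives (stem + *-en*); T/O primes contain the
whole target after a prefix; F primes share the onset and differ in one rime
letter (position-specific overlap above 60%); S/U primes are independent
stems of variable length (overlap around 10–25%). `letter_overlap()`
computes position-specific overlap with the target length as denominator
(configurable to the longer string); unequal lengths compare up to the
shorter string. No real German lexicon, frequencies, or semantics are
modelled.

## The epoch generator

Each trial of condition $c$ on channel $k$ is

$$x(k, t) = g_s \sum_j a_j(c)\; w_j(k)\; e^{-\tfrac{1}{2}\left(\tfrac{t - \mu_j}{\sigma_j}\right)^2} + \varepsilon(k, t)$$

where $a_j(c)$ is component $j$'s amplitude (µV) for the condition,
$w_j(k) \in [0,1]$ its scalp topography, $\mu_j, \sigma_j$ its peak latency
and temporal SD in ms, and $g_s$ a subject-level log-normal gain with mean
one and log-SD `subject_amp_sd` (default 0.2) — multiplicative because ERP
component amplitudes vary proportionally, not additively, across people.
The default components (`default_components()`) encode the qualitative
result pattern: N400 amplitudes U −5, F −4, S −3, T = O −1.5 µV at the
centro-parietal topography peak; an N250 with the same ordering compressed;
a central P325 enhanced for T/O; a right-frontal positivity for F (weakly
for T/O). `effect_scale = 0` collapses all conditions onto the unrelated
waveform — null data with realistic morphology.

Trial noise $\varepsilon$ is stationary AR(1) in time (lag-one coefficient
`noise_ar1`, default 0.95 at 500 Hz; stationary SD `noise_sd`, default
10 µV, a typical single-trial EEG scale) and is then low-passed by a
zero-phase windowed-sinc FIR at `lowpass_hz` (default 40 Hz), mirroring a
DC–40 Hz acquisition band. Channels are independent in the noise; spatial
correlation enters only through component topographies. That is the main
idealization: real EEG noise is also spatially correlated, so passing tests
here demonstrate correctness of the procedure, not its behaviour under
every realistic spatial covariance.

Artifacts are injectable per trial (probability `artifact_step_rate`,
default 0.03): a step of ±120 µV on one random channel from a random sample
onward, and optionally a linear drift. Response errors are flagged with
probability `error_rate` (default 0.05) and *kept* at generation time;
exclusion is the averaging stage's job. All randomness descends from one
integer seed through `derive_seed(seed, label)`, so stages are independent
and every output is bit-reproducible.

## Preprocessing chain

Fixed order, each step linear where linearity matters:

1. **Drift correction** (`correct_drift()`): off by default (the generator
   makes no drift unless asked). The available method is least-squares
   linear detrending per channel, per block or per trial. It is a documented
   stand-in, not a reimplementation of any specific published DC-correction
   algorithm.
2. **Artifact rejection** (`reject_artifacts()`): a trial is removed iff on
   any channel the per-sample voltage step exceeds 50 µV or the
   within-trial peak-to-peak amplitude exceeds 100 µV (both strict
   inequalities; the boundary trial survives). The "trial segment" for the
   range criterion is the whole epoch including the baseline; all channels
   count. Both choices are configurable. Rejection is monotone in its
   thresholds.
3. **Baseline correction** (`baseline_correct()`): subtracts the mean of
   the half-open window [−100, 0) ms per trial and channel — the sample at
   target onset belongs to the response, not the baseline.
4. **Electrode pooling** (`pool_electrodes()`): unweighted mean of three
   adjacent recording electrodes per standard site; the shipped map
   (`default_pooling_map()`) takes the 61-channel montage to the 19
   standard 10–20 electrodes. Pooling and baselining commute.
5. **Averaging** (`average_erps()`): per subject × condition means over
   retained, correct-response trials, with trial counts recorded and an
   explicit error for empty cells.

## Inference

**Pointwise t** (`pointwise_t()`): at each (channel, sample), the paired
one-sample statistic $t = \bar d / (s_d / \sqrt{n})$ on the subject
differences, df = n − 1. Zero-variance convention: t = 0 when the mean is
also 0, otherwise sign(mean) × 10⁶ — the cap also bounds degenerate
variances arising from floating-point cancellation.

**Running-t ROI** (`find_rois()`): samples with |t| above the two-tailed
Student critical value at α = 5% are marked; maximal supra-threshold runs
lasting at least 50 ms per channel are admitted. Run duration is the number
of samples × sample period, so 25 samples at 500 Hz count as exactly 50 ms
and are admitted ("at least"); at 250 Hz the shortest admissible run is 13
samples (52 ms). Detection is pointwise α, with no duration-corrected
threshold — the duration rule itself is the multiplicity filter at this
stage.

**Sign-flip max-t permutation** (`tmax_permutation()`): under the paired
null, x and −x are equally likely, so each permutation flips every
subject's *entire* difference array by an independent ±1 — whole-subject
flips preserve the spatio-temporal correlation structure, which is what
makes the max-t distribution honest. Per draw, the maximum |t| over all ROI
points is recorded; the critical value is the nearest-rank 95th percentile
(the ⌈0.95·B⌉-th order statistic — interpolation would change borderline
decisions, so the choice is fixed and documented); the p-value uses the
add-one convention (1 + #{null ≥ observed}) / (1 + B), guaranteeing p > 0.
Points with observed |t| above the critical value are flagged; flags exist
only inside the ROI. The implementation exploits that per-point sums of
squares are flip-invariant, so all B draws reduce to one matrix product.

**Contrast suite** (`run_pipeline()`): S−U, T−U, O−U, F−U each in their own
running-t ROI; the T−O test restricted to the S−U ROI
(`restricted_contrast()`), because a real transparency effect should appear
where semantic priming is visible and restricting the point set raises
power; O−F; and the double difference (O−F)−(T−S), form-without-meaning
versus meaning. The report serializes the resolved configuration, audit,
condition means and every contrast, so each number is reproducible from the
report alone.

## Circularity, and what the FWER calibration measures

Defining the ROI from S−U and then permutation-testing **S−U** in that ROI
is a *selected* analysis: the ROI was chosen where the observed t was
extreme, so the observed max-t is biased upward relative to its own
flip-null. The package reproduces this layout because the original analysis
used it, but labels it descriptive. The calibration harness
(`calibrate_fwer()`) makes the distinction measurable on complete-null
data:

- **self-test layout** (`test_pair = roi_pair`): rejects far above the
  nominal level whenever a null ROI happens to be found — a direct
  demonstration of the selection effect;
- **confirmatory layout** (ROI from S−U, test of T−O): the tested
  differences are independent of the ROI definition, the permutation stage
  is exact, and the unconditional FWER is the nominal level multiplied by
  the probability that the running-t gate opens at all, hence at or below
  5%. The `conditional_rate` field isolates the permutation stage's level
  among experiments where a ROI existed.

`analysis/04_fwer_calibration.R` computes both; `scripts/acceptance.R`
recomputes the confirmatory FWER from scratch. Under the complete null the
gate opens in well under 100% of experiments, so the unconditional rate
sits below the nominal level: the whole procedure is conservative, and the
conditional rate is the quantity that matches the nominal 5%.

Calibration problem size (chosen once, stated here as the package's own
reduced-scale design): 17 subjects, the 19 pooled channels simulated
directly, 250 Hz from −100 to 600 ms, AR(1) lag-one 0.90 at 250 Hz (the
smoothness of roughly 40-Hz-band-limited EEG at that rate) with no
additional FIR stage, 10 trials per condition (the null t distribution is
invariant to per-condition trial count), ROI detection on 0–600 ms,
1,000 permutation draws, 500 replicates.

## Numerical and design choices

- **Quantile rule**: nearest-rank, not interpolated; with B = 1,000 the
  critical value is the 950th order statistic.
- **p-value**: add-one convention; with B = 10,000 the smallest reportable
  p is 1/10001.
- **Zero-variance t**: 0 when mean 0, else ±10⁶ (capped, logged in code).
- **Degenerate inputs**: empty ROI is an explicit "nothing to test" error,
  never a silent pass; empty subject × condition cells name the subject and
  condition; montage mismatches name the missing electrodes; malformed
  epoch sidecars name the missing field.
- **Baseline window** is half-open at 0; **rejection thresholds** are
  strict inequalities; both verified by boundary bisection in the tests.
- **Seeding**: one master seed, split per stage by a deterministic label
  hash below 2³¹; permutation draws never share a stream with simulation
  draws.
- **Epoch interchange**: JSON sidecar plus a TSV payload whose amplitudes
  are C99 hexadecimal float literals — plain text, byte-reproducible, and
  exactly lossless for doubles, which ordinary decimal formatting is not.
  There is no universal text standard for epoched ERP data, so the format
  is bespoke but documented and versioned.

## Scope and limitations

- Simulated noise is spatially independent across channels; topographies
  supply the only spatial structure. FWER statements transfer to spatially
  correlated noise by the permutation argument (whole-subject flips), but
  power figures do not.
- The drift corrector is a linear stand-in; continuous-recording (e.g.
  EDF) ingestion is not implemented — the epoch format is the entry point.
- Cluster-mass statistics, parametric mixed models, FDR control and source
  localization are out of scope: the procedure under study is max-t within
  a running-t ROI.
- Reduced problem sizes (250 Hz axes, critical-pairs-only designs, 19
  channels simulated directly) are used in the test suite and analysis
  drivers; full-scale 61-channel, 500 Hz, 720-trial simulation is supported
  and exercised at smaller subject counts.

## Reproducing the analyses

```{r}
# design, simulation + preprocessing, contrast suite, calibration:
# Rscript analysis/01_design.R
# Rscript analysis/02_simulate_preprocess.R
# Rscript analysis/03_contrasts.R
# N_SIMS=500 Rscript analysis/04_fwer_calibration.R

# headline FWER recomputation:
# Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
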