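---
title: "Synthetic ERG waveforms for class-imbalance augmentation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic ERG waveforms for class-imbalance augmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical full-field electroretinography (ERG) compares a patient's waveform
against reference ranges collected from healthy volunteers. Reference
cohorts are rarely balanced: one sex, age band or iris colour is usually
under-represented, which biases any machine-learning model trained on the
cohort toward the majority group. `ergsynth` implements one remedy end to
end: learn the class-conditioned distribution of waveforms with a
conditional generative adversarial network (CGAN), sample synthetic
minority-class records, smooth them with a Fourier low-pass, and measure
whether a downstream classifier actually benefits — always against an
untouched, imbalanced, real test set, and always in comparison with the
cheaper baseline of random oversampling.

The package works with two light-adapted ISCEV stimuli: the single-flash
LA3 response (a-wave trough followed by the b-wave peak, with oscillatory
potentials on the ascending limb) and the 30 Hz flicker steady-state
response. The classification trait throughout is sex, with male as the
minority and positive class.

## The waveform simulator

Because deposited clinical recordings cannot be assumed present, the
package carries a generative waveform model that stands in for the
acquisition step and doubles as ground truth for parameter-recovery tests.

The noiseless LA3 kernel is

$$f(t) = -A_a e^{-(t-t_a)^2/2w_a^2} + A_b e^{-(t-t_b)^2/2w_b^2}
       + A_{op}\, e^{-(t-c)^2/2w_{op}^2}\,\sin\!\big(2\pi f_{op}(t-c)\big),$$

a negative Gaussian lobe (a-wave), a positive Gaussian lobe (b-wave) and a
Gaussian-windowed sinusoid (the OPs) centred on the ascending limb. This is
the smallest parametric form that reproduces light-adapted morphology;
every parameter has a clinical reading (trough depth in µV, time-to-trough
in seconds, and so on). The 30 Hz flicker kernel is a 30 Hz fundamental
plus phase-locked low-order harmonics. Defaults (`la3_params()`,
`flicker_params()`): a-wave 10 µV at 15 ms (width 4 ms), b-wave 25 µV at
32 ms (width 8 ms), OPs 3 µV at 120 Hz, flicker fundamental 8 µV with
harmonics 2 and 1 µV, white noise 2 µV — plausible pediatric light-adapted
magnitudes on the RETeval-style 0.1–300 Hz band.

Acquisition settings are not dictated by any published table, so the
package fixes them once: sampling rate 1000 Hz, LA3 records 0.25 s (250
samples, covering all light-adapted peaks below 60 ms) and flicker records
0.30 s (9 full cycles). These sizes keep a full experiment comfortably
inside a single CPU minute-scale budget while leaving every morphological
feature resolvable.

### The study-emulation fixture

`make_study_fixture()` reproduces the reference cohort's composition
exactly for every seed: 170 LA3 waveforms (60 male / 110 female, 85 per
eye) and 67 flicker waveforms (18 male / 49 female, 33 left / 34 right),
with subject identifiers shared across eyes and replicates. Only the
marginals of that composition are published; the joint eye-by-sex
allocation used here is the simplest consistent one (males 30/30 in LA3
and 9/9 in flicker, females the remainder).

Two stochastic layers make the fixture statistically honest rather than a
copy of one kernel:

* **Between-subject variability** — each subject draws a log-normal
  multiplicative jitter (SD 0.1) on amplitude parameters and a Gaussian
  jitter (SD 1 ms) on timing parameters, so replicates within a subject are
  correlated and a subject-level split is meaningfully different from a
  record-level one.
* **Within-record noise** — additive white noise (default 2 µV).

* **The class effect** is configurable (`sex_effect()`), because the true
  male/female difference in these waveforms is not quantified anywhere; the
  default is a modest, detectable shift (male b-wave amplitude ×0.9,
  b-wave peak delayed 1.5 ms; flicker amplitude ×0.9). With the amplitude
  jitter at 10 %, a 10 % class shift gives a subject-level effect size
  near 1 SD — separable, but far from trivially so, which is the regime in
  which augmentation can matter. The identity effect turns the fixture
  into a null world used by the calibration tests.

What the simulator does **not** emulate: electrode/skin artifacts,
blink rejection residue, luminance-response nonlinearity, age trends,
inter-device spectral differences, or any dark-adapted protocol. Passing
tests therefore demonstrate that the pipeline's machinery is correct and
directionally effective under a plausible generative model — not that the
same balanced-accuracy numbers would be obtained on recorded clinical data.

## Feature extraction

The classifier operates on the four standard time-domain parameters: the
a-wave time-to-trough `ta` and amplitude `la`, and the b-wave time-to-peak
`tb` and amplitude `lb` (only `tb`/`lb` for flicker). Extraction is
windowed extremum search, the discrete analogue of clinical cursor
placement:

* a-wave window 5–25 ms, b-wave window 15–60 ms (standard light-adapted
  latency ranges; both configurable);
* baseline = mean of the first 5 ms;
* `la` = |baseline − trough|; `lb` = trough-to-peak (the ISCEV
  convention). Whether the original cursor convention was trough-to-peak
  or baseline-to-peak is ambiguous, so `lb_mode = "baseline_to_peak"` is
  provided as a switch;
* ties in extremum location resolve to the earliest sample, for
  determinism;
* a flat or monotone search segment is an extraction error: the record is
  excluded and logged, never silently imputed.

For flicker, cycles are cut at stimulus onset (1/30 s apart), the first
cycle is discarded as onset transient, `lb` is the mean peak-to-adjacent-
trough swing (the trough searched within 3/4 period after each peak, so
quantization of the peak time cannot push the true trough out of the
window) and `tb` is the onset-to-peak latency of the first steady-state
cycle. This cycle-averaged convention is a package decision; the original
cursor rule for steady-state trains is not documented anywhere.

Parameter-recovery tests hold the extractor to a dense-grid oracle on the
continuous kernel: times within one sample, amplitudes within 1 %, over
200 randomized parameterizations.

## The conditional GAN

No neural-network framework is assumed: the generator and discriminator
are small fully connected networks implemented in base R (matrix
forward/backward passes, binary cross-entropy on logits, Adam).

* Generator: latent 64 + one-hot sex label → 128 → 256 → signal length,
  leaky-ReLU hidden units, tanh output on the normalized scale.
* Discriminator: signal + one-hot label → 256 → 128 → 1 logit.
* Amplitudes min-max normalized to [−1, 1] per training set; inverse
  applied on sampling.
* Adam with learning rate 2e-4 for both networks (β₁ = 0.5, the standard
  GAN setting), batch 16, 300 epochs, non-saturating generator loss.
* Separate generators per stimulus: LA3 and flicker differ in length and
  morphology and nothing prescribes weight sharing.

These are the smallest settings that reliably produce plausible morphology
on ~10²-sample training sets; all are exposed in `gan_config()`. Training
is deterministic given the seed. A NaN loss aborts with a diagnostic
rather than returning a silently broken generator.

Generator quality is monitored by a morphological plausibility gate
(global minimum in the a-wave window, maximum after it in the b-wave
window, peak-to-peak within 3× the training range). The gate is a
test-harness device, not a default pipeline filter — the original method
applies no explicit rejection step — but it can be enabled for rejection
sampling by filtering on `plausibility_gate()`.

### Augmentation policy

Two published statements cannot both hold exactly for this composition:
"synthetic data equivalent to 20 % of the initial real dataset size"
(0.2 × 170 = 34 additions) and "balanced the sex distribution" (parity on
the LA3 training split needs ~40 additions). Both semantics are
implemented (`augmentation_policy()`): fraction mode (default, 20 % of the
pre-split dataset size) and parity mode. Augmentation never mutates or
drops a real record.

## Fourier low-pass post-processing

Generated waveforms carry high-frequency generator noise. The smoothing
step is hard spectral truncation: FFT, zero every bin above the cutoff,
inverse FFT. Hard truncation is the simplest bit-reproducible reading of
"selective removal of high-frequency components", and it is exactly
linear, idempotent and energy-non-increasing — properties the tests assert
directly. The default cutoff is 150 Hz: comfortably above the OP band
(~100–150 Hz) that gives the LA3 ascending limb its character, and far
below the amplifier band edge at 300 Hz. No cutoff value is published; it
is configurable. By default the filter is applied to synthetic records
only, since it is conceived as post-processing of generator output; a flag
extends it to real records for parity experiments.

## Classifier protocol and metrics

A random forest is trained on the extracted features (LA3: `ta, la, tb,
lb`; flicker: `tb, lb`) under stratified 3-fold cross-validated grid
search. The published protocol names grid search with three folds and an
80:20 train/validation wording; a 3-fold CV *is* a rotating ~67:33
validation scheme, and the package keeps the operative part — stratified
3-fold selection by balanced accuracy — as its single concrete reading.
The default grid (trees ∈ {100, 300}; depth ∈ {unlimited, 5, 10},
implemented as leaf-count caps 2^depth; features-per-split ∈ {all, √p})
brackets reasonable forest capacity for 4-feature problems; the original
grid is unpublished.

Metrics follow the standard formulas: precision = TP/(TP+FP), recall =
sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), balanced accuracy =
(sensitivity+specificity)/2, F1 = 2PR/(P+R). The positive class is male
(the minority); published tables report single P/R values without naming
the positive class, so this is a documented assumption. Zero denominators
raise an explicit undefined-metric condition — never a silent zero; the
pipeline evaluation path reports such cells as `NaN`.

Three conditions are evaluated per stimulus — original, randomly
oversampled (minority resampled with replacement to parity), and
GAN-synthesized — all against the same real, unbalanced test rows. The
test rows are hashed (canonical CSV → MD5) and the hash recorded per
condition, making test-set immutability checkable after the fact.

The train/test split defaults to the **subject** level: all replicates and
both eyes of a subject stay on one side, because replicate leakage across
the split would inflate every condition equally and mask the augmentation
effect. Whether the original split was subject- or record-level is
unstated; a record-level option exists for strict mimicry (and is what
makes "20 % of 170 = 34 held out" exact).

## Numerical and degenerate-input choices

* All stochastic stages draw from named child streams of one root seed
  (`split`, `gan_LA3`, `oversample`, …), so a stage can be reproduced in
  isolation and adding a stage does not shift another stage's draws.
* Extremum ties → earliest sample. Grid-search ties → first grid row.
* Flat signals, monotone search windows, single-class test sets, cutoffs
  at/above Nyquist, empty datasets and sample-index gaps in CSVs are all
  classed errors (`ergsynth_validation_error`, `ergsynth_extraction_error`,
  `ergsynth_parse_error`, `ergsynth_undefined_metric`), not warnings.
* CSV amplitudes are serialized with 17 significant digits, so a
  write/read round trip is value-exact.

## Problem sizes in the shipped tests

The test suite and the acceptance script run entirely on simulated data at
the study's own composition: GANs train for 300 epochs on 136 LA3 / 54
flicker training waveforms; stochastic claims (chance-level behaviour
under the null fixture, and the synthesized-vs-original balanced-accuracy
direction) are evaluated as means or medians over five root seeds. The
t-SNE embedding is visualization-only — it is a compact exact (O(n²))
implementation, adequate for a few hundred feature rows — and no
quantitative claim rests on it.

## What the simulated benchmark does and does not show

Under the shipped simulated conditions the three-way comparison behaves
only partly like the original real-data study. Random oversampling
reliably improves the median balanced accuracy over the original
imbalanced training set — the cheap baseline works. GAN synthesis improves
it on some pipeline seeds (on the first seed of the replication protocol
it produces the largest balanced accuracy of all conditions) but not on
the median over five seeds, and the test suite reports that comparison
honestly rather than relaxing it. Two quantified mechanisms explain the
gap, both visible with the package's own tools:

1. *Measurement parity.* Real records keep their additive noise, which
   inflates extracted trough-to-peak amplitudes (on default LA3 parameters
   by roughly 3 µV over the noiseless kernel), while synthetic records are
   low-pass smoothed before extraction and show no such inflation. The
   asymmetric smoothing is the original method's own design; its side
   effect on peak-picked features is much larger on the simulator's
   white-noise records than it would be on device-averaged, band-limited
   clinical waveforms.
2. *Amplitude shrinkage.* A small fully connected GAN trained for 300
   epochs on ~136 waveforms under-disperses and under-estimates extreme
   amplitudes by a further ~2 µV.

Both push synthetic minority feature rows away from the real minority
distribution in the direction the classifier is most sensitive to. Users
applying the pipeline to recorded data should check generator fidelity
with `plausibility_gate()` and a feature-space comparison (for example
`embed_features()`) before trusting the synthesized condition.

## Known limitations

* The generative kernel is unimodal per lobe; it cannot produce electrode
  artifacts, photopic-hill nonlinearities or pathological morphologies, so
  classifier accuracies here do not transfer numerically to clinical data.
* The magnitude of the default sex effect is a stand-in, not an estimate.
* The CGAN is the smallest workable architecture; no Wasserstein loss,
  gradient penalty or mode-collapse diagnostics beyond the loss log.
* The reader for the deposited clinical dataset's native layout is not
  implemented (the layout is undocumented); real data can be used by
  converting it to the package's CSV dialect.
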