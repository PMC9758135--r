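---
title: "Simulating and decoding preparatory feature-based attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and decoding preparatory feature-based attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the pipeline addresses

When an observer is cued to attend a visual feature (say, leftward motion)
several seconds before the stimulus appears, cortex carries a *preparatory*
signal during the delay. Two hypotheses about its format make different
multivariate predictions. Under a **sensory template** account, preparing
for a feature pre-activates the same multivoxel pattern the feature itself
evokes, so a classifier trained on stimulus-evoked patterns from a
single-feature baseline task should generalize to preparatory patterns.
Under a **non-sensory (abstract) template** account, preparatory patterns
carry feature information in a different format: they are decodable
within-task, but a sensory-trained classifier transfers only to the
stimulus period, not to the delay.

`prepdecode` implements this logic as a parameter-recovery experiment on
synthetic BOLD data. The generator embeds a *preparatory* pattern axis and
a *sensory* pattern axis whose cosine similarity — the `overlap` parameter
in `make_ground_truth()` — is exact ground truth. `overlap = 1` simulates
a sensory template, `overlap = 0` an orthogonal abstract template. The
analysis chain (preprocessing, FIR deconvolution, voxel selection, pattern
extraction, FLD decoding with leave-one-run-out cross-validation,
cross-task generalization, group permutation inference) then has to
recover the corresponding dissociation.

## Task designs the generator emulates

The attention task: a 0.5 s color cue, a delay of 1.7/3.9/6.1/8.3 s with
10/10/40/40% frequency (exact per-run counts, so 80% of trials are
long-delay by construction), a 0.5 s compound motion stimulus, and an ITI
of 4.4–8.8 s in 2.2 s steps; 6 runs of 30 trials; behavioral accuracy is
Bernoulli at a configured ~75%, standing in for a staircase that is not
itself simulated. The baseline task: a single 0.5 s dot field per trial,
two directions, ITIs of 3.9–8.3 s (we use 2.2 s steps by analogy with the
attention task, since only the range is constrained); 2 runs of 61 trials.
The TR is 2.2 s throughout.

All onsets are chained from the nominal event durations and snapped to the
TR grid (both values are recorded). Snapping makes the onset-to-TR mapping
in the FIR design exact and keeps windowed extraction in whole TRs, at the
cost of up to 1.1 s of timing quantization — immaterial here because every
analysis operates in TR units.

## The generative BOLD model

Each trial contributes a preparatory neural event — by default a boxcar
from cue onset to stimulus onset (sustained preparation), optionally a
0.5 s transient at the cue — and a 0.5 s stimulus event. Events are
convolved with a double-gamma HRF (peak 5 s, undershoot 15 s, ratio 6) on
a 0.1 s grid; each convolved shape is normalized to unit peak so that
amplitude parameters are the peak percent-signal-change of the evoked
response. Per-voxel condition amplitudes are
`mean_amplitude ± pattern_amplitude * axis / 2`, where the preparatory and
sensory difference axes are unit vectors constructed by Gram–Schmidt so
their cosine equals `overlap` to machine precision. The summed percent
modulation rides on a raw baseline (default 1000) with i.i.d. Gaussian
noise (default 1 psc), optional AR(1) correlation and linear drift.
Baseline-task trials carry only the sensory event.

Defaults: `mean_amplitude_prep = 0.3`, `mean_amplitude_stim = 1.0` psc
(a preparatory baseline shift about a third of the stimulus response, in
the range univariate studies report), `pattern_amplitude_* = 0.5` psc
(condition information much smaller than the condition-common response,
which is why these questions need MVPA at all), `noise_sd = 1`
psc. With 70 voxels these defaults put within-task decoding in the 0.6–0.8
range typical of visual-cortex attention decoding. Incorrect trials carry
the same pattern as correct ones (only the label differs); a flag can swap
the pattern on incorrect trials to emulate misallocated attention.

What the generator does **not** emulate: 3-D geometry and spatial
autocorrelation, head motion, physiological noise, HRF variability across
voxels and subjects, and staircase dynamics. Passing recovery tests
therefore show the *analysis logic* is sound — not that it is robust to
every artifact of real data.

## Preprocessing and FIR deconvolution

Per run: percent-signal-change conversion (divide by the voxel's run mean),
then projection out of a nuisance basis containing the mean, a linear
trend, and discrete-cosine components below 0.01 Hz (a deterministic,
edge-artifact-free high-pass). Voxels exceeding 10 psc anywhere are
dropped from all runs; runs are then concatenated with onset offsets.

The FIR model follows the task's regressor decomposition: 10 regressors
for the attention task (2 attended directions × 2 long delays for correct
trials, 2 short-delay regressors collapsed over direction, and 4
incorrect-trial regressors, one per delay length) × 12 bins, and 2
regressors × 8 bins for the baseline task. The stated regressor total and
the phrase describing incorrect-trial regressors cannot both be read
literally (4 + 2 + 2 ≠ 10); we resolve to one incorrect regressor per
delay length, which reproduces the total, and expose the labeling.
Betas are the minimum-norm pseudoinverse solution; all-zero columns (a
run with no incorrect trials at some delay) yield zero betas.

One numerical point matters: the **design matrix is filtered with the same
nuisance projection as the data** (`filter_fir_design()`). Because the
mean and slow components removed from the data contain part of the event
responses, fitting an unfiltered indicator design to filtered data shifts
every beta downward (in our noiseless tests the 0.3 psc preparatory
plateau estimated as −0.12 without filtering, correctly with it). This is
standard GLM practice and is applied wherever the pipeline fits FIR
models; `fit_fir()` itself stays agnostic so that design-generated
recovery tests remain exact.

## Windows, the baseline shift index, and the quadrant control

"k TRs after onset" means FIR bin k with bin 0 at the onset TR — the
convention is fixed here because the counting origin is otherwise
ambiguous; all windows are configurable `window_spec()`s. Stimulus-anchored
windows inside the trial-locked FIR use bin `round(delay / TR)`, averaged
across the two long delays.

The baseline shift index is the peak of the condition-averaged response in
bins 1–3 after trial onset divided by the peak in bins 1–3 after stimulus
onset. Under sustained preparation the BOLD response is still rising at
6.6 s, so the measurable preparation peak is ~0.65 of the neural plateau
and the BSI underestimates the neural amplitude ratio (0.18 for an
embedded ratio of 0.3); under transient cue events, whose response peaks
inside the window, BSI recovers 0.3 within 0.05. Our tests pin both
behaviors, the sustained one against a convolution oracle. This is worth
remembering when interpreting BSI from real data: it is a hemodynamic
ratio, not a neural one.

The covert-spatial-attention control assigns each voxel a visual-field
quadrant (ground-truth metadata here, retinotopy in real data) and
contrasts preparatory amplitude in hypothesized attended vs unattended
quadrants (`upper_two`: attend-left → UL; `diagonal_four`: attend-left →
UL+LR), with a group paired t-test. The generator can inject a quadrant
bias to verify detection; with uniform patterns the contrast is exactly
zero and its type-I rate is nominal under exchangeable noise.

## Decoding and inference

Single-trial patterns are window means (default bins 2–3) of the psc
series, anchored at trial onset (preparation, baseline) or stimulus onset
(stimulus period); attention-task extraction keeps long-delay correct
trials only. Patterns are z-normalized per voxel across trials — by
default with statistics computed on the training folds only and applied
to the test fold (leakage-free); a pooled mode normalizes the whole set
once, matching descriptions that z-score before fold splitting. The
sample standard deviation is used (as `scale()` does).

The classifier is a two-class Fisher linear discriminant with
diagonal-loading shrinkage, `S_λ = (1−λ)S + λ tr(S)/V · I`, default
`λ = 0.05`: with ~70 voxels and ~112 training trials the pooled covariance
is near-singular, and a small deterministic ridge keeps the solve stable
without materially rotating the weights. Ties at score 0 go to the first
class lexicographically, for reproducibility. Cross-task generalization
trains once on the (separately z-normalized) baseline patterns and
evaluates once on the attention-task patterns through the left/right label
correspondence — no cross-validation, since train and test come from
different runs.

Group inference follows the subject-averaged permutation logic: each
subject contributes a null distribution of decoding accuracies; the
per-permutation average across subjects forms the group null; the observed
group mean is compared to its 95th percentile (nearest rank), with
`p = (1 + #{null ≥ obs}) / (1 + n_perm)` so p is never zero, and
Benjamini–Hochberg FDR across schemes.

**Permutation scheme.** The textbook description — shuffle the training
labels, score against the true labels — is *not* exchangeable under
leave-one-run-out cross-validation: the scoring labels are the same vector
that trained the other folds, so the observed statistic has slightly
larger variance than the permutation draws (0.097 vs 0.083 on small null
cohorts) and the group test over-rejects (~11% at the 5% level in our
null-cohort simulations). `subject_permutation_null()` therefore defaults
to a full-label permutation — the permuted labels are used for training
*and* scoring, making the observed value one draw from the same ensemble —
which essentially restores the nominal level: 6.4% over 1200 null-cohort
simulations, versus ~11% for the train-only scheme. The remaining fraction
of a point reflects that trial patterns from filtered BOLD are only
approximately exchangeable (the non-causal high-pass induces weak
dependence among trials), so the permutation argument is exact at the
pattern level but slightly approximate end-to-end. The train-only variant
remains available (`shuffle = "train_only"`) for comparison with the
literature. Cross-task permutation shuffles training labels only, which
is already exchangeable there because the training and test label vectors
belong to disjoint trial sets.

**A filtering artifact worth knowing about.** With a strong stimulus
response, baseline→preparation generalization lands slightly *below* 0.5
rather than at it. The run-level detrend/high-pass is non-causal: the
smooth fit subtracted from each voxel contains part of that trial's own
(label-locked) stimulus response, bleeding a negative sensory-pattern
component into the same trial's preparation window. The one-sided
permutation decision is unaffected (the test asks whether accuracy exceeds
the null, and it does not), but the point estimate is not an unbiased
chance level. At realistic amplitudes the effect is negligible; our
dissociation test documents it explicitly.

## Inferential utilities

`paired_t()`/`one_sample_t()` wrap the standard t machinery;
repeated-measures ANOVAs are computed by `aov()` with the appropriate
error strata (each effect against its own effect-by-subject term,
uncorrected df by default, Greenhouse–Geisser optional), with a guard that
reports F = 0 when an effect's sum of squares is numerically zero (the
0/0 ratio is otherwise floating-point noise). The JZS Bayes factor is the
Rouder-style marginal likelihood ratio with a Cauchy(√2/2) prior —
the JASP default scale — integrated adaptively over the inverse-gamma
mixing variable; our tests verify it against an independent quadrature
oracle to 1% over a (t, n) grid. Cousineau within-subject SEMs subtract
subject means before computing per-condition errors; the Morey cluster
correction is available but off by default, matching the plain Cousineau
citation. Two-way RM-ANOVA df note: a 2 × 10 within-subject design gives
df = (1, 11) for the period main effect under the standard partitioning;
published reports sometimes pool error terms differently (e.g. F(1, 99)),
which we deliberately do not reverse-engineer.

## Problem sizes used by the tests

The packaged checks run at sizes chosen to exercise the full pipeline
while staying light: chance calibration uses 12 subjects × 70 voxels × 6
runs of 30 trials with zero pattern amplitudes; type-I calibration uses
200 replicates of reduced cohorts (6 subjects, 20 voxels, 6 runs of 10
trials, 200 permutations); the dissociation experiment uses 12 subjects
with pattern amplitudes 3 psc and noise 0.5 psc so that stimulus decoding
is near ceiling, making the presence/absence of cross-task transfer the
only question. Oracle tests (FIR recovery, FLD closed form, ANOVA and FDR
sums-of-squares, JZS quadrature, convolution) run at toy sizes.

## Known limitations

- The generator's noise is temporally white by default; real BOLD noise is
  autocorrelated and spatially structured, which widens decoding nulls.
- Amplitude parameters are calibrated in peak psc per event shape, so
  changing the HRF or the preparation mode rescales effective amplitudes.
- The below-chance filtering artifact above means cross-task point
  estimates should be interpreted against the permutation null, not
  against 0.5.
- The pipeline assumes two conditions throughout; multiclass decoding is
  out of scope.
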