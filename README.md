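# prepdecode

Simulation and multivariate decoding of **preparatory feature-based
attention** in fMRI, as a tested parameter-recovery pipeline.

## The problem

When observers are cued to attend a visual feature (e.g. leftward vs
rightward motion) seconds before the stimulus appears, cortex carries a
preparatory signal during the delay. Is that signal a **sensory
template** — a pre-activation of the same multivoxel pattern the feature
itself evokes — or a **non-sensory, abstract template**? The two accounts
dissociate in a cross-task generalization design:

- decode the attended feature from *preparatory* (pre-stimulus) activity
  patterns within the attention task (leave-one-run-out cross-validation);
- train a classifier on stimulus-evoked patterns from a *single-feature
  baseline task* and test whether it transfers to the preparatory period
  and to the stimulus period of the attention task.

A sensory template predicts transfer to both periods; an abstract template
predicts within-task decodability of preparation *without* baseline →
preparation transfer, alongside intact baseline → stimulus transfer.

`prepdecode` implements the full analysis chain and a synthetic BOLD
generator in which the truth is known: the cosine similarity between the
preparatory and sensory pattern axes (`overlap`) is an exact ground-truth
parameter, so the pipeline's ability to recover either regime can be
tested rather than assumed.

## What is in the package

| Stage | Functions |
| --- | --- |
| Task designs & behavior | `make_attention_design()`, `make_baseline_design()`, `simulate_behavior()` |
| Ground truth & BOLD | `make_ground_truth()`, `render_bold()`, `generate_cohort()` |
| Preprocessing | `to_percent_signal_change()`, `detrend_highpass()`, `remove_noisy_voxels()`, `concatenate_runs()`, `preprocess_runs()` |
| FIR deconvolution | `attention_fir_spec()`, `build_fir_design()`, `filter_fir_design()`, `fit_fir()`, `compute_r2()`, `select_top_voxels()` |
| Univariate | `condition_timecourse()`, `window_amplitude()`, `compute_bsi()`, `quadrant_contrast()` |
| MVPA | `extract_trial_patterns()`, `znorm_patterns()`, `fld_fit()`, `fld_predict()`, `cv_loro()`, `cross_decode()`, `subject_permutation_null()`, `group_permutation_test()` |
| Statistics | `paired_t()`, `one_sample_t()`, `rm_anova_oneway()`, `rm_anova_twoway()`, `jzs_bf01_paired()`, `bh_fdr()`, `cousineau_sem()` |
| Orchestration | `pipeline_config()`, `run_experiment()`, `summarise_experiment()` |

The core quantities, in the field's notation:

- **FIR deconvolution**: each condition's hemodynamic response is a set of
  free per-TR coefficients; betas are the minimum-norm least-squares
  solution `β = X⁺ y`, with the design matrix filtered by the same
  nuisance projection (mean, trend, < 0.01 Hz DCT) as the data.
- **Baseline shift index**: `BSI = max(prep window) / max(stim window)`
  of the condition-averaged long-delay FIR response — proportionally how
  much anticipatory activity precedes the stimulus response.
- **Fisher linear discriminant** with shrinkage:
  `w = S_λ⁻¹ (μ₊ − μ₋)`, `S_λ = (1−λ)S + λ tr(S)/V · I`, decision at the
  class-mean midpoint.
- **Group permutation test**: per-subject null distributions of decoding
  accuracy are averaged permutation-wise into one group null; the observed
  group mean is compared to its 95th percentile (nearest rank), with
  `p = (1 + #{null ≥ obs}) / (1 + n_perm)`.

## Worked example

A small experiment with an abstract preparatory template (`overlap = 0`)
and moderate signal:

```r
library(prepdecode)

cfg <- pipeline_config(
  cohort = cohort_spec(n_subjects = 4, n_voxels = 40, seed = 1),
  overlap = 0,
  truth_args = list(pattern_amplitude_prep = 2, pattern_amplitude_stim = 2,
                    noise_sd = 0.8),
  n_perm = 200
)
bundle <- run_experiment(cfg)
bundle$group_decoding
#>   scheme      period accuracy threshold       p   p_fdr significant
#> 1   loro preparation    0.629     0.556 0.00498 0.00622        TRUE
#> 2   loro    stimulus    0.867     0.547 0.00498 0.00622        TRUE
#> 3  cross preparation    0.479     0.556 0.77114 0.77114       FALSE
#> 4  cross    stimulus    0.852     0.576 0.00498 0.00622        TRUE
#> 5   loro    baseline    0.754     0.541 0.00498 0.00622        TRUE
```

Reading the table: the attended direction is decodable from preparatory
activity within-task (`loro preparation`, 63% vs a 55.6% permutation
threshold), and the baseline-trained sensory classifier transfers to the
stimulus period (85%) but **not** to the preparatory period (48%, p ≈
0.77) — the abstract-template signature, matching the generative truth.
Setting `overlap = 1` instead makes `cross preparation` significant.

The bundle also carries the univariate side:

```r
round(bundle$bsi$values, 3)
#> [1] 0.184 0.210 0.203 0.128
bundle$bsi$test
#> t(3) = 9.813, p = 0.002249 (mean diff 0.1814)
```

a positive baseline shift during preparation in every simulated subject.

## Analysis workflow

The `analysis/` directory holds the narrative drivers, each writing tidy
TSVs under `results/`:

1. `01_simulate.R` — cohort generation, design conformance (exactly 80%
   long-delay trials), behavioral summary, example events/BOLD files.
2. `02_univariate.R` — group FIR time courses, baseline shift index with
   group test and Bayes factor, covert-spatial-attention quadrant control.
3. `03_decode.R` — the decoding experiment on overlap-0 and overlap-1
   cohorts with permutation inference.
4. `04_report.R` — combined tables, period × cohort repeated-measures
   ANOVA on cross-task accuracy, Cousineau within-subject error bars.

Run them in order from the repository root with `Rscript analysis/01_simulate.R`
etc. after installing the package.

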