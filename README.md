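# cortexlrp

Explainable CNN classification of cortical current-density maps, with
layer-wise relevance propagation (LRP) and clinical-score correlation — an
end-to-end, fully synthetic-data-driven R implementation of the analysis
design used to characterize abnormal working-memory cortical activity in
restless legs syndrome (RLS) patients versus controls.

## What it does

Single-trial event-related potentials, source-localized to ~15,000 cortical
vertices, are hard to analyze point-by-point: mass-univariate statistics
lose single-trial information and drown in multiple comparisons. The
alternative implemented here is to *classify* single trials and then ask the
classifier where it looked:

1. **Simulate** (`generate_source_space()`, `generate_trials()`) — a
   Fibonacci lattice source space on two half-sphere hemisphere charts, with
   named spherical-cap regions; single-trial current densities
   `x(v,t) = baseline + g·δ_r(v)·w(t) + b_s(v) + ε(v,t)` (patient indicator
   `g`, raised-cosine temporal bump `w` on 100–300 ms, subject random
   effects, trial noise), an EOG artifact channel, and patient clinical
   scores (IRLS, PSQI, ESS, ISI, BDI, HADS) linearly coupled to regional
   activity. Defaults match the emulated study: 22 subjects (13 control /
   9 patient), 2014 + 1580 trials, 400 samples/s, epoch [-200, 1500) ms.
2. **Preprocess** (`reject_by_eog()`, `window_average()`) — drop trials with
   |EOG| > 100 µV, average 150–250 ms (41 samples) per vertex.
3. **Project** (`mollweide_theta()`, `project_trials()`) — equal-area
   Mollweide flattening of each hemisphere to a 60×60 square
   (`2θ + sin 2θ = π sin φ`; `x = (2√2/π)λcosθ`, `y = √2 sinθ`), assembled
   into a z-scored 60×120 image per trial with an invertible vertex↔pixel
   map.
4. **Classify** (`build_cnn()`, `train_cnn()`, `crossval_cnn()`) — VGG-style
   stack (two 3×3 valid convolutions + 2×2 max-pool, twice; three dense
   layers, 50% dropout, sigmoid), trained with Adam on binary cross-entropy
   under leave-one-subject-out cross-validation with majority-class
   subsampling, a stratified 1/11 validation split, early stopping and an
   optional learning-rate grid search. From 60×120 input the feature trace
   ends at 12×27×128 = 41,472 flattened units.
5. **Explain** (`lrp_explain()`, `pixel_to_vertex()`) — composite LRP:
   LRP-0 on dense layers, LRP-ε on the upper conv block, LRP-γ on the lower
   conv block; winner-take-all through pooling; relevance initialized at the
   pre-sigmoid score, conserved exactly through bias-free layers, and
   back-projected to cortical vertices through the projection map.
6. **Correlate** (`critical_regions()`, `build_correlation_table()`) — the
   top-3% relevance vertices, grouped by region, correlated with the seven
   clinical scores by Spearman ρ (mid-ranks, t-approximation p, flagged at
   p < 0.05, uncorrected).

`run_pipeline()` chains all stages with one master seed, per-stage derived
seeds, resumable RDS artifacts, CSV/JSON tables and a checksum manifest.

## Worked example

A desk-scale run of the full pipeline (250 vertices, 5 subjects, 16×32
images, 3-epoch cap):

```r
library(cortexlrp)
cfg <- pipeline_config(
  simulation = list(n_vertices = 250, n_subjects_control = 2,
                    n_subjects_patient = 3, trials_per_subject = 6,
                    epoch_ms = c(0, 400), effect_size = c(insular = 3),
                    subject_sd = 0.1, noise_sd = 0.4, eog_blink_prob = 0),
  projection = list(grid_size = 16),
  training = list(channels = c(2, 3), hidden = c(6, 4), lr = 2e-3,
                  batch_size = 8, max_epochs = 3, patience = 2),
  stats = list(fraction = 0.05),
  seed = 3
)
manifest <- run_pipeline(cfg, "pipe_out")
#> [space] computing
#> [simulate] computing
#> [preprocess] computing
#> [project] computing
#> [crossval] computing
#> [explain] computing
#> [correlate] computing
manifest$accuracy_mean   # mean held-out accuracy over the 5 LOOCV folds
manifest$auc             # pooled ROC area
```

`pipe_out/` then contains `clinical.csv`, `fold_results.csv` (per-subject
accuracy and confusion counts), `crossval_summary.json`,
`correlations.csv` (regions × 7 scores, `*` at p < 0.05) and
`manifest.json`. Rerunning with the same seed reproduces every checksum;
`resume = TRUE` after deleting one artifact recomputes only that stage and
downstream.

At miniature scale the accuracy numbers are noisy; the properly powered
recovery experiment (2000 vertices, 22 subjects, strongly separable insular
effect) lives in the test suite, where the LOOCV mean accuracy reaches ~1.0,
the top-3% relevance mask overlaps the injected region, and the configured
PSQI–insular coupling is recovered as a significant positive Spearman ρ.

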