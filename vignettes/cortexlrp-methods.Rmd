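---
title: "Explainable classification of cortical current-density maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explainable classification of cortical current-density maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexlrp)
```

## The analysis problem

`cortexlrp` implements, end to end, an explainable machine-learning analysis
of event-related cortical activity in a two-group clinical study design:
restless legs syndrome (RLS) patients versus healthy controls performing a
working-memory task. The raw observable is the single-trial cortical current
density — source-level activity estimated on ~15,000 points of the cortical
surface from scalp EEG by an inverse method — sampled at 400 samples/s over
an epoch of [-200, 1500) ms around the retrieval probe. The pipeline:

1. rejects trials whose electrooculogram exceeds 100 µV in absolute value
   (strictly greater-than; ocular artifacts),
2. averages each retained trial over the critical 150–250 ms window of
   working-memory retrieval, yielding one value per cortical vertex,
3. flattens each hemisphere to a square 60 × 60 raster with the equal-area
   Mollweide projection and concatenates them into a z-scored 60 × 120
   input image per trial,
4. trains a compact VGG-style CNN to classify single trials as patient or
   control under leave-one-subject-out cross-validation (LOOCV) with class
   balancing, a 1/11 validation split and early stopping,
5. attributes each trained classifier's decisions back to input pixels with
   composite layer-wise relevance propagation (LRP) and back-projects pixel
   relevance to cortical vertices,
6. extracts the top-3% relevance vertices as *critical regions* and
   correlates their window-averaged activity with seven clinical scores
   (IRLS, PSQI, ESS, ISI, BDI, HADS anxiety/depression) by Spearman rank
   correlation over the patient group.

The study data this design comes from are private, so the package is driven
by a first-class synthetic-data generator that emulates the study's
statistical structure with a known ground truth; all quantitative claims in
the test suite are recovery results on that generator, not reproductions of
the clinical findings.

## The synthetic generator

### Source space

`generate_source_space()` places vertices on two half-sphere charts (left
and right hemispheres), each with latitude $\phi \in [-\pi/2, \pi/2]$ and
longitude $\lambda \in [-\pi/2, \pi/2]$. Placement is a deterministic
Fibonacci-style lattice — uniform in $\sin\phi$, golden-ratio increments in
$\lambda$ — which gives near-uniform area coverage with a reproducible,
testable structure (the nearest-neighbour distance CV on a 1000-vertex
lattice is well under 0.5). Treating each hemisphere as a half-sphere is
what makes its Mollweide image square, reconciling the projection's 2:1
full-sphere aspect with two square per-hemisphere rasters.

Named regions are six spherical caps labelled after the cortical areas of
the emulated study design (left superior frontal, inferior temporal,
insular, superior parietal, lateral occipital; right superior temporal).
Their chart coordinates are synthetic stand-ins chosen to be mutually
non-overlapping, not anatomical positions; overlap, if configured, resolves
by listed priority with a warning.

### Trial model

`generate_trials()` draws
$$x(v,t) = \mu + g\,\delta_{r(v)}\,w(t) + b_s(v) + \varepsilon(v,t)$$
with $g = 1$ for patient trials and $0$ for controls, a raised-cosine bump
$w(t)$ supported on 100–300 ms and peaking at 200 ms, a subject-by-vertex
random offset $b_s(v) \sim N(0, \sigma_s^2)$ and white noise
$\varepsilon \sim N(0, \sigma_\varepsilon^2)$. The bump is normalized to
unit mean over the samples inside the 150–250 ms analysis window, so the
per-region effect size $\delta_r$ *is* the expected patient-minus-control
difference of window-averaged current density — which makes configured
effects directly checkable downstream.

Defaults reproduce the study conditions: 13 control and 9 patient subjects;
2014 control and 1580 patient trials distributed deterministically over
subjects (floor share, remainder to the first subjects); 400 samples/s over
the half-open epoch [-200, 1500) ms, giving 680 samples with $t = 0$ on a
sample and 41 samples inside the inclusive 150–250 ms window.

The EOG channel is background noise plus occasional raised-cosine blinks
(10% of trials, amplitude ~N(120, 30²) µV by default) so that the 100 µV
rejection rule has work to do. Inter-trial amplitude distributions and
artifact statistics are not documented for the original recordings; these
defaults are explicit stand-ins chosen to look like plausible ERP-era EOG,
and nothing downstream depends on their exact shape.

Patient clinical scores are linear in the subject's mean activity of a
coupled region over 150–250 ms, plus Gaussian score noise. The default
coupling pattern mirrors the sign structure the analysis is expected to
recover: insular coupled positively to PSQI, ISI, HADS anxiety and IRLS;
inferior temporal negatively to PSQI and IRLS; right superior temporal
negatively to ESS; BDI and HADS depression uncoupled. Scores are kept
continuous rather than integer-valued — Spearman correlation only consumes
ranks, so rounding would add a tie-handling complication without changing
what is being tested.

### What the generator does not emulate

Real single-trial ERPs have structured (1/f, oscillatory) noise, spatially
correlated source leakage from the inverse solution, non-Gaussian artifacts
and latency jitter across trials and subjects. The generator's noise is
white in time and space by design: recovery results on it demonstrate that
the pipeline's machinery is correct and self-consistent, not that the
clinical effect sizes or accuracies of the original study would replicate
on real recordings.

## Preprocessing

Rejection uses a strict inequality (a peak exactly at 100 µV is retained).
Window averaging includes both endpoints and no baseline correction is
applied — none is described for the current-density stage of the emulated
design, and the windowed mean is shift-invariant downstream anyway because
images are z-scored per trial.

## Mollweide projection and rasterization

The auxiliary angle $\theta$ solves $2\theta + \sin 2\theta = \pi\sin\phi$;
then $x = (2\sqrt{2}/\pi)\lambda\cos\theta$, $y = \sqrt{2}\sin\theta$.
`mollweide_theta()` runs Newton–Raphson from $\theta_0 = \phi$ with a
step-size stopping rule and falls back to bisection; poles are returned
analytically. Near the poles the objective is cubically flat, so requiring
only a small residual would leave $\theta$ underdetermined — the step-based
rule keeps the solution accurate to ~1e-12 in $\theta$ wherever the
equation can resolve it in double precision.

Rasterization partitions the square $[-\sqrt{2}, \sqrt{2}]^2$ into
half-open bins (last bin closed, rows indexed top-down from $+y$); a
pixel's value is the mean of its vertices' values and empty pixels are 0
before z-scoring. The projected hemisphere chart fills the disk of radius
$\sqrt{2}$ inscribed in that square, so about 19% of pixels (the corners)
are unreachable by construction and stay empty; the recorded
`projection_map` lets LRP exclude them from vertex back-projection. The
per-trial image is the horizontal concatenation (left, right) and is
standardized to z-scores over all its pixels — per image, not per pixel
across the dataset, because classification inputs are single trials; a
constant image maps to all zeros rather than NaN.

## The classifier

The stack is two 3×3 valid convolutions (ReLU) and one 2×2 max pool,
repeated twice, then three fully connected layers with ReLU + 50% dropout
on the first two and a single sigmoid output (patient = 1, decision
threshold 0.5 with ties to patient). Valid padding is forced by the shape
arithmetic: from a 60×120 input the trace is 58×118 → 56×116 → 28×58 →
26×56 → 24×54 → 12×27, and with 128 second-block channels the flattened
dimension is 128·12·27 = 41 472. The first-block channel count (64), the
hidden widths (256, 64), batch size 64 and Adam's defaults
($\beta_1 = 0.9$, $\beta_2 = 0.999$) are package choices in VGG convention;
the emulated design fixes only the final 128 channels.

Training minimizes binary cross-entropy with Adam; after each epoch the
validation accuracy is evaluated and training stops when it has not
improved for `patience` epochs (default 20), returning the
best-validation-accuracy weights. "No improvement" is the operational
reading of accuracy "not changing" for that many epochs. The learning rate
can be grid-searched per training session on the same seeded split, ties
going to the smaller rate.

Everything is implemented in vectorized base R: convolutions are im2col
gatherings followed by one BLAS matrix product, the transpose direction is
a precomputed sparse scatter matrix, and max-pool switches are recorded for
exact winner-take-all backward routing. Evaluation-mode prediction is a
pure function of weights and input. Memory in the forward pass scales with
batch × patches × kernel volume, so prediction and LRP run in mini-batches.

## Cross-validation harness

One fold per subject; the held-out subject's trials are never seen in
training or validation. Within each fold the majority class is subsampled
(without replacement, seeded) to the minority count, and 1/11 of the
balanced trials form a class-stratified validation set, with quotas
apportioned by largest remainder so the total is exactly
`round(fraction·N)`. Balancing, splitting, initialization and training use
fold-indexed seeds derived from one master seed, so reruns are
bit-identical. Whether the original grid search ran per fold or once
globally is not documented; per-fold is implemented.

ROC curves sweep the unique predicted probabilities; tied scores collapse
into one sweep point, which makes the trapezoidal AUC equal the pairwise
concordance probability (Mann–Whitney with ties counted ½) — a property the
tests verify by brute force and against an independent implementation.

## Composite LRP

For a linear layer $z_k = \sum_j a_j w_{jk} + b_k$, relevance flows
backward as $R_j = \sum_k \frac{z_{jk}}{\sum_j z_{jk}} R_k$ with
$z_{jk} = a_j w_{jk}$ (LRP-0); the epsilon rule adds
$\varepsilon\,\mathrm{sign}(\cdot)$ to the denominator, and the gamma rule
replaces $z_{jk}$ by $z_{jk} + \gamma z_{jk}^+$. Since
$(aw)^+ = a^+w^+ + a^-w^-$, the gamma-modified pass decomposes into three
plain linear passes, which is how the convolutional version avoids ever
materializing the unrolled weight matrix (tests verify conv ≡ unrolled
dense on small instances). Bias terms enter the denominator but receive no
redistributed relevance, so bias-free layers conserve total relevance
exactly; a zero denominator under LRP-0 is stabilized with 1e-9 and a
warning. Max pooling routes relevance winner-take-all to the recorded
argmax (ties to the first element in row-major order); ReLU, dropout and
flatten pass it through unchanged.

The composite assignment is LRP-0 on the three dense layers, epsilon on the
second (upper) convolution block and gamma on the first (lower) block —
the finest grouping consistent with "lower / middle / fully connected".
Defaults $\varepsilon = 0.01$ and $\gamma = 0.25$ are common composite-LRP
practice and configurable. Relevance starts from the pre-sigmoid score of
the predicted class (+logit for patient, −logit for control) so that LRP-0
conservation is exact rather than squashed through the sigmoid.

Heatmaps are computed for held-out trials by the fold model that did not
see them, filtered to correctly classified trials, and averaged — pooled
over all trials by default, per subject as an option (whether the emulated
design averaged subject means or pooled trials is not documented).
Pixel relevance returns to the cortex by equipartition: each vertex
receives its pixel's relevance divided by the pixel's vertex count.

## Critical regions and statistics

The top `round(0.03 · n)` vertices by aggregate relevance (ties at the
cutoff broken by ascending vertex id) form the critical set, grouped by the
source space's hemisphere + region labels — the synthetic ground truth
standing in for an anatomical atlas. Per-subject activity is the mean over
the subject's retained trials and the masked vertices of the windowed
current density (trial-mean; the alternative per-subject summaries are not
documented in the emulated design). Spearman's $\rho$ is the Pearson
correlation of mid-ranks, with the two-sided p-value from
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom and $p = 0$
at $|\rho| = 1$; cells are flagged at $p < 0.05$ with **no**
multiple-testing correction, mirroring the per-cell stars of the emulated
design's table — a deliberate caveat, not an oversight: with 42 cells and
$n = 9$ patients, a few false flags per table are expected under the null.

## Numerical and scale choices

Problem sizes in the tests are chosen for a single desktop CPU. The
end-to-end recovery experiment runs at reduced scale — 2000 vertices, 22
subjects × 40 trials, epoch [50, 350) ms (the analysis window sits fully
inside), 30×60 images, channel plan (8, 16), hidden (32, 16), learning
rate 1e-3, epoch cap 20 with patience 3 — with a single injected
discriminative region (left insular, $\delta = 3$, trial noise 0.5,
subject SD 0.3) and one clinical coupling (PSQI ↔ insular, slope +5,
score noise 0.05). These scenario constants are the package's definition
of "strongly separable" with a near-noiseless clinical coupling; at this
signal-to-noise ratio the LOOCV accuracy is expected near ceiling, the
top-3% relevance mask should overlap the injected cap (Dice well above
0.3), and the configured coupling should reappear as a significant positive
Spearman correlation.

Known limitations: white synthetic noise (above); the full-scale default
architecture (60×120, 64/128 channels, 41 472-dimensional flatten) is
buildable and usable for single-trial prediction and LRP but training it at
the full 3594-trial scale in pure R is not a supported use case; and the
correlation stage inherits the emulated design's uncorrected multiple
testing.

## A worked miniature

```{r mini, eval = FALSE}
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
```

The same configuration and seed reproduce identical artifacts and manifest
checksums; deleting a stage artifact and rerunning with `resume = TRUE`
recomputes only that stage and those downstream.
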