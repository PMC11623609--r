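---
title: "Room reliability and memory reinstatement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Room reliability and memory reinstatement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palacerel)
```

This vignette is the package's account of the science it implements: the
statistical model behind each stage, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where the procedure was genuinely open.

## The scientific question

A spatial context (a "room" in a virtual memory palace) can serve as a
retrieval cue for the items experienced in it. The hypothesis implemented
here is that a room whose neural representation is *reliable* — stable over
time and distinct from other rooms — acts as a better scaffold: the object
later paired with that room is reinstated more strongly during verbal
recall. Critically, reliability is measured from scans taken *before* the
room–object pairings are learned, and decoding of objects is done across
participants, each of whom has an independent random pairing; both features
break the circularity that would otherwise confound room and object
information.

## Stage by stage

### Searchlights (`build_searchlights`)

Surface vertices are grouped into overlapping searchlights: initially one
unit per vertex (members = vertices within `radius_hops` mesh hops; default
2), then greedy redundancy removal. At each step the removable unit with
the largest summed member coverage is deleted — removable meaning every one
of its members would still be covered by at least `min_coverage` units
(study value 10) — and ties go to the lowest center index. The greedy rule
is deterministic for a fixed vertex labeling; since redundancy ties are
broken by index, relabeling the mesh can reach a different (equally valid)
fixed point, so only fixed-point properties are label-invariant. The
"most-redundant-first" criterion and the hop-based radius are this
package's concrete choices; the coverage floor of 10 is the study's.

The hippocampus enters the analysis as two extra candidate units, split
from a subcortical ROI by an anterior/posterior coordinate threshold
(`split_roi_by_axis`, strictly `y > −20` mm vs `y ≤ −20` mm, ties
posterior).

### Event matrices (`events_from_segments`, `video_events`)

Transcripts and stimulus schedules are converted to TR resolution (1.3 s)
with the midpoint rule: TR *t*, covering `[t·TR, (t+1)·TR)` 0-based,
receives the label of the segment containing its midpoint. The midpoint
rule is unbiased for block designs and unambiguous at boundaries.
Same-kind overlapping segments are rejected; where a room and an object
segment cover the same midpoint the later-onset segment wins (ties to the
object), reflecting that the most recent utterance indexes current
retrieval.

### Templates (`build_design_matrix`, `fit_templates`)

Condition regressors are boxcars convolved with a canonical double-gamma
HRF (peak 6 s, undershoot 16 s, undershoot ratio 1/6, truncated at 32 s),
sampled at the TR and z-scored. The specific double-gamma parameterisation
is exposed in `hrf_params` because downstream statistics should be robust
to it; only the template *scaling* changes under reasonable variants, and
every downstream statistic is correlation- or rank-based. Templates are
ordinary least squares coefficients per vertex — no prewhitening, no
nuisance regressors (assumed removed upstream). Room templates are fitted
per run (two sets, needed for the cross-run similarity), object templates
jointly across both object-video runs (one set, as used for classifier
training).

### Room reliability (`similarity_matrix`, `reliability_scores`)

`S[i, j]` is the Pearson correlation between the run-1 template of room
`i` and the run-2 template of room `j`; the matrix is intentionally not
symmetrized. Reliability of room `r` is `S[r, r] − mean(S[r, −r])` using
the off-diagonals of *row* r (run-1 room against the other run-2 rooms);
the column variant is available via `margin = "col"`. Group-level
inference: reliability averaged over rooms within participant, one-sample
t-test across participants per searchlight, BH-FDR across searchlights.

### Cross-participant decoding (`train_classifier`, `predict_evidence`)

The classifier is L2-penalized (ridge) multinomial logistic regression,
fitted with glmnet at a fixed penalty (`regularization_strength`, default
0.01) identical across folds; the fitted object is reduced to a plain
weight matrix and prediction is an explicit softmax, so evidence can be
verified against hand computation. Training samples are the N−1 training
participants' template rows (for room decoding, both per-run room template
sets are used, doubling the training set). Feature standardization before
fitting is on by default and recorded in the spec object. Test timeseries
are aligned to events by a 4-TR shift (the probability at event TR *t*
comes from signal at TR *t* + 4 ≈ 5.2 s, approximating the HRF delay);
trailing event TRs with no shifted signal are dropped and counted.
Accuracy is argmax agreement over labeled TRs, ties to the lowest class id.

The permutation null preserves temporal contiguity: the label sequence is
cut into maximal same-label segments and the segment identities are
permuted without replacement, keeping boundaries and lengths. Network
selection z-scores each candidate unit's accuracy against its null
(accuracies and nulls averaged element-wise across participants and runs
the same way) and takes the top 50.

### Reinstatement scoring (`reinstatement_scores`)

For each object, all TRs across a task's recall runs in which the object
was being verbally described are pooled (the 11 guided runs pooled
together; free recall separate) — a TR-pooled mean, not a mean of per-run
means — regardless of whether the paired room was also recalled. The same
function scores room evidence during room-speaking TRs and, via
`label_map`, room evidence during paired-object-speaking TRs; those two
quantities are the covariates of the partial-correlation control.

### Map-level statistics (`scaffold.R`)

Within participant, the 23 room reliabilities at a searchlight are
Pearson-correlated with the 23 paired objects' reinstatement scores
(pairs with missing scores dropped pairwise; at least 4 complete pairs
required, otherwise the participant is excluded for that task).
Correlations are Fisher-z transformed with |r| clipped at 1 − 1e−7 (so a
degenerate perfect correlation stays finite), averaged across
participants, then across the two recall task types. Pearson (not
Spearman) is used, consistent with the Fisher-z averaging.

Inference is permutation-based throughout: each permutation draws **one**
room-relabeling per participant and applies it to both task types —
equivalent to shuffling the object labels themselves, and essential for
validity: guided and free scores share structure whenever a real effect
exists, and shuffling the tasks independently produces a null that is too
narrow (we observed inflated false-positive rates in noise searchlights
before adopting the shared shuffle). Two-sided p-values use the add-one
correction `p = (1 + #{|null| ≥ |obs|}) / (1 + n_perm)`; FDR is
Benjamini–Hochberg, with significance at `q ≤` threshold (the step-up
convention, which matches the usual worked examples of BH).

**Participant-specific ΔR²** compares the in-sample R² of predicting a
participant's reinstatement scores from their own reliabilities against
the average R² from refitting the same simple regression with each other
participant's reliability vector as the predictor ("refit", not
"transferred coefficients" — the alternative reading would conflate scale
differences between participants with predictive value). Positive ΔR²
means reliability carries idiosyncratic predictive information; the final
map intersects significant positive ΔR² with the significant positive
composite map.

**Partial-correlation control**: both reinstatement scores and
reliabilities are residualized (OLS with intercept) on the two
room-reinstatement covariates within participant; residuals are correlated
and composited identically. Constant covariate columns are dropped
silently — so with all-zero covariates the partial map equals the raw map
exactly — while genuinely collinear non-constant covariates exclude the
participant with a warning. The null shuffles the score residuals within
participant using the same shared permutation stream, which keeps the raw
and partial nulls paired so that their difference (`map_contrast`) has a
valid paired permutation null.

## The synthetic-data generator

`simulate_dataset` emulates the study design: a 23-room palace graph with
degree sequence 16 × 2, 6 × 3, 1 × 4 (configuration-model sampling with
connectivity rejection); 25 participants by default, each with an
independent uniform room–object bijection; two pre-learning room-video
runs, two post-learning object-video runs, two room-video object-recall
runs (10 s videos, 5 s ISI), 11 guided-recall runs cued by 5-room
self-avoiding walks, and one free recall.

The planted-effect model, per participant *s* and room *r*:

* reliability `λ = clip(λ0 + g_r + u_sr, 0.01, 0.99)` with group component
  `g_r ~ N(0, g_sd²)` and idiosyncratic `u_sr ~ N(0, u_sd²)`
  (defaults λ0 = 0.5, g_sd = u_sd = 0.15, a mid-range reliability with
  comparable group and individual variation);
* room reinstatement amplitude `m = γ·λ + noise` (γ = 0.8);
* object reinstatement amplitude `a = α + β_dir·λ + β_med·m + noise`,
  drawn separately for guided and free recall (α = 0.3, amplitude noise
  sd 0.1);
* participant templates mix a group template with idiosyncrasy τ
  (`P = √(1−τ)·G + √τ·η`, default τ = 0.3), and reliability enters the
  neural data as a *mixing weight*: the run-k room pattern is
  `√λ·P + √(1−λ)·fresh noise`, which makes the empirical cross-run
  correlation monotone in λ by construction;
* per run, active condition patterns × amplitudes are convolved with the
  canonical HRF at the TR, unit-variance white vertex noise is added, and
  each vertex is z-scored per run. Recall runs carry the recalled object at
  amplitude `a` plus the cued/recalled room at amplitude `m`; the
  room-video object-recall runs carry the presented room at amplitude 1
  plus covert object reinstatement; the object-video runs carry the
  presented object plus covert reinstatement of its paired room (which is
  what makes room decoding from object videos — the RRCN wiring —
  non-vacuous).

Searchlights in the simulation are *disjoint* vertex blocks (default 40
blocks of 30 vertices), and only a configured fraction (default 25%)
carries any room/object structure; the rest are pure noise, which makes
map-level sensitivity and specificity directly measurable. The generator
also emits a truth table with every planted λ, m and a value, plus
room-reinstatement covariate measurements (`m` plus small measurement
noise, sd 0.02, standing for low-noise network-averaged evidence), and
recall transcripts with segment durations uniform on 3–10 s and a 0.95
per-item recall probability.

What the generator does **not** emulate: hemodynamic nonlinearity,
autocorrelated (AR) noise — the modeled preprocessing removes slow drifts,
and white noise keeps the OLS stage exactly matched to the generative
model — motion or physiological confounds, overlapping searchlights,
between-run template drift other than the λ mixing, and imperfect
transcript timing. Passing tests therefore show that the *statistical
machinery* is correct and calibrated under the design's structure, not
that real data meet these assumptions.

A deliberate consequence of the mediation model: with the default
γ = 0.8, room reinstatement `m` correlates ≈ 0.85 with λ, so partialling
out the covariates genuinely attenuates even a purely direct
reliability→object effect. The "direct path" validation scenario therefore
sets γ = 0 (room reinstatement unrelated to reliability); the "mediated"
scenario keeps γ = 0.8 with β_dir = 0. This is a property of the
generative configurations, not of the analysis.

## Numerical choices and degenerate inputs

* Zero-variance design columns (conditions absent from a run) are kept as
  flagged all-zero columns; their template rows are `NA`, and
  zero-variance patterns propagate `NaN` similarity entries with warnings.
* Zero-variance vertex columns are left at zero by the z-scorer rather
  than `NaN`.
* Constant training features are excluded from classifier fitting (weight
  0); if no feature varies, the model degrades to intercept-only
  (class-frequency probabilities).
* Uniform-evidence argmax ties resolve to the lowest class id; network
  selection ties resolve to the lowest unit id; units with zero null
  variance are excluded from selection with a warning.
* Permutation p-values are never zero (add-one correction); Fisher-z is
  clipped at |r| = 1 − 1e−7.
* All stochastic functions take explicit seeds and restore the caller's
  RNG state, so results are reproducible per (configuration, seed) pair.

## Simulation sizes used by the test suite

The validation battery runs the map machinery at 8 participants, 23 rooms,
40 searchlights × 30 vertices, 200 permutations, with 20 replicate
datasets for null calibration and 3–5 replicates per planted-effect
scenario; decoding transfer uses 4 participants and 60-vertex units. These
sizes give stable rates (hundreds of searchlight-level decisions per
scenario) while keeping the whole battery in the low minutes on one CPU.
The reliability-monotonicity property is checked at 300 vertices per
searchlight, where template-estimation noise is small enough for the
rank-correlation bound to be informative about the statistic rather than
about sampling error.

## Known limitations

* The greedy searchlight reduction is O(n²) in vertices and intended for
  meshes in the low tens of thousands of vertices or below.
* In-sample R² is used in the ΔR² comparison (both models are fitted on
  the same 23 pairs); the comparison is between predictors, not a
  generalization estimate.
* The partial-correlation control removes *linear* dependence on the two
  covariates only.
* With 200 permutations the smallest attainable p is 1/201 ≈ 0.005, which
  bounds how far FDR can discriminate very strong effects; increase
  `n_perm` for finer maps.
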