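---
title: "Question-answering encoding models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Question-answering encoding models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(qaenc)
```

## The model

A language encoding model predicts a brain signal timecourse from features of
a speech stimulus and is judged by its held-out prediction correlation. The
models in this package make the feature space itself the scientific object:
each feature is a yes/no question expressing a qualitative theory of language
selectivity ("Does the input mention a specific location?"). An annotator —
in practice an LLM, here any deterministic function with the same contract —
answers every question for a short text window ending at each word, giving a
binary embedding of the stimulus. A linear model per voxel (fMRI) or
electrode (ECoG) then weights each question's answers, so a large weight for
a question in a target reads directly as "this theory explains this target's
responses": the weight vector of one question across targets is a
selectivity map.

The pipeline is, in order:

1. **Windowing** (`make_windows`). One window per word: the up-to-*n* most
   recent words (n-gram mode, default 10), or all words within a fixed
   context length in seconds (used for the ECoG timescales 0 s, 1.5 s, 3 s).
2. **Annotation** (`annotate`, `ensemble_vote`). Binary answers per
   (window, question); several annotators combine by majority vote, with
   ties answering yes — a fixed, testable rule. Answers are cached so
   annotation is idempotent and resumable; the cache key is the
   (annotator id, question text, window text) tuple.
3. **Resampling and delays** (`lanczos_downsample`, `add_fir_delays`). For
   fMRI, word-rate features are low-pass resampled to the scan grid with a
   Lanczos kernel (3 lobes, cutoff at the output Nyquist `1/(2 TR)`, weights
   normalised to unit row sum so constants survive), then each column is
   copied at FIR delays of 1–4 samples (TR = 2 s by default) so the linear
   model can absorb the hemodynamic lag without an explicit response
   function.
4. **Fitting** (`fit_ridge_cv`). Per-target ridge regression; each target's
   penalty is chosen from a log-spaced grid (default `1`–`1e4`, 10 points)
   to maximise mean held-out correlation over contiguous-chunk CV folds
   (default 20-sample chunks dealt round-robin into 5 folds). Design and
   response columns are z-scored with training statistics only; held-out
   data never touches the scaling. Shuffled row-wise CV is deliberately
   unavailable: narrative timecourses are autocorrelated and row-wise
   shuffling inflates held-out estimates.
5. **Scoring** (`score_predictions`). Per-target Pearson correlation between
   prediction and observation. Degenerate targets (constant prediction or
   observation) score the sentinel 0 and carry a validity flag rather than
   propagating `NaN` into map arithmetic.

## Stability selection

To compress a large question bank to a compact set, `stability_select`
refits an L1-penalised regression of each target on the design over many
chunk-respecting subsamples (complementary contiguous-chunk halves,
B = 100 by default) and a shared lasso penalty grid. A question counts as
selected in a fit when any of its delay columns is nonzero — questions, not
delays, are the scientific unit. Its selection frequency is the maximum over
the grid of the fraction of fits selecting it, pooled over targets by the
mean; `target_k` keeps the top *k* by frequency, with ties broken by mean
absolute coefficient and then qid, a total order for reproducibility.

The penalty grid matters more than any other tuning choice. The default runs
from `lambda_max` (the smallest penalty zeroing every coefficient) down to
the larger of `0.2 * lambda_max` and the pure-noise entry scale
`mean(sd(y)) * sqrt(log(F) / n_sub)`. The floor keeps the grid in the sparse
region of the path: without it, a null response shrinks `lambda_max` itself
to the noise scale and deep-path fits select most columns in most
subsamples, making selection frequencies meaningless. With the floor, null
frequencies stay near zero while planted questions — which enter the path
far earlier — reach the top of the ranking.

## Map-level evaluation

Weight maps are evaluated with four statistics, all masked to well-predicted
targets where appropriate (`top_fraction_mask`, boundary ties to the lower
index):

* **Reference-map correlation** (`map_correlation`): Pearson across targets
  against an external map, e.g. a meta-analytic selectivity map. Raw (not
  z-scored) weights are correlated; correlation is scale-free, so the choice
  only matters for degenerate flags, and it is recorded by the validity
  attribute.
* **Permutation test on the mean** (`permutation_pvalue_mean`): the
  reference map — not the weight map — is permuted across targets per
  question, preserving the weight maps' spatial statistics; the p-value uses
  the add-one rule, so its floor is `1/(1 + n_perm)`.
* **BH-FDR** (`bh_fdr`): the standard step-up rule with an inclusive
  boundary, delegated to `stats::p.adjust` and cross-checked in the tests
  against a brute-force evaluation of the definition.
* **Inter-subject consistency** (`intersubject_consistency`): each subject's
  maps are correlated with the template-averaged, back-projected mean of the
  other subjects'. Alignment operators are consumed as user-supplied linear
  resamplers; registration itself is out of scope, and identity operators
  serve for synthetic data.
* **Condition averages** (`condition_average_response`): stimulus segments
  tagged to a question are averaged after a fixed hemodynamic shift of +2
  samples (about 4 s at TR = 2 s, configurable); comparing these averages to
  the fitted weights is the condition-average (generative-causal-testing
  style) check of a selectivity map.

## The ECoG branch

`build_multiscale_features` annotates the transcript at the word level and
with 1.5 s and 3 s of context, so a 35-question bank yields 105 QA columns;
per-word spectral features (supplied as a matrix) are appended unchanged.
`fit_lagged_models` fits one cross-validated ridge model per lag of the
response grid relative to word onset (negative lags are allowed — context
carries information before a word is heard), scoring each electrode by its
held-out CV correlation. Downstream, electrodes are kept by their minimum
score across models, clustered by Ward agglomeration on z-scored,
timescale-averaged question-weight profiles at the best lag, and compared
across modalities by interpolating vertex maps to electrode positions with
an inverse-distance-weighted average of the 10 nearest vertices (a
coincident vertex is copied exactly; the result is a convex combination).
`crossmodal_correlation_test` then correlates interpolated fMRI values with
ECoG weights per question over the best fraction of electrodes, and tests
the mean paired difference against draws that permute the electrode
assignment — one shared permutation across questions per draw, preserving
the paired structure.

## The synthetic-data generator

Every statistical claim in the test suite is exercised on fully synthetic
data with planted structure; nothing requires recordings or LLM calls.

`generate_synthetic_corpus` samples a word stream in which each question has
a small disjoint trigger lexicon; the per-word trigger probability is
calibrated as `1 - (1 - rate)^(1/n)` so each question is positive in a
target fraction of n-gram windows. The default per-question window rate is
0.10: with 35 disjoint single-word lexicons and 10-gram windows the trigger
probabilities must sum well below 1, which caps the feasible per-question
rate near 0.12. Gold annotations are computed from the lexicons by
construction, so the matching keyword annotator reproduces them exactly —
faithfulness 1.0 is a structural identity, not an empirical finding.

`simulate_bold_responses` projects the resampled gold features through
sparse planted weights (default: 5 active questions, each driving 20% of
200 targets), convolves each target with a canonical double-gamma HRF (peak
5 s, undershoot 15 s, ratio 1/6), and adds AR(1) noise (coefficient 0.3, a
realistic fMRI autocorrelation that keeps chunked CV meaningful) scaled per
target to the requested SNR. At SNR *s* the signal fraction is `s/(1+s)`
and the attainable test correlation is about `sqrt(s/(1+s))`.
`simulate_ecog_responses` places the linear signal at exactly one planted
lag with matched-scale noise elsewhere, with optionally graded per-electrode
SNR.

What the generator does *not* emulate: vascular and physiological noise
structure, annotator error (gold annotations are exact), correlated
question semantics, non-linearities, and spatial smoothness of maps.
Passing tests therefore certify the estimators and their statistics, not
performance on real recordings.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations for a
single-CPU desk run: the standard fMRI condition is a 35-question bank,
1000 scans at TR = 2 s (about 4000 words), 200 targets, SNR 1; stability
selection uses B = 50 over 10 seeds; calibration batteries use 200
replicates of 199-permutation tests and 1000 random p-vectors. The
square-root attenuation check runs at 2000 scans and 30 targets: its closed
form is an asymptotic statement that presumes negligible weight-estimation
error, and at 1000 scans with 140 regressors estimation noise still biases
the mean held-out correlation visibly below the ceiling.

Other numerical decisions, fixed once: ensemble ties answer yes; constant
annotation columns get off-diagonal correlation 0 (flagged) so descriptive
heatmaps stay computable; degenerate correlations are sentinel 0 with a
flag everywhere; clustering of identical profiles is degenerate but
deterministic; all generators are pure functions of (configuration, seed).

## A small worked example

```{r example, eval = FALSE}
bank <- qa35_bank()
corp <- generate_synthetic_corpus(bank, n_words = 2000, seed = 1)
gt   <- synthetic_ground_truth(bank, n_targets = 50, n_active = 5, seed = 1)
sim  <- simulate_bold_responses(gt, corp$gold, tr = 2, n_tr = 500, snr = 1, seed = 2)

X   <- add_fir_delays(sim$X_tr)
sel <- stability_select(X, sim$Y, B = 50, target_k = 5, seed = 3)
sel$selected_qids            # compare with gt$active_qids

m  <- fit_ridge_cv(compact_design(X, sel), sim$Y)
glance(m)
autoplot(sel)
```

## Known limitations

* The LLM-backed annotator is a contract, not an implementation: any
  function from (window text, question) to {0, 1} plugs in, and the shipped
  keyword annotator is the deterministic reference. Faithfulness of a real
  LLM annotator must be checked against gold labels with
  `annotator_faithfulness`.
* Registration, high-gamma extraction and baseline feature spaces are
  consumed as inputs, never computed.
* Serialization uses plain-text TSV/JSON formats; there are no volumetric
  or HDF5 writers.
* The shipped 35-question bank is a synthetic reconstruction of a compact
  published set whose full wording is not public; treat it as a template.
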