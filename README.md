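# qaenc

Interpretable **question-answering (QA) encoding models** of brain responses
to narrative language, in R.

Data-driven encoding models predict brain activity from language stimuli
with high accuracy but explain little: their features are opaque embedding
dimensions. QA encoding models replace them with qualitative theories
phrased as yes/no questions — *Does the input mention a specific location?*
*Does the input include dialogue?* — answered by an annotator (an LLM in
practice, any deterministic function here) for a short window of text ending
at every word. The resulting binary embedding feeds linear models per voxel
(fMRI) or per electrode and lag (ECoG), so each fitted weight is directly
readable: the weights of one question across cortex form a **selectivity
map** for that theory.

The package is for computational neuroscientists who want to fit, compress
and evaluate such models:

* **Corpus layer** — timed transcripts (TSV or Praat TextGrid), question
  banks (JSON/CSV), windowing (n-gram or seconds-of-context), pluggable
  annotators with caching and ensemble voting, answer-correlation summaries.
* **Modeling layer** — Lanczos resampling of word-rate features to the scan
  grid, FIR delays for the hemodynamic lag, per-target ridge regression with
  contiguous-chunk cross-validation, held-out correlation scoring.
* **Compression** — stability selection: resampled lasso fits over
  chunk-respecting half-samples rank questions by how reliably they enter
  sparse models, reducing a large bank to a compact set (`target_k`).
* **Map evaluation** — best-predicted-target masks, reference-map
  correlation, permutation tests on mean correlations, Benjamini–Hochberg
  FDR, inter-subject consistency through user-supplied alignment operators,
  condition-average (generative-causal-testing style) comparisons.
* **ECoG branch** — multi-timescale QA features (word / 1.5 s / 3 s; 105
  columns for a 35-question bank) plus spectral columns, per-lag models
  around word onset, electrode selection, Ward clustering of weight
  profiles, and fMRI↔ECoG cross-modality correlation with a paired
  permutation test.
* **Synthetic data** — a deterministic generator with planted weights,
  HRF-convolved AR(1)-noise BOLD responses and lagged ECoG responses, so the
  whole pipeline is testable offline.

The core fit is, per target $v$ with design $X$ (windows annotated, resampled,
FIR-delayed, z-scored on training rows):

$$\hat\beta_v = \arg\min_\beta \lVert y_v - X\beta\rVert_2^2 + \alpha_v \lVert\beta\rVert_2^2,$$

with $\alpha_v$ chosen per target to maximise mean held-out Pearson $r$ over
contiguous-chunk CV folds, and model quality reported as the held-out test
correlation.

## Worked example

Recover a planted 5-question support from a synthetic 35-question study:

```r
library(qaenc)
bank <- qa35_bank()                       # packaged 35-question bank
corp <- generate_synthetic_corpus(bank, n_words = 2000, seed = 1)
gt   <- synthetic_ground_truth(bank, n_targets = 50, n_active = 5, seed = 1)
sim  <- simulate_bold_responses(gt, corp$gold, tr = 2, n_tr = 500, snr = 1, seed = 2)

X   <- add_fir_delays(sim$X_tr)           # 35 questions x 4 FIR delays
sel <- stability_select(X, sim$Y, B = 50, target_k = 5, seed = 3)
gt$active_qids
#> [1] "q01" "q04" "q11" "q14" "q23"
sel$selected_qids
#> [1] "q11" "q01" "q04" "q23" "q14"

m <- fit_ridge_cv(compact_design(X, sel), sim$Y)
glance(m)
#> # A tibble: 1 × 5
#>   n_features n_targets mean_cv_r median_alpha n_degenerate
#>        <int>     <int>     <dbl>        <dbl>        <int>
#> 1         20        50     0.467         464.            0
```

The selection recovers exactly the five planted questions; the compact
20-column model reaches a mean held-out correlation of 0.467 across the 50
synthetic targets at SNR 1 (the noise ceiling across all targets, most of
which carry partial or no signal, sits well below 1). `autoplot(sel)`,
`autoplot(m_scores)` and `tidy()`/`glance()` methods cover the usual
inspection steps.

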