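---
title: "Methods: conformal uncertainty and fairness auditing for embedding classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformal uncertainty and fairness auditing for embedding classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its statistical machinery: the
models and procedures, the tunable parameters and why their defaults are what
they are, the numerical edge cases, and the limits of what the synthetic
cohorts can demonstrate.

## The pipeline

A frozen foundation-model backbone turns each dermatology image into a
fixed-length embedding; everything in this package happens downstream of
that. The workflow is

1. **cohort** — embeddings + labels + demographics (synthetic or from files);
2. **split** — train / validation / test / calibration;
3. **train** — a small MLP head, optionally with the dynamic F1-weight sampler;
4. **calibrate** — a score quantile on the held-out calibration set;
5. **predict-sets** — one conformal label set per test sample;
6. **audit** — demographic-stratified uncertainty tables.

Each stage writes a plain-text artifact, and all randomness flows from one
master seed through `derive_seed()`, so a run is reproducible end to end.

## Split protocol

`split_cohort()` takes 20% of *each class* for the test set (floored;
remainders stay in the pool), 10% of all records for validation, and then
carves the calibration set out of the remaining training records (10% of
them by default, or an exact count via `calibration_size`). Stratifying the
test split keeps per-class metrics defined even for classes with a few tens
of records; the calibration set must come from the same pool as training
data but never be trained on, because the coverage guarantee needs
calibration and test samples to be exchangeable and the model to be
independent of both.

## The dynamic F1-weight sampler

Severe class imbalance starves minority classes of gradient signal. The
sampler resamples each epoch's training indices with per-class weights:

- **Initialization** (inverse frequency): `w_i = (1/n_i) / Σ_j (1/n_j)`.
- **Refresh** every `refresh_period` epochs: evaluate the current model on
  the validation set, compute mean classwise F1 over `k_folds` stratified
  folds, and set `w_i = (1/x̄_i) / Σ_j (1/x̄_j)`. Folding smooths the
  estimate for rare classes; the model is only re-evaluated, never retrained
  per fold, since refreshing happens inside a fixed training budget.
- **Regulation**: with `m = mean(w)` and `s` the *population* SD of `w`,
  classes with `w_i ≥ λ = m + λ_m·s` (the challenging ones) keep their
  weight, capped at `β = m + β_m·s`; classes below the threshold are
  baseline-sampled at the mean weight. The result is renormalized. With all
  weights equal, `s = 0` and the rule is the identity.

Defaults `λ_m = 1`, `β_m = 2`, `refresh_period = 4`, `k_folds = 10` are the
dermoscopy profile; clinical-photograph collections with fewer samples per
class refresh faster (`refresh_period = 2`). Population SD is used because
weight vectors are short (one entry per class) and the sample SD would be
noticeably inflated at 8 entries. `f1_floor = 1e-3` replaces zero (or
undefined) classwise F1 so inverse weights stay finite; a class the model
gets entirely wrong then receives essentially the whole F1 weight mass
before regulation, which is the intended "focus on the hardest class"
behaviour with the cap as the safety valve.

Two parts of the regulation rule admit alternative readings (whether `β`
caps hard classes or floors easy ones, and what "baseline" means). The rule
above — cap at `β`, baseline at the mean — is the package's documented
interpretation; `baseline_rule` exposes `"min"` and `"keep"` variants so a
different reading is one configuration line away. Per-record draw
probability is `w_c / n_c`, which makes the *expected class share* of an
epoch exactly `w_c` regardless of class sizes.

Sampling changes the class mixture seen by the optimizer, so the predicted
probabilities are tilted toward minority classes relative to the data
frequencies. The conformal layer is agnostic to this: whatever the model's
probabilities are, the calibration quantile adapts. What sampling buys is
minority recall; what it costs is some majority-class confidence. The
package treats "with sampler" and "without" as first-class configurations
precisely so that this trade-off can be audited.

## The MLP head

`train_head()` fits a multilayer perceptron: `n_blocks` blocks of
fully-connected layer (each half the width of the previous), 1-D batch
normalization, ReLU and dropout, then a final linear layer onto the classes.
The canonical profile for 2048-dimensional foundation embeddings is 6 blocks
(`mlp_config_paper()`); the package default is sized for 64-dimensional test
embeddings (3 blocks), since widths halve and must not drop below the class
count. Activation, optimizer (Adam) and loss (cross-entropy) are fixed
defaults — reasonable, explicitly chosen, and config-exposed; batch size 128
and learning rate 1e-3 likewise. Small experiments in the test suite pass
batch 32–64 and learning rate 3e-3 instead, because a few hundred training
records at batch 128 give Adam too few steps to converge within a short
epoch budget — this is an optimizer-step-count effect, not a property of the
data. Best-epoch selection is by validation macro-F1, and the per-epoch log
(loss, validation macro-F1, active class weights) doubles as the sampler's
audit trail. Training is deterministic given the config seed: epoch index
draws, dropout masks and initialization all derive from it. Inference uses
batch-norm running statistics with dropout off, so prediction is
deterministic and row-normalized.

## Split conformal prediction

The nonconformity score of a labelled sample is `s = 1 − p̂(true label)` —
the minimal "deviation between prediction and truth" functional on
probability outputs. With `n` calibration scores, `calibrate()` takes the
`⌈(n+1)(1−α)⌉`-th smallest as the threshold `q̂`; the rank is clamped to
`[1, n+1]`, with rank `n+1` yielding `q̂ = +∞` (every set is the full label
space; this happens at `α = 0` or whenever `α < 1/(n+1)`), and `α = 1`
clamping to the minimum score. A test sample's prediction set is every label
with `1 − p̂_label ≤ q̂`, ordered by descending probability with ties broken
by column order. For exchangeable calibration/test data this yields the
marginal guarantee `1 − α ≤ P(truth ∈ set) ≤ 1 − α + 1/(n+1)`.

Three deliberate choices:

- **Reported confidences are raw probabilities**, not renormalized within
  the set — a two-label set `{MEL: 32%, BKL: 28%}` intentionally shows that
  40% of the mass lies outside it.
- **Nonempty fallback**: when no label clears the threshold, the argmax
  label is returned alone. A clinical consumer of a prediction set cannot act
  on an empty set; the fallback can only increase coverage, so the lower
  bound survives. It is toggleable (`nonempty = FALSE`) for exact-procedure
  studies.
- **Labels with zero probability never enter a set** even under `q̂ = +∞`,
  keeping reported confidences strictly positive.

`ece_mce()` audits the top-label set confidences against set correctness
with equal-width bins (`n_bins = 10` by default; a confidence of exactly 1
falls in the last bin). ECE is the count-weighted mean absolute gap over
nonempty bins, MCE the maximum gap, so ECE ≤ MCE always.

## The fairness audit

All audit views are computed from the prediction sets plus a metadata table:

- **A2 accuracy**: per class, the share of test samples whose truth is among
  the two most probable labels *of their set* (a singleton set has only rank
  1). "Top two" is read within the set, not over the full probability row —
  the set is what a user of the system sees.
- **Set-size distributions** per demographic level; set length is the
  per-sample difficulty signal, so a subgroup with systematically larger
  sets is getting less decisive predictions. `setsize_permutation_test()`
  formalizes the comparison (statistic: largest pairwise gap in level means;
  null by permuting levels).
- **Ground-truth confidence distributions** (violin-plot data), restricted
  to sets that contain the truth, optionally further restricted to rank ≤ 2
  (`top2_guarantee()`).
- **Region ranking**: among samples whose truth is in the top two, the
  percentage of each anatomical site per class, in decreasing order — the
  denominators are the per-class top-2 totals, matching the restriction
  under which the ranking is meaningful.
- Age bands are `<30`, `30–60`, `>60` with left-inclusive edges ( 30 →
  `30–60`, 60 → `>60`); `"unknown"` is a first-class level everywhere, so a
  cohort with no patient metadata still audits.

## The synthetic cohort generator

`generate_cohort()` draws isotropic Gaussian class clusters with unit base
noise, class means on mutually orthogonal random directions scaled so every
pair of means is exactly `class_separation` apart. That family is the
simplest in which attainable F1 is a monotone, controllable function of one
scalar. Demographics are sampled independently of class by default — fairness
gaps must be *planted*, never accidental — via three effect types:

- `noise_mult`: inflate a subgroup's within-class residuals
  (out-of-distribution difficulty);
- `shift` / `cohort_shift`: constant offsets along a fixed direction
  (covariate shift between sources);
- `separation_mult`: shrink a subgroup's class means toward the cohort
  centre (boundary difficulty — the subgroup's classes genuinely overlap).

The distinction between the first and third matters and is itself a finding
the test suite encodes: a ReLU network is typically *overconfident* far from
its training data, so noise-inflated samples often get confidently wrong
predictions and therefore *small* prediction sets — the set-size audit
detects boundary difficulty (`separation_mult < 1`) far more reliably than
norm-inflating noise. Lower coverage and A2, not set size, are the audit
signals for the out-of-distribution kind. Only effects that place samples in
genuinely ambiguous regions should be expected to widen sets.

Default demographic marginals emulate a dermoscopy registry: slight male
excess, age mass in 30–60, anatomical sites dominated by the torso. Class
counts default to the ISIC 2019 proportions (`isic2019_counts()`), whose
48:1 extreme imbalance is the regime the sampler exists for.

What the generator does **not** emulate: the actual geometry of foundation
embeddings (anisotropy, manifold structure, label noise), inter-class
semantic similarity (synthetic classes are mutually equidistant), or
correlations between demographics and class prevalence. Passing tests
demonstrate the *procedures* — coverage, calibration arithmetic, sampler
mechanics, audit counting — under controlled conditions; they do not certify
accuracy or fairness of any particular real-world classifier.

## Numerical choices and problem sizes

- Weight vectors must be nonnegative and sum to 1 within 1e-9; probability
  rows within 1e-6. Batch-norm epsilon 1e-5, momentum 0.1; log-loss clipped
  at 1e-12.
- The replicated coverage study (`coverage_experiment()`) uses 8 classes at
  ISIC proportions rescaled to ~8,000 records, embedding dimension 64,
  calibration size 500, `α = 0.2`, 10 training epochs, 20 replicate seeds.
  `class_separation = 3.5` places the trained head near 70% test accuracy —
  the realistic difficulty regime for this task. This choice is load-bearing
  for verifying the *upper* coverage bound: at much larger separations the
  head saturates, most calibration scores collapse into numerical ties at
  zero, and the upper bound (which assumes continuous scores) becomes
  vacuous while the lower bound still holds. The same study is what
  `scripts/acceptance.R` runs.
- Sampler-efficacy and audit-detection experiments in the test suite use
  4-class cohorts of 1,500–1,900 records at embedding dimension 16 with
  10–15 epochs — small enough to replicate twenty times in seconds, large
  enough that binomial noise does not swamp the planted effects.

## Known limitations

- The coverage guarantee is *marginal*. Per-subgroup coverage can and does
  drift below `1 − α` for planted-hard subgroups; the audit measures this
  rather than preventing it. Class-conditional (Mondrian) calibration is out
  of scope.
- The score `1 − p̂(truth)` ignores the probability ordering below the true
  label; adaptive/cumulative scores that shape set composition differently
  are out of scope.
- The pure-R MLP is intended for embedding-sized inputs and desk-scale
  cohorts; it is not a GPU training stack, and the 2048-dimensional 6-block
  profile trains in minutes, not seconds.
- With heavy sampling toward minorities, majority-class probabilities
  shrink; ECE/MCE of the conformal confidences should be compared between
  sampler configurations rather than interpreted in isolation.
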