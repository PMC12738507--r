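# dermconformal

Conformal uncertainty quantification and demographic fairness auditing for
skin-lesion classifiers built on frozen foundation-model embeddings.

Modern dermatology AI increasingly consumes fixed-length embedding vectors
from a frozen pre-trained backbone and trains only a small classifier head on
top. Two problems follow the data into that head: **severe class imbalance**
(in the 8-class ISIC 2019 ground truth, melanocytic nevus has 11,557 images
and dermatofibroma 239 — roughly 48:1) and **opaque, uncalibrated
confidence**, which matters clinically because error rates can differ across
patient sex, age and ethnicity. `dermconformal` addresses both for anyone
auditing such a classifier:

- **Challenge-regulated F1-weight dynamic sampling.** Training epochs are
  resampled with per-class weights, initialized at inverse frequency,
  `w_i = (1/n_i) / Σ_j (1/n_j)`, and periodically refreshed from validation
  performance as inverse mean classwise F1 over k folds,
  `w_i = (1/x̄_i) / Σ_j (1/x̄_j)`. A threshold `λ = mean(w) + λ_m·SD(w)`
  decides which classes keep their F1 weight (capped at
  `β = mean(w) + β_m·SD(w)`) and which are baseline-sampled at the mean
  weight, so hard minority classes get seen more without starving the rest.
- **Split conformal prediction.** With nonconformity score
  `s = 1 − p̂(true label)` on a held-out calibration set of size *n*, the
  threshold is the `⌈(n+1)(1−α)⌉`-th smallest score, and the prediction set
  for a test sample is every label with `1 − p̂ ≤ q̂`. For exchangeable data
  this guarantees marginal coverage
  `1 − α ≤ P(Y_test ∈ C(X_test)) ≤ 1 − α + 1/(n+1)`.
- **Fairness audit.** Prediction-set size, A2 accuracy (truth among the two
  most probable set labels), ground-truth confidence distributions, ECE/MCE
  and anatomical-region rankings, all stratified by sex, age band
  (`<30`, `30–60`, `>60`), site and cohort — plus a permutation test that
  flags subgroups with systematically larger sets.
- **A seeded synthetic cohort generator** (Gaussian class clusters with
  controllable separation, imbalance, demographics and plantable subgroup
  difficulty) so the whole pipeline is testable with no image data or
  embedding API.

## Worked example

```r
library(dermconformal)

spec <- cohort_spec(isic2019_counts(total = 4000), embed_dim = 64,
                    class_separation = 3.5, seed = 42)
cohort <- generate_cohort(spec)
sp <- split_cohort(cohort, seed = 43, calibration_size = 300)

cfg <- mlp_config(input_dim = 64, epochs = 25, batch_size = 64,
                  learning_rate = 3e-3, seed = 44, sampler = sampler_config())
model <- train_head(subset_cohort(cohort, sp$train),
                    subset_cohort(cohort, sp$validation), cfg)
#> <mlp_head> 64->32->16->8->8 classes, best epoch 24 (val macro-F1 0.528)

cal <- subset_cohort(cohort, sp$calibration)
calib <- calibrate(nonconformity_scores(predict_proba(model, cal), cal$labels),
                   alpha = 0.2)
#> <calibration_result> n=300 alpha=0.200 q_hat=0.7863

test <- subset_cohort(cohort, sp$test)
sets <- build_sets(predict_proba(model, test), calib, truth = test$labels)
sets[[3]]
#> <prediction_set SYN_000708> { 'MEL': 31.95%, 'BKL': 28.43% } truth=MEL

audit_report(sets, cohort$demographics)
#> <audit_report> 797 samples, coverage 0.812, ECE 0.2832, MCE 0.3726
#> A2 accuracy by class (%):
#>  class   n   a2_pct
#>     AK  28 82.14286
#>    BCC 110 84.54545
#>    BKL  87 75.86207
#>     DF   8 25.00000
#>    MEL 150 85.33333
#>     NV 385 81.81818
#>    SCC  21 80.95238
#>   VASC   8 37.50000
```

Reading the output: the calibration threshold `q_hat = 0.786` means any label
predicted with probability above `1 − 0.786 = 0.214` enters a test sample's
prediction set. Sample `SYN_000708` gets a two-label set — the model cannot
separate MEL from BKL for it, and the set says so instead of bluffing.
Empirical coverage 0.812 honours the `α = 0.2` guarantee (the band here is
[0.800, 0.803] in expectation; a single split fluctuates around it). A2
accuracy is high for well-represented classes and visibly lower for the
rarest ones (DF, VASC have 8 test samples each) — exactly the kind of gap
the audit exists to surface.

The same workflow runs from a shell via the thin CLI in `inst/cli/`:

```sh
inst/cli/dermconformal run-all --config cfg.yaml --out run/
```

with per-stage subcommands (`simulate`, `split`, `train`, `calibrate`,
`predict-sets`, `audit`) that resume from the artifacts under `run/`. Real
data plugs in through the same files the synthetic generator writes: an
embeddings JSON (image ID → vector), a ground-truth CSV (one-hot or
`id,label`), and an optional metadata CSV.

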