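# Small end-to-end experiment runners shared by the acceptance suite.

# Train on an imbalanced 4-class cohort with one hard minority class and
# return the minority's test recall, with or without the dynamic sampler.
minority_recall_replicate <- function(seed, use_sampler) {
  co <- generate_cohort(cohort_spec(
    c(C1 = 600, C2 = 600, C3 = 600, C4 = 60), embed_dim = 16,
    class_separation = 5, class_noise = c(1, 1, 1, 2), seed = seed))
  sp <- split_cohort(co, seed = derive_seed(seed, "split"))
  smp <- if (use_sampler) sampler_config(refresh_period = 2, k_folds = 5) else NULL
  cfg <- mlp_config(input_dim = 16, n_blocks = 2, epochs = 10, batch_size = 32,
                    learning_rate = 3e-3, seed = derive_seed(seed, "train"),
                    sampler = smp)
  m <- suppressWarnings(train_head(subset_cohort(co, sp$train),
                                   subset_cohort(co, sp$validation), cfg))
  te <- subset_cohort(co, sp$test)
  p <- predict_proba(m, te)
  pred <- colnames(p)[max.col(p, ties.method = "first")]
  mean(pred[te$labels == "C4"] == "C4")
}

# Full pipeline on a balanced 4-class cohort, optionally with boundary
# difficulty planted on one sex; returns the prediction sets + demographics.
subgroup_audit_replicate <- function(seed, planted, class_separation = 4) {
  eff <- if (planted)
    list(list(attribute = "sex", level = "male", separation_mult = 0.4))
  else list()
  co <- generate_cohort(cohort_spec(
    stats::setNames(rep(400, 4), paste0("C", 1:4)), embed_dim = 16,
    class_separation = class_separation, subgroup_effects = eff, seed = seed))
  sp <- split_cohort(co, seed = derive_seed(seed, "split"))
  cfg <- mlp_config(input_dim = 16, n_blocks = 2, epochs = 15, batch_size = 32,
                    learning_rate = 3e-3, seed = derive_seed(seed, "train"))
  m <- train_head(subset_cohort(co, sp$train),
                  subset_cohort(co, sp$validation), cfg)
  cal <- subset_cohort(co, sp$calibration)
  calib <- calibrate(nonconformity_scores(predict_proba(m, cal), cal$labels), 0.2)
  te <- subset_cohort(co, sp$test)
  list(sets = build_sets(predict_proba(m, te), calib, truth = te$labels),
       demographics = te$demographics)
}

mean_size_by <- function(rep, attribute) {
  sizes <- vapply(rep$sets, `[[`, numeric(1), "size")
  ids <- vapply(rep$sets, `[[`, character(1), "id")
  grp <- rep$demographics[[attribute]][match(ids, rep$demographics$id)]
  tapply(sizes, grp, mean)
}
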