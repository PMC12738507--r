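# Shared builders for small in-code fixtures.

# A prediction_set with given ordered labels/confidences.
toy_set <- function(id, labels, conf, truth = NA_character_) {
  structure(list(id = id, labels = labels, confidence = conf,
                 truth = truth, size = length(labels)),
            class = "prediction_set")
}

as_sets <- function(...) structure(list(...), class = "prediction_sets")

# A normalized class_weights built directly (bypassing the constructors under test).
new_cw <- function(w) {
  structure(list(weights = w / sum(w), origin = "f1"), class = "class_weights")
}

# Nearest-class-mean probe: an independent linear classifier used as an
# oracle against generated cohorts (never the package's own model).
nearest_mean_predict <- function(train_x, train_labels, test_x) {
  mu <- do.call(rbind, lapply(levels(train_labels), function(cl)
    colMeans(train_x[train_labels == cl, , drop = FALSE])))
  d2 <- outer(rowSums(test_x^2), rep(1, nrow(mu))) -
    2 * test_x %*% t(mu) + outer(rep(1, nrow(test_x)), rowSums(mu^2))
  factor(levels(train_labels)[max.col(-d2)], levels = levels(train_labels))
}

# Small trained model on a mildly overlapping 2-class cohort, reused by
# several conformal/audit tests.
small_model_fixture <- function(seed = 11, separation = 3, n = 200) {
  co <- generate_cohort(cohort_spec(c(A = n, B = n), embed_dim = 8,
                                    class_separation = separation, seed = seed))
  sp <- split_cohort(co, seed = seed + 1)
  cfg <- mlp_config(input_dim = 8, n_blocks = 1, epochs = 10, batch_size = 32,
                    learning_rate = 3e-3, seed = seed + 2)
  model <- train_head(subset_cohort(co, sp$train),
                      subset_cohort(co, sp$validation), cfg)
  list(cohort = co, split = sp, model = model)
}

as_sets_list <- function(lst) structure(lst, class = "prediction_sets")
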