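#' Configure the challenge-regulated F1 sampler
#'
#' The dynamic sampler keeps two regulation parameters, both expressed in
#' population standard deviations above the mean of the current weight vector:
#' the threshold `lambda` decides which classes are baseline-sampled (weights
#' below it — the easy majority classes) and which keep their F1-derived
#' weight (the challenging minority classes), and the minimum weight `beta`
#' caps the F1-weighted classes so a single very hard class cannot swallow the
#' whole epoch. The dermoscopy profile used throughout the package is
#' `lambda_multiplier = 1`, `beta_multiplier = 2`, refresh every 4 epochs with
#' 10-fold mean classwise F1; a clinical-photograph profile would refresh
#' every alternate epoch (`refresh_period = 2`).
#'
#' @param lambda_multiplier SDs above the mean weight for the threshold.
#' @param beta_multiplier SDs above the mean weight for the cap.
#' @param refresh_period Epochs between weight refreshes (>= 1).
#' @param k_folds Folds for the mean classwise F1 on the validation set (>= 2).
#' @param f1_floor Small positive value replacing zero F1 scores (inverse
#'   weights must stay finite).
#' @param baseline_rule How classes below the threshold are treated:
#'   `"mean"` (default, set to the mean weight), `"min"` (min of own weight and
#'   the mean), or `"keep"` (left untouched).
#' @return A `sampler_config`.
#' @export
sampler_config <- function(lambda_multiplier = 1, beta_multiplier = 2,
                           refresh_period = 4, k_folds = 10, f1_floor = 1e-3,
                           baseline_rule = c("mean", "min", "keep")) {
  if (!is_count(refresh_period) || refresh_period < 1)
    bad_field("refresh_period", "must be an integer >= 1")
  if (!is_count(k_folds) || k_folds < 2)
    bad_field("k_folds", "must be an integer >= 2")
  if (!is.numeric(f1_floor) || f1_floor <= 0)
    bad_field("f1_floor", "must be > 0")
  structure(list(lambda_multiplier = lambda_multiplier,
                 beta_multiplier = beta_multiplier,
                 refresh_period = as.integer(refresh_period),
                 k_folds = as.integer(k_folds),
                 f1_floor = f1_floor,
                 baseline_rule = match.arg(baseline_rule)),
            class = "sampler_config")
}

new_class_weights <- function(w, origin) {
  if (any(w < 0)) stop("class weights must be nonnegative")
  w <- w / sum(w)
  stopifnot(abs(sum(w) - 1) <= 1e-9)
  structure(list(weights = w, origin = origin), class = "class_weights")
}

#' @export
print.class_weights <- function(x, ...) {
  cat(sprintf("<class_weights origin=%s>\n", x$origin))
  print(round(x$weights, 4))
  invisible(x)
}

#' Inverse-frequency class weights
#'
#' Initial sampler weights `w_i = (1/n_i) / sum_j (1/n_j)`: rare classes get
#' proportionally larger sampling weight.
#'
#' @param class_counts Per-class sample counts, all >= 1 (zero counts have no
#'   finite inverse and are an error).
#' @return A `class_weights` with origin `"frequency"`.
#' @examples
#' frequency_weights(c(10, 40))  # 0.8, 0.2
#' @export
frequency_weights <- function(class_counts) {
  if (!is.numeric(class_counts) || length(class_counts) == 0)
    bad_field("class_counts", "must be a numeric vector")
  if (any(class_counts <= 0))
    bad_field("class_counts", "zero/negative counts have undefined inverse weight")
  inv <- 1 / class_counts
  new_class_weights(inv / sum(inv), "frequency")
}

#' Inverse-mean-F1 class weights
#'
#' Refresh weights from validation performance: `w_i = (1/x_i) / sum_j (1/x_j)`
#' where `x_i` is the mean classwise F1 over k folds. Classes the model finds
#' hard (low F1) are sampled more. F1 values below `f1_floor` (including exact
#' zeros and non-finite values for classes absent from validation) are raised
#' to the floor so weights stay finite.
#'
#' @param mean_f1 Per-class mean F1 scores in `[0, 1]`.
#' @param f1_floor Positive floor replacing tiny/zero F1 (default 1e-3).
#' @return A `class_weights` with origin `"f1"`.
#' @examples
#' f1_weights(c(0.5, 1.0))  # 2/3, 1/3
#' @export
f1_weights <- function(mean_f1, f1_floor = 1e-3) {
  if (!is.numeric(mean_f1) || length(mean_f1) == 0)
    bad_field("mean_f1", "must be a numeric vector")
  bad <- is.finite(mean_f1) & (mean_f1 < 0 | mean_f1 > 1)
  if (any(bad)) bad_field("mean_f1", "values must lie in [0, 1]")
  x <- ifelse(!is.finite(mean_f1) | mean_f1 < f1_floor, f1_floor, mean_f1)
  inv <- 1 / x
  new_class_weights(inv / sum(inv), "f1")
}

#' Regulate raw weights with the threshold/cap rule
#'
#' Applies the challenge-regulation step: with `m = mean(w)` and `s` the
#' population SD of `w`, the threshold is `lambda = m + lambda_multiplier * s`
#' and the cap is `beta = m + beta_multiplier * s`. Classes at or above the
#' threshold (the challenging, F1-weighted classes) keep their weight capped at
#' `beta`; classes below the threshold are baseline-sampled at the mean weight
#' (under the default `baseline_rule = "mean"`). The result is renormalized.
#' When all weights are equal the SD is zero, the threshold equals the mean,
#' and the rule is the identity.
#'
#' @param raw A `class_weights` (normalized).
#' @param cfg A [sampler_config()].
#' @return A `class_weights` with origin `"regulated"`.
#' @examples
#' w <- f1_weights(c(0.2, 1, 1, 1))
#' regulate_weights(w, sampler_config())
#' @export
regulate_weights <- function(raw, cfg) {
  stopifnot(inherits(raw, "class_weights"), inherits(cfg, "sampler_config"))
  w <- raw$weights
  m <- mean(w)
  s <- pop_sd(w)
  lambda <- m + cfg$lambda_multiplier * s
  beta <- m + cfg$beta_multiplier * s
  hi <- w >= lambda
  out <- w
  out[hi] <- pmin(w[hi], beta)
  out[!hi] <- switch(cfg$baseline_rule,
                     mean = m,
                     min = pmin(w[!hi], m),
                     keep = w[!hi])
  new_class_weights(out / sum(out), "regulated")
}

#' Draw one epoch of training indices from class weights
#'
#' Samples `n_draws` record indices with replacement. Each record's
#' probability is `w_c / n_c` for its class `c`, so the expected class share of
#' the draws equals the class weight exactly. Deterministic given `seed`.
#'
#' @param weights A `class_weights`; names (if any) must cover the label levels.
#' @param labels Factor (or integer) class labels, one per record.
#' @param n_draws Number of indices to draw.
#' @param seed Integer seed.
#' @return Integer vector of length `n_draws` indexing the records.
#' @export
sample_epoch <- function(weights, labels, n_draws, seed = 1L) {
  stopifnot(inherits(weights, "class_weights"))
  labels <- as.factor(labels)
  w <- weights$weights
  if (length(w) != nlevels(labels))
    stop("weight vector length must equal number of label levels")
  counts <- tabulate(labels, nbins = nlevels(labels))
  starved <- w > 0 & counts == 0
  if (any(starved))
    stop("positive-weight class with no records: ",
         paste(levels(labels)[starved], collapse = ", "))
  p <- w[as.integer(labels)] / counts[as.integer(labels)]
  set.seed(seed)
  sample.int(length(labels), n_draws, replace = TRUE, prob = p)
}

# classwise F1 of hard predictions; classes absent from `truth` get NA.
classwise_f1 <- function(truth, pred, n_classes) {
  f1 <- rep(NA_real_, n_classes)
  for (c in seq_len(n_classes)) {
    tp <- sum(truth == c & pred == c)
    fp <- sum(truth != c & pred == c)
    fn <- sum(truth == c & pred != c)
    if (tp + fn == 0) next  # class absent
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- tp / (tp + fn)
    f1[c] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  f1
}

#' Mean classwise F1 over k stratified folds
#'
#' Partitions the validation set into `k` stratified folds, computes per-fold
#' classwise F1 of the argmax predictions, and averages each class over the
#' folds in which it appears. The model is only re-evaluated, never retrained.
#' If `k` exceeds the smallest class count it is reduced (with a warning);
#' `k = 1` degenerates to whole-set classwise F1.
#'
#' @param prob_matrix Validation probability matrix (rows = samples).
#' @param labels Validation labels (factor or integer, matched to the columns).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return Numeric vector of per-class mean F1 (NA for classes absent from the
#'   whole validation set).
#' @export
kfold_mean_f1 <- function(prob_matrix, labels, k = 10, seed = 1L) {
  if (NROW(prob_matrix) == 0) stop("empty validation set")
  labels <- as.factor(labels)
  stopifnot(NROW(prob_matrix) == length(labels))
  n_classes <- ncol(prob_matrix)
  pred <- max.col(prob_matrix, ties.method = "first")
  truth <- as.integer(labels)
  counts <- tabulate(truth, nbins = n_classes)
  k_eff <- max(1L, min(k, min(counts[counts > 0])))
  if (k_eff < k)
    warning(sprintf("k reduced from %d to %d (smallest class count)", k, k_eff))
  if (k_eff == 1L) return(classwise_f1(truth, pred, n_classes))
  set.seed(seed)
  fold <- integer(length(truth))
  for (c in which(counts > 0)) {
    idx <- sample(which(truth == c))
    fold[idx] <- rep_len(seq_len(k_eff), length(idx))
  }
  per_fold <- vapply(seq_len(k_eff), function(f) {
    sel <- fold == f
    classwise_f1(truth[sel], pred[sel], n_classes)
  }, numeric(n_classes))
  rowMeans(per_fold, na.rm = TRUE)
}
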