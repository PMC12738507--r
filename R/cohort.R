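#' ISIC-2019-proportioned class counts
#'
#' Per-class image counts of the 8-class ISIC 2019 challenge ground truth
#' (UNK-labelled images excluded), with melanocytic nevus at 11,557 and
#' dermatofibroma at 239 — a max:min imbalance of roughly 48:1. Useful as a
#' realistic imbalance profile for synthetic cohorts; `total` rescales the
#' counts proportionally (each class keeps at least 10 samples).
#'
#' @param total Optional target total sample count; `NULL` returns the raw counts.
#' @return Named integer vector over classes MEL, NV, BCC, AK, BKL, DF, VASC, SCC.
#' @export
isic2019_counts <- function(total = NULL) {
  counts <- c(MEL = 4522, NV = 11557, BCC = 3323, AK = 867,
              BKL = 2624, DF = 239, VASC = 253, SCC = 628)
  if (is.null(total)) return(counts)
  stopifnot(is.numeric(total), total >= length(counts) * 10)
  scaled <- pmax(10L, as.integer(round(counts * total / sum(counts))))
  stats::setNames(scaled, names(counts))
}

# Default demographic marginals: a mostly-Caucasian dermoscopy cohort with the
# usual male excess and a 30-60 age bulk; single source cohort unless a shift
# is being planted.
default_marginals <- function() {
  list(
    sex = c(male = 0.54, female = 0.46),
    age_band = c("<30" = 0.15, "30-60" = 0.55, ">60" = 0.30),
    anatom_site = c("anterior torso" = 0.25, "posterior torso" = 0.20,
                    "lower extremity" = 0.18, "upper extremity" = 0.15,
                    "head/neck" = 0.12, "palms/soles" = 0.05,
                    "lateral torso" = 0.03, "oral/genital" = 0.02),
    cohort = c(A = 1)
  )
}

#' Specify a synthetic embedding cohort
#'
#' Defines a seeded, demographically annotated, class-imbalanced cohort of
#' fixed-length embedding vectors. Each class is an isotropic Gaussian cluster
#' with unit base noise; class means sit on mutually orthogonal random
#' directions scaled so that every pair of class means is `class_separation`
#' apart, which makes attainable F1 a monotone function of the separation.
#' Difficulty can be planted per class (`class_noise`) or per demographic
#' subgroup (`subgroup_effects`), and a covariate shift can be applied to one
#' source cohort (`cohort_shift`). Demographics are sampled independently of
#' class, so fairness gaps only exist where they are explicitly planted.
#'
#' @param class_counts Named or unnamed vector of per-class sample counts (all >= 1).
#' @param embed_dim Embedding length (default 64; accepts e.g. 2048).
#' @param class_separation Distance between any two class means (>= 0).
#' @param class_noise Per-class noise scale (recycled; default 1 = base noise).
#' @param subgroup_effects List of effects, each
#'   `list(attribute=, level=, noise_mult=, shift=, separation_mult=)`: records
#'   in the subgroup get their within-class residual scaled by `noise_mult`
#'   (out-of-distribution difficulty), their mean moved by `shift` along a
#'   fixed unit direction (covariate offset), and/or their class mean shrunk
#'   toward the cohort centre by `separation_mult` (< 1 plants boundary
#'   difficulty: the subgroup's classes genuinely overlap more, which is the
#'   kind of difficulty that widens conformal prediction sets).
#' @param cohort_shift Scalar mean offset applied to every cohort level except
#'   the first, along a fixed unit direction (covariate shift between sources).
#' @param demographic_marginals Named list of probability vectors for
#'   `sex`, `age_band`, `anatom_site`, `cohort`; each must sum to 1. The level
#'   `"unknown"` is legitimate anywhere (cohorts without metadata).
#' @param class_names Optional class labels; defaults to the names of
#'   `class_counts`, else `C1..Ck` (or the 8 ISIC codes when k = 8).
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [split_cohort()]
#' @export
cohort_spec <- function(class_counts,
                        embed_dim = 64,
                        class_separation = 6,
                        class_noise = 1,
                        subgroup_effects = list(),
                        cohort_shift = 0,
                        demographic_marginals = default_marginals(),
                        class_names = NULL,
                        seed = 1L) {
  if (!is_count(class_counts) || any(class_counts < 1))
    bad_field("class_counts", "must be integer counts >= 1")
  if (!is_count(embed_dim) || embed_dim < 2)
    bad_field("embed_dim", "must be an integer >= 2")
  if (!is.numeric(class_separation) || class_separation < 0)
    bad_field("class_separation", "must be >= 0")
  k <- length(class_counts)
  class_noise <- rep_len(class_noise, k)
  if (any(class_noise <= 0)) bad_field("class_noise", "must be positive")
  if (embed_dim < k)
    bad_field("embed_dim", "must be >= number of classes (orthogonal class means)")
  need <- c("sex", "age_band", "anatom_site", "cohort")
  if (!all(need %in% names(demographic_marginals)))
    bad_field("demographic_marginals",
              paste("must contain", paste(need, collapse = ", ")))
  for (a in need) {
    p <- demographic_marginals[[a]]
    if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      bad_field("demographic_marginals",
                sprintf("probabilities for '%s' must be named, nonnegative, sum to 1", a))
  }
  for (eff in subgroup_effects) {
    if (!all(c("attribute", "level") %in% names(eff)))
      bad_field("subgroup_effects", "each effect needs 'attribute' and 'level'")
    if (!eff$attribute %in% need)
      bad_field("subgroup_effects", sprintf("unknown attribute '%s'", eff$attribute))
  }
  if (is.null(class_names)) {
    class_names <- names(class_counts)
    if (is.null(class_names))
      class_names <- if (k == 8) names(isic2019_counts()) else paste0("C", seq_len(k))
  }
  if (length(class_names) != k || anyDuplicated(class_names))
    bad_field("class_names", "must be unique and match length(class_counts)")
  structure(
    list(class_counts = stats::setNames(as.integer(class_counts), class_names),
         embed_dim = as.integer(embed_dim),
         class_separation = class_separation,
         class_noise = class_noise,
         subgroup_effects = subgroup_effects,
         cohort_shift = cohort_shift,
         demographic_marginals = demographic_marginals,
         class_names = class_names,
         seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Generate a synthetic embedding cohort
#'
#' Draws exactly `sum(class_counts)` records according to a [cohort_spec()].
#' Record IDs follow the pattern `SYN_<zero-padded index>`. Demographics are
#' sampled independently of class from the spec's marginals; an `age_approx`
#' value is drawn uniformly within the sampled age band. Subgroup effects and
#' the cohort shift are applied after the base class clusters are drawn.
#'
#' @param spec A `cohort_spec`.
#' @return A `cohort` object: list with `x` (numeric matrix, one row per record,
#'   rownames = IDs), `labels` (factor over the class names), `demographics`
#'   (data.frame with id, sex, age_approx, age_band, anatom_site, cohort),
#'   and the originating `spec`.
#' @examples
#' co <- generate_cohort(cohort_spec(c(a = 30, b = 30), embed_dim = 8, seed = 7))
#' table(co$labels)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) bad_field("spec", "must be a cohort_spec")
  set.seed(spec$seed)
  k <- length(spec$class_counts)
  d <- spec$embed_dim
  n <- sum(spec$class_counts)

  # Orthonormal class-mean directions via QR; pairwise mean distance is then
  # exactly class_separation after scaling by 1/sqrt(2).
  q <- qr.Q(qr(matrix(stats::rnorm(d * k), d, k)))
  means <- t(q) * spec$class_separation / sqrt(2)  # k x d

  labels <- rep(seq_len(k), times = spec$class_counts)
  x <- matrix(stats::rnorm(n * d), n, d) * spec$class_noise[labels] + means[labels, , drop = FALSE]

  ids <- sprintf("SYN_%06d", seq_len(n))
  rownames(x) <- ids

  m <- spec$demographic_marginals
  demo <- data.frame(
    id = ids,
    sex = sample(names(m$sex), n, TRUE, prob = m$sex),
    age_band = sample(names(m$age_band), n, TRUE, prob = m$age_band),
    anatom_site = sample(names(m$anatom_site), n, TRUE, prob = m$anatom_site),
    cohort = sample(names(m$cohort), n, TRUE, prob = m$cohort),
    stringsAsFactors = FALSE)
  demo$age_approx <- ifelse(
    demo$age_band == "<30", stats::runif(n, 5, 29.99),
    ifelse(demo$age_band == "30-60", stats::runif(n, 30, 59.99),
           ifelse(demo$age_band == ">60", stats::runif(n, 60, 90), NA_real_)))
  demo$age_approx <- round(demo$age_approx)
  demo <- demo[c("id", "sex", "age_approx", "age_band", "anatom_site", "cohort")]

  u <- rep(1 / sqrt(d), d)  # fixed unit direction for planted mean shifts
  for (eff in spec$subgroup_effects) {
    hit <- demo[[eff$attribute]] == eff$level
    if (!any(hit)) next
    mult <- if (is.null(eff$noise_mult)) 1 else eff$noise_mult
    shift <- if (is.null(eff$shift)) 0 else eff$shift
    sep_mult <- if (is.null(eff$separation_mult)) 1 else eff$separation_mult
    mu <- means[labels[hit], , drop = FALSE]
    x[hit, ] <- mu * sep_mult + (x[hit, , drop = FALSE] - mu) * mult
    if (shift != 0) x[hit, ] <- sweep(x[hit, , drop = FALSE], 2, u * shift, `+`)
  }
  if (spec$cohort_shift != 0) {
    shifted <- demo$cohort != names(m$cohort)[1]
    if (any(shifted))
      x[shifted, ] <- sweep(x[shifted, , drop = FALSE], 2, u * spec$cohort_shift, `+`)
  }

  structure(list(x = x,
                 labels = factor(spec$class_names[labels], levels = spec$class_names),
                 demographics = demo,
                 spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d records, %d classes, embed_dim %d\n",
              nrow(x$x), nlevels(x$labels), ncol(x$x)))
  print(table(x$labels))
  invisible(x)
}

#' Subset a cohort by record IDs
#'
#' @param cohort A `cohort`.
#' @param ids Character vector of record IDs to keep (order preserved).
#' @return A `cohort` restricted to `ids`.
#' @export
subset_cohort <- function(cohort, ids) {
  stopifnot(inherits(cohort, "cohort"))
  miss <- setdiff(ids, rownames(cohort$x))
  if (length(miss))
    stop("unknown record IDs: ", paste(utils::head(miss, 5), collapse = ", "))
  idx <- match(ids, rownames(cohort$x))
  structure(list(x = cohort$x[idx, , drop = FALSE],
                 labels = cohort$labels[idx],
                 demographics = cohort$demographics[idx, , drop = FALSE],
                 spec = cohort$spec),
            class = "cohort")
}

#' Split a cohort into train / validation / test / calibration sets
#'
#' The test set takes 20% of each class (floored, remainder stays in the pool);
#' the validation set takes 10% of all records from the remaining pool; the
#' calibration set — the held-out samples whose nonconformity-score quantile
#' later sets the conformal threshold — is carved out of the post-split
#' training set (10% of it by default, or an exact `calibration_size`).
#' The four parts are pairwise disjoint and exhaustive, and the split is
#' deterministic given `seed`.
#'
#' @param cohort A `cohort`.
#' @param seed Integer seed.
#' @param test_frac Per-class test fraction (default 0.2).
#' @param val_frac Overall validation fraction (default 0.1).
#' @param cal_frac Calibration fraction of the post-split train set (default 0.1).
#' @param calibration_size Exact calibration count, overriding `cal_frac`.
#' @return A `dataset_split`: list of ID vectors `train`, `validation`, `test`,
#'   `calibration`.
#' @export
split_cohort <- function(cohort, seed = 1L, test_frac = 0.2, val_frac = 0.1,
                         cal_frac = 0.1, calibration_size = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  tab <- table(cohort$labels)
  small <- names(tab)[tab < 10]
  if (length(small))
    stop("classes with fewer than 10 records cannot be split: ",
         paste(small, collapse = ", "))
  set.seed(seed)
  ids <- rownames(cohort$x)
  test <- character(0)
  for (cl in levels(cohort$labels)) {
    cl_ids <- ids[cohort$labels == cl]
    test <- c(test, sample(cl_ids, floor(test_frac * length(cl_ids))))
  }
  pool <- setdiff(ids, test)
  validation <- sample(pool, floor(val_frac * length(ids)))
  train0 <- setdiff(pool, validation)
  n_cal <- if (is.null(calibration_size)) floor(cal_frac * length(train0))
           else as.integer(calibration_size)
  if (n_cal > length(train0)) stop("calibration_size exceeds available train records")
  calibration <- sample(train0, n_cal)
  train <- setdiff(train0, calibration)
  structure(list(train = train, validation = validation,
                 test = test, calibration = calibration),
            class = "dataset_split")
}

#' Convert an age in years to the audit's age band
#'
#' Bands are `<30`, `30-60` and `>60`, with left-inclusive edges: 30 falls in
#' `30-60`, 60 falls in `>60`. `NA` maps to `"unknown"`.
#'
#' @param age Numeric vector of ages.
#' @return Character vector of band labels.
#' @export
age_to_band <- function(age) {
  out <- ifelse(is.na(age), "unknown",
                ifelse(age < 30, "<30", ifelse(age < 60, "30-60", ">60")))
  out
}
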