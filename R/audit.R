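# Flatten prediction sets to one row per sample, optionally joined to
# demographic metadata by record ID.
sets_frame <- function(sets, metadata = NULL) {
  rows <- lapply(sets, function(s) {
    rank <- match(s$truth, s$labels)
    data.frame(id = s$id, truth = s$truth, size = s$size,
               top_label = s$labels[1], top_conf = s$confidence[1],
               gt_in_set = !is.na(rank),
               gt_rank = ifelse(is.na(rank), NA_integer_, rank),
               gt_conf = ifelse(is.na(rank), NA_real_, s$confidence[rank]),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (!is.null(metadata)) {
    ord <- df$id
    df <- merge(df, metadata, by = "id", all.x = TRUE, sort = FALSE)
    df <- df[match(ord, df$id), , drop = FALSE]
    rownames(df) <- NULL
    for (col in setdiff(names(metadata), "id"))
      if (is.character(df[[col]])) df[[col]][is.na(df[[col]])] <- "unknown"
  }
  df
}

check_ordered <- function(sets) {
  ok <- vapply(sets, function(s) !is.unsorted(rev(s$confidence)), logical(1))
  if (!all(ok))
    stop("prediction-set entries must be ordered by descending confidence")
}

#' A2 accuracy: truth among the two most probable set labels
#'
#' For each class, the percentage of test samples whose ground-truth label is
#' among the two most probable labels of their prediction set, out of all test
#' samples of that class. "Two most probable" means the top two entries by
#' reported confidence within the set (a singleton set only has rank 1).
#' Optionally stratified by a demographic attribute; groups with zero samples
#' of a class report `NA`, never 0.
#'
#' @param sets A `prediction_sets` with truths.
#' @param metadata Optional data.frame keyed by `id` with demographic columns.
#' @param group_by Optional attribute name in `metadata` to stratify by.
#' @return data.frame with columns class, group (if stratified), n, a2_pct.
#' @export
a2_accuracy <- function(sets, metadata = NULL, group_by = NULL) {
  check_ordered(sets)
  df <- sets_frame(sets, metadata)
  if (any(is.na(df$truth))) stop("every set needs a truth label for A2 accuracy")
  df$hit2 <- !is.na(df$gt_rank) & df$gt_rank <= 2
  split_cols <- if (is.null(group_by)) list(class = df$truth)
                else list(class = df$truth, group = df[[group_by]])
  agg <- stats::aggregate(df$hit2, by = split_cols,
                   FUN = function(z) c(n = length(z), pct = 100 * mean(z)))
  out <- data.frame(agg[setdiff(names(agg), "x")],
                    n = as.integer(agg$x[, "n"]), a2_pct = agg$x[, "pct"])
  out[order(out$class), , drop = FALSE]
}

#' Prediction-set size distribution per demographic level
#'
#' Counts of set sizes within each level of a demographic attribute — the set
#' length of a sample is the model's difficulty signal, so systematically
#' larger sets in one subgroup flag a fairness concern. Histogram counts per
#' level sum to the number of audited samples in that level.
#'
#' @param sets A `prediction_sets`.
#' @param metadata data.frame keyed by `id` with the attribute column.
#' @param attribute Attribute name (e.g. `"sex"`, `"age_band"`, `"anatom_site"`).
#' @return data.frame with columns level, size, count.
#' @export
set_size_distribution <- function(sets, metadata, attribute) {
  df <- sets_frame(sets, metadata)
  if (!attribute %in% names(df)) stop("attribute not present in metadata: ", attribute)
  tab <- as.data.frame(table(level = df[[attribute]], size = df$size),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "count"
  tab$size <- as.integer(tab$size)
  tab[tab$count > 0 | TRUE, , drop = FALSE]
}

#' Ground-truth confidence values per class
#'
#' The distribution of the confidence assigned to the ground-truth label by
#' each prediction set that contains it (sets missing the truth are excluded) —
#' the data behind per-class violin plots. Optionally stratified.
#'
#' @inheritParams a2_accuracy
#' @return data.frame with columns class, group (if stratified), confidence.
#' @export
gt_confidence_values <- function(sets, metadata = NULL, group_by = NULL) {
  df <- sets_frame(sets, metadata)
  df <- df[df$gt_in_set, , drop = FALSE]
  out <- data.frame(class = df$truth, confidence = df$gt_conf)
  if (!is.null(group_by)) out$group <- df[[group_by]]
  out[order(out$class), , drop = FALSE]
}

#' Ground-truth confidences where the truth ranks in the top two
#'
#' Restriction of [gt_confidence_values()] to sets where the ground truth is
#' among the two most probable labels — combining the A2-accuracy view with
#' the guarantee view: high values here mean the correct label carries a
#' usable share of the coverage even in multi-label sets.
#'
#' @param sets A `prediction_sets` with truths.
#' @return data.frame with columns class, confidence.
#' @export
top2_guarantee <- function(sets) {
  check_ordered(sets)
  df <- sets_frame(sets)
  df <- df[!is.na(df$gt_rank) & df$gt_rank <= 2, , drop = FALSE]
  out <- data.frame(class = df$truth, confidence = df$gt_conf)
  out[order(out$class), , drop = FALSE]
}

#' Classwise ranking of anatomical regions of occurrence
#'
#' Among samples whose ground truth is in the top two labels of their
#' prediction set, the percentage of each anatomical site per class, ranked in
#' decreasing order. Percentages within a class sum to 100 (up to rounding)
#' when every sample has a known site.
#'
#' @param sets A `prediction_sets` with truths.
#' @param metadata data.frame keyed by `id` with an `anatom_site` column.
#' @return data.frame with columns class, rank, region, pct.
#' @export
region_table <- function(sets, metadata) {
  check_ordered(sets)
  df <- sets_frame(sets, metadata)
  if (!"anatom_site" %in% names(df)) stop("metadata must contain 'anatom_site'")
  df <- df[!is.na(df$gt_rank) & df$gt_rank <= 2, , drop = FALSE]
  out <- lapply(split(df, df$truth), function(g) {
    tab <- sort(table(g$anatom_site), decreasing = TRUE)
    data.frame(class = g$truth[1], rank = seq_along(tab),
               region = names(tab), pct = 100 * as.numeric(tab) / nrow(g))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Permutation test for subgroup differences in set size
#'
#' Tests whether mean prediction-set size differs between the levels of a
#' demographic attribute more than chance allows. The statistic is the
#' maximum absolute pairwise difference of level means; the null distribution
#' comes from permuting the level labels.
#'
#' @param sets A `prediction_sets`.
#' @param metadata data.frame keyed by `id`.
#' @param attribute Attribute to test.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return list with `statistic`, `p_value`, `group_means`.
#' @export
setsize_permutation_test <- function(sets, metadata, attribute,
                                     n_perm = 999, seed = 1L) {
  df <- sets_frame(sets, metadata)
  g <- factor(df[[attribute]])
  if (nlevels(g) < 2) stop("attribute needs at least two levels")
  stat <- function(sizes, grp) {
    mu <- tapply(sizes, grp, mean)
    max(stats::dist(mu))
  }
  obs <- stat(df$size, g)
  set.seed(seed)
  null <- replicate(n_perm, stat(df$size, sample(g)))
  list(statistic = obs,
       p_value = (1 + sum(null >= obs)) / (n_perm + 1),
       group_means = tapply(df$size, g, mean))
}

#' Assemble the demographic fairness-audit report
#'
#' Combines all stratified uncertainty views over one batch of prediction
#' sets: overall and per-attribute A2 accuracy, set-size histograms,
#' ground-truth confidence distributions, top-2 guarantee values, the
#' anatomical-region ranking (when sites are available), ECE/MCE of the
#' top-label conformal confidences against set correctness, and the empirical
#' coverage.
#'
#' @param sets A `prediction_sets` with truths.
#' @param metadata data.frame keyed by `id` with demographic columns.
#' @param attributes Attributes to stratify by (default sex, age_band,
#'   anatom_site, cohort; silently skips those absent from the metadata).
#' @param ece_bins Bins for [ece_mce()] (default 10).
#' @return An `audit_report` list.
#' @export
audit_report <- function(sets, metadata,
                         attributes = c("sex", "age_band", "anatom_site", "cohort"),
                         ece_bins = 10) {
  check_ordered(sets)
  attributes <- intersect(attributes, names(metadata))
  df <- sets_frame(sets, metadata)
  rep <- list(
    n = length(sets),
    coverage = empirical_coverage(sets),
    a2_overall = a2_accuracy(sets),
    a2_by_group = lapply(stats::setNames(attributes, attributes), function(a)
      a2_accuracy(sets, metadata, group_by = a)),
    setsize_hist = lapply(stats::setNames(attributes, attributes), function(a)
      set_size_distribution(sets, metadata, a)),
    gt_confidences = gt_confidence_values(sets),
    top2_guarantees = top2_guarantee(sets),
    calibration = ece_mce(df$top_conf, df$gt_in_set, n_bins = ece_bins)
  )
  if ("anatom_site" %in% attributes)
    rep$region_table <- region_table(sets, metadata)
  structure(rep, class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat(sprintf("<audit_report> %d samples, coverage %.3f, ECE %.4g, MCE %.4g\n",
              x$n, x$coverage, x$calibration$ece, x$calibration$mce))
  cat("A2 accuracy by class (%):\n")
  print(x$a2_overall, row.names = FALSE)
  invisible(x)
}
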