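#' Nonconformity scores from predicted probabilities
#'
#' The nonconformity score of a labelled sample is the deviation between the
#' prediction and the truth, `s = 1 - p(true label)`: 0 when the model is
#' certain of the truth, close to 1 when it assigns the truth almost no mass.
#'
#' @param prob_matrix Probability matrix (rows sum to 1).
#' @param truth True labels: factor/character matched against column names, or
#'   integer column indices.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
nonconformity_scores <- function(prob_matrix, truth) {
  prob_matrix <- as.matrix(prob_matrix)
  idx <- if (is.numeric(truth)) as.integer(truth)
         else match(as.character(truth), colnames(prob_matrix))
  if (any(is.na(idx)) || any(idx < 1) || any(idx > ncol(prob_matrix)))
    stop("truth labels outside the probability matrix columns")
  stopifnot(length(idx) == nrow(prob_matrix))
  1 - prob_matrix[cbind(seq_len(nrow(prob_matrix)), idx)]
}

#' Calibrate the conformal threshold
#'
#' Split-conformal calibration: with `n` calibration scores and error rate
#' `alpha`, the threshold is the `ceil((n+1)(1-alpha))`-th smallest score —
#' the finite-sample-corrected `1-alpha` quantile. The rank is clamped to
#' `[1, n+1]`; when it exceeds `n` (e.g. `alpha = 0`) the threshold is `+Inf`
#' and every prediction set is the full label space. This choice yields the
#' marginal coverage guarantee
#' `1 - alpha <= P(truth in set) <= 1 - alpha + 1/(n+1)` for exchangeable
#' calibration and test samples.
#'
#' @param scores Nonempty numeric vector of calibration nonconformity scores.
#' @param alpha User-chosen error rate in `[0, 1]`.
#' @return A `calibration_result`: list with `alpha`, `n`, `scores`, `q_hat`.
#' @examples
#' calibrate(c(0.1, 0.2, 0.3, 0.4), alpha = 0.2)$q_hat  # 0.4
#' @export
calibrate <- function(scores, alpha) {
  if (length(scores) == 0) stop("empty calibration scores")
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]")
  n <- length(scores)
  rank <- ceiling((n + 1) * (1 - alpha))
  rank <- max(1L, min(n + 1L, as.integer(rank)))
  q_hat <- if (rank > n) Inf else sort(scores)[rank]
  structure(list(alpha = alpha, n = n, scores = scores, q_hat = q_hat),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> n=%d alpha=%.3f q_hat=%.4f\n",
              x$n, x$alpha, x$q_hat))
  invisible(x)
}

#' Build the conformal prediction set for one probability row
#'
#' Includes every label whose nonconformity `1 - p` is at most the calibrated
#' threshold, ordered by descending probability (ties broken by column order).
#' Reported per-label confidences are the raw predicted probabilities; labels
#' with zero probability are never reported. If the thresholded set is empty,
#' the argmax label is returned alone when `nonempty = TRUE` (a documented
#' deviation from the pure procedure that guarantees a usable prediction).
#'
#' @param prob_row Numeric probability vector (named by class, or names taken
#'   from `calib` consumers); sums to 1.
#' @param calib A [calibrate()] result.
#' @param id Sample identifier stored in the set.
#' @param truth Optional true label (character) stored for auditing.
#' @param nonempty Guarantee a nonempty set via the argmax fallback (default TRUE).
#' @return A `prediction_set`: list with `id`, `labels`, `confidence`, `truth`,
#'   `size`.
#' @export
build_set <- function(prob_row, calib, id = NA_character_, truth = NA_character_,
                      nonempty = TRUE) {
  stopifnot(inherits(calib, "calibration_result"))
  p <- as.numeric(prob_row)
  lab <- names(prob_row)
  if (is.null(lab)) lab <- paste0("C", seq_along(p))
  keep <- which((1 - p) <= calib$q_hat & p > 0)
  if (length(keep) == 0 && nonempty) keep <- which.max(p)
  ord <- keep[order(-p[keep], keep)]
  structure(list(id = id, labels = lab[ord], confidence = p[ord],
                 truth = truth, size = length(ord)),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  entries <- paste(sprintf("'%s': %05.2f%%", x$labels, 100 * x$confidence),
                   collapse = ", ")
  cat(sprintf("<prediction_set %s> { %s }%s\n", x$id, entries,
              if (!is.na(x$truth)) paste0(" truth=", x$truth) else ""))
  invisible(x)
}

#' Build prediction sets for a whole probability matrix
#'
#' @param prob_matrix Probability matrix (class-named columns, ID rownames).
#' @param calib A [calibrate()] result.
#' @param truth Optional vector of true labels (character/factor).
#' @param nonempty See [build_set()].
#' @return A `prediction_sets` list (one `prediction_set` per row) with the
#'   calibration attached as attribute `calibration`.
#' @export
build_sets <- function(prob_matrix, calib, truth = NULL, nonempty = TRUE) {
  prob_matrix <- as.matrix(prob_matrix)
  ids <- rownames(prob_matrix)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(prob_matrix)))
  if (!is.null(truth)) truth <- as.character(truth)
  sets <- lapply(seq_len(nrow(prob_matrix)), function(i) {
    build_set(prob_matrix[i, ], calib, id = ids[i],
              truth = if (is.null(truth)) NA_character_ else truth[i],
              nonempty = nonempty)
  })
  structure(sets, class = "prediction_sets", calibration = calib)
}

#' Empirical marginal coverage of prediction sets
#'
#' Fraction of sets containing their true label.
#'
#' @param sets A `prediction_sets` (or list of `prediction_set`).
#' @param truths Optional true labels overriding those stored in the sets.
#' @return Coverage in `[0, 1]`.
#' @export
empirical_coverage <- function(sets, truths = NULL) {
  if (is.null(truths)) truths <- vapply(sets, `[[`, character(1), "truth")
  truths <- as.character(truths)
  if (any(is.na(truths))) stop("every set needs a truth label")
  covered <- mapply(function(s, t) t %in% s$labels, sets, truths)
  mean(covered)
}

#' Expected and maximum calibration error
#'
#' Bins confidences into `n_bins` equal-width bins on `[0, 1]`; the per-bin gap
#' is the absolute difference between mean correctness and mean confidence.
#' ECE is the sample-weighted mean gap over nonempty bins, MCE the maximum
#' gap. In the conformal audit, confidences are the per-set top-label
#' probabilities and correctness is membership of the truth in the set.
#'
#' @param confidences Numeric vector in `[0, 1]`.
#' @param correctness Logical (or 0/1) vector of the same length.
#' @param n_bins Number of bins (default 10).
#' @return Named list `list(ece =, mce =)`.
#' @export
ece_mce <- function(confidences, correctness, n_bins = 10) {
  if (any(!is.finite(confidences)) || any(confidences < 0) || any(confidences > 1))
    stop("confidences must lie in [0, 1]")
  if (!is_count(n_bins) || n_bins < 1) stop("n_bins must be >= 1")
  correctness <- as.numeric(correctness)
  stopifnot(length(confidences) == length(correctness))
  bin <- pmin(floor(confidences * n_bins) + 1L, n_bins)
  gaps <- c(); wts <- c()
  for (b in unique(bin)) {
    sel <- bin == b
    gaps <- c(gaps, abs(mean(correctness[sel]) - mean(confidences[sel])))
    wts <- c(wts, sum(sel))
  }
  list(ece = sum(gaps * wts) / sum(wts), mce = max(gaps))
}

#' Expected versus observed coverage over a grid of error rates
#'
#' Recalibrates on the calibration scores at each `alpha` and measures the
#' empirical coverage on the test samples, giving the points of an expected
#' (`1 - alpha`) versus observed coverage plot. The argmax fallback of
#' [build_set()] is honoured: a sample with an empty thresholded set counts as
#' covered iff its argmax equals the truth.
#'
#' @param prob_cal,truth_cal Calibration probability matrix and labels.
#' @param prob_test,truth_test Test probability matrix and labels.
#' @param alphas Error-rate grid in `(0, 1)`.
#' @param nonempty Honour the nonempty-set fallback (default TRUE).
#' @return data.frame with columns alpha, expected, observed.
#' @export
coverage_curve <- function(prob_cal, truth_cal, prob_test, truth_test,
                           alphas = seq(0.05, 0.5, by = 0.05), nonempty = TRUE) {
  if (any(alphas <= 0) || any(alphas >= 1)) stop("alphas must lie in (0, 1)")
  s_cal <- nonconformity_scores(prob_cal, truth_cal)
  s_test <- nonconformity_scores(prob_test, truth_test)
  maxp <- apply(as.matrix(prob_test), 1, max)
  idx_truth <- match(as.character(truth_test), colnames(prob_test))
  argmax_hit <- max.col(as.matrix(prob_test), ties.method = "first") == idx_truth
  out <- lapply(alphas, function(a) {
    q <- calibrate(s_cal, a)$q_hat
    covered <- s_test <= q
    if (nonempty) covered <- covered | ((maxp < 1 - q) & argmax_hit)
    data.frame(alpha = a, expected = 1 - a, observed = mean(covered))
  })
  do.call(rbind, out)
}
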