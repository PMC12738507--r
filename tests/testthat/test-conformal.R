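test_that("nonconformity is one minus the truth probability", {
  probs <- rbind(c(0.8544, 0.0574, 0.0882),
                 c(1, 0, 0),
                 rep(1 / 8, 3) * (8 / 3))  # row sums 1
  colnames(probs) <- c("NEV", "MEL", "BCC")
  probs[3, ] <- c(1 / 8, 1 / 8, 6 / 8)
  s <- nonconformity_scores(probs, c("NEV", "NEV", "MEL"))
  expect_equal(s, c(0.1456, 0, 0.875))
  expect_error(nonconformity_scores(probs, c("NEV", "XX", "MEL")), "outside")
})

test_that("calibration uses the finite-sample-corrected quantile rank", {
  cal <- calibrate(c(0.1, 0.2, 0.3, 0.4), alpha = 0.2)
  expect_equal(cal$q_hat, 0.4)  # rank ceil(5 * 0.8) = 4
  expect_equal(cal$n, 4)

  # alpha 0: rank n+1 -> infinite threshold, full label space
  expect_equal(calibrate(runif(10), 0)$q_hat, Inf)
  # alpha 1: rank clamps to 1 -> smallest score
  sc <- runif(10)
  expect_equal(calibrate(sc, 1)$q_hat, min(sc))
  expect_error(calibrate(numeric(0), 0.1), "empty")
  expect_error(calibrate(c(0.1), 2), "alpha")
})

test_that("build_set thresholds, orders and falls back to the argmax", {
  cal <- structure(list(alpha = 0.2, n = 10, scores = NULL, q_hat = 0.2),
                   class = "calibration_result")
  s <- build_set(c(A = 0.85, B = 0.10, C = 0.05), cal)
  expect_equal(s$labels, "A")
  expect_equal(s$confidence, 0.85)
  expect_equal(s$size, 1)

  # infinite threshold: every positive-probability label, descending
  cal$q_hat <- Inf
  s2 <- build_set(c(A = 0.2, B = 0.5, C = 0.3, D = 0), cal)
  expect_equal(s2$labels, c("B", "C", "A"))
  expect_true(all(diff(s2$confidence) < 0))
  expect_true(all(s2$confidence > 0))

  # zero threshold with no certain label: argmax singleton fallback
  cal$q_hat <- 0
  s3 <- build_set(c(A = 0.6, B = 0.4), cal)
  expect_equal(s3$labels, "A")
  expect_equal(build_set(c(A = 0.6, B = 0.4), cal, nonempty = FALSE)$size, 0)
})

test_that("build_set agrees with the include-iff-score-below-threshold oracle", {
  set.seed(5)
  for (i in 1:100) {
    k <- sample(2:8, 1)
    p <- rexp(k); p <- p / sum(p); names(p) <- paste0("L", seq_len(k))
    q <- runif(1)
    cal <- structure(list(alpha = 0.2, n = 1, scores = NULL, q_hat = q),
                     class = "calibration_result")
    s <- build_set(p, cal, nonempty = FALSE)
    oracle <- names(p)[(1 - p) <= q & p > 0]
    expect_setequal(s$labels, oracle)
  }
})

test_that("set size is non-increasing as alpha grows", {
  set.seed(8)
  scores <- runif(200)
  p <- rexp(6); p <- p / sum(p); names(p) <- paste0("L", 1:6)
  sizes <- vapply(seq(0.05, 0.95, by = 0.05), function(a)
    build_set(p, calibrate(scores, a))$size, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("empirical coverage is an exact recount", {
  sets <- as_sets(toy_set("1", c("A", "B"), c(0.6, 0.3), truth = "A"),
                  toy_set("2", "B", 0.9, truth = "A"),
                  toy_set("3", c("C", "A"), c(0.5, 0.4), truth = "A"),
                  toy_set("4", "A", 0.99, truth = "A"))
  expect_equal(empirical_coverage(sets), 3 / 4)
  # override truths: B is in sets 1 and 2 only
  expect_equal(empirical_coverage(sets, truths = c("B", "B", "B", "B")), 2 / 4)
  all_in <- as_sets(toy_set("1", "A", 1, truth = "A"))
  expect_equal(empirical_coverage(all_in), 1)
})

test_that("ECE/MCE match single-bin arithmetic and their ordering invariant", {
  r <- ece_mce(rep(0.9, 10), rep(c(TRUE, FALSE), 5), n_bins = 1)
  expect_equal(r$ece, 0.4)
  expect_equal(r$mce, 0.4)

  set.seed(12)
  for (i in 1:50) {
    n <- 200
    conf <- runif(n)
    corr <- runif(n) < runif(n)
    r <- ece_mce(conf, corr, n_bins = sample(2:15, 1))
    expect_lte(r$ece, r$mce + 1e-12)
    expect_gte(r$ece, 0)
  }
  expect_error(ece_mce(c(0.5, 1.2), c(TRUE, FALSE)), "\\[0, 1\\]")
})

test_that("a perfectly calibrated stream has near-zero calibration error", {
  set.seed(3)
  n <- 20000
  conf <- runif(n)
  corr <- runif(n) < conf
  r <- ece_mce(conf, corr, n_bins = 10)
  expect_lt(r$ece, 0.02)
  expect_lt(r$mce, 0.05)
})

test_that("coverage curve reduces to empirical coverage and decreases in alpha", {
  fix <- small_model_fixture()
  cal <- subset_cohort(fix$cohort, fix$split$calibration)
  te <- subset_cohort(fix$cohort, fix$split$test)
  p_cal <- predict_proba(fix$model, cal)
  p_te <- predict_proba(fix$model, te)

  cc <- coverage_curve(p_cal, cal$labels, p_te, te$labels, alphas = 0.2)
  calib <- calibrate(nonconformity_scores(p_cal, cal$labels), 0.2)
  sets <- build_sets(p_te, calib, truth = te$labels)
  expect_equal(cc$observed, empirical_coverage(sets))
  expect_equal(cc$expected, 0.8)

  grid <- coverage_curve(p_cal, cal$labels, p_te, te$labels,
                         alphas = seq(0.05, 0.6, by = 0.05))
  expect_true(all(diff(grid$observed) <= 1e-12))
})
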