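toy_meta <- data.frame(
  id = as.character(1:6),
  sex = c("male", "male", "female", "female", "male", "female"),
  age_band = c("<30", "30-60", "30-60", ">60", ">60", "30-60"),
  anatom_site = c("head/neck", "head/neck", "anterior torso", "anterior torso",
                  "anterior torso", "head/neck"),
  cohort = "A",
  stringsAsFactors = FALSE)

# truth ranks: 1, 2, 3, absent, 1, 2  (classes X and Y)
toy_audit_sets <- function() {
  as_sets(
    toy_set("1", c("X", "Y"), c(0.7, 0.2), truth = "X"),
    toy_set("2", c("Y", "X"), c(0.5, 0.3), truth = "X"),
    toy_set("3", c("Y", "Z", "X"), c(0.4, 0.3, 0.2), truth = "X"),
    toy_set("4", c("Z"), 0.9, truth = "Y"),
    toy_set("5", c("Y", "X"), c(0.6, 0.3), truth = "Y"),
    toy_set("6", c("X", "Y", "Z"), c(0.5, 0.3, 0.1), truth = "Y"))
}

test_that("A2 accuracy counts truths among the two most probable set labels", {
  sets <- toy_audit_sets()
  a2 <- a2_accuracy(sets)
  # class X: ranks 1,2,3 -> 2/3; class Y: absent, 1, 2 -> 2/3
  expect_equal(a2$a2_pct[a2$class == "X"], 100 * 2 / 3)
  expect_equal(a2$a2_pct[a2$class == "Y"], 100 * 2 / 3)
  expect_equal(a2$n, c(3L, 3L))

  by_sex <- a2_accuracy(sets, toy_meta, group_by = "sex")
  # males: X ranks 1,2 -> 100%; Y rank 1 -> 100%
  expect_equal(by_sex$a2_pct[by_sex$class == "X" & by_sex$group == "male"], 100)
  # females: X rank 3 -> 0%; Y absent + rank 2 -> 50%
  expect_equal(by_sex$a2_pct[by_sex$class == "X" & by_sex$group == "female"], 0)
  expect_equal(by_sex$a2_pct[by_sex$class == "Y" & by_sex$group == "female"], 50)

  # singleton wrong-label sets score zero
  wrong <- as_sets(toy_set("1", "B", 0.9, truth = "A"))
  expect_equal(a2_accuracy(wrong)$a2_pct, 0)
  # unordered entries are rejected
  bad <- as_sets(toy_set("1", c("A", "B"), c(0.1, 0.9), truth = "A"))
  expect_error(a2_accuracy(bad), "ordered")
})

test_that("A2 dominates top-1 accuracy on random instances", {
  set.seed(31)
  for (i in 1:20) {
    labs <- paste0("L", 1:4)
    sets <- as_sets_list(lapply(1:30, function(j) {
      k <- sample(1:4, 1)
      p <- sort(runif(k), decreasing = TRUE)
      toy_set(as.character(j), sample(labs, k), p, truth = sample(labs, 1))
    }))
    df <- dermconformal:::sets_frame(sets)
    top1 <- mean(df$top_label == df$truth)
    a2_all <- sum(!is.na(df$gt_rank) & df$gt_rank <= 2) / nrow(df)
    expect_gte(a2_all, top1)
  }
})

test_that("set-size histograms conserve group totals", {
  sets <- toy_audit_sets()
  h <- set_size_distribution(sets, toy_meta, "sex")
  expect_equal(sum(h$count[h$level == "male"]), 3)
  expect_equal(sum(h$count[h$level == "female"]), 3)
  expect_equal(sum(h$count), length(sets))
  # all-singleton sets put the whole mass at size 1
  singles <- as_sets(toy_set("1", "A", 1, "A"), toy_set("2", "B", 1, "B"))
  h1 <- set_size_distribution(singles, toy_meta[1:2, ], "sex")
  expect_true(all(h1$size[h1$count > 0] == 1))
  expect_error(set_size_distribution(sets, toy_meta, "shoe_size"), "attribute")
})

test_that("ground-truth confidences cover exactly the truth-containing sets", {
  sets <- toy_audit_sets()
  g <- gt_confidence_values(sets)
  # set 4 misses its truth; the other five contribute their gt confidence
  expect_equal(nrow(g), 5)
  expect_equal(sort(g$confidence[g$class == "X"]), c(0.2, 0.3, 0.7))
  expect_true(all(g$confidence > 0 & g$confidence <= 1))

  t2 <- top2_guarantee(sets)
  # rank-3 entry (set 3) drops out
  expect_equal(sort(t2$confidence[t2$class == "X"]), c(0.3, 0.7))
  expect_equal(sort(t2$confidence[t2$class == "Y"]), c(0.3, 0.6))

  # truth rank 3 everywhere -> empty
  deep <- as_sets(toy_set("1", c("A", "B", "C"), c(0.5, 0.3, 0.2), truth = "C"))
  expect_equal(nrow(top2_guarantee(deep)), 0)
})

test_that("region ranking percentages are per-class top-2 shares, descending", {
  sets <- toy_audit_sets()
  rt <- region_table(sets, toy_meta)
  # class X top-2 samples: sets 1,2 -> both head/neck
  x <- rt[rt$class == "X", ]
  expect_equal(x$region, "head/neck")
  expect_equal(x$pct, 100)
  # class Y top-2 samples: sets 5 (anterior torso), 6 (head/neck) -> 50/50
  y <- rt[rt$class == "Y", ]
  expect_equal(sort(y$pct), c(50, 50))
  expect_true(all(tapply(rt$pct, rt$class, sum) <= 100 + 1e-9))
  expect_true(all(unlist(tapply(rt$pct, rt$class, diff)) <= 0))
})

test_that("the assembled report is coherent and serializes round-trip", {
  sets <- toy_audit_sets()
  rep <- audit_report(sets, toy_meta)
  expect_equal(rep$n, 6)
  expect_equal(rep$coverage, 5 / 6)
  expect_true(all(c("sex", "age_band", "anatom_site", "cohort") %in%
                    names(rep$setsize_hist)))
  expect_lte(rep$calibration$ece, rep$calibration$mce)

  dir <- withr::local_tempdir()
  write_audit_report(rep, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "report.json", "setsize_by_group.csv", "a2_by_group.csv",
    "gt_confidence.csv", "top2_guarantee.csv", "region_ranking.csv")))))
  j <- jsonlite::fromJSON(file.path(dir, "report.json"))
  expect_equal(j$coverage, 5 / 6)
})

test_that("permutation test separates real gaps from none", {
  set.seed(9)
  n <- 200
  meta <- data.frame(id = as.character(1:n),
                     sex = rep(c("male", "female"), each = n / 2))
  big <- as_sets_list(lapply(1:n, function(i) {
    size <- if (i <= n / 2) sample(2:4, 1) else 1L
    toy_set(as.character(i), paste0("L", seq_len(size)),
            sort(runif(size), decreasing = TRUE), truth = "L1")
  }))
  r <- setsize_permutation_test(big, meta, "sex", n_perm = 199, seed = 2)
  expect_lt(r$p_value, 0.01)
  expect_gt(r$group_means[["male"]], r$group_means[["female"]])

  flat <- as_sets_list(lapply(1:n, function(i) {
    size <- sample(1:3, 1)
    toy_set(as.character(i), paste0("L", seq_len(size)),
            sort(runif(size), decreasing = TRUE), truth = "L1")
  }))
  r0 <- setsize_permutation_test(flat, meta, "sex", n_perm = 199, seed = 3)
  expect_gt(r0$p_value, 0.01)
})
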