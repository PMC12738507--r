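test_that("analytic gradients match numerical gradients", {
  set.seed(99)
  n <- 12; d <- 12; k <- 3
  X <- matrix(rnorm(n * d), n, d)
  y <- sample(k, n, replace = TRUE)
  onehot <- matrix(0, n, k); onehot[cbind(1:n, y)] <- 1
  params <- dermconformal:::mlp_init(d, 2, k)

  loss_fn <- function(p) {
    P <- dermconformal:::softmax(dermconformal:::mlp_forward(p, X, 0, TRUE)$logits)
    -mean(log(P[cbind(1:n, y)]))
  }
  fwd <- dermconformal:::mlp_forward(params, X, 0, TRUE)
  grads <- dermconformal:::mlp_backward(params, fwd, onehot, 0)

  eps <- 1e-5
  check <- function(get, set, g) {
    p0 <- get(params)
    for (idx in sample(length(p0), min(4, length(p0)))) {
      pp <- params; pm <- params
      v <- p0; v[idx] <- v[idx] + eps; pp <- set(pp, v)
      v <- p0; v[idx] <- v[idx] - eps; pm <- set(pm, v)
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      expect_equal(g[idx], num, tolerance = 1e-4)
    }
  }
  check(function(p) p$final$W, function(p, v) { p$final$W[] <- v; p },
        grads$final$W)
  check(function(p) p$blocks[[1]]$W, function(p, v) { p$blocks[[1]]$W[] <- v; p },
        grads$blocks[[1]]$W)
  check(function(p) p$blocks[[2]]$gamma,
        function(p, v) { p$blocks[[2]]$gamma <- v; p },
        grads$blocks[[2]]$gamma)
  check(function(p) p$blocks[[1]]$beta,
        function(p, v) { p$blocks[[1]]$beta <- v; p },
        grads$blocks[[1]]$beta)
})

test_that("the head learns separable data and training is reproducible", {
  co <- generate_cohort(cohort_spec(c(a = 120, b = 120), embed_dim = 16,
                                    class_separation = 10, seed = 31))
  sp <- split_cohort(co, seed = 32)
  cfg <- mlp_config(input_dim = 16, n_blocks = 2, epochs = 25, batch_size = 16,
                    learning_rate = 3e-3, seed = 33)
  tr <- subset_cohort(co, sp$train); va <- subset_cohort(co, sp$validation)
  m <- train_head(tr, va, cfg)
  expect_equal(max(m$log$val_macro_f1), 1)

  # loss trends down in the separable regime
  expect_lt(tail(m$log$train_loss, 1), 0.5 * m$log$train_loss[1])

  m2 <- train_head(tr, va, cfg)
  expect_identical(m$log, m2$log)
  expect_identical(m$params, m2$params)

  # argmax matches truth on held-out separable data
  te <- subset_cohort(co, sp$test)
  p <- predict_proba(m, te)
  expect_equal(mean(colnames(p)[max.col(p)] == as.character(te$labels)), 1)
})

test_that("predicted probabilities are row-normalized and deterministic", {
  fix <- small_model_fixture()
  te <- subset_cohort(fix$cohort, fix$split$test)
  p <- predict_proba(fix$model, te)
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_true(all(p >= 0))
  # duplicated input row -> identical output rows (inference mode is frozen)
  x2 <- te$x[c(1, 1), ]
  p2 <- predict_proba(fix$model, x2)
  expect_identical(p2[1, ], p2[2, ])
  expect_error(predict_proba(list(), te), "not a trained")
})

test_that("train_head validates embedding dimensions with the record named", {
  fix <- small_model_fixture()
  co <- fix$cohort
  bad <- co; bad$x <- bad$x[, 1:4]
  expect_error(train_head(bad, co, mlp_config(input_dim = 8, n_blocks = 1)),
               "SYN_")
})

test_that("block widths must stay at or above the class count", {
  co <- generate_cohort(cohort_spec(stats::setNames(rep(30, 6), paste0("c", 1:6)),
                                    embed_dim = 8, seed = 3))
  cfg <- mlp_config(input_dim = 8, n_blocks = 2, epochs = 1)
  expect_error(train_head(co, co, cfg), "reduce n_blocks")
})

test_that("classwise metrics match hand-computed confusion arithmetic", {
  # 3-class hand case: rows = truth a,a,a,b,b,c ; argmax = a,b,a,b,b,a
  probs <- rbind(c(0.8, 0.1, 0.1), c(0.2, 0.7, 0.1), c(0.6, 0.2, 0.2),
                 c(0.1, 0.8, 0.1), c(0.3, 0.5, 0.2), c(0.5, 0.3, 0.2))
  colnames(probs) <- c("a", "b", "c")
  truth <- factor(c("a", "a", "a", "b", "b", "c"), levels = c("a", "b", "c"))
  m <- classwise_metrics(truth, probs)
  # class a: tp 2, fn 1, fp 1 -> recall 2/3, prec 2/3, F1 2/3
  expect_equal(m$recall[m$class == "a"], 2 / 3)
  expect_equal(m$accuracy[m$class == "a"], 2 / 3)
  expect_equal(m$f1[m$class == "a"], 2 / 3)
  # class b: tp 2, fn 0? truth b = 2, pred b = 3 -> recall 1, prec 2/3
  expect_equal(m$recall[m$class == "b"], 1)
  expect_equal(m$f1[m$class == "b"], 2 * (2 / 3) / (1 + 2 / 3))
  # class c never predicted -> recall 0, F1 0
  expect_equal(m$f1[m$class == "c"], 0)

  # perfect predictions: everything 1
  perfect <- diag(3)[as.integer(truth), ]
  colnames(perfect) <- c("a", "b", "c")
  mp <- classwise_metrics(truth, perfect)
  expect_equal(mp$recall, rep(1, 3))
  expect_equal(mp$auc, rep(1, 3))

  # absent class is undefined, not zero
  truth2 <- factor(c("a", "a", "b", "b", "b", "b"), levels = c("a", "b", "c"))
  m2 <- classwise_metrics(truth2, probs)
  expect_true(is.na(m2$recall[m2$class == "c"]))
})

test_that("metrics agree with a brute-force confusion oracle on random inputs", {
  set.seed(17)
  for (i in 1:20) {
    k <- sample(2:5, 1); n <- 60
    probs <- matrix(rexp(n * k), n, k)
    probs <- probs / rowSums(probs)
    colnames(probs) <- paste0("k", seq_len(k))
    truth <- factor(sample(colnames(probs), n, TRUE), levels = colnames(probs))
    m <- classwise_metrics(truth, probs)
    pred <- colnames(probs)[max.col(probs, ties.method = "first")]
    cm <- table(factor(pred, levels = colnames(probs)), truth)
    for (c in colnames(probs)) {
      nt <- sum(truth == c)
      if (nt == 0) next
      expect_equal(m$recall[m$class == c], cm[c, c] / nt)
    }
  }
})

test_that("random uniform probabilities give chance-level AUC", {
  set.seed(23)
  n <- 4000
  probs <- matrix(runif(n * 2), n, 2)
  probs <- probs / rowSums(probs)
  colnames(probs) <- c("a", "b")
  truth <- factor(sample(c("a", "b"), n, TRUE), levels = c("a", "b"))
  m <- classwise_metrics(truth, probs)
  # Mann-Whitney null sd ~ sqrt((n1+n2+1)/(12 n1 n2)); 3 sigma band around 0.5
  n1 <- sum(truth == "a"); n2 <- n - n1
  expect_lt(abs(m$auc[1] - 0.5), 3 * sqrt((n1 + n2 + 1) / (12 * n1 * n2)))
})
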