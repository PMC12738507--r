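#' Configure the MLP classifier head
#'
#' The head is a small multilayer perceptron trained on frozen embeddings:
#' `n_blocks` blocks, each a fully connected layer with half the neurons of
#' the previous one followed by 1-D batch normalization, a ReLU activation and
#' dropout, then a final fully connected layer onto the classes. The default
#' profile is sized for 64-dimensional test embeddings (3 halving blocks);
#' [mlp_config_paper()] gives the full 2048-input, 6-block profile used with
#' foundation-model embeddings. Optimizer is Adam on the cross-entropy loss.
#' Training is deterministic given `seed`.
#'
#' @param input_dim Embedding length (default 64).
#' @param n_blocks Number of halving blocks (default 3).
#' @param dropout_rate Dropout probability in each block.
#' @param epochs Training epochs (default 40).
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param seed Integer seed governing init, shuffling and dropout.
#' @param sampler Optional [sampler_config()]; when present, each epoch's
#'   indices are drawn by the challenge-regulated F1 sampler.
#' @return An `mlp_config`.
#' @export
mlp_config <- function(input_dim = 64, n_blocks = 3, dropout_rate = 0.2,
                       epochs = 40, batch_size = 128, learning_rate = 1e-3,
                       seed = 1L, sampler = NULL) {
  if (!is_count(epochs) || epochs < 1) bad_field("epochs", "must be >= 1")
  if (!is_count(n_blocks) || n_blocks < 1) bad_field("n_blocks", "must be >= 1")
  if (!is.null(sampler) && !inherits(sampler, "sampler_config"))
    bad_field("sampler", "must be a sampler_config or NULL")
  structure(list(input_dim = as.integer(input_dim),
                 n_blocks = as.integer(n_blocks),
                 dropout_rate = dropout_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 seed = as.integer(seed),
                 sampler = sampler),
            class = "mlp_config")
}

#' @rdname mlp_config
#' @param ... Overrides passed on to [mlp_config()].
#' @export
mlp_config_paper <- function(...) {
  args <- utils::modifyList(list(input_dim = 2048, n_blocks = 6), list(...))
  do.call(mlp_config, args)
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

mlp_init <- function(input_dim, n_blocks, n_classes) {
  widths <- input_dim
  for (b in seq_len(n_blocks)) widths <- c(widths, widths[length(widths)] %/% 2)
  if (any(widths < n_classes))
    stop(sprintf(
      "block widths (%s) fall below the number of classes (%d); reduce n_blocks",
      paste(widths, collapse = ","), n_classes))
  blocks <- lapply(seq_len(n_blocks), function(b) {
    fan_in <- widths[b]; fan_out <- widths[b + 1]
    list(W = matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)), fan_in, fan_out),
         b = rep(0, fan_out),
         gamma = rep(1, fan_out), beta = rep(0, fan_out),
         rm = rep(0, fan_out), rv = rep(1, fan_out))
  })
  fan_in <- widths[n_blocks + 1]
  final <- list(W = matrix(stats::rnorm(fan_in * n_classes, sd = sqrt(2 / fan_in)),
                           fan_in, n_classes),
                b = rep(0, n_classes))
  list(blocks = blocks, final = final, widths = widths)
}

mlp_forward <- function(params, X, dropout_rate, training) {
  caches <- vector("list", length(params$blocks))
  H <- X
  for (i in seq_along(params$blocks)) {
    bl <- params$blocks[[i]]
    Z <- H %*% bl$W
    Z <- sweep(Z, 2, bl$b, `+`)
    if (training) {
      mu <- colMeans(Z)
      v <- colMeans(Z^2) - mu^2
      v[v < 0] <- 0
    } else {
      mu <- bl$rm; v <- bl$rv
    }
    zh <- sweep(sweep(Z, 2, mu, `-`), 2, sqrt(v + BN_EPS), `/`)
    A <- sweep(sweep(zh, 2, bl$gamma, `*`), 2, bl$beta, `+`)
    R <- pmax(A, 0)
    if (training && dropout_rate > 0) {
      keep <- 1 - dropout_rate
      mask <- (matrix(stats::runif(length(R)), nrow(R)) < keep) / keep
      Hout <- R * mask
    } else {
      mask <- NULL
      Hout <- R
    }
    caches[[i]] <- list(H_in = H, Z = Z, mu = mu, v = v, zh = zh, A = A, mask = mask)
    H <- Hout
  }
  logits <- sweep(H %*% params$final$W, 2, params$final$b, `+`)
  list(logits = logits, H_last = H, caches = caches)
}

softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Gradients of mean cross-entropy w.r.t. all parameters; updates running BN
# stats as a side effect (returned with the grads).
mlp_backward <- function(params, fwd, y_onehot, dropout_rate) {
  m <- nrow(y_onehot)
  P <- softmax(fwd$logits)
  dlogits <- (P - y_onehot) / m
  grads <- list(blocks = vector("list", length(params$blocks)), final = NULL)
  grads$final <- list(W = crossprod(fwd$H_last, dlogits), b = colSums(dlogits))
  dH <- dlogits %*% t(params$final$W)
  for (i in rev(seq_along(params$blocks))) {
    bl <- params$blocks[[i]]
    ca <- fwd$caches[[i]]
    if (!is.null(ca$mask)) dH <- dH * ca$mask
    dA <- dH * (ca$A > 0)
    dgamma <- colSums(dA * ca$zh)
    dbeta <- colSums(dA)
    dzh <- sweep(dA, 2, bl$gamma, `*`)
    inv_sd <- 1 / sqrt(ca$v + BN_EPS)
    Zc <- sweep(ca$Z, 2, ca$mu, `-`)
    dv <- colSums(dzh * Zc) * (-0.5) * inv_sd^3
    dmu <- -colSums(dzh) * inv_sd
    dZ <- sweep(dzh, 2, inv_sd, `*`) +
      sweep(Zc, 2, 2 * dv / nrow(dA), `*`) +
      matrix(dmu / nrow(dA), nrow(dA), ncol(dA), byrow = TRUE)
    grads$blocks[[i]] <- list(W = crossprod(ca$H_in, dZ), b = colSums(dZ),
                              gamma = dgamma, beta = dbeta,
                              rm_new = (1 - BN_MOMENTUM) * bl$rm + BN_MOMENTUM * ca$mu,
                              rv_new = (1 - BN_MOMENTUM) * bl$rv + BN_MOMENTUM * ca$v)
    dH <- dZ %*% t(bl$W)
  }
  grads
}

adam_init <- function(params) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(m = list(blocks = lapply(params$blocks, function(b) zero_like(b[c("W", "b", "gamma", "beta")])),
                final = zero_like(params$final)),
       v = list(blocks = lapply(params$blocks, function(b) zero_like(b[c("W", "b", "gamma", "beta")])),
                final = zero_like(params$final)),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(p, g, m, v) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^state$t)
    vhat <- v / (1 - b2^state$t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  for (i in seq_along(params$blocks)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      r <- upd(params$blocks[[i]][[nm]], grads$blocks[[i]][[nm]],
               state$m$blocks[[i]][[nm]], state$v$blocks[[i]][[nm]])
      params$blocks[[i]][[nm]] <- r$p
      state$m$blocks[[i]][[nm]] <- r$m
      state$v$blocks[[i]][[nm]] <- r$v
    }
    params$blocks[[i]]$rm <- grads$blocks[[i]]$rm_new
    params$blocks[[i]]$rv <- grads$blocks[[i]]$rv_new
  }
  for (nm in c("W", "b")) {
    r <- upd(params$final[[nm]], grads$final[[nm]],
             state$m$final[[nm]], state$v$final[[nm]])
    params$final[[nm]] <- r$p
    state$m$final[[nm]] <- r$m
    state$v$final[[nm]] <- r$v
  }
  list(params = params, state = state)
}

macro_f1 <- function(truth, pred, n_classes) {
  f1 <- classwise_f1(truth, pred, n_classes)
  mean(f1, na.rm = TRUE)
}

#' Train the MLP head on embedding records
#'
#' Trains the head with minibatch Adam on the cross-entropy loss. When the
#' config carries a [sampler_config()], per-epoch indices come from
#' [sample_epoch()]: weights start at [frequency_weights()] and are refreshed
#' every `refresh_period` epochs by evaluating the current model on the
#' validation set ([kfold_mean_f1()] -> [f1_weights()] -> [regulate_weights()]).
#' Without a sampler, epochs are plain shuffles of the training set. The
#' returned model carries the parameters of the best epoch by validation
#' macro-F1, and a per-epoch log of loss, validation macro-F1 and the active
#' class weights.
#'
#' @param train,validation `cohort` objects (embeddings + labels).
#' @param cfg An [mlp_config()].
#' @return An `mlp_head` model with elements `params` (best state), `log`
#'   (data.frame), `best_epoch`, `class_levels`, `cfg`.
#' @export
train_head <- function(train, validation, cfg) {
  stopifnot(inherits(train, "cohort"), inherits(validation, "cohort"),
            inherits(cfg, "mlp_config"))
  if (nrow(train$x) == 0) stop("empty training set")
  if (ncol(train$x) != cfg$input_dim)
    stop(sprintf("embedding length %d of record '%s' does not match input_dim %d",
                 ncol(train$x), rownames(train$x)[1], cfg$input_dim))
  if (ncol(validation$x) != cfg$input_dim)
    stop(sprintf("embedding length %d of record '%s' does not match input_dim %d",
                 ncol(validation$x), rownames(validation$x)[1], cfg$input_dim))
  class_levels <- levels(train$labels)
  n_classes <- length(class_levels)
  y <- as.integer(train$labels)
  yv <- as.integer(factor(validation$labels, levels = class_levels))
  n <- nrow(train$x)

  set.seed(cfg$seed)
  params <- mlp_init(cfg$input_dim, cfg$n_blocks, n_classes)
  opt <- adam_init(params)

  weights <- NULL
  if (!is.null(cfg$sampler))
    weights <- frequency_weights(tabulate(y, nbins = n_classes))

  log_rows <- vector("list", cfg$epochs)
  best_f1 <- -Inf; best_params <- params; best_epoch <- 0L

  for (epoch in seq_len(cfg$epochs)) {
    if (!is.null(cfg$sampler) && epoch > 1 &&
        (epoch - 1) %% cfg$sampler$refresh_period == 0) {
      val_probs <- softmax(mlp_forward(params, validation$x, 0, FALSE)$logits)
      mf1 <- kfold_mean_f1(val_probs, yv, k = cfg$sampler$k_folds,
                           seed = derive_seed(cfg$seed, paste0("folds", epoch)))
      weights <- regulate_weights(f1_weights(mf1, cfg$sampler$f1_floor), cfg$sampler)
    }
    idx <- if (is.null(weights)) sample(n)
           else sample_epoch(weights, train$labels, n,
                             seed = derive_seed(cfg$seed, paste0("epoch", epoch)))
    losses <- c()
    for (start in seq(1, length(idx), by = cfg$batch_size)) {
      bidx <- idx[start:min(start + cfg$batch_size - 1, length(idx))]
      Xb <- train$x[bidx, , drop = FALSE]
      yb <- y[bidx]
      fwd <- mlp_forward(params, Xb, cfg$dropout_rate, TRUE)
      P <- softmax(fwd$logits)
      losses <- c(losses, -mean(log(pmax(P[cbind(seq_along(yb), yb)], 1e-12))))
      onehot <- matrix(0, length(yb), n_classes)
      onehot[cbind(seq_along(yb), yb)] <- 1
      grads <- mlp_backward(params, fwd, onehot, cfg$dropout_rate)
      st <- adam_step(params, grads, opt, cfg$learning_rate)
      params <- st$params; opt <- st$state
    }
    val_probs <- softmax(mlp_forward(params, validation$x, 0, FALSE)$logits)
    vf1 <- macro_f1(yv, max.col(val_probs, ties.method = "first"), n_classes)
    if (vf1 > best_f1) { best_f1 <- vf1; best_params <- params; best_epoch <- epoch }
    wrow <- if (is.null(weights)) rep(NA_real_, n_classes) else weights$weights
    log_rows[[epoch]] <- data.frame(epoch = epoch, train_loss = mean(losses),
                                    val_macro_f1 = vf1,
                                    t(stats::setNames(wrow, paste0("w_", class_levels))))
  }

  structure(list(params = best_params, final_params = params,
                 log = do.call(rbind, log_rows), best_epoch = best_epoch,
                 class_levels = class_levels, cfg = cfg),
            class = "mlp_head")
}

#' @export
print.mlp_head <- function(x, ...) {
  cat(sprintf("<mlp_head> %d->%s->%d classes, best epoch %d (val macro-F1 %.3f)\n",
              x$cfg$input_dim, paste(x$params$widths[-1], collapse = "->"),
              length(x$class_levels), x$best_epoch,
              max(x$log$val_macro_f1)))
  invisible(x)
}

#' Predict class probabilities
#'
#' Inference-mode forward pass (batch-norm running statistics, dropout off):
#' deterministic, and each row is a probability vector summing to 1.
#'
#' @param model A trained `mlp_head`.
#' @param newdata A `cohort` or a numeric matrix of embeddings.
#' @return Probability matrix with class-level column names and input rownames.
#' @export
predict_proba <- function(model, newdata) {
  if (!inherits(model, "mlp_head")) stop("model is not a trained mlp_head")
  X <- if (inherits(newdata, "cohort")) newdata$x else as.matrix(newdata)
  if (ncol(X) != model$cfg$input_dim)
    stop(sprintf("embedding length %d does not match input_dim %d",
                 ncol(X), model$cfg$input_dim))
  P <- softmax(mlp_forward(model$params, X, 0, FALSE)$logits)
  colnames(P) <- model$class_levels
  rownames(P) <- rownames(X)
  P
}

#' Classwise accuracy, recall, F1 and one-vs-rest AUC
#'
#' Per-class test metrics of a probability matrix against true labels. The
#' reported classwise "accuracy" is the class's recall (diagonal of the
#' confusion matrix over its row sum) — the convention of classwise results
#' tables in dermoscopy benchmarks. AUC is one-vs-rest on the predicted
#' probability of the class. Classes absent from `truth` are reported as `NA`
#' (undefined), never zero.
#'
#' @param truth Factor of true labels (levels matching the matrix columns).
#' @param prob_matrix Probability matrix with one column per class.
#' @return data.frame with columns class, n, accuracy, recall, f1, auc.
#' @export
classwise_metrics <- function(truth, prob_matrix) {
  class_levels <- colnames(prob_matrix)
  truth <- factor(truth, levels = class_levels)
  stopifnot(length(truth) == nrow(prob_matrix))
  ti <- as.integer(truth)
  pred <- max.col(prob_matrix, ties.method = "first")
  f1 <- classwise_f1(ti, pred, length(class_levels))
  out <- data.frame(class = class_levels,
                    n = as.integer(tabulate(ti, nbins = length(class_levels))),
                    accuracy = NA_real_, recall = NA_real_,
                    f1 = f1, auc = NA_real_)
  for (c in seq_along(class_levels)) {
    if (out$n[c] == 0) next
    rec <- sum(ti == c & pred == c) / out$n[c]
    out$accuracy[c] <- rec
    out$recall[c] <- rec
    if (out$n[c] < length(ti)) {
      roc <- pROC::roc(response = as.integer(ti == c),
                       predictor = prob_matrix[, c],
                       levels = c(0, 1), direction = "<", quiet = TRUE)
      out$auc[c] <- as.numeric(pROC::auc(roc))
    }
  }
  out
}
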