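# Emotion readout: the backbone's classification layer is replaced by a
# two-unit head (target emotion vs rest) trained with cross-entropy by
# stochastic gradient descent while every backbone weight stays frozen.
# Performance is measured with the F1-score of the target emotion.

#' Binary emotion recognition task
#'
#' @param positive the emotion treated as the positive class; the task is
#'   `positive` versus non-`positive`.
#' @return object of class `readout_task`.
#' @export
readout_task <- function(positive = c("pleasant", "neutral", "unpleasant")) {
  positive <- match.arg(positive)
  structure(list(positive = positive), class = "readout_task")
}

#' Readout training configuration
#'
#' Defaults follow the reference protocol: learning rate 1e-3, 10 epochs,
#' batch size 128, 50/25/25 train/validation/test split. Class balancing
#' defaults to inverse-prevalence weights in the cross-entropy, which guards
#' against the trivial majority classifier in the one-vs-rest framing.
#'
#' @param lr learning rate for plain stochastic gradient descent.
#' @param epochs number of passes over the training set (>= 1).
#' @param batch_size minibatch size.
#' @param split train/validation/test proportions summing to 1.
#' @param seed RNG seed governing the split and batch shuffling.
#' @param class_weights `"balanced"` (inverse prevalence) or `"none"`.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, epochs = 10L, batch_size = 128L,
                         split = c(0.5, 0.25, 0.25), seed = 1L,
                         class_weights = c("balanced", "none")) {
  class_weights <- match.arg(class_weights)
  assert_that(epochs >= 1L, "epochs must be >= 1")
  assert_that(length(split) == 3L && abs(sum(split) - 1) < 1e-8,
              "split ratios must be three values summing to 1")
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), split = split,
                 seed = as.integer(seed), class_weights = class_weights),
            class = "train_config")
}

subset_stimuli <- function(stimuli, idx) {
  structure(list(images = stimuli$images[, , idx, drop = FALSE],
                 meta = stimuli$meta[idx, , drop = FALSE]),
            class = "stimulus_set")
}

#' Stratified train/validation/test split
#'
#' Partitions a stimulus set into disjoint subsets at the configured ratios,
#' stratified by emotion category; identical seeds give identical splits.
#'
#' @param stimuli a `stimulus_set`.
#' @param config a [train_config()] (its `split` and `seed` are used).
#' @return named list of `stimulus_set`s: `train`, `val`, `test`.
#' @export
split_dataset <- function(stimuli, config = train_config()) {
  cat_tab <- table(stimuli$meta$category)
  assert_that(all(cat_tab >= 4L), "need at least 4 images per category")
  n <- nrow(stimuli$meta)
  assign <- integer(n)
  with_seed(config$seed, {
    for (cat in names(cat_tab)) {
      idx <- sample(which(stimuli$meta$category == cat))
      m <- length(idx)
      n_tr <- floor(config$split[1L] * m)
      n_va <- floor(config$split[2L] * m)
      assign[idx[seq_len(n_tr)]] <- 1L
      assign[idx[n_tr + seq_len(n_va)]] <- 2L
      rest <- idx[setdiff(seq_len(m), seq_len(n_tr + n_va))]
      assign[rest] <- 3L
    }
  })
  list(train = subset_stimuli(stimuli, which(assign == 1L)),
       val = subset_stimuli(stimuli, which(assign == 2L)),
       test = subset_stimuli(stimuli, which(assign == 3L)))
}

binary_labels <- function(meta, task) {
  as.integer(meta$category == task$positive) # 1 = positive class
}

softmax2 <- function(logits) {
  m <- pmax(logits[, 1L], logits[, 2L])
  e1 <- exp(logits[, 1L] - m)
  e2 <- exp(logits[, 2L] - m)
  cbind(e1, e2) / (e1 + e2)
}

#' Train the two-unit emotion readout
#'
#' Extracts frozen-backbone features for the training and validation images
#' (baseline gains), standardizes them with training-set statistics, and fits
#' the two-unit softmax head by minibatch SGD under (optionally
#' class-weighted) cross-entropy. No backbone weight is touched; the model
#' records the backbone checksum so that later evaluations can verify
#' provenance.
#'
#' @param backbone a `cnn_backbone`.
#' @param task a [readout_task()].
#' @param train,val `stimulus_set`s.
#' @param config a [train_config()].
#' @return object of class `readout_model` with head weights, feature
#'   scaling, per-epoch training losses and validation F1.
#' @export
train_readout <- function(backbone, task, train, val, config = train_config()) {
  assert_that(inherits(task, "readout_task"), "task must be a readout_task")
  assert_that(nrow(train$meta) >= 1L, "empty training set")
  assert_that(task$positive %in% train$meta$category,
              "task emotion absent from training labels")
  X <- backbone_features(backbone, train)
  y <- binary_labels(train$meta, task) # 1 positive, 0 negative
  mu <- colMeans(X)
  sg <- pmax(apply(X, 2L, stats::sd), 1e-8)
  Xs <- sweep(sweep(X, 2L, mu), 2L, sg, "/")
  n <- nrow(Xs)
  wts <- if (config$class_weights == "balanced") {
    prev <- mean(y)
    ifelse(y == 1L, 0.5 / max(prev, 1e-12), 0.5 / max(1 - prev, 1e-12))
  } else rep(1, n)
  D <- ncol(Xs)
  W <- matrix(0, 2L, D) # rows: (negative, positive) unit
  b <- numeric(2L)
  losses <- numeric(config$epochs)
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      tot <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        Xb <- Xs[idx, , drop = FALSE]
        yb <- y[idx]
        wb <- wts[idx]
        P <- softmax2(Xb %*% t(W) + matrix(b, length(idx), 2L, byrow = TRUE))
        tgt <- cbind(1 - yb, yb)
        tot <- tot - sum(wb * log(pmax(P[cbind(seq_along(idx), yb + 1L)], 1e-12)))
        G <- (P - tgt) * wb / length(idx)
        W <- W - config$lr * t(G) %*% Xb
        b <- b - config$lr * colSums(G)
      }
      losses[ep] <- tot / n
    }
  })
  model <- structure(list(W = W, b = b, mu = mu, sigma = sg, task = task,
                          config = config,
                          backbone_checksum = weights_checksum(backbone),
                          train_losses = losses),
                     class = "readout_model")
  model$val_f1 <- if (!is.null(val) && nrow(val$meta) > 0L) {
    evaluate_readout(backbone, model, gain_config(), val)
  } else NA_real_
  model
}

readout_predict <- function(model, feats) {
  Xs <- sweep(sweep(feats, 2L, model$mu), 2L, model$sigma, "/")
  logits <- Xs %*% t(model$W) + matrix(model$b, nrow(Xs), 2L, byrow = TRUE)
  as.integer(logits[, 2L] > logits[, 1L])
}

#' F1-score
#'
#' `2TP / (2TP + FP + FN)` for the positive class, defined as 0 when the
#' denominator is 0. `average = "macro"` averages the positive-class and
#' negative-class F1.
#'
#' @param predictions,labels equal-length vectors.
#' @param positive the value treated as the positive class.
#' @param average `"binary"` (default) or `"macro"`.
#' @return scalar in `[0, 1]`.
#' @export
f1_score <- function(predictions, labels, positive = 1L,
                     average = c("binary", "macro")) {
  average <- match.arg(average)
  assert_that(length(predictions) == length(labels),
              "predictions and labels must have equal length")
  assert_that(positive %in% c(predictions, labels), "unknown positive class")
  one <- function(pos) {
    tp <- sum(predictions == pos & labels == pos)
    fp <- sum(predictions == pos & labels != pos)
    fn <- sum(predictions != pos & labels == pos)
    den <- 2 * tp + fp + fn
    if (den == 0) 0 else 2 * tp / den
  }
  if (average == "binary") return(one(positive))
  classes <- unique(c(predictions, labels))
  mean(vapply(classes, one, 1.0))
}

#' Evaluate the readout under a gain configuration
#'
#' Runs the test images through the backbone with [gain_forward()] semantics
#' under the supplied gains, applies the frozen readout head, and returns the
#' F1-score of the task's positive emotion. With baseline (all-zero) gains
#' this reproduces the unmanipulated test performance exactly.
#'
#' @param backbone the `cnn_backbone` the readout was trained on.
#' @param model a `readout_model`.
#' @param gains a [gain_config()].
#' @param test a `stimulus_set`.
#' @return test F1 (scalar).
#' @export
evaluate_readout <- function(backbone, model, gains, test) {
  assert_that(inherits(model, "readout_model"), "model must be a readout_model")
  assert_that(identical(model$backbone_checksum, weights_checksum(backbone)),
              "backbone does not match the one the readout was trained on")
  feats <- backbone_features(backbone, test, gains)
  pred <- readout_predict(model, feats)
  f1_score(pred, binary_labels(test$meta, model$task), positive = 1L)
}

#' Export readout predictions
#'
#' @param backbone,model,gains,test as in [evaluate_readout()].
#' @param path CSV output path.
#' @return `path`, invisibly; the CSV has columns `image_id`, `score`
#'   (positive-unit logit margin), `predicted`, `label`.
#' @export
write_predictions <- function(backbone, model, gains, test, path) {
  feats <- backbone_features(backbone, test, gains)
  Xs <- sweep(sweep(feats, 2L, model$mu), 2L, model$sigma, "/")
  logits <- Xs %*% t(model$W) + matrix(model$b, nrow(Xs), 2L, byrow = TRUE)
  utils::write.csv(data.frame(image_id = test$meta$image_id,
                              score = logits[, 2L] - logits[, 1L],
                              predicted = as.integer(logits[, 2L] > logits[, 1L]),
                              label = binary_labels(test$meta, model$task)),
                   path, row.names = FALSE)
  invisible(path)
}
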