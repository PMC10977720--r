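# Full backpropagation training of the mini backbone on a labeled image task.
# Used to obtain the "trained on object recognition" condition against which
# a randomly initialized backbone is contrasted. Training always runs at
# baseline gain (alpha = 0); gain manipulations are an inference-time device.

forward_train <- function(backbone, A0, H0, W0) {
  nl <- n_conv_layers(backbone)
  caches <- vector("list", nl)
  A <- A0; H <- H0; W <- W0
  for (l in seq_len(nl)) {
    layer <- backbone$layers[[l]]
    cl <- conv_linear(layer, A, H, W)
    relu <- pmax(cl$Z, 0)
    cache <- list(cols = cl$cols, mask = cl$Z > 0, H = cl$Ho, W = cl$Wo,
                  in_H = H, in_W = W, prepool = NULL, pooled = NULL)
    H <- cl$Ho; W <- cl$Wo
    if (layer$pool) {
      p <- maxpool2(relu, H, W)
      cache$prepool <- relu
      cache$pooled <- p$A
      A <- p$A; H <- p$H; W <- p$W
    } else {
      A <- relu
    }
    caches[[l]] <- cache
  }
  list(caches = caches, features = as.vector(A), K = nrow(A), H = H, W = W)
}

unpool_grad <- function(dA, prepool, pooled, H, W) {
  p <- pool_index(H, W)
  M1 <- prepool[, p$i1, drop = FALSE] == pooled
  M2 <- (prepool[, p$i2, drop = FALSE] == pooled) & !M1
  M3 <- (prepool[, p$i3, drop = FALSE] == pooled) & !M1 & !M2
  M4 <- !(M1 | M2 | M3)
  d <- matrix(0, nrow(dA), H * W)
  d[, p$i1] <- dA * M1
  d[, p$i2] <- d[, p$i2] + dA * M2
  d[, p$i3] <- d[, p$i3] + dA * M3
  d[, p$i4] <- d[, p$i4] + dA * M4
  d
}

backward_train <- function(backbone, fw, dfeat) {
  nl <- n_conv_layers(backbone)
  grads <- vector("list", nl)
  dA <- matrix(dfeat, fw$K, fw$H * fw$W)
  for (l in rev(seq_len(nl))) {
    layer <- backbone$layers[[l]]
    cache <- fw$caches[[l]]
    if (layer$pool) dA <- unpool_grad(dA, cache$prepool, cache$pooled,
                                      cache$H, cache$W)
    dZ <- dA * cache$mask
    grads[[l]] <- list(W = dZ %*% t(cache$cols), b = rowSums(dZ))
    if (l > 1L) {
      dcols <- crossprod(layer$W, dZ)
      Hp <- cache$in_H + 2L * layer$pad
      Wp <- cache$in_W + 2L * layer$pad
      dP <- numeric(layer$C * Hp * Wp)
      g <- im2col_index(layer$C, cache$in_H, cache$in_W, layer$kh, layer$kw,
                        layer$pad)
      agg <- rowsum(as.vector(dcols), group = as.vector(g$idx))
      dP[as.integer(rownames(agg))] <- agg
      dA <- matrix(dP, layer$C, Hp * Wp)[, pad_interior_index(cache$in_H,
                                                              cache$in_W,
                                                              layer$pad),
                                         drop = FALSE]
    }
  }
  grads
}

#' Train the backbone end-to-end on a labeled image task
#'
#' Attaches a linear classification head to the flattened final pooled
#' activations and trains all convolutional weights plus the head with
#' minibatch stochastic gradient descent (momentum 0.9) under a softmax
#' cross-entropy loss. This provides the "trained to recognize objects"
#' condition; a freshly built backbone is the random-weight control.
#'
#' @param backbone a `cnn_backbone` (modified copy is returned).
#' @param images 3-D array `H x W x N` or a `stimulus_set`-like image array.
#' @param labels factor (or character) of class labels, length N.
#' @param epochs,lr,batch_size,momentum training hyperparameters.
#' @param clip_norm cap on the per-example global gradient norm (stabilizes
#'   SGD with momentum at the default learning rate).
#' @param seed RNG seed for shuffling (training is deterministic given it).
#' @return the trained `cnn_backbone`, with a `head` component
#'   (`W`, `b`, `classes`) and an `history` attribute of per-epoch mean loss.
#' @export
train_backbone <- function(backbone, images, labels, epochs = 10L, lr = 0.05,
                           batch_size = 32L, momentum = 0.9, seed = 1L,
                           clip_norm = 5) {
  imgs <- as_image_array(images)
  labels <- factor(labels)
  N <- dim(imgs)[3L]
  assert_that(length(labels) == N, "labels must match the number of images")
  assert_that(nlevels(labels) >= 2L, "need at least 2 classes")
  nc <- nlevels(labels)
  y <- as.integer(labels)
  nl <- n_conv_layers(backbone)
  S <- backbone$input_size

  probe <- forward_train(backbone, prepare_input(backbone, imgs[, , 1L]), S, S)
  D <- length(probe$features)
  history <- numeric(epochs)
  with_seed(seed, {
    Wh <- matrix(stats::rnorm(nc * D, sd = sqrt(1 / D)), nc, D)
    bh <- numeric(nc)
    vel <- lapply(backbone$layers, function(l) list(W = l$W * 0, b = l$b * 0))
    velWh <- Wh * 0
    velbh <- bh * 0
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      losses <- numeric(0)
      for (start in seq(1L, N, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, N)]
        gW <- lapply(backbone$layers, function(l) l$W * 0)
        gb <- lapply(backbone$layers, function(l) l$b * 0)
        gWh <- Wh * 0
        gbh <- bh * 0
        bl <- 0
        for (n in idx) {
          fw <- forward_train(backbone, prepare_input(backbone, imgs[, , n]), S, S)
          logits <- as.vector(Wh %*% fw$features) + bh
          logits <- logits - max(logits)
          p <- exp(logits) / sum(exp(logits))
          bl <- bl - log(max(p[y[n]], 1e-12))
          dlog <- p
          dlog[y[n]] <- dlog[y[n]] - 1
          gWh <- gWh + outer(dlog, fw$features)
          gbh <- gbh + dlog
          grads <- backward_train(backbone, fw, as.vector(crossprod(Wh, dlog)))
          for (l in seq_len(nl)) {
            gW[[l]] <- gW[[l]] + grads[[l]]$W
            gb[[l]] <- gb[[l]] + grads[[l]]$b
          }
        }
        m <- length(idx)
        # clip the global gradient norm; keeps SGD stable at higher rates
        gnorm <- sqrt((sum(gWh^2) + sum(gbh^2) +
                         sum(vapply(seq_len(nl), function(l)
                           sum(gW[[l]]^2) + sum(gb[[l]]^2), 1.0))) / m^2)
        if (gnorm > clip_norm) {
          sc <- clip_norm / gnorm
          gWh <- gWh * sc
          gbh <- gbh * sc
          for (l in seq_len(nl)) {
            gW[[l]] <- gW[[l]] * sc
            gb[[l]] <- gb[[l]] * sc
          }
        }
        for (l in seq_len(nl)) {
          vel[[l]]$W <- momentum * vel[[l]]$W - lr * gW[[l]] / m
          vel[[l]]$b <- momentum * vel[[l]]$b - lr * gb[[l]] / m
          backbone$layers[[l]]$W <- backbone$layers[[l]]$W + vel[[l]]$W
          backbone$layers[[l]]$b <- backbone$layers[[l]]$b + vel[[l]]$b
        }
        velWh <- momentum * velWh - lr * gWh / m
        velbh <- momentum * velbh - lr * gbh / m
        Wh <- Wh + velWh
        bh <- bh + velbh
        losses <- c(losses, bl / m)
      }
      history[ep] <- mean(losses)
    }
    backbone$head <- list(W = Wh, b = bh, classes = levels(labels))
  })
  attr(backbone, "history") <- history
  backbone
}

#' Predict task labels with a trained backbone head
#'
#' @param backbone a `cnn_backbone` trained with [train_backbone()].
#' @param images 3-D image array or `stimulus_set`.
#' @return character vector of predicted class labels.
#' @export
predict_backbone <- function(backbone, images) {
  assert_that(!is.null(backbone$head), "backbone has no classification head")
  feats <- backbone_features(backbone, images)
  logits <- feats %*% t(backbone$head$W) +
    matrix(backbone$head$b, nrow(feats), length(backbone$head$b), byrow = TRUE)
  backbone$head$classes[max.col(logits, ties.method = "first")]
}
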