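# Independent oracles: literal transcriptions of the selectivity formulas
# and a naive spatial convolution, used to cross-check the vectorized
# implementations.

emo_levels <- c("pleasant", "neutral", "unpleasant")

# tuning value: mean deviation from the grand mean within category e,
# normalized by the population SD over all images
oracle_tuning <- function(p, labels) {
  N <- length(p)
  p_hat <- sum(p) / N
  den <- sqrt(sum((p - p_hat)^2) / N)
  vapply(emo_levels, function(e) {
    idx <- which(labels == e)
    num <- sum(p[idx] - p_hat) / length(idx)
    if (den == 0) 0 else num / den
  }, 1.0)
}

# one-vs-rest d-prime, population variances, non-target pair pooled first
oracle_dprime <- function(p, labels) {
  m <- vapply(emo_levels, function(e) mean(p[labels == e]), 1.0)
  v <- vapply(emo_levels, function(e) {
    x <- p[labels == e]
    sum((x - mean(x))^2) / length(x)
  }, 1.0)
  vapply(seq_along(emo_levels), function(i) {
    o <- setdiff(seq_along(emo_levels), i)
    num <- m[i] - (m[o[1]] + m[o[2]]) / 2
    den <- sqrt((v[i] + (v[o[1]] + v[o[2]]) / 2) / 2)
    if (den == 0) { if (num == 0) 0 else sign(num) * Inf } else num / den
  }, 1.0)
}

# direct spatial convolution of one filter over a padded multichannel input
oracle_conv <- function(w_row, A, C, H, W, kh, kw, pad) {
  Ap <- array(0, dim = c(C, H + 2 * pad, W + 2 * pad))
  for (c in seq_len(C)) {
    Ap[c, (pad + 1):(pad + H), (pad + 1):(pad + W)] <- matrix(A[c, ], H, W)
  }
  Kn <- array(w_row, dim = c(C, kh, kw))
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    out[i, j] <- sum(Ap[, i:(i + kh - 1), j:(j + kw - 1), drop = FALSE] * Kn)
  }
  as.vector(out)
}

# rectified mean matched-filter energy of an image for a 3x3 kernel
oracle_matched_energy <- function(img, kern) {
  H <- nrow(img); W <- ncol(img)
  A <- matrix(as.vector(img), 1L)
  mean(pmax(oracle_conv(as.vector(kern), A, 1L, H, W, 3L, 3L, 1L), 0))
}

# small deterministic fixtures -------------------------------------------------

tiny_backbone <- function(seed = 3L, filters = c(4L, 6L), size = 8L) {
  build_backbone(backbone_spec("mini-cnn", filters = filters,
                               input_size = size, seed = seed))
}

tiny_set <- function(seed = 5L, n = 4L, size = 8L, effect = 3, tag = "tiny") {
  generate_affective_set(synth_config(size = size, images_per_category = n,
                                      effect_size = effect, dataset = tag,
                                      seed = seed))
}

# response matrix with hand-set values and proper naming
manual_responses <- function(values, layer = 1L, ids = NULL) {
  m <- as.matrix(values)
  if (is.null(ids)) ids <- sprintf("img_%03d", seq_len(nrow(m)))
  rownames(m) <- ids
  colnames(m) <- sprintf("L%d.K%d", layer, seq_len(ncol(m)) - 1L)
  attr(m, "layer") <- layer
  attr(m, "dataset") <- "manual"
  class(m) <- c("response_matrix", class(m))
  m
}
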