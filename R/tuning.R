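# Tuning values, tuning curves, d-prime and the selectivity index (SI).
#
# For a neuron with spatially averaged responses p(n) over a dataset of N
# images with grand mean p_hat, the tuning value for emotion category e is
#     S_e = (1/N_e) * sum_{n in e} (p(n) - p_hat) / sqrt((1/N) sum_n (p(n) - p_hat)^2),
# the mean z-scored response to that category (population SD over all
# images). The d-prime of a target category e against the other two pooled is
#     d'(e) = (m_e - (m_o1 + m_o2)/2) / sqrt((v_e + (v_o1 + v_o2)/2) / 2)
# and the selectivity index SI is the largest of the three d' values; the
# arg-max category is the neuron's selective emotion.

response_layer <- function(responses) {
  l <- attr(responses, "layer")
  if (is.null(l)) 1L else as.integer(l)
}

neuron_table_from_responses <- function(responses) {
  cn <- colnames(responses)
  l <- response_layer(responses)
  if (!is.null(cn) && all(grepl("^L\\d+\\.K\\d+$", cn))) {
    data.frame(layer = as.integer(sub("^L(\\d+)\\..*", "\\1", cn)),
               filter = as.integer(sub("^.*\\.K(\\d+)$", "\\1", cn)))
  } else {
    neurons(l, seq_len(ncol(responses)) - 1L)
  }
}

#' Tuning values and preferred emotion per neuron
#'
#' Computes, for every neuron (column of the response matrix), the three
#' category tuning values, the preferred category (arg-max tuning value, ties
#' broken in the fixed order pleasant < neutral < unpleasant), and a
#' degeneracy flag for zero-variance (dead) neurons, whose tuning values are
#' reported as 0.
#'
#' @param responses numeric matrix `N x K` of spatially averaged responses
#'   (a `response_matrix`).
#' @param labels emotion category per image (pleasant/neutral/unpleasant),
#'   aligned to rows.
#' @return a `data.frame` (one row per neuron) with columns `neuron`,
#'   `layer`, `filter`, `s_pleasant`, `s_neutral`, `s_unpleasant`,
#'   `preferred`, `degenerate`.
#' @export
tuning_values <- function(responses, labels) {
  assert_that(is.matrix(responses) && nrow(responses) >= 2L,
              "need at least 2 images")
  labels <- check_labels(labels, nrow(responses))
  assert_that(all(EMOTIONS %in% labels), "every category must be present")
  N <- nrow(responses)
  grand <- colMeans(responses)
  dev <- sweep(responses, 2L, grand)
  sdev <- sqrt(colMeans(dev^2))
  degenerate <- sdev == 0
  S <- vapply(EMOTIONS, function(e) {
    colMeans(dev[labels == e, , drop = FALSE]) /
      ifelse(degenerate, 1, sdev)
  }, numeric(ncol(responses)))
  if (!is.matrix(S)) S <- matrix(S, nrow = 1L, dimnames = list(NULL, EMOTIONS))
  S[degenerate, ] <- 0
  pref <- EMOTIONS[apply(S, 1L, which.max)]
  nrn <- neuron_table_from_responses(responses)
  data.frame(neuron = neuron_ids(nrn), layer = nrn$layer, filter = nrn$filter,
             s_pleasant = S[, "pleasant"], s_neutral = S[, "neutral"],
             s_unpleasant = S[, "unpleasant"], preferred = pref,
             degenerate = degenerate, row.names = NULL)
}

category_moments <- function(responses, labels, var_type) {
  lapply(EMOTIONS, function(e) {
    X <- responses[labels == e, , drop = FALSE]
    m <- colMeans(X)
    v <- colMeans(sweep(X, 2L, m)^2)
    if (var_type == "sample") v <- v * nrow(X) / (nrow(X) - 1L)
    list(mean = m, var = v, n = nrow(X))
  })
}

#' d-prime values and selectivity index per neuron
#'
#' One-vs-rest d-prime for each emotion category; SI is the largest d-prime
#' and the arg-max category is the neuron's selective emotion (ties broken
#' pleasant < neutral < unpleasant). Neurons with zero across-image variance
#' are flagged degenerate and get all d' = 0. When a non-degenerate contrast
#' has a zero pooled-variance denominator, d' is 0 for a zero mean difference
#' and +/-Inf otherwise.
#'
#' @inheritParams tuning_values
#' @param var_type `"population"` (divide by N_e; default, consistent with the
#'   population standard deviation of the tuning-value normalization) or
#'   `"sample"`.
#' @param pooling how the three category variances enter the denominator:
#'   `"paired"` (default) pools the two non-target variances first,
#'   `sqrt((v_e + (v_o1 + v_o2)/2)/2)`, mirroring the numerator; `"flat"` uses
#'   `sqrt((v_e + v_o1 + v_o2)/2)`.
#' @return a `data.frame` (one row per neuron) with columns `neuron`, `layer`,
#'   `filter`, `d_pleasant`, `d_neutral`, `d_unpleasant`, `si`, `emotion`,
#'   `degenerate`, carrying attributes `layer` and `dataset` from the
#'   response matrix.
#' @export
dprime_si <- function(responses, labels, var_type = c("population", "sample"),
                      pooling = c("paired", "flat")) {
  var_type <- match.arg(var_type)
  pooling <- match.arg(pooling)
  assert_that(is.matrix(responses) && nrow(responses) >= 2L,
              "need at least 2 images")
  labels <- check_labels(labels, nrow(responses))
  counts <- table(labels)
  assert_that(all(counts >= 2L), "every category needs at least 2 images")
  mom <- category_moments(responses, labels, var_type)
  names(mom) <- EMOTIONS
  grand_var <- colMeans(sweep(responses, 2L, colMeans(responses))^2)
  degenerate <- grand_var == 0
  D <- vapply(seq_along(EMOTIONS), function(i) {
    oth <- setdiff(seq_along(EMOTIONS), i)
    num <- mom[[i]]$mean - (mom[[oth[1L]]]$mean + mom[[oth[2L]]]$mean) / 2
    den2 <- if (pooling == "paired") {
      (mom[[i]]$var + (mom[[oth[1L]]]$var + mom[[oth[2L]]]$var) / 2) / 2
    } else {
      (mom[[i]]$var + mom[[oth[1L]]]$var + mom[[oth[2L]]]$var) / 2
    }
    den <- sqrt(den2)
    ifelse(den > 0, num / den, ifelse(num == 0, 0, sign(num) * Inf))
  }, numeric(ncol(responses)))
  if (!is.matrix(D)) D <- matrix(D, nrow = 1L)
  D[degenerate, ] <- 0
  colnames(D) <- EMOTIONS
  best <- apply(D, 1L, which.max)
  nrn <- neuron_table_from_responses(responses)
  out <- data.frame(neuron = neuron_ids(nrn), layer = nrn$layer,
                    filter = nrn$filter,
                    d_pleasant = D[, "pleasant"], d_neutral = D[, "neutral"],
                    d_unpleasant = D[, "unpleasant"],
                    si = D[cbind(seq_len(nrow(D)), best)],
                    emotion = EMOTIONS[best],
                    degenerate = degenerate, row.names = NULL)
  attr(out, "layer") <- response_layer(responses)
  attr(out, "dataset") <- attr(responses, "dataset")
  out
}

#' Images eliciting the strongest responses of a neuron
#'
#' @param responses a `response_matrix` (with image-id rownames).
#' @param neuron a one-row [neurons()] table (the layer must match the
#'   response matrix).
#' @param k number of images to return; when `k > N` all N are returned.
#' @return character vector of image ids sorted by descending response,
#'   ties broken by ascending image id.
#' @export
top_k_images <- function(responses, neuron, k) {
  assert_that(k >= 1L, "k must be >= 1")
  assert_that(nrow(neuron) == 1L, "one neuron at a time")
  id <- neuron_ids(neuron)
  assert_that(id %in% colnames(responses),
              sprintf("unknown neuron %s for this response matrix", id))
  x <- responses[, id]
  ids <- rownames(responses)
  ord <- order(-x, ids)
  ids[ord][seq_len(min(k, length(x)))]
}

#' Selectivity records for several layers in one call
#'
#' Convenience wrapper: extract responses and compute [dprime_si()] for each
#' requested layer.
#'
#' @inheritParams extract_responses
#' @param ... passed to [dprime_si()].
#' @return named list of selectivity record data frames, one per layer.
#' @export
selectivity_records <- function(backbone, stimuli, layers = NULL,
                                gains = gain_config(), ...) {
  resp <- extract_responses(backbone, stimuli, layers = layers, gains = gains)
  lapply(resp, dprime_si, labels = stimuli$meta$category, ...)
}
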