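# internal helpers shared across modules

EMOTIONS <- c("pleasant", "neutral", "unpleasant")

# run code with a fixed RNG state, restoring whatever state was there before
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# cache for im2col / pooling index matrices, keyed by geometry
.geom_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  val <- builder()
  .geom_cache[[key]] <- val
  val
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Construct a table of neuron identifiers
#'
#' Neurons are convolutional filters, addressed by a 1-based convolutional
#' layer index and a 0-based filter index within that layer.
#'
#' @param layer integer vector of 1-based convolutional layer indices.
#' @param filter integer vector of 0-based filter indices (recycled against
#'   `layer`).
#' @return a `data.frame` with columns `layer` and `filter`.
#' @export
neurons <- function(layer, filter) {
  layer <- as.integer(layer)
  filter <- as.integer(filter)
  n <- if (length(layer) == 0L || length(filter) == 0L) 0L else
    max(length(layer), length(filter))
  df <- data.frame(layer = rep_len(layer, n), filter = rep_len(filter, n))
  assert_that(all(df$layer >= 1L), "layer indices are 1-based and positive")
  assert_that(all(df$filter >= 0L), "filter indices are 0-based and non-negative")
  df
}

neuron_ids <- function(nrn) sprintf("L%d.K%d", nrn$layer, nrn$filter)

# canonical category factor, fixed order used for all tie-breaks
as_emotion <- function(x) factor(as.character(x), levels = EMOTIONS)

check_labels <- function(labels, n) {
  labels <- as_emotion(labels)
  assert_that(!anyNA(labels), "labels must all be pleasant/neutral/unpleasant")
  assert_that(length(labels) == n, "labels must align with response-matrix rows")
  labels
}

# checksum of backbone weights via serialization; used for provenance checks
weights_checksum <- function(backbone) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(lapply(backbone$layers, function(l) list(W = l$W, b = l$b)), f)
  unname(tools::md5sum(f))
}
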