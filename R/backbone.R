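# Layered convolutional backbones with a gain-parameterized rectifier.
#
# Every convolutional filter ("neuron") k in layer l computes
#     x_lk = (1 + alpha_lk) * max(0, w_lk * x_{l-1})
# where * is spatial convolution and alpha is a tunable slope offset:
# alpha = 0 is the plain ReLU baseline, alpha = -1 silences (lesions) the
# neuron, alpha > 0 raises its gain, emulating feature-based attention.
# Convolutions are stride-1, 3x3, zero-padded ("same"), each optionally
# followed by 2x2 max pooling. Implemented as im2col + matrix products.

VGG16_FILTERS <- c(64L, 64L, 128L, 128L, 256L, 256L, 256L,
                   512L, 512L, 512L, 512L, 512L, 512L)
VGG16_POOL_AFTER <- c(2L, 4L, 7L, 10L, 13L)

#' Describe a convolutional backbone
#'
#' @param architecture `"mini-cnn"` (desk-scale, single-channel input) or
#'   `"vgg16-layout"` (the standard 13-convolutional-layer layout with pooling
#'   after layers 2, 4, 7, 10 and 13; three input channels).
#' @param filters integer vector of per-layer filter counts. Defaults to
#'   `c(8, 16, 32)` for the mini network and the standard 64...512 progression
#'   for the vgg16 layout (where it must not be overridden).
#' @param input_size input image side length in pixels (square input).
#'   Defaults to 32 for the mini network, 224 for the vgg16 layout.
#' @param kernel spatial kernel side length (odd), default 3.
#' @param seed integer seed recorded and used for random weight
#'   initialization.
#' @param weights optional path to a weight container written by
#'   [save_backbone()]; when given it must match the layout.
#' @return an object of class `backbone_spec`.
#' @export
backbone_spec <- function(architecture = c("mini-cnn", "vgg16-layout"),
                          filters = NULL, input_size = NULL, kernel = 3L,
                          seed = 1L, weights = NULL) {
  architecture <- match.arg(architecture)
  if (architecture == "vgg16-layout") {
    if (!is.null(filters) && !identical(as.integer(filters), VGG16_FILTERS)) {
      stop("the vgg16 layout has a fixed filter progression", call. = FALSE)
    }
    filters <- VGG16_FILTERS
    if (is.null(input_size)) input_size <- 224L
    pool_after <- VGG16_POOL_AFTER
    in_channels <- 3L
    preprocess <- list(mean = 0.449, sd = 0.226, replicate = 3L)
  } else {
    if (is.null(filters)) filters <- c(8L, 16L, 32L)
    filters <- as.integer(filters)
    if (is.null(input_size)) input_size <- 32L
    pool_after <- seq_along(filters)
    in_channels <- 1L
    preprocess <- list(mean = 0.5, sd = 0.5, replicate = 1L)
  }
  assert_that(length(filters) >= 2L, "a backbone needs at least 2 convolutional layers")
  assert_that(all(filters > 0L), "filter counts must be positive")
  kernel <- as.integer(kernel)
  assert_that(kernel >= 1L && kernel %% 2L == 1L, "kernel size must be odd and >= 1")
  n_pools <- length(pool_after)
  assert_that(input_size %% 2L^n_pools == 0L,
              "input size must be divisible by 2^(number of pooling stages)")
  structure(list(architecture = architecture, filters = filters,
                 kernel = kernel, input_size = as.integer(input_size),
                 in_channels = in_channels, pool_after = as.integer(pool_after),
                 preprocess = preprocess, seed = as.integer(seed),
                 weights = weights),
            class = "backbone_spec")
}

#' Build a backbone from its specification
#'
#' Random-weight builds use He-scaled Gaussian initialization and are
#' bit-reproducible given `spec$seed`. When `spec$weights` points to a saved
#' container, the stored weights are loaded after a layout check.
#'
#' @param spec a [backbone_spec()].
#' @return an object of class `cnn_backbone` with individually addressable
#'   convolutional layers.
#' @export
build_backbone <- function(spec) {
  assert_that(inherits(spec, "backbone_spec"), "spec must be a backbone_spec")
  if (!is.null(spec$weights)) {
    bb <- load_backbone(spec$weights)
    ok <- identical(bb$spec$architecture, spec$architecture) &&
      identical(bb$spec$filters, spec$filters) &&
      identical(bb$spec$kernel, spec$kernel) &&
      identical(bb$spec$input_size, spec$input_size)
    assert_that(ok, "weight container does not match the requested layout")
    return(bb)
  }
  k2 <- spec$kernel^2
  layers <- with_seed(spec$seed, {
    cin <- spec$in_channels
    lapply(seq_along(spec$filters), function(l) {
      K <- spec$filters[l]
      C <- if (l == 1L) cin else spec$filters[l - 1L]
      W <- matrix(stats::rnorm(K * C * k2, sd = sqrt(2 / (C * k2))), nrow = K)
      list(W = W, b = numeric(K), C = C, K = K,
           kh = spec$kernel, kw = spec$kernel,
           pad = (spec$kernel - 1L) %/% 2L,
           pool = l %in% spec$pool_after)
    })
  })
  structure(list(architecture = spec$architecture, layers = layers,
                 input_size = spec$input_size, in_channels = spec$in_channels,
                 preprocess = spec$preprocess, spec = spec, head = NULL),
            class = "cnn_backbone")
}

#' @export
print.cnn_backbone <- function(x, ...) {
  cat(sprintf("<cnn_backbone> %s: %d conv layers, input %dx%d, %d input channel(s)\n",
              x$architecture, length(x$layers), x$input_size, x$input_size,
              x$in_channels))
  for (l in seq_along(x$layers)) {
    L <- x$layers[[l]]
    cat(sprintf("  conv %2d: %3d filters %dx%d%s\n", l, L$K, L$kh, L$kw,
                if (L$pool) " + maxpool2" else ""))
  }
  invisible(x)
}

n_conv_layers <- function(backbone) length(backbone$layers)

#' Save / load backbone weights
#'
#' The container is a single RDS file holding a layout manifest
#' (architecture, filter counts, kernel and input sizes, a weight checksum)
#' together with the weight arrays; [load_backbone()] verifies the checksum.
#'
#' @param backbone a `cnn_backbone`.
#' @param path file path for the container.
#' @return `save_backbone` returns `path` invisibly; `load_backbone` returns
#'   the rebuilt `cnn_backbone`.
#' @export
save_backbone <- function(backbone, path) {
  assert_that(inherits(backbone, "cnn_backbone"), "not a cnn_backbone")
  manifest <- list(architecture = backbone$architecture,
                   filters = vapply(backbone$layers, function(l) l$K, 1L),
                   kernel = backbone$layers[[1L]]$kh,
                   input_size = backbone$input_size,
                   checksum = weights_checksum(backbone))
  saveRDS(list(manifest = manifest, backbone = backbone), path)
  invisible(path)
}

#' @rdname save_backbone
#' @export
load_backbone <- function(path) {
  obj <- readRDS(path)
  assert_that(is.list(obj) && !is.null(obj$manifest) && !is.null(obj$backbone),
              "not a backbone container")
  assert_that(identical(obj$manifest$checksum, weights_checksum(obj$backbone)),
              "backbone container checksum mismatch")
  obj$backbone
}

# ---- geometry: im2col / padding / pooling indices (cached) -----------------

im2col_index <- function(C, H, W, kh, kw, pad) {
  key <- sprintf("i2c:%d:%d:%d:%d:%d:%d", C, H, W, kh, kw, pad)
  cached(key, function() {
    Hp <- H + 2L * pad
    Ho <- Hp - kh + 1L
    Wo <- W + 2L * pad - kw + 1L
    oy <- rep(seq_len(Ho), times = Wo)
    ox <- rep(seq_len(Wo), each = Ho)
    dy <- rep(seq_len(kh), times = kw)
    dx <- rep(seq_len(kw), each = kh)
    yy <- outer(dy, oy, `+`) - 1L          # (kh*kw) x (Ho*Wo)
    xx <- outer(dx, ox, `+`) - 1L
    colp <- (xx - 1L) * Hp + yy            # padded spatial column index
    base <- (colp - 1L) * C                # vector offset, channel-fastest rows
    idx <- base[rep(seq_len(kh * kw), each = C), , drop = FALSE] +
      rep_len(seq_len(C), C * kh * kw)
    storage.mode(idx) <- "integer"
    list(idx = idx, Ho = Ho, Wo = Wo)
  })
}

pad_interior_index <- function(H, W, pad) {
  key <- sprintf("pad:%d:%d:%d", H, W, pad)
  cached(key, function() {
    Hp <- H + 2L * pad
    as.integer(outer((pad + 1L):(pad + H), (pad + 1L):(pad + W),
                     function(y, x) (x - 1L) * Hp + y))
  })
}

pool_index <- function(H, W) {
  key <- sprintf("pool:%d:%d", H, W)
  cached(key, function() {
    Ho <- H %/% 2L
    Wo <- W %/% 2L
    oi <- rep(seq_len(Ho), times = Wo)
    oj <- rep(seq_len(Wo), each = Ho)
    list(Ho = Ho, Wo = Wo,
         i1 = (2L * oj - 2L) * H + (2L * oi - 1L),
         i2 = (2L * oj - 2L) * H + 2L * oi,
         i3 = (2L * oj - 1L) * H + (2L * oi - 1L),
         i4 = (2L * oj - 1L) * H + 2L * oi)
  })
}

pad_activation <- function(A, H, W, pad) {
  if (pad == 0L) return(A)
  C <- nrow(A)
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  P <- matrix(0, C, Hp * Wp)
  P[, pad_interior_index(H, W, pad)] <- A
  P
}

conv_linear <- function(layer, A, H, W) {
  g <- im2col_index(layer$C, H, W, layer$kh, layer$kw, layer$pad)
  P <- pad_activation(A, H, W, layer$pad)
  cols <- P
  dim(cols) <- NULL
  cols <- cols[g$idx]
  dim(cols) <- dim(g$idx)
  list(Z = layer$W %*% cols + layer$b, cols = cols, Ho = g$Ho, Wo = g$Wo)
}

maxpool2 <- function(A, H, W) {
  p <- pool_index(H, W)
  m <- pmax(A[, p$i1, drop = FALSE], A[, p$i2, drop = FALSE],
            A[, p$i3, drop = FALSE], A[, p$i4, drop = FALSE])
  list(A = m, H = p$Ho, W = p$Wo)
}

# ---- gains -----------------------------------------------------------------

#' Per-neuron gain configuration
#'
#' Maps neurons to the slope offset alpha of the gain-parameterized rectifier
#' `(1 + alpha) * max(0, .)`. `alpha = 0` leaves a neuron at baseline,
#' `alpha = -1` lesions it (output forced to zero), `alpha > 0` enhances it.
#'
#' @param targets a [neurons()] table of neurons to override (or `NULL`).
#' @param alpha slope offsets for the targets, recycled; every alpha must be
#'   `>= -1`.
#' @param default alpha applied to every other neuron (default 0).
#' @return an object of class `gain_config`.
#' @export
gain_config <- function(targets = NULL, alpha = numeric(0), default = 0) {
  assert_that(default >= -1, "alpha must be >= -1")
  if (is.null(targets) || nrow(targets) == 0L) {
    ov <- data.frame(layer = integer(0), filter = integer(0), alpha = numeric(0))
  } else {
    alpha <- rep_len(alpha, nrow(targets))
    assert_that(all(alpha >= -1), "alpha must be >= -1")
    ov <- data.frame(layer = targets$layer, filter = targets$filter,
                     alpha = alpha)
    assert_that(!anyDuplicated(neuron_ids(ov)), "duplicate neuron overrides")
  }
  structure(list(default = default, overrides = ov), class = "gain_config")
}

#' @rdname gain_config
#' @export
lesion_gains <- function(targets) gain_config(targets, alpha = -1)

#' @rdname gain_config
#' @param enhance_alpha single alpha > 0 applied to all targets.
#' @export
enhance_gains <- function(targets, enhance_alpha) {
  assert_that(length(enhance_alpha) == 1L && enhance_alpha >= -1,
              "alpha must be a single value >= -1")
  gain_config(targets, alpha = enhance_alpha)
}

# (1 + alpha) multipliers per layer, validated against the backbone
resolve_gains <- function(backbone, gains) {
  if (is.null(gains)) gains <- gain_config()
  assert_that(inherits(gains, "gain_config"), "gains must be a gain_config")
  out <- lapply(backbone$layers, function(l) rep(1 + gains$default, l$K))
  ov <- gains$overrides
  if (nrow(ov)) {
    assert_that(all(ov$layer >= 1L & ov$layer <= length(out)),
                "gain entry references a nonexistent layer")
    for (r in seq_len(nrow(ov))) {
      l <- ov$layer[r]
      assert_that(ov$filter[r] >= 0L && ov$filter[r] < length(out[[l]]),
                  "gain entry references a nonexistent filter")
      out[[l]][ov$filter[r] + 1L] <- 1 + ov$alpha[r]
    }
  }
  out
}

# ---- forward pass ----------------------------------------------------------

# grayscale [0,1] image matrix -> preprocessed C x (H*W) activation
prepare_input <- function(backbone, img) {
  assert_that(is.matrix(img) &&
                nrow(img) == backbone$input_size &&
                ncol(img) == backbone$input_size,
              sprintf("image must be %dx%d", backbone$input_size,
                      backbone$input_size))
  v <- (as.vector(img) - backbone$preprocess$mean) / backbone$preprocess$sd
  matrix(rep(v, each = backbone$in_channels), nrow = backbone$in_channels)
}

# core inference pass from layer `from` given input activation A (C x H*W).
# gfac: list of per-layer (1+alpha) multipliers. Returns post-rectifier,
# post-gain, pre-pool maps per layer (when keep_maps) and the pooled output.
nn_infer <- function(backbone, A, H, W, gfac, from = 1L, keep_maps = TRUE) {
  nl <- n_conv_layers(backbone)
  maps <- if (keep_maps) vector("list", nl) else NULL
  dims <- vector("list", nl)
  for (l in from:nl) {
    layer <- backbone$layers[[l]]
    cl <- conv_linear(layer, A, H, W)
    A <- pmax(cl$Z, 0) * gfac[[l]]
    H <- cl$Ho
    W <- cl$Wo
    if (keep_maps) maps[[l]] <- A
    dims[[l]] <- c(H, W)
    if (layer$pool) {
      p <- maxpool2(A, H, W)
      A <- p$A
      H <- p$H
      W <- p$W
    }
  }
  list(maps = maps, dims = dims, out = A, H = H, W = W)
}

stimulus_images <- function(stimuli) {
  assert_that(inherits(stimuli, "stimulus_set"), "expected a stimulus_set")
  stimuli$images
}

#' Gain-modulated forward pass
#'
#' Runs a batch of images through the backbone with every filter's rectified
#' output scaled by its `(1 + alpha)` gain factor before being passed
#' downstream, and returns the resulting activation maps of every
#' convolutional layer.
#'
#' @param backbone a `cnn_backbone`.
#' @param images a single H-by-W grayscale matrix (values in `[0, 1]`), a
#'   3-D array `H x W x N`, or a `stimulus_set`.
#' @param gains a [gain_config()].
#' @return a list with one element per convolutional layer; each element is an
#'   array `K x H_l x W_l x N` of post-rectifier, post-gain activation maps.
#' @export
gain_forward <- function(backbone, images, gains = gain_config()) {
  gfac <- resolve_gains(backbone, gains)
  imgs <- as_image_array(images)
  N <- dim(imgs)[3L]
  nl <- n_conv_layers(backbone)
  per_layer <- NULL
  for (n in seq_len(N)) {
    A0 <- prepare_input(backbone, imgs[, , n])
    fw <- nn_infer(backbone, A0, backbone$input_size, backbone$input_size,
                   gfac, keep_maps = TRUE)
    if (is.null(per_layer)) {
      per_layer <- lapply(seq_len(nl), function(l) {
        d <- fw$dims[[l]]
        array(0, dim = c(backbone$layers[[l]]$K, d[1L], d[2L], N))
      })
    }
    for (l in seq_len(nl)) per_layer[[l]][, , , n] <- fw$maps[[l]]
  }
  names(per_layer) <- sprintf("layer_%d", seq_len(nl))
  per_layer
}

as_image_array <- function(images) {
  if (inherits(images, "stimulus_set")) return(images$images)
  if (is.matrix(images)) return(array(images, dim = c(dim(images), 1L)))
  assert_that(is.array(images) && length(dim(images)) == 3L,
              "images must be a matrix, 3-D array or stimulus_set")
  images
}

#' Spatial mean of one filter's activation map
#'
#' The neuronal response to an image: the activation map averaged across all
#' of its units, `(1/WH) * sum(X_ij)`.
#'
#' @param map numeric matrix (one filter's activation map for one image).
#' @return a scalar.
#' @export
mean_filter_response <- function(map) {
  assert_that(is.numeric(map) && length(map) >= 1L, "empty activation map")
  mean(map)
}

#' Extract spatially averaged responses per layer
#'
#' Presents every image to the backbone under the given gain configuration
#' and records, for each requested convolutional layer, the per-filter
#' spatially averaged response, yielding one images-by-neurons response
#' matrix per layer.
#'
#' @param backbone a `cnn_backbone`.
#' @param stimuli a `stimulus_set`.
#' @param layers integer vector of 1-based convolutional layer indices
#'   (default: all layers).
#' @param gains a [gain_config()].
#' @return a named list (`layer_<l>`) of `response_matrix` objects: numeric
#'   matrices `N x K` with image-id rownames, neuron-id colnames and
#'   attributes `layer` and `dataset`.
#' @export
extract_responses <- function(backbone, stimuli, layers = NULL,
                              gains = gain_config()) {
  assert_that(inherits(stimuli, "stimulus_set"), "stimuli must be a stimulus_set")
  N <- nrow(stimuli$meta)
  assert_that(N >= 1L, "stimulus set is empty")
  nl <- n_conv_layers(backbone)
  if (is.null(layers)) layers <- seq_len(nl)
  layers <- as.integer(layers)
  assert_that(all(layers >= 1L & layers <= nl), "invalid layer index")
  gfac <- resolve_gains(backbone, gains)
  upto <- max(layers)
  mats <- lapply(layers, function(l) {
    matrix(0, N, backbone$layers[[l]]$K,
           dimnames = list(stimuli$meta$image_id,
                           neuron_ids(neurons(l, seq_len(backbone$layers[[l]]$K) - 1L))))
  })
  names(mats) <- sprintf("layer_%d", layers)
  S <- backbone$input_size
  for (n in seq_len(N)) {
    A <- prepare_input(backbone, stimuli$images[, , n])
    H <- S; W <- S
    for (l in seq_len(upto)) {
      layer <- backbone$layers[[l]]
      cl <- conv_linear(layer, A, H, W)
      A <- pmax(cl$Z, 0) * gfac[[l]]
      H <- cl$Ho; W <- cl$Wo
      j <- match(l, layers)
      if (!is.na(j)) mats[[j]][n, ] <- rowMeans(A)
      if (layer$pool) {
        p <- maxpool2(A, H, W)
        A <- p$A; H <- p$H; W <- p$W
      }
    }
  }
  dataset <- unique(as.character(stimuli$meta$dataset))
  for (j in seq_along(mats)) {
    attr(mats[[j]], "layer") <- layers[j]
    attr(mats[[j]], "dataset") <- if (length(dataset) == 1L) dataset else NA_character_
    class(mats[[j]]) <- c("response_matrix", class(mats[[j]]))
  }
  mats
}

#' Backbone feature vectors
#'
#' Flattened activations of the final (pooled) convolutional stage, the
#' representation the emotion readout head is trained on.
#'
#' @inheritParams extract_responses
#' @return numeric matrix `N x D` with image-id rownames.
#' @export
backbone_features <- function(backbone, stimuli, gains = gain_config()) {
  gfac <- resolve_gains(backbone, gains)
  imgs <- as_image_array(stimuli)
  N <- dim(imgs)[3L]
  out <- NULL
  for (n in seq_len(N)) {
    A0 <- prepare_input(backbone, imgs[, , n])
    fw <- nn_infer(backbone, A0, backbone$input_size, backbone$input_size,
                   gfac, keep_maps = FALSE)
    v <- as.vector(fw$out)
    if (is.null(out)) out <- matrix(0, N, length(v))
    out[n, ] <- v
  }
  if (inherits(stimuli, "stimulus_set")) rownames(out) <- stimuli$meta$image_id
  out
}

# cache activations entering layer `layer` (baseline gains upstream), so that
# gain sweeps confined to `layer` only recompute from there on
precompute_inputs <- function(backbone, stimuli, layer) {
  gfac <- resolve_gains(backbone, gain_config())
  imgs <- as_image_array(stimuli)
  N <- dim(imgs)[3L]
  acts <- vector("list", N)
  S <- backbone$input_size
  for (n in seq_len(N)) {
    A <- prepare_input(backbone, imgs[, , n])
    H <- S; W <- S
    if (layer > 1L) {
      for (l in seq_len(layer - 1L)) {
        ly <- backbone$layers[[l]]
        cl <- conv_linear(ly, A, H, W)
        A <- pmax(cl$Z, 0) * gfac[[l]]
        H <- cl$Ho; W <- cl$Wo
        if (ly$pool) {
          p <- maxpool2(A, H, W)
          A <- p$A; H <- p$H; W <- p$W
        }
      }
    }
    acts[[n]] <- A
  }
  list(acts = acts, H = H, W = W, layer = layer)
}

# resume a cached forward pass from `cache$layer` under new gains
features_from_cache <- function(backbone, cache, gains) {
  gfac <- resolve_gains(backbone, gains)
  N <- length(cache$acts)
  out <- NULL
  for (n in seq_len(N)) {
    fw <- nn_infer(backbone, cache$acts[[n]], cache$H, cache$W, gfac,
                   from = cache$layer, keep_maps = FALSE)
    v <- as.vector(fw$out)
    if (is.null(out)) out <- matrix(0, N, length(v))
    out[n, ] <- v
  }
  out
}
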