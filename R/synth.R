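# Seeded synthetic affective stimuli with known ground truth.
#
# Each emotion category is linked to one low-level texture statistic of
# controllable strength, superimposed on nuisance noise:
#   pleasant   - high-frequency checkerboard energy (period 2),
#   neutral    - horizontal orientation energy (period-4 grating along y),
#   unpleasant - vertical orientation energy (period-4 grating along x).
# Valence ratings are drawn from truncated normal distributions centered at
# 7 / 5 / 3 on the 1-9 scale, restricted to the category's band under the
# soft thresholds, so thresholding the rating reproduces the category.
# These statistics are deliberately plantable: matched 3x3 kernels exist, so
# a backbone with known "planted" selective neurons can be constructed and
# the whole selection/manipulation pipeline validated against ground truth.

#' Construct a stimulus set
#'
#' @param images 3-D array `H x W x N` of grayscale values in `[0, 1]`.
#' @param valence numeric vector of 1-9 valence ratings, length N.
#' @param category emotion category per image.
#' @param dataset dataset tag (single string).
#' @param image_id optional image identifiers (default generated from the
#'   dataset tag).
#' @return object of class `stimulus_set` with components `images` and `meta`
#'   (`image_id`, `valence`, `category`, `dataset`).
#' @export
stimulus_set <- function(images, valence, category, dataset = "synth",
                         image_id = NULL) {
  assert_that(is.array(images) && length(dim(images)) == 3L,
              "images must be a 3-D array H x W x N")
  N <- dim(images)[3L]
  assert_that(length(valence) == N && length(category) == N,
              "valence and category must align with images")
  assert_that(all(valence >= 1 & valence <= 9), "valence must lie in [1, 9]")
  if (is.null(image_id)) image_id <- sprintf("%s_%04d", dataset, seq_len(N))
  structure(list(images = images,
                 meta = data.frame(image_id = image_id, valence = valence,
                                   category = as.character(category),
                                   dataset = dataset)),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<stimulus_set> '%s': %d images %dx%d\n",
              unique(x$meta$dataset)[1L], d[3L], d[1L], d[2L]))
  print(table(x$meta$category))
  invisible(x)
}

#' Synthetic affective stimulus configuration
#'
#' @param size image side length in pixels.
#' @param images_per_category images generated for each emotion category.
#' @param effect_size separation of the category-linked texture statistic,
#'   in units of the nuisance-noise standard deviation (0 = no signal).
#' @param noise nuisance noise level (standard deviations of 0.06 grayscale
#'   units per pixel).
#' @param valence_centers named centers of the per-category valence
#'   distributions on the 1-9 scale.
#' @param valence_sd spread of the valence distributions.
#' @param thresholds low and high valence thresholds separating
#'   unpleasant/neutral and neutral/pleasant.
#' @param half_width soft-threshold half-width; ratings closer than this to a
#'   threshold are "unknown" and never generated.
#' @param dataset dataset tag.
#' @param seed RNG seed; identical configurations and seeds give identical
#'   sets.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(size = 32L, images_per_category = 60L,
                         effect_size = 3, noise = 1,
                         valence_centers = c(pleasant = 7, neutral = 5,
                                             unpleasant = 3),
                         valence_sd = 0.8, thresholds = c(4.3, 6.0),
                         half_width = 0, dataset = "synth", seed = 1L) {
  assert_that(images_per_category >= 1L, "need at least one image per category")
  assert_that(effect_size >= 0, "effect size must be >= 0")
  assert_that(thresholds[1L] < thresholds[2L], "thresholds must be increasing")
  assert_that(half_width >= 0 &&
                thresholds[1L] + half_width < thresholds[2L] - half_width,
              "soft bands must not overlap")
  structure(list(size = as.integer(size),
                 images_per_category = as.integer(images_per_category),
                 effect_size = effect_size, noise = noise,
                 valence_centers = valence_centers, valence_sd = valence_sd,
                 thresholds = thresholds, half_width = half_width,
                 dataset = dataset, seed = as.integer(seed)),
            class = "synth_config")
}

# grayscale amplitude of one noise / effect unit
AMP_UNIT <- 0.06

category_pattern <- function(category, size) {
  x <- matrix(rep(seq_len(size), each = size), size, size)  # column index
  y <- matrix(rep(seq_len(size), times = size), size, size) # row index
  switch(category,
    unpleasant = function() sqrt(2) * sin(2 * pi * (x + stats::runif(1, 0, 4)) / 4),
    neutral = function() sqrt(2) * sin(2 * pi * (y + stats::runif(1, 0, 4)) / 4),
    pleasant = function() (-1)^(x + y + sample(0:1, 1L)))
}

truncnorm_band <- function(n, center, sd, lo, hi) {
  plo <- stats::pnorm(lo, center, sd)
  phi <- stats::pnorm(hi, center, sd)
  stats::qnorm(stats::runif(n, plo, phi), center, sd)
}

valence_band <- function(category, thresholds, half_width) {
  low <- thresholds[1L]; high <- thresholds[2L]
  switch(category,
         unpleasant = c(1, low - half_width - 1e-9),
         neutral = c(low + half_width + 1e-9, high - half_width - 1e-9),
         pleasant = c(high + half_width + 1e-9, 9))
}

#' Generate a synthetic affective stimulus set
#'
#' @param config a [synth_config()].
#' @return a `stimulus_set` with `3 * images_per_category` images (ordered
#'   pleasant, neutral, unpleasant) whose category-linked texture statistics
#'   are separated by `effect_size` noise units.
#' @export
generate_affective_set <- function(config) {
  assert_that(inherits(config, "synth_config"), "config must be a synth_config")
  S <- config$size
  npc <- config$images_per_category
  N <- 3L * npc
  imgs <- array(0, dim = c(S, S, N))
  valence <- numeric(N)
  category <- character(N)
  with_seed(config$seed, {
    i <- 0L
    for (cat in EMOTIONS) {
      pat <- category_pattern(cat, S)
      band <- valence_band(cat, config$thresholds, config$half_width)
      for (j in seq_len(npc)) {
        i <- i + 1L
        amp <- config$effect_size * stats::runif(1, 0.8, 1.2) * AMP_UNIT
        img <- 0.5 + amp * pat() +
          config$noise * AMP_UNIT * matrix(stats::rnorm(S * S), S, S)
        imgs[, , i] <- pmin(pmax(img, 0), 1)
        valence[i] <- truncnorm_band(1L, config$valence_centers[[cat]],
                                     config$valence_sd, band[1L], band[2L])
        category[i] <- cat
      }
    }
  })
  stimulus_set(imgs, valence, category, dataset = config$dataset)
}

#' Categorize a valence rating under soft thresholds
#'
#' Ratings below the low threshold are unpleasant, above the high threshold
#' pleasant, otherwise neutral; with a positive soft half-width, ratings
#' within the half-width of either threshold are "unknown" (to be excluded
#' downstream). An exact-threshold rating with half-width 0 goes to the lower
#' band.
#'
#' @param rating numeric valence ratings in `[1, 9]`.
#' @param thresholds low/high thresholds, default `c(4.3, 6.0)`.
#' @param half_width soft-threshold half-width, default 0.
#' @return character vector in
#'   `{"pleasant", "neutral", "unpleasant", "unknown"}`.
#' @export
categorize_valence <- function(rating, thresholds = c(4.3, 6.0),
                               half_width = 0) {
  assert_that(all(rating >= 1 & rating <= 9), "ratings must lie in [1, 9]")
  low <- thresholds[1L]; high <- thresholds[2L]
  out <- ifelse(rating <= low, "unpleasant",
                ifelse(rating <= high, "neutral", "pleasant"))
  if (half_width > 0) {
    soft <- abs(rating - low) <= half_width | abs(rating - high) <= half_width
    out[soft] <- "unknown"
  }
  out
}

# matched 3x3 kernels for the three category statistics (unit Frobenius norm)
matched_kernels <- function() {
  k_unp <- matrix(rep(c(-1, 0, 1), each = 3L), 3L, 3L) / sqrt(6)
  k_neu <- t(k_unp)
  k_ple <- matrix(c(1, -1, 1, -1, 1, -1, 1, -1, 1), 3L, 3L) / 3
  list(pleasant = k_ple, neutral = k_neu, unpleasant = k_unp)
}

#' Build a backbone with planted emotion-selective neurons
#'
#' Starts from a random mini backbone and adds, to each planted filter of the
#' first convolutional layer, `strength` times the matched kernel of its
#' emotion's texture statistic (all other filters stay purely random;
#' `strength = 0` leaves the backbone indistinguishable from a random one).
#' When `strength > 0` the construction is verified empirically on a probe
#' stimulus set: every planted neuron must respond more, on average, to its
#' own category than to either other category.
#'
#' @param spec a `"mini-cnn"` [backbone_spec()] with 3x3 kernels.
#' @param planted named list (`pleasant`, `neutral`, `unpleasant`) of
#'   [neurons()] tables, all in layer 1 and mutually disjoint.
#' @param strength planting strength (kernel multiple added to the random
#'   weights).
#' @param probe_config [synth_config()] used for the empirical check
#'   (default: a small high-effect probe set derived from `spec$seed`).
#' @return a `cnn_backbone` whose `planted` component records the ground
#'   truth.
#' @export
plant_backbone <- function(spec, planted, strength = 3,
                           probe_config = NULL) {
  assert_that(spec$architecture == "mini-cnn", "planting requires the mini backbone")
  assert_that(spec$kernel == 3L, "matched kernels are 3x3")
  assert_that(all(names(planted) %in% EMOTIONS), "planted sets are per emotion")
  all_planted <- do.call(rbind, planted[lengths(planted) > 0])
  if (!is.null(all_planted) && nrow(all_planted)) {
    assert_that(all(all_planted$layer == 1L),
                "planting is supported in the first convolutional layer only")
    assert_that(!anyDuplicated(all_planted$filter),
                "planted sets must be disjoint across emotions")
    assert_that(all(all_planted$filter < spec$filters[1L]),
                "planted set too large for the layer")
  }
  bb <- build_backbone(spec)
  kern <- matched_kernels()
  for (e in names(planted)) {
    tg <- planted[[e]]
    if (is.null(tg) || nrow(tg) == 0L) next
    for (f in tg$filter) {
      bb$layers[[1L]]$W[f + 1L, ] <- bb$layers[[1L]]$W[f + 1L, ] +
        strength * as.vector(kern[[e]])
    }
  }
  bb$planted <- lapply(planted, function(tg) tg)
  if (strength > 0 && !is.null(all_planted) && nrow(all_planted)) {
    if (is.null(probe_config)) {
      probe_config <- synth_config(size = spec$input_size,
                                   images_per_category = 12L,
                                   seed = spec$seed + 90001L)
    }
    probe <- generate_affective_set(probe_config)
    resp <- extract_responses(bb, probe, layers = 1L)[[1L]]
    for (e in names(planted)) {
      tg <- planted[[e]]
      if (is.null(tg) || nrow(tg) == 0L) next
      for (f in tg$filter) {
        col <- resp[, neuron_ids(neurons(1L, f))]
        own <- mean(col[probe$meta$category == e])
        oth <- vapply(setdiff(EMOTIONS, e), function(o)
          mean(col[probe$meta$category == o]), 1.0)
        assert_that(all(own > oth),
                    sprintf("planted %s filter %d fails the response check", e, f))
      }
    }
  }
  bb
}

#' Generate a toy object-recognition task
#'
#' Desk-scale stand-in for large-scale object pre-training: classes are
#' distinct composite textured shapes (discs carrying a vertical grating, a
#' horizontal grating, a checkerboard texture, or plain bright/dark fill) at
#' random positions and sizes over a noisy background. A mini backbone
#' trained on this task is the "trained" condition for the
#' trained-versus-random contrast.
#'
#' @param n_classes number of object classes (2 to 5).
#' @param images_per_class images per class.
#' @param size image side length in pixels.
#' @param seed RNG seed.
#' @return list with `images` (`size x size x N` array), `labels` (factor)
#'   and `classes`.
#' @export
generate_object_task <- function(n_classes = 4L, images_per_class = 60L,
                                 size = 32L, seed = 1L) {
  assert_that(n_classes >= 2L && n_classes <= 5L, "n_classes must be in 2..5")
  assert_that(images_per_class >= 1L && size >= 16L, "degenerate sizes")
  N <- n_classes * images_per_class
  imgs <- array(0, dim = c(size, size, N))
  classes <- c("v_grating_disc", "h_grating_disc", "checker_disc",
               "bright_disc", "dark_disc")[seq_len(n_classes)]
  labels <- rep(classes, each = images_per_class)
  x <- matrix(rep(seq_len(size), each = size), size, size)
  y <- matrix(rep(seq_len(size), times = size), size, size)
  with_seed(seed, {
    for (i in seq_len(N)) {
      cx <- stats::runif(1, size * 0.3, size * 0.7)
      cy <- stats::runif(1, size * 0.3, size * 0.7)
      r <- stats::runif(1, size * 0.2, size * 0.35)
      mask <- (x - cx)^2 + (y - cy)^2 <= r^2
      tex <- switch(labels[i],
        v_grating_disc = 0.35 * sin(2 * pi * (x + stats::runif(1, 0, 4)) / 4),
        h_grating_disc = 0.35 * sin(2 * pi * (y + stats::runif(1, 0, 4)) / 4),
        checker_disc = 0.25 * (-1)^(x + y + sample(0:1, 1L)),
        bright_disc = matrix(0.3, size, size),
        dark_disc = matrix(-0.3, size, size))
      img <- 0.5 + 0.05 * matrix(stats::rnorm(size^2), size, size)
      img[mask] <- img[mask] + tex[mask]
      imgs[, , i] <- pmin(pmax(img, 0), 1)
    }
  })
  list(images = imgs, labels = factor(labels, levels = classes),
       classes = classes)
}

#' Load a shipped fixture configuration
#'
#' Versioned YAML configurations for the synthetic experiments (planted
#' high-effect recovery, null calibration, toy object task).
#'
#' @param name fixture name, e.g. `"planted-high-effect"`.
#' @return the parsed configuration list.
#' @export
fixture_config <- function(name) {
  path <- system.file("extdata", "fixtures", paste0(name, ".yaml"),
                      package = "emoselect")
  assert_that(nzchar(path), sprintf("unknown fixture '%s'", name))
  yaml::read_yaml(path)
}
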