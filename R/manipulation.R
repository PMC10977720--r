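# Functional validation of emotion-selective neurons: gain-enhancement
# sweeps (alpha from 0 to 5 in steps of 0.1, best alpha chosen on the
# validation split) and lesions (alpha = -1), each compared against
# same-size random-neuron controls run through the identical protocol.

#' Signed percent performance change
#'
#' `100 * (manipulated - original) / original`.
#'
#' @param original,manipulated F1 scores; `original` must be positive.
#' @return signed percent change.
#' @export
percent_change <- function(original, manipulated) {
  assert_that(all(original > 0), "original performance must be > 0")
  100 * (manipulated - original) / original
}

#' The reference enhancement grid: alpha from 0 to 5 in steps of 0.1
#' @return numeric vector of 51 values.
#' @export
alpha_grid <- function() seq(0, 5, by = 0.1)

manipulation_targets_ok <- function(targets) {
  assert_that(is.data.frame(targets) && nrow(targets) >= 1L,
              "empty target set")
  assert_that(length(unique(targets$layer)) == 1L,
              "one layer is manipulated at a time")
  unique(targets$layer)
}

# Shared protocol core: evaluate the readout at each alpha of `grid` applied
# to `targets`, on the validation and test sets, reusing activation caches
# below the manipulated layer. This single code path serves both the
# selective sets and the random controls.
fast_f1 <- function(backbone, model, cache, stimuli_labels, gains) {
  feats <- features_from_cache(backbone, cache, gains)
  f1_score(readout_predict(model, feats), stimuli_labels, positive = 1L)
}

gain_sweep_eval <- function(backbone, model, targets, grid, cache_val,
                            cache_test, yval, ytest) {
  vapply(grid, function(a) {
    g <- gain_config(targets, alpha = a)
    c(val = fast_f1(backbone, model, cache_val, yval, g),
      test = fast_f1(backbone, model, cache_test, ytest, g))
  }, c(val = 0, test = 0))
}

#' Gain-enhancement sweep over a neuron set
#'
#' Applies each alpha of the grid to the target neurons, picks the alpha
#' maximizing validation F1 (ties resolved toward the smallest alpha), and
#' reports the test F1 at that alpha together with the full curves. A grid
#' containing 0 anchors the sweep at the unmanipulated baseline.
#'
#' @param backbone a `cnn_backbone`.
#' @param model a trained `readout_model`.
#' @param targets a [neurons()] table, all in one layer.
#' @param grid alpha values (default [alpha_grid()], 0 to 5 by 0.1).
#' @param val,test `stimulus_set`s.
#' @return list with `best_alpha`, `val_f1`, `test_f1`, `baseline_test_f1`
#'   (test F1 at alpha 0) and `curve` (data frame alpha/val_f1/test_f1).
#' @export
enhancement_sweep <- function(backbone, model, targets, grid = alpha_grid(),
                              val, test) {
  assert_that(length(grid) >= 1L, "empty alpha grid")
  layer <- manipulation_targets_ok(targets)
  assert_that(identical(model$backbone_checksum, weights_checksum(backbone)),
              "backbone does not match the one the readout was trained on")
  cache_val <- precompute_inputs(backbone, val, layer)
  cache_test <- precompute_inputs(backbone, test, layer)
  yval <- binary_labels(val$meta, model$task)
  ytest <- binary_labels(test$meta, model$task)
  sw <- gain_sweep_eval(backbone, model, targets, grid, cache_val, cache_test,
                        yval, ytest)
  best <- which.max(sw["val", ])
  baseline <- if (any(grid == 0)) sw["test", which(grid == 0)[1L]] else NA_real_
  list(best_alpha = unname(grid[best]), val_f1 = unname(sw["val", best]),
       test_f1 = unname(sw["test", best]), baseline_test_f1 = unname(baseline),
       curve = data.frame(alpha = grid, val_f1 = sw["val", ],
                          test_f1 = sw["test", ]))
}

#' Lesion a neuron set and evaluate
#'
#' Equivalent to [evaluate_readout()] under a gain configuration with
#' alpha = -1 on the targets (outputs forced to zero) and 0 elsewhere.
#'
#' @inheritParams enhancement_sweep
#' @return test F1 with the targets lesioned.
#' @export
lesion_run <- function(backbone, model, targets, test) {
  manipulation_targets_ok(targets)
  evaluate_readout(backbone, model, lesion_gains(targets), test)
}

#' Random-neuron control manipulations
#'
#' Draws `R` same-size neuron sets uniformly from the layer's neurons
#' excluding the selective targets, applies the identical protocol (the full
#' alpha sweep for `"enhance"`, alpha = -1 for `"lesion"`), and returns the R
#' percent performance changes. Fully seeded.
#'
#' @param backbone a `cnn_backbone`.
#' @param model a trained `readout_model`.
#' @param layer 1-based convolutional layer index to draw from.
#' @param size control set size (must not exceed the available non-target
#'   neurons).
#' @param mode `"enhance"` or `"lesion"`.
#' @param R number of control repetitions.
#' @param seed RNG seed for the draws.
#' @param val,test evaluation sets (the validation set is used to choose
#'   alpha in enhance mode, mirroring the selective protocol).
#' @param exclude [neurons()] table of neurons (the selective set) excluded
#'   from the control pool.
#' @param grid alpha grid for enhance mode.
#' @return list with `pct_changes` (length R), `original_f1`, and the drawn
#'   control sets.
#' @export
random_control <- function(backbone, model, layer, size,
                           mode = c("enhance", "lesion"), R = 20L, seed = 1L,
                           val = NULL, test, exclude = NULL,
                           grid = alpha_grid()) {
  mode <- match.arg(mode)
  assert_that(R >= 1L, "R must be >= 1")
  K <- backbone$layers[[layer]]$K
  pool <- seq_len(K) - 1L
  if (!is.null(exclude) && nrow(exclude)) {
    pool <- setdiff(pool, exclude$filter[exclude$layer == layer])
  }
  assert_that(size <= length(pool),
              "control set size exceeds available neurons in the layer")
  draws <- with_seed(seed, {
    lapply(seq_len(R), function(r) sort(sample(pool, size)))
  })
  assert_that(identical(model$backbone_checksum, weights_checksum(backbone)),
              "backbone does not match the one the readout was trained on")
  cache_test <- precompute_inputs(backbone, test, layer)
  ytest <- binary_labels(test$meta, model$task)
  baseline <- fast_f1(backbone, model, cache_test, ytest, gain_config())
  cache_val <- if (mode == "enhance") precompute_inputs(backbone, val, layer) else NULL
  yval <- if (mode == "enhance") binary_labels(val$meta, model$task) else NULL
  pct <- vapply(draws, function(f) {
    tg <- neurons(layer, f)
    manip <- if (mode == "enhance") {
      sw <- gain_sweep_eval(backbone, model, tg, grid, cache_val, cache_test,
                            yval, ytest)
      sw["test", which.max(sw["val", ])]
    } else {
      fast_f1(backbone, model, cache_test, ytest, lesion_gains(tg))
    }
    percent_change(baseline, manip)
  }, 1.0)
  list(pct_changes = pct, original_f1 = baseline, controls = draws)
}

#' Empirical comparison of a selective-set effect against controls
#'
#' One-sided permutation p-value: in enhance mode the fraction of controls
#' whose change is at least the selective change, in lesion mode at most.
#' `p = (1 + #{extreme controls}) / (R + 1)`.
#'
#' @param selective_change percent change of the selective manipulation.
#' @param control_changes vector of R control percent changes (R >= 5).
#' @param mode `"enhance"` or `"lesion"`.
#' @return empirical p-value.
#' @export
compare_selective_vs_random <- function(selective_change, control_changes,
                                        mode = c("enhance", "lesion")) {
  mode <- match.arg(mode)
  R <- length(control_changes)
  assert_that(R >= 5L, "need at least 5 control values")
  extreme <- if (mode == "enhance") {
    sum(control_changes >= selective_change)
  } else {
    sum(control_changes <= selective_change)
  }
  (1 + extreme) / (R + 1)
}

#' Run the full manipulation protocol for one emotion and layer
#'
#' Enhancement sweep and lesion of the given selective set with matched
#' random controls, summarized in a tidy one-row-per-mode data frame.
#'
#' @param backbone,model as above.
#' @param targets selective [neurons()] set (single layer).
#' @param val,test evaluation sets.
#' @param dataset,emotion descriptive tags for the output rows.
#' @param R control repetitions.
#' @param seed seed for control draws.
#' @param grid alpha grid for the enhancement sweep.
#' @return data frame with columns `dataset`, `emotion`, `layer`, `mode`,
#'   `original_f1`, `manipulated_f1`, `pct_change`, `alpha`, `p_value`.
#' @export
run_manipulations <- function(backbone, model, targets, val, test,
                              dataset = NA_character_,
                              emotion = NA_character_, R = 20L, seed = 1L,
                              grid = alpha_grid()) {
  layer <- manipulation_targets_ok(targets)
  enh <- enhancement_sweep(backbone, model, targets, grid, val, test)
  baseline <- enh$baseline_test_f1
  if (is.na(baseline)) {
    baseline <- evaluate_readout(backbone, model, gain_config(), test)
  }
  les_f1 <- lesion_run(backbone, model, targets, test)
  ctrl_enh <- random_control(backbone, model, layer, nrow(targets),
                             mode = "enhance", R = R, seed = seed,
                             val = val, test = test, exclude = targets,
                             grid = grid)
  ctrl_les <- random_control(backbone, model, layer, nrow(targets),
                             mode = "lesion", R = R, seed = seed + 1L,
                             test = test, exclude = targets)
  enh_pct <- percent_change(baseline, enh$test_f1)
  les_pct <- percent_change(baseline, les_f1)
  out <- data.frame(
    dataset = dataset, emotion = emotion, layer = layer,
    mode = c("enhance", "lesion"),
    original_f1 = baseline,
    manipulated_f1 = c(enh$test_f1, les_f1),
    pct_change = c(enh_pct, les_pct),
    alpha = c(enh$best_alpha, -1),
    p_value = c(compare_selective_vs_random(enh_pct, ctrl_enh$pct_changes,
                                            "enhance"),
                compare_selective_vs_random(les_pct, ctrl_les$pct_changes,
                                            "lesion")))
  attr(out, "controls") <- list(enhance = ctrl_enh$pct_changes,
                                lesion = ctrl_les$pct_changes)
  out
}

#' Summarize manipulation results in reference-table form
#'
#' For each dataset, emotion and mode, reports the layer-wise extremum of the
#' percent change (maximum for enhancement, minimum for lesion) and the layer
#' at which it is attained. Export convention: enhancement percentages
#' rounded to 2 decimals, lesion percentages to integers.
#'
#' @param results data frame(s) as returned by [run_manipulations()]
#'   (rows may cover several layers).
#' @return data frame with columns `dataset`, `emotion`, `mode`,
#'   `pct_change`, `layer`, `pct_change_rounded`.
#' @export
summarize_manipulations <- function(results) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- do.call(rbind, results)
  }
  assert_that(is.data.frame(results) && nrow(results) >= 1L, "empty results")
  keys <- unique(results[, c("dataset", "emotion", "mode")])
  do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- merge(results, keys[i, , drop = FALSE])
    j <- if (keys$mode[i] == "enhance") which.max(sub$pct_change) else
      which.min(sub$pct_change)
    pc <- sub$pct_change[j]
    data.frame(dataset = keys$dataset[i], emotion = keys$emotion[i],
               mode = keys$mode[i], pct_change = pc, layer = sub$layer[j],
               pct_change_rounded = if (keys$mode[i] == "enhance")
                 round(pc, 2) else round(pc))
  }))
}

#' Write tidy manipulation results to CSV
#'
#' @param results data frame from [run_manipulations()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_manipulation_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
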