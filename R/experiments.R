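# Packaged experiment protocols over the shipped fixture configurations.
# These drive the full pipeline (synthetic data -> backbone -> selectivity ->
# selection -> readout -> manipulation) so that validation runs and reports
# execute one shared, seeded code path.

fixture_stimulus_config <- function(fx, tag, seed, effect = NULL) {
  st <- fx$stimulus
  synth_config(size = st$size, images_per_category = st$images_per_category,
               effect_size = if (is.null(effect)) st$effect_size else effect,
               noise = st$noise, dataset = tag, seed = seed)
}

fixture_backbone_spec <- function(fx, seed) {
  backbone_spec("mini-cnn", filters = unlist(fx$backbone$filters),
                input_size = fx$backbone$input_size, seed = seed)
}

fixture_planted <- function(fx) {
  lapply(stats::setNames(EMOTIONS, EMOTIONS), function(e)
    neurons(fx$planted$layer, unlist(fx$planted[[e]])))
}

#' Planted-neuron recovery experiment
#'
#' Runs the complete pipeline on the high-effect-size planted fixture: builds
#' a mini backbone with planted selective neurons, generates two independent
#' affective stimulus sets, identifies genuine emotion-selective neurons by
#' SI thresholding plus cross-dataset overlap, scores recovery of the planted
#' ground truth, and runs the enhancement/lesion manipulation protocol (with
#' random controls) on the recovered set of the probe emotion.
#'
#' @param seed base seed; all dataset, training and control seeds derive from
#'   it.
#' @param fixture fixture name (default `"planted-high-effect"`).
#' @param emotion the emotion probed with the readout manipulations.
#' @return list with `precision`, `recall`, `selection`, `manipulation`
#'   (data frame from [run_manipulations()]), `controls`, `baseline_f1`.
#' @export
recovery_experiment <- function(seed = 1L, fixture = "planted-high-effect",
                                emotion = "pleasant") {
  fx <- fixture_config(fixture)
  spec <- fixture_backbone_spec(fx, seed)
  planted <- fixture_planted(fx)
  bb <- plant_backbone(spec, planted, strength = fx$planted$strength)
  setA <- generate_affective_set(fixture_stimulus_config(fx, "synthA", seed + 10L))
  setB <- generate_affective_set(fixture_stimulus_config(fx, "synthB", seed + 20L))
  recA <- selectivity_records(bb, setA, layers = fx$planted$layer)[[1L]]
  recB <- selectivity_records(bb, setB, layers = fx$planted$layer)[[1L]]
  sel <- overlap_selection(recA, recB, fx$selection$keep_fraction)
  truth <- unlist(lapply(EMOTIONS, function(e)
    paste0(e, ":", planted[[e]]$filter)))
  found <- unlist(lapply(EMOTIONS, function(e)
    paste0(e, ":", sel$emotions[[e]]$genuine$filter)))
  precision <- if (length(found)) length(intersect(found, truth)) / length(found) else NA_real_
  recall <- length(intersect(found, truth)) / length(truth)
  splits <- split_dataset(setA, train_config(seed = seed))
  model <- train_readout(bb, readout_task(emotion), splits$train, splits$val,
                         train_config(seed = seed))
  manip <- run_manipulations(bb, model, sel$emotions[[emotion]]$genuine,
                             splits$val, splits$test, dataset = "synthA",
                             emotion = emotion, R = fx$controls$R,
                             seed = seed + 100L)
  list(precision = precision, recall = recall, selection = sel,
       manipulation = manip, controls = attr(manip, "controls"),
       baseline_f1 = manip$original_f1[1L], model = model, backbone = bb,
       splits = splits)
}

#' Null-calibration experiment
#'
#' At effect size 0 (no category-linked image structure) the pipeline's
#' genuine-set sizes should match the chance-overlap expectation and
#' manipulation effects should center at zero. Selection uses two stimulus
#' sets; the readout is trained and evaluated on a third, independent set so
#' that chance-selective neurons share no noise with the evaluation images.
#' Seeds with an entirely empty genuine selection contribute a zero percent
#' change (nothing to manipulate leaves performance at baseline).
#'
#' @param seeds integer vector of per-replicate seeds.
#' @param fixture fixture name (default `"null-effect"`).
#' @return data frame with one row per seed (`overlap_dev` = mean observed
#'   minus chance overlap across emotions, `lesion_pct`, `enhance_pct`) and a
#'   `summary` attribute of means and standard errors.
#' @export
null_calibration <- function(seeds = 1:10, fixture = "null-effect") {
  fx <- fixture_config(fixture)
  rows <- lapply(seeds, function(seed) {
    bb <- build_backbone(fixture_backbone_spec(fx, seed))
    A <- generate_affective_set(fixture_stimulus_config(fx, "nullA", seed + 11L))
    B <- generate_affective_set(fixture_stimulus_config(fx, "nullB", seed + 22L))
    C <- generate_affective_set(fixture_stimulus_config(fx, "nullC", seed + 33L))
    recA <- selectivity_records(bb, A, layers = 1L)[[1L]]
    recB <- selectivity_records(bb, B, layers = 1L)[[1L]]
    sel <- overlap_selection(recA, recB, fx$selection$keep_fraction)
    dev <- vapply(sel$emotions, function(e)
      e$observed_overlap - e$chance_expected_overlap, 1.0)
    sizes <- vapply(sel$emotions, function(e) nrow(e$genuine), 1L)
    if (max(sizes) == 0L) {
      return(data.frame(seed = seed, overlap_dev = mean(dev), baseline_f1 = NA,
                        lesion_pct = 0, enhance_pct = 0))
    }
    emo <- names(sizes)[which.max(sizes)]
    splits <- split_dataset(C, train_config(seed = seed))
    model <- train_readout(bb, readout_task(emo), splits$train, splits$val,
                           train_config(seed = seed))
    tgt <- sel$emotions[[emo]]$genuine
    base <- evaluate_readout(bb, model, gain_config(), splits$test)
    les <- lesion_run(bb, model, tgt, splits$test)
    enh <- enhancement_sweep(bb, model, tgt, alpha_grid(), splits$val,
                             splits$test)
    data.frame(seed = seed, overlap_dev = mean(dev), baseline_f1 = base,
               lesion_pct = percent_change(base, les),
               enhance_pct = percent_change(base, enh$test_f1))
  })
  out <- do.call(rbind, rows)
  n <- nrow(out)
  attr(out, "summary") <- data.frame(
    metric = c("overlap_dev", "lesion_pct", "enhance_pct"),
    mean = c(mean(out$overlap_dev), mean(out$lesion_pct), mean(out$enhance_pct)),
    se = c(stats::sd(out$overlap_dev), stats::sd(out$lesion_pct),
           stats::sd(out$enhance_pct)) / sqrt(n))
  out
}

#' Trained-versus-random contrast experiment
#'
#' For each seed: trains a mini backbone on the toy object-recognition task,
#' then counts genuine emotion-selective neurons (summed over emotions) in
#' the deepest convolutional layer for the trained network and for the
#' untrained random-weight network, using two independent affective stimulus
#' sets whose category signal is weak relative to the nuisance noise.
#'
#' @param seeds integer vector of per-replicate seeds.
#' @param fixture fixture name (default `"object-task"`).
#' @return data frame with columns `seed`, `object_accuracy` (training-set
#'   accuracy of the object classifier), `overlap_trained`, `overlap_random`.
#' @export
trained_vs_random_experiment <- function(seeds = 1:5, fixture = "object-task") {
  fx <- fixture_config(fixture)
  rows <- lapply(seeds, function(seed) {
    ob <- generate_object_task(fx$object$n_classes, fx$object$images_per_class,
                               fx$object$size, seed = seed)
    spec <- backbone_spec("mini-cnn", filters = c(16L, 16L, 32L),
                          input_size = fx$object$size, seed = seed)
    rand <- build_backbone(spec)
    trained <- train_backbone(rand, ob$images, ob$labels,
                              epochs = fx$object$epochs, lr = fx$object$lr,
                              batch_size = fx$object$batch_size, seed = seed)
    acc <- mean(predict_backbone(trained, ob$images) == as.character(ob$labels))
    mk <- function(tag, s) generate_affective_set(synth_config(
      size = fx$affective$size,
      images_per_category = fx$affective$images_per_category,
      effect_size = fx$affective$effect_size, noise = fx$affective$noise,
      dataset = tag, seed = s))
    A <- mk("tvrA", seed + 101L)
    B <- mk("tvrB", seed + 202L)
    nlayers <- length(spec$filters)
    count_genuine <- function(bb) {
      rA <- selectivity_records(bb, A, layers = nlayers)[[1L]]
      rB <- selectivity_records(bb, B, layers = nlayers)[[1L]]
      s <- overlap_selection(rA, rB, fx$selection$keep_fraction)
      sum(vapply(s$emotions, function(e) e$observed_overlap, 1L))
    }
    data.frame(seed = seed, object_accuracy = acc,
               overlap_trained = count_genuine(trained),
               overlap_random = count_genuine(rand))
  })
  do.call(rbind, rows)
}
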