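test_that("percent change reproduces the derived reference cells", {
  expect_equal(percent_change(0.70, 0.73), 4.29, tolerance = 1e-3)
  expect_equal(percent_change(0.70, 0.56), -20, tolerance = 1e-12)
  expect_equal(percent_change(0.5, 0.5), 0)
  expect_error(percent_change(0, 0.5), "> 0")
})

test_that("the reference alpha grid spans 0 to 5 in 51 steps", {
  g <- alpha_grid()
  expect_equal(length(g), 51L)
  expect_equal(g[1], 0)
  expect_equal(g[51], 5)
  expect_equal(diff(g)[1], 0.1, tolerance = 1e-12)
})

test_that("empirical permutation p-values follow the counting formula", {
  expect_equal(compare_selective_vs_random(10, rep(1, 19), "enhance"), 1 / 20)
  expect_equal(compare_selective_vs_random(-50, rep(-1, 19), "lesion"), 1 / 20)
  ctrl <- seq(-10, 10, length.out = 21)
  p_mid <- compare_selective_vs_random(0, ctrl, "enhance")
  expect_true(abs(p_mid - 0.5) < 0.06)
  expect_error(compare_selective_vs_random(1, c(1, 2, 3), "enhance"),
               "at least 5")
})

test_that("summaries report the layer-wise extremum per dataset/emotion/mode", {
  res <- data.frame(
    dataset = "iaps",
    emotion = rep(c("pleasant", "neutral", "unpleasant"), each = 2),
    layer = rep(1:2, 3),
    mode = "enhance",
    original_f1 = c(0.70, 0.70, 0.63, 0.63, 0.62, 0.62),
    manipulated_f1 = c(0.73, 0.71, 0.69, 0.64, 0.69, 0.63),
    pct_change = c(percent_change(0.70, 0.73), percent_change(0.70, 0.71),
                   percent_change(0.63, 0.69), percent_change(0.63, 0.64),
                   percent_change(0.62, 0.69), percent_change(0.62, 0.63)),
    alpha = 1, p_value = 0.05)
  sm <- summarize_manipulations(res)
  expect_equal(sm$pct_change_rounded[sm$emotion == "pleasant"], 4.29)
  expect_equal(sm$pct_change_rounded[sm$emotion == "neutral"], 9.52)
  expect_equal(sm$pct_change_rounded[sm$emotion == "unpleasant"], 11.29)
  expect_equal(sm$layer, rep(1L, 3))
  single <- summarize_manipulations(res[1, ])
  expect_equal(single$pct_change, res$pct_change[1])
  # lesion mode takes the minimum (largest drop) and rounds to integers
  les <- res[1:2, ]
  les$mode <- "lesion"
  les$manipulated_f1 <- c(0.56, 0.60)
  les$pct_change <- percent_change(0.70, les$manipulated_f1)
  sml <- summarize_manipulations(les)
  expect_equal(sml$pct_change_rounded, -20)
})

test_that("enhancement sweep anchors at baseline and optimizes on validation", {
  bb <- tiny_backbone(filters = c(4L, 4L), size = 8L)
  st <- tiny_set(n = 8L, size = 8L, effect = 2)
  sp <- split_dataset(st, train_config(seed = 2L))
  mod <- train_readout(bb, readout_task("pleasant"), sp$train, sp$val,
                       train_config(seed = 2L))
  base <- evaluate_readout(bb, mod, gain_config(), sp$test)
  one <- enhancement_sweep(bb, mod, neurons(1L, 0:1), grid = 0,
                           val = sp$val, test = sp$test)
  expect_equal(one$best_alpha, 0)
  expect_equal(one$test_f1, base)
  sw <- enhancement_sweep(bb, mod, neurons(1L, 0:1),
                          grid = seq(0, 2, by = 0.5),
                          val = sp$val, test = sp$test)
  expect_equal(nrow(sw$curve), 5L)
  expect_gte(sw$val_f1, sw$curve$val_f1[1]) # alpha = 0 is in the feasible set
  expect_equal(sw$curve$test_f1[1], base)
  expect_error(enhancement_sweep(bb, mod, neurons(1L, integer(0)),
                                 val = sp$val, test = sp$test),
               "empty target")
})

test_that("lesion_run equals evaluation under alpha = -1 gains", {
  bb <- tiny_backbone(filters = c(4L, 4L), size = 8L)
  st <- tiny_set(n = 8L, size = 8L)
  sp <- split_dataset(st, train_config(seed = 3L))
  mod <- train_readout(bb, readout_task("unpleasant"), sp$train, sp$val,
                       train_config(seed = 3L))
  tg <- neurons(1L, c(0L, 2L))
  expect_identical(lesion_run(bb, mod, tg, sp$test),
                   evaluate_readout(bb, mod, lesion_gains(tg), sp$test))
  # lesioning every filter in layer 1 collapses predictions to one class
  f1_all <- lesion_run(bb, mod, neurons(1L, 0:3), sp$test)
  feats <- backbone_features(bb, sp$test, lesion_gains(neurons(1L, 0:3)))
  expect_true(all(feats == 0))
})

test_that("random controls are seeded, exclusive and size-checked", {
  bb <- tiny_backbone(filters = c(6L, 4L), size = 8L)
  st <- tiny_set(n = 8L, size = 8L)
  sp <- split_dataset(st, train_config(seed = 5L))
  mod <- train_readout(bb, readout_task("pleasant"), sp$train, sp$val,
                       train_config(seed = 5L))
  excl <- neurons(1L, 0:1)
  c1 <- random_control(bb, mod, layer = 1L, size = 2L, mode = "lesion",
                       R = 3L, seed = 7L, test = sp$test, exclude = excl)
  c2 <- random_control(bb, mod, layer = 1L, size = 2L, mode = "lesion",
                       R = 3L, seed = 7L, test = sp$test, exclude = excl)
  expect_identical(c1$controls, c2$controls)
  expect_identical(c1$pct_changes, c2$pct_changes)
  c3 <- random_control(bb, mod, layer = 1L, size = 2L, mode = "lesion",
                       R = 3L, seed = 8L, test = sp$test, exclude = excl)
  expect_false(identical(c1$controls, c3$controls))
  for (dr in c1$controls) expect_false(any(dr %in% excl$filter))
  expect_error(random_control(bb, mod, layer = 1L, size = 5L, mode = "lesion",
                              R = 2L, seed = 1L, test = sp$test,
                              exclude = excl),
               "exceeds")
})
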