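test_that("backbone construction is seeded, layered and validated", {
  spec <- backbone_spec("mini-cnn", seed = 7L)
  b1 <- build_backbone(spec)
  b2 <- build_backbone(spec)
  expect_identical(b1$layers, b2$layers)

  vgg <- build_backbone(backbone_spec("vgg16-layout", seed = 1L))
  expect_equal(length(vgg$layers), 13L)
  expect_equal(vapply(vgg$layers, function(l) l$K, 1L),
               c(64L, 64L, 128L, 128L, 256L, 256L, 256L,
                 512L, 512L, 512L, 512L, 512L, 512L))

  expect_error(backbone_spec("alexnet"), "arg")
  expect_error(backbone_spec("mini-cnn", filters = integer(0)), "at least 2")
  expect_error(backbone_spec("mini-cnn", filters = 8L), "at least 2")
})

test_that("convolution matches a naive spatial-convolution oracle", {
  bb <- tiny_backbone()
  set.seed(42)
  img <- matrix(runif(64), 8, 8)
  A0 <- emoselect:::prepare_input(bb, img)
  cl <- emoselect:::conv_linear(bb$layers[[1]], A0, 8L, 8L)
  for (k in 1:4) {
    expect_equal(cl$Z[k, ],
                 oracle_conv(bb$layers[[1]]$W[k, ], A0, 1L, 8L, 8L, 3L, 3L, 1L) +
                   bb$layers[[1]]$b[k],
                 tolerance = 1e-12)
  }
  A1 <- pmax(cl$Z, 0)
  p <- emoselect:::maxpool2(A1, 8L, 8L)
  cl2 <- emoselect:::conv_linear(bb$layers[[2]], p$A, 4L, 4L)
  for (k in 1:6) {
    expect_equal(cl2$Z[k, ],
                 oracle_conv(bb$layers[[2]]$W[k, ], p$A, 4L, 4L, 4L, 3L, 3L, 1L) +
                   bb$layers[[2]]$b[k],
                 tolerance = 1e-12)
  }
})

test_that("baseline gains reproduce the plain forward pass bitwise", {
  bb <- tiny_backbone()
  st <- tiny_set()
  r0 <- extract_responses(bb, st)
  rz <- extract_responses(bb, st, gains = gain_config(default = 0))
  expect_identical(unclass(r0$layer_1), unclass(rz$layer_1))
  expect_identical(unclass(r0$layer_2), unclass(rz$layer_2))
  f0 <- backbone_features(bb, st)
  fz <- backbone_features(bb, st, gains = gain_config())
  expect_identical(f0, fz)
})

test_that("lesioning a neuron zeroes its map and removes its downstream trace", {
  bb <- tiny_backbone()
  st <- tiny_set()
  les <- lesion_gains(neurons(1L, 2L))
  r <- extract_responses(bb, st, gains = les)
  expect_true(all(r$layer_1[, "L1.K2"] == 0))
  # downstream responses must be invariant to the lesioned filter's weights
  bb2 <- bb
  bb2$layers[[1]]$W[3, ] <- rnorm(9, sd = 10)
  bb2$layers[[1]]$b[3] <- 5
  r2 <- extract_responses(bb2, st, gains = les)
  expect_equal(unclass(r$layer_2), unclass(r2$layer_2), tolerance = 1e-15)
  expect_identical(backbone_features(bb, st, les), backbone_features(bb2, st, les))
})

test_that("gain scales a neuron's response column by (1 + alpha)", {
  bb <- tiny_backbone()
  st <- tiny_set()
  r0 <- extract_responses(bb, st, layers = 1L)[[1]]
  for (a in c(0.5, 1, 4)) {
    ra <- extract_responses(bb, st, layers = 1L,
                            gains = gain_config(neurons(1L, 1L), alpha = a))[[1]]
    expect_equal(ra[, "L1.K1"], (1 + a) * r0[, "L1.K1"], tolerance = 1e-12)
    expect_equal(ra[, "L1.K0"], r0[, "L1.K0"], tolerance = 0) # untouched column
  }
})

test_that("gain configuration is validated", {
  bb <- tiny_backbone()
  st <- tiny_set()
  expect_error(gain_config(neurons(1L, 0L), alpha = -1.5), ">= -1")
  expect_error(extract_responses(bb, st, gains = gain_config(neurons(9L, 0L), alpha = 1)),
               "nonexistent layer")
  expect_error(extract_responses(bb, st, gains = gain_config(neurons(1L, 99L), alpha = 1)),
               "nonexistent filter")
})

test_that("mean_filter_response is the spatial mean", {
  expect_equal(mean_filter_response(matrix(c(1, 0, 3, 4), 2, 2)), 2.0)
  expect_equal(mean_filter_response(matrix(5, 1, 1)), 5.0)
  expect_equal(mean_filter_response(matrix(0, 3, 3)), 0.0)
  expect_error(mean_filter_response(numeric(0)), "empty")
})

test_that("gain_forward returns per-layer maps consistent with extract_responses", {
  bb <- tiny_backbone()
  st <- tiny_set(n = 2L)
  maps <- gain_forward(bb, st)
  expect_named(maps, c("layer_1", "layer_2"))
  expect_equal(dim(maps$layer_1), c(4L, 8L, 8L, 6L))
  r <- extract_responses(bb, st, layers = 1L)[[1]]
  for (n in 1:6) for (k in 1:4) {
    expect_equal(mean_filter_response(maps$layer_1[k, , , n]), r[n, k],
                 tolerance = 1e-12)
  }
})

test_that("response matrices are non-negative with shape and alignment contracts", {
  bb <- tiny_backbone()
  st <- tiny_set(n = 1L)
  r <- extract_responses(bb, st, layers = 2L)
  expect_equal(dim(r[[1]]), c(3L, 6L))
  expect_true(all(r[[1]] >= 0))
  expect_identical(rownames(r[[1]]), st$meta$image_id)
})

test_that("backbone containers round-trip and reject layout mismatches", {
  bb <- tiny_backbone()
  f <- tempfile(fileext = ".rds")
  save_backbone(bb, f)
  bb2 <- load_backbone(f)
  expect_identical(bb$layers, bb2$layers)
  spec_other <- backbone_spec("mini-cnn", filters = c(3L, 5L), input_size = 8L,
                              weights = f)
  expect_error(build_backbone(spec_other), "does not match")
  spec_same <- backbone_spec("mini-cnn", filters = c(4L, 6L), input_size = 8L,
                             weights = f)
  expect_identical(build_backbone(spec_same)$layers, bb$layers)
})
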