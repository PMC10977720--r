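test_that("tuning values match hand-computed and oracle values", {
  resp <- manual_responses(c(1, 2, 3, 4, 5, 6))
  labels <- c("pleasant", "pleasant", "neutral", "neutral",
              "unpleasant", "unpleasant")
  tv <- tuning_values(resp, labels)
  # grand mean 3.5, population SD sqrt(17.5/6); S_P = -2 / SD
  expect_equal(tv$s_pleasant, -2 / sqrt(17.5 / 6), tolerance = 1e-12)
  expect_equal(tv$s_pleasant, -1.1711, tolerance = 1e-4)
  expect_equal(tv$s_neutral, 0, tolerance = 1e-12)
  expect_equal(tv$s_unpleasant, 1.1711, tolerance = 1e-4)
  expect_equal(tv$preferred, "unpleasant")
  expect_false(tv$degenerate)
  orc <- oracle_tuning(c(1, 2, 3, 4, 5, 6), labels)
  expect_equal(unlist(tv[, c("s_pleasant", "s_neutral", "s_unpleasant")]),
               orc, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("zero-variance neurons are degenerate with zero tuning values", {
  resp <- manual_responses(cbind(rep(2, 6), 1:6))
  labels <- rep(c("pleasant", "neutral", "unpleasant"), each = 2)
  tv <- tuning_values(resp, labels)
  expect_true(tv$degenerate[1])
  expect_false(tv$degenerate[2])
  expect_equal(unlist(tv[1, c("s_pleasant", "s_neutral", "s_unpleasant")]),
               c(0, 0, 0), ignore_attr = TRUE)
})

test_that("the preferred category attains the maximal tuning value", {
  set.seed(8)
  labels <- rep(c("pleasant", "neutral", "unpleasant"), each = 5)
  resp <- manual_responses(cbind(rnorm(15), rnorm(15) + rep(c(0, 0, 3), each = 5)))
  tv <- tuning_values(resp, labels)
  S <- as.matrix(tv[, c("s_pleasant", "s_neutral", "s_unpleasant")])
  for (i in seq_len(nrow(tv))) {
    expect_equal(match(tv$preferred[i],
                       c("pleasant", "neutral", "unpleasant")),
                 unname(which.max(S[i, ])))
  }
  expect_equal(tv$preferred[2], "unpleasant")
})

test_that("tuning conservation: category-size-weighted tuning values sum to zero", {
  set.seed(11)
  for (rep_i in 1:5) {
    n_per <- sample(3:9, 3)
    labels <- rep(c("pleasant", "neutral", "unpleasant"), times = n_per)
    resp <- manual_responses(matrix(rnorm(sum(n_per) * 4), ncol = 4))
    tv <- tuning_values(resp, labels)
    S <- as.matrix(tv[, c("s_pleasant", "s_neutral", "s_unpleasant")])
    tot <- S %*% n_per
    expect_true(all(abs(tot) < 1e-9 * max(1, max(abs(S)))))
  }
})

test_that("d-prime matches the stated moment example and the oracle", {
  # exact category moments: means (2, 0, 0), population variances (1, 1, 1)
  vals <- c(1, 3, -1, 1, -1, 1)
  labels <- rep(c("pleasant", "neutral", "unpleasant"), each = 2)
  rec <- dprime_si(manual_responses(vals), labels)
  expect_equal(rec$d_pleasant, 2.0, tolerance = 1e-12)
  expect_equal(rec$si, 2.0, tolerance = 1e-12)
  expect_equal(rec$emotion, "pleasant")
  expect_equal(c(rec$d_pleasant, rec$d_neutral, rec$d_unpleasant),
               oracle_dprime(vals, labels), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("identical category distributions give zero d-prime everywhere", {
  vals <- rep(c(1, 5), times = 3)
  labels <- rep(c("pleasant", "neutral", "unpleasant"), each = 2)
  rec <- dprime_si(manual_responses(vals), labels)
  expect_equal(c(rec$d_pleasant, rec$d_neutral, rec$d_unpleasant), c(0, 0, 0))
  expect_equal(rec$si, 0)
})

test_that("d-prime of the target is invariant to swapping the non-target labels", {
  set.seed(21)
  vals <- rnorm(18)
  labels <- rep(c("pleasant", "neutral", "unpleasant"), each = 6)
  swapped <- labels
  swapped[labels == "neutral"] <- "unpleasant"
  swapped[labels == "unpleasant"] <- "neutral"
  r1 <- dprime_si(manual_responses(vals), labels)
  r2 <- dprime_si(manual_responses(vals), swapped)
  expect_equal(r1$d_pleasant, r2$d_pleasant, tolerance = 1e-12)
})

test_that("scale and shift invariance of tuning values and d-prime", {
  set.seed(31)
  vals <- rnorm(24)
  labels <- rep(c("pleasant", "neutral", "unpleasant"), each = 8)
  base_t <- tuning_values(manual_responses(vals), labels)
  base_d <- dprime_si(manual_responses(vals), labels)
  for (tf in list(function(x) 3.7 * x, function(x) x + 11,
                  function(x) 0.2 * x - 4)) {
    tt <- tuning_values(manual_responses(tf(vals)), labels)
    dd <- dprime_si(manual_responses(tf(vals)), labels)
    expect_equal(tt$s_pleasant, base_t$s_pleasant, tolerance = 1e-10)
    expect_equal(dd$si, base_d$si, tolerance = 1e-10)
    expect_equal(dd$emotion, base_d$emotion)
  }
})

test_that("the flat variance-pooling variant follows its formula", {
  set.seed(41)
  vals <- rnorm(18)
  labels <- rep(c("pleasant", "neutral", "unpleasant"), each = 6)
  rec <- dprime_si(manual_responses(vals), labels, pooling = "flat")
  m <- tapply(vals, labels, mean)[c("pleasant", "neutral", "unpleasant")]
  v <- tapply(vals, labels, function(x) mean((x - mean(x))^2))[
    c("pleasant", "neutral", "unpleasant")]
  expect_equal(rec$d_pleasant,
               (m[1] - (m[2] + m[3]) / 2) / sqrt(sum(v) / 2),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("top responding images are ranked with deterministic ties", {
  resp <- manual_responses(c(5, 1, 9), ids = c("a", "b", "c"))
  expect_equal(top_k_images(resp, neurons(1L, 0L), 2L), c("c", "a"))
  expect_setequal(top_k_images(resp, neurons(1L, 0L), 3L), c("a", "b", "c"))
  expect_equal(length(top_k_images(resp, neurons(1L, 0L), 100L)), 3L)
  tied <- manual_responses(c(2, 2, 1), ids = c("zz", "aa", "bb"))
  expect_equal(top_k_images(tied, neurons(1L, 0L), 2L), c("aa", "zz"))
  expect_error(top_k_images(resp, neurons(3L, 0L), 1L), "unknown neuron")
})

test_that("preconditions on labels and category counts are enforced", {
  resp <- manual_responses(1:4)
  expect_error(tuning_values(resp, rep("pleasant", 4)), "category")
  expect_error(dprime_si(manual_responses(1:5),
                         c("pleasant", "pleasant", "neutral", "neutral",
                           "unpleasant")),
               "at least 2")
  expect_error(tuning_values(resp, c("pleasant", "neutral")), "align")
})
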