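fake_records <- function(si, emotion, layer = 1L, degenerate = NULL) {
  K <- length(si)
  if (is.null(degenerate)) degenerate <- rep(FALSE, K)
  data.frame(neuron = sprintf("L%d.K%d", layer, seq_len(K) - 1L),
             layer = layer, filter = seq_len(K) - 1L,
             d_pleasant = 0, d_neutral = 0, d_unpleasant = 0,
             si = si, emotion = emotion, degenerate = degenerate)
}

test_that("SI thresholding keeps the top fraction, never degenerate neurons", {
  rec <- fake_records(si = 10:1 / 10, emotion = rep("pleasant", 10))
  sel <- threshold_by_si(rec, 0.8)
  expect_equal(sort(sel$pleasant$filter), 0:7) # the 8 highest-SI neurons
  expect_equal(attr(sel, "population"), 10L)

  all_kept <- threshold_by_si(rec, 1.0)
  expect_equal(sort(all_kept$pleasant$filter), 0:9)

  degen <- fake_records(si = c(0.9, 0, 0.8, 0.7), emotion = rep("neutral", 4),
                        degenerate = c(FALSE, TRUE, FALSE, FALSE))
  s2 <- threshold_by_si(degen, 1.0)
  expect_false(1L %in% s2$neutral$filter)

  expect_error(threshold_by_si(rec[0, ], 0.8), "empty")
  expect_error(threshold_by_si(rec, 0), "keep_fraction")
})

test_that("SI ties across the cut resolve by filter index at fixed set size", {
  rec <- fake_records(si = c(0.9, 0.5, 0.5, 0.5, 0.1),
                      emotion = rep("unpleasant", 5))
  sel <- threshold_by_si(rec, 0.8) # floor(0.8 * 5) = 4 retained
  expect_equal(nrow(sel$unpleasant), 4L)
  expect_equal(sort(sel$unpleasant$filter), c(0L, 1L, 2L, 3L))
})

test_that("monotone containment across keep fractions", {
  set.seed(13)
  rec <- fake_records(si = runif(30),
                      emotion = sample(c("pleasant", "neutral", "unpleasant"),
                                       30, replace = TRUE))
  fr <- c(0.2, 0.5, 0.8, 1.0)
  sels <- lapply(fr, function(f) threshold_by_si(rec, f))
  for (i in seq_len(length(fr) - 1)) {
    for (e in c("pleasant", "neutral", "unpleasant")) {
      expect_true(all(sels[[i]][[e]]$filter %in% sels[[i + 1]][[e]]$filter))
    }
  }
})

test_that("analytic chance overlap is the hypergeometric mean", {
  expect_equal(chance_overlap(10, 20, 100), 2.0)
  expect_equal(chance_overlap(50, 20, 50), 20) # n1 = N saturation
  expect_error(chance_overlap(60, 20, 50), "subset sizes")
  # brute-force enumeration oracle at n1 = n2 = 2, N = 4
  subs <- utils::combn(4, 2, simplify = FALSE)
  ov <- outer(seq_along(subs), seq_along(subs),
              Vectorize(function(i, j) length(intersect(subs[[i]], subs[[j]]))))
  expect_equal(mean(ov), chance_overlap(2, 2, 4))
})

test_that("Monte-Carlo chance overlap converges to the analytic mean", {
  mc <- chance_overlap(8, 8, 64, method = "montecarlo", draws = 10000L,
                       seed = 2L)
  se <- mc$sd / sqrt(10000)
  expect_lt(abs(mc$mean - 1.0), 3 * se)
  # seeded reproducibility
  mc2 <- chance_overlap(8, 8, 64, method = "montecarlo", draws = 100L, seed = 9L)
  mc3 <- chance_overlap(8, 8, 64, method = "montecarlo", draws = 100L, seed = 9L)
  expect_identical(mc2$draws, mc3$draws)
})

test_that("overlap selection intersects per emotion with chance attached", {
  set.seed(17)
  emo <- sample(c("pleasant", "neutral", "unpleasant"), 20, replace = TRUE)
  rec <- fake_records(si = runif(20), emotion = emo)
  sel <- overlap_selection(rec, rec, 0.8)
  for (e in c("pleasant", "neutral", "unpleasant")) {
    em <- sel$emotions[[e]]
    expect_equal(em$genuine, em$set_a)
    expect_equal(em$observed_overlap, nrow(em$set_a))
    expect_equal(em$chance_expected_overlap,
                 nrow(em$set_a) * nrow(em$set_b) / 20)
    expect_true(all(em$genuine$filter %in% em$set_a$filter))
    expect_true(all(em$genuine$filter %in% em$set_b$filter))
  }
  # disjoint selective emotions: empty intersections
  recA <- fake_records(si = runif(20), emotion = rep("pleasant", 20))
  recB <- fake_records(si = runif(20), emotion = rep("neutral", 20))
  s2 <- overlap_selection(recA, recB, 0.8)
  expect_equal(s2$emotions$pleasant$observed_overlap, 0L)
  expect_equal(s2$emotions$neutral$observed_overlap, 0L)
  # population mismatch
  expect_error(overlap_selection(rec, rec[-1, ], 0.8), "identical neuron")
})

test_that("trained-vs-random comparison tabulates overlap differences", {
  rec <- fake_records(si = 20:1 / 20,
                      emotion = rep(c("pleasant", "neutral", "unpleasant"),
                                    length.out = 20))
  s1 <- overlap_selection(rec, rec, 0.8)
  tab <- trained_vs_random_comparison(s1, s1)
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$difference == 0))
  rec2 <- fake_records(si = 1:20 / 20, emotion = rep("pleasant", 20))
  s2 <- overlap_selection(rec2, rec2, 0.5)
  expect_error(trained_vs_random_comparison(list(s1, s1), list(s1)), "layer sets")
  tab2 <- trained_vs_random_comparison(s1, s2)
  expect_equal(tab2$overlap_trained - tab2$overlap_random, tab2$difference)
})

test_that("threshold sweep evaluates the callback over the grid", {
  rec <- fake_records(si = 10:1 / 10,
                      emotion = rep(c("pleasant", "neutral"), 5))
  flat <- threshold_sweep(rec, rec, c(0.2, 0.5, 1.0), function(sel) 7)
  expect_equal(flat$value, c(7, 7, 7))
  one <- threshold_sweep(rec, rec, 1.0, function(sel)
    sel$emotions$pleasant$observed_overlap)
  expect_equal(nrow(one), 1L)
  expect_equal(one$value, 5)
  expect_error(threshold_sweep(rec, rec, numeric(0), function(sel) 1), "empty")
})

test_that("selection results export to JSON", {
  rec <- fake_records(si = 10:1 / 10, emotion = rep("pleasant", 10))
  sel <- overlap_selection(rec, rec, 0.8)
  f <- tempfile(fileext = ".json")
  write_selection_json(sel, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$layer, 1L)
  expect_equal(back$emotions$pleasant$observed_overlap, 8L)
  df <- as.data.frame(sel)
  expect_equal(df$observed_overlap[df$emotion == "pleasant"], 8L)
})
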