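# Identification of emotion-selective neurons: SI-percentile thresholding
# within a layer and dataset, cross-dataset overlap ("genuine" selective
# neurons), and comparison against the hypergeometric chance baseline
# n1 * n2 / N for the overlap of two random neuron subsets.

#' Retain the top fraction of neurons by selectivity index
#'
#' Neurons of one layer and one dataset are rank-ordered by SI (descending;
#' ties broken by ascending layer then filter index) and the top
#' `floor(keep_fraction * K)` are retained (minimum 1 whenever any
#' non-degenerate neuron exists), then partitioned by selective emotion.
#' Degenerate (zero-variance) neurons are never retained.
#'
#' @param records selectivity records from [dprime_si()] (one layer, one
#'   dataset).
#' @param keep_fraction fraction of neurons kept, in `(0, 1]`. The protocol
#'   default is 0.8, i.e. discarding the 20 percent of neurons with the
#'   smallest SI.
#' @return named list (`pleasant`, `neutral`, `unpleasant`) of [neurons()]
#'   tables; attribute `population` carries the layer's total neuron count.
#' @export
threshold_by_si <- function(records, keep_fraction = 0.8) {
  assert_that(is.data.frame(records) && nrow(records) >= 1L,
              "empty record list")
  assert_that(keep_fraction > 0 && keep_fraction <= 1,
              "keep_fraction must be in (0, 1]")
  assert_that(length(unique(records$layer)) == 1L,
              "records must come from a single layer")
  K <- nrow(records)
  live <- records[!records$degenerate, , drop = FALSE]
  n_keep <- min(floor(keep_fraction * K), nrow(live))
  if (nrow(live) > 0L) n_keep <- max(n_keep, 1L)
  live <- live[order(-live$si, live$layer, live$filter), , drop = FALSE]
  kept <- live[seq_len(n_keep), , drop = FALSE]
  out <- lapply(EMOTIONS, function(e) {
    sub <- kept[kept$emotion == e, , drop = FALSE]
    neurons(sub$layer, sub$filter)
  })
  names(out) <- EMOTIONS
  attr(out, "population") <- K
  out
}

#' Expected chance overlap of two random neuron subsets
#'
#' The intersection size of uniformly drawn subsets of sizes `n1` and `n2`
#' from a population of `N` neurons has hypergeometric mean `n1 * n2 / N`.
#'
#' @param n1,n2 subset sizes.
#' @param N population size.
#' @param method `"analytic"` (the mean) or `"montecarlo"` (seeded empirical
#'   draws).
#' @param draws number of Monte-Carlo draws.
#' @param seed RNG seed for the Monte-Carlo method.
#' @return for `"analytic"`, a single number; for `"montecarlo"`, a list with
#'   `mean`, `sd` and the vector of `draws` overlap counts.
#' @export
chance_overlap <- function(n1, n2, N, method = c("analytic", "montecarlo"),
                           draws = 10000L, seed = 1L) {
  method <- match.arg(method)
  assert_that(N >= 1L, "population must be >= 1")
  assert_that(n1 >= 0L && n1 <= N && n2 >= 0L && n2 <= N,
              "subset sizes must lie in [0, N]")
  if (method == "analytic") return(n1 * n2 / N)
  counts <- with_seed(seed, {
    vapply(seq_len(draws), function(i) {
      a <- sample.int(N, n1)
      b <- sample.int(N, n2)
      length(intersect(a, b))
    }, 1L)
  })
  list(mean = mean(counts), sd = stats::sd(counts), draws = counts)
}

#' Cross-dataset overlap of selective neurons
#'
#' Applies [threshold_by_si()] to the records of two datasets covering the
#' same neuron population, intersects the per-emotion selections (the
#' "genuine" emotion-selective neurons), and attaches observed and chance
#' overlap counts.
#'
#' @param records_a,records_b selectivity records for the same layer from
#'   two stimulus datasets.
#' @inheritParams threshold_by_si
#' @return object of class `selection_result`: list with `layer`,
#'   `keep_fraction`, `population`, and per-emotion entries holding `set_a`,
#'   `set_b`, `genuine` neuron tables plus `observed_overlap` and
#'   `chance_expected_overlap`.
#' @export
overlap_selection <- function(records_a, records_b, keep_fraction = 0.8) {
  assert_that(identical(sort(records_a$neuron), sort(records_b$neuron)),
              "the two record sets must cover identical neuron populations")
  sel_a <- threshold_by_si(records_a, keep_fraction)
  sel_b <- threshold_by_si(records_b, keep_fraction)
  N <- attr(sel_a, "population")
  ems <- lapply(EMOTIONS, function(e) {
    a <- sel_a[[e]]; b <- sel_b[[e]]
    inter <- a[neuron_ids(a) %in% neuron_ids(b), , drop = FALSE]
    rownames(inter) <- NULL
    list(set_a = a, set_b = b, genuine = inter,
         observed_overlap = nrow(inter),
         chance_expected_overlap = chance_overlap(nrow(a), nrow(b), N))
  })
  names(ems) <- EMOTIONS
  structure(list(layer = unique(records_a$layer),
                 keep_fraction = keep_fraction, population = N,
                 emotions = ems),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> layer %d, keep %.2f, population %d\n",
              x$layer, x$keep_fraction, x$population))
  for (e in EMOTIONS) {
    em <- x$emotions[[e]]
    cat(sprintf("  %-10s |A|=%d |B|=%d overlap=%d (chance %.2f)\n", e,
                nrow(em$set_a), nrow(em$set_b), em$observed_overlap,
                em$chance_expected_overlap))
  }
  invisible(x)
}

#' Flatten selection results for plotting or export
#'
#' @param x a `selection_result`.
#' @param ... unused.
#' @return data frame with one row per emotion.
#' @export
as.data.frame.selection_result <- function(x, ...) {
  do.call(rbind, lapply(EMOTIONS, function(e) {
    em <- x$emotions[[e]]
    data.frame(layer = x$layer, emotion = e,
               keep_fraction = x$keep_fraction,
               n_a = nrow(em$set_a), n_b = nrow(em$set_b),
               observed_overlap = em$observed_overlap,
               chance_expected_overlap = em$chance_expected_overlap)
  }))
}

#' Compare genuine-selective counts between two networks
#'
#' Side-by-side overlap counts (typically an object-trained versus a
#' randomly initialized backbone) per layer and emotion, with their
#' difference. Purely descriptive; no statistical claim attached.
#'
#' @param selection_trained,selection_random lists of `selection_result`
#'   objects (or single results) covering the same layer set.
#' @return data frame with columns `layer`, `emotion`, `overlap_trained`,
#'   `overlap_random`, `difference`.
#' @export
trained_vs_random_comparison <- function(selection_trained, selection_random) {
  as_list <- function(x) if (inherits(x, "selection_result")) list(x) else x
  st <- as_list(selection_trained)
  sr <- as_list(selection_random)
  lt <- vapply(st, function(s) s$layer, 1L)
  lr <- vapply(sr, function(s) s$layer, 1L)
  assert_that(identical(sort(lt), sort(lr)), "layer sets must match")
  sr <- sr[match(lt, lr)]
  do.call(rbind, lapply(seq_along(st), function(i) {
    data.frame(layer = lt[i], emotion = EMOTIONS,
               overlap_trained = vapply(EMOTIONS, function(e)
                 st[[i]]$emotions[[e]]$observed_overlap, 1L),
               overlap_random = vapply(EMOTIONS, function(e)
                 sr[[i]]$emotions[[e]]$observed_overlap, 1L),
               row.names = NULL)
  })) -> tab
  tab$difference <- tab$overlap_trained - tab$overlap_random
  tab
}

#' Performance as a function of the keep fraction
#'
#' Evaluates a user-supplied callback on the overlap selection obtained at
#' each keep fraction of a grid, e.g. downstream readout performance after
#' enhancing the retained neurons. Seeds inside the callback should be held
#' fixed across grid points by the caller.
#'
#' @param records_a,records_b selectivity records of the two datasets.
#' @param keep_fractions numeric grid in `(0, 1]`.
#' @param eval_fn callback `function(selection_result) -> scalar`.
#' @return data frame with columns `keep_fraction` and `value`.
#' @export
threshold_sweep <- function(records_a, records_b, keep_fractions, eval_fn) {
  assert_that(length(keep_fractions) >= 1L, "empty keep-fraction grid")
  assert_that(all(keep_fractions > 0 & keep_fractions <= 1),
              "keep fractions must be in (0, 1]")
  vals <- vapply(keep_fractions, function(f) {
    as.numeric(eval_fn(overlap_selection(records_a, records_b, f)))
  }, 1.0)
  data.frame(keep_fraction = keep_fractions, value = vals)
}

#' Export a selection result as JSON
#'
#' @param x a `selection_result` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(x, path) {
  as_list <- function(s) list(
    layer = s$layer, keep_fraction = s$keep_fraction,
    population = s$population,
    emotions = lapply(s$emotions, function(em) list(
      set_a = neuron_ids(em$set_a), set_b = neuron_ids(em$set_b),
      genuine = neuron_ids(em$genuine),
      observed_overlap = em$observed_overlap,
      chance_expected_overlap = em$chance_expected_overlap)))
  obj <- if (inherits(x, "selection_result")) as_list(x) else lapply(x, as_list)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
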