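---
title: "Emotion-selective neurons in convolutional network models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emotion-selective neurons in convolutional network models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the model

Convolutional networks trained to recognize objects develop units that are
selective for stimulus properties they were never trained on. `emoselect`
implements a complete pipeline for asking whether *emotion* selectivity —
consistent, category-specific responding to pleasant, neutral and unpleasant
images — emerges in the convolutional filters of such a network, and whether
the selective filters matter functionally for emotion recognition.

A filter ("neuron") $k$ in convolutional layer $l$ computes

$$x^{lk} = (1+\alpha)\,\max\!\left[0,\; w^{lk} * x^{l-1}\right],$$

a standard convolution-plus-ReLU whose slope carries a tunable offset
$\alpha$. The offset is the package's single manipulation primitive:
$\alpha = 0$ is the baseline network, $\alpha > 0$ raises the neuron's gain
(the standard network-level model of feature-based attention), and
$\alpha = -1$ silences the neuron — an in-silico lesion. Gains act only on
convolutional filters; fully connected stages are never modulated, because
the selectivity analysis itself is defined over convolutional filters only.

The neuronal response to an image is the activation map averaged over space,
$\bar p^{lk}(n) = \tfrac1{WH}\sum_{ij} X^{lk}_{ij}(n)$. From the responses
over a dataset of $N$ images with grand mean $\hat p^{lk}$, two statistics
are computed per neuron:

* **Tuning value** for category $e$:
  $$S^{lk}_e = \frac{\tfrac1{N_e}\sum_{n\in e}\left(\bar p^{lk}(n)-\hat p^{lk}\right)}
  {\sqrt{\tfrac1N \sum_n \left(\bar p^{lk}(n)-\hat p^{lk}\right)^2}},$$
  the mean z-scored response to the category. The arg-max category is the
  neuron's *preferred* emotion. Because the numerators sum (weighted by
  category sizes) to the total deviation from the grand mean, the identity
  $\sum_e N_e S_e = 0$ holds for every non-degenerate neuron — a useful
  internal consistency check that the test suite enforces.

* **d′ and the selectivity index**. For target category $e$ against the other
  two categories $o_1, o_2$:
  $$d'(e) = \frac{\bar X_e - \tfrac12(\bar X_{o_1}+\bar X_{o_2})}
  {\sqrt{\tfrac12\left(\sigma^2_e + \tfrac12(\sigma^2_{o_1}+\sigma^2_{o_2})\right)}}.$$
  The selectivity index SI is the largest of the three d′ values and its
  arg-max category is the neuron's *selective emotion*.

Two conventions in the d′ formula are genuinely underdetermined and are
therefore explicit configuration switches of `dprime_si()`:

* **Variance pooling.** The denominator above pools the two non-target
  variances first, mirroring the numerator's $\tfrac12(\cdot+\cdot)$
  structure; this is the default. The alternative flat reading
  $\sqrt{(\sigma^2_e+\sigma^2_{o_1}+\sigma^2_{o_2})/2}$ is available via
  `pooling = "flat"`. The two differ only by a monotone rescaling per neuron
  when variances are comparable, so selections are typically similar but not
  identical.
* **Variance estimator.** Population variance (divide by $N_e$) is the
  default, for consistency with the population standard deviation in the
  tuning-value denominator; `var_type = "sample"` switches to the unbiased
  estimator.

Degenerate (dead, zero-variance) filters get tuning values and d′ of 0 and
are flagged; they are excluded from selection and never propagate NaN. When
a non-degenerate contrast has a zero pooled variance with a nonzero mean
difference, d′ is reported as signed infinity rather than clipped. Arg-max
ties in both the preferred category and SI are broken in the fixed order
pleasant < neutral < unpleasant, so every result is deterministic.

## Identifying genuine emotion-selective neurons

Small SI values are noise-dominated, so neurons are rank-ordered by SI
within each layer and dataset and only the top `keep_fraction` retained
(default 0.8: the bottom 20% are discarded; `threshold_sweep()` exposes the
curve that justifies such a choice). The retained count is
$\lfloor f\cdot K\rfloor$ with a floor of one whenever any non-degenerate
neuron exists; ties at the cut resolve by the deterministic ordering
(SI descending, then layer, then filter index). Thresholding is per layer
and per dataset — a global pool would mix activation scales across layers.

A neuron retained and assigned the *same* emotion in two independent
stimulus datasets is a *genuine* emotion-selective neuron
(`overlap_selection()`). The observed per-emotion overlap count is compared
against the chance expectation for two uniformly random subsets,
$\mathbb E|A\cap B| = n_1 n_2/N$ (the hypergeometric mean). The analytic
form is the default; a seeded Monte-Carlo estimate (`chance_overlap(...,
method = "montecarlo")`) is used to verify the calibration in the test
suite. `trained_vs_random_comparison()` tabulates genuine counts for two
networks side by side (no statistical claim attached).

## The readout and the manipulation protocol

Functional relevance is probed with a *frozen-backbone readout*: the
network's classification layer is replaced by a two-unit head trained with
cross-entropy (plain SGD, learning rate 1e-3, 10 epochs, batch size 128,
50/25/25 stratified train/validation/test split) to decode one emotion
against the rest. No backbone weight changes — the implementation verifies
this with a weight checksum recorded in the model and re-checked at every
evaluation. Because the one-vs-rest framing is imbalanced (one category
against two), the cross-entropy uses inverse-prevalence class weights by
default; features are standardized with training-set statistics. Both are
the package's own choices for desk-scale robustness (`class_weights =
"none"` disables the former). Performance is the F1-score of the target
emotion (`average = "macro"` is available but not the default).

Manipulations are applied at evaluation time only, one layer at a time:

* **Enhancement**: $\alpha$ sweeps from 0 to 5 in steps of 0.1 over the
  target set; the best $\alpha$ is chosen on the *validation* split
  (choosing on test would leak) and performance is reported as test F1 at
  that $\alpha$. Since $\alpha = 0$ is in the grid, the validation optimum
  can never fall below baseline.
* **Lesion**: the target set is fixed at $\alpha = -1$.

Every manipulation is compared against `R = 20` random controls (the count
is a package default; it is configurable and fully seeded): same-size neuron
sets drawn uniformly from the same layer *excluding* the selective set, so
the comparison isolates selectivity rather than layer identity, run through
the byte-identical protocol including the $\alpha$ sweep. The comparison is
a one-sided empirical permutation test,
$p = (1 + \#\{\text{controls at least as extreme}\})/(R+1)$, the package's
choice of a distribution-free test for small $R$.

## The synthetic ground-truth world

Real affective picture sets are access-restricted, so the package ships a
seeded generator whose study conditions are fixed and fully known:

* Each image is mid-gray plus white Gaussian nuisance noise plus one
  category-linked texture: a period-4 vertical grating (unpleasant), a
  period-4 horizontal grating (neutral), or a period-2 checkerboard
  (pleasant), with random phase and ±20% amplitude jitter. `effect_size`
  scales the texture amplitude in units of the noise standard deviation
  (0.06 grayscale units per unit); `effect_size = 0` produces pure noise.
  These three statistics are mutually near-orthogonal under 3×3 matched
  kernels, which is what makes ground truth *plantable*.
* Valence ratings are drawn from truncated normal distributions centered at
  7 / 5 / 3 (sd 0.8) on the 1–9 scale, restricted to each category's band
  under the soft thresholds (4.3 and 6.0, half-width configurable), so
  `categorize_valence()` always reproduces the generated label; ratings in
  the soft band are "unknown" and are never generated.
* `plant_backbone()` adds `strength` times the matched kernel to chosen
  first-layer filters of an otherwise random mini network (strength 0 leaves
  it exactly random) and verifies empirically, on a probe set, that every
  planted neuron responds most to its own category. Planting is supported in
  the first convolutional layer, where a filter's input is the image itself
  and a matched kernel has a closed form; deeper planting would require
  composing kernels through the random layers.
* `generate_object_task()` provides a toy object-recognition task (textured
  discs drawn from the same feature family plus plain discs) for
  `train_backbone()`, the desk-scale analog of large-scale object
  pre-training used in the trained-versus-random contrast.

What the generator deliberately does **not** emulate: the category signal is
low-level by construction, whereas the scientific claim for real affective
images is precisely that their emotion selectivity is *not* reducible to
low-level features. Passing recovery tests therefore demonstrates that the
pipeline's statistics, selection and manipulation machinery are correct and
calibrated — not that emotion selectivity emerges in real networks viewing
real images. Photorealistic content, semantic categories, faces and animacy
are out of scope.

## Backbones and numerical conventions

Two layouts are built by `build_backbone()`: the standard 13-layer
vgg16-style stack (3×3 kernels, pooling after layers 2, 4, 7, 10, 13,
224×224 input, three channels) and a desk-scale `mini-cnn` (default
8/16/32 filters, 32×32 single-channel input, pooling after every layer).
Grayscale inputs are replicated to three channels for the vgg16 layout and
normalized with fixed constants recorded in the backbone (mean 0.449,
sd 0.226; the mini network uses 0.5/0.5) — the channel handling and
normalization are package conventions, since no standard exists for
grayscale input to a three-channel network. Convolutions are computed in
double precision via im2col and matrix products; random weights use
He-scaled Gaussians and every random build records its seed. Layer indices
are 1-based over convolutional layers; filter indices are 0-based within a
layer (`L3.K12`).

## Fixture problem sizes

The shipped experiment fixtures are sized for a single desk CPU, chosen once
as the package's standard study conditions:

* `planted-high-effect`: 16/16/32-filter mini network, 12 of 16 first-layer
  filters planted (4 per emotion, strength 3), two 180-image datasets
  (60 per category) at effect size 3, noise 1; keep fraction 0.8 retains
  floor(0.8·16) = 12 neurons, so a perfect recovery is exactly the planted
  set. Recovery is scored as precision/recall of the genuine sets (with
  matching emotion) against the planted truth.
* `null-effect`: same backbone, effect size 0, 135-image datasets, 10
  replicate seeds. Selection uses two datasets; the readout is trained and
  evaluated on a **third, independent** dataset. This matters: selectivity
  estimated on the same images later used for evaluation injects
  noise-correlations that bias manipulation effects upward even at null.
  With an independent evaluation set, a chance-selective neuron shares no
  noise with the test images and manipulation effects center at zero, which
  is the calibration property the suite asserts. Seeds in which no genuine
  neuron survives selection contribute a zero percent change (manipulating
  an empty set leaves performance at baseline).
* `object-task`: 4 classes × 60 images, 6 epochs. The affective sets for the
  trained-versus-random contrast use effect size 0.7 with noise 3 — a weak
  signal regime. This is intentional: with a strong low-level signal even a
  random-weight network yields saturated, dataset-consistent selectivity and
  the contrast degenerates; with a weak signal, individual random filters
  are noise-dominated while object training builds matched features that
  raise the signal-to-noise ratio in deep layers, producing the directional
  trained ≥ random effect the experiment is designed to detect.

## Known limitations

* The backbone is not pre-trained on a large natural-image corpus; absolute
  selectivity profiles and readout F1 values of such a network are out of
  reach at desk scale and are not reproduced — the pipeline validates
  against planted ground truth instead.
* Planting is first-layer only, and the planted statistics are low-level
  (see above).
* The enhancement/lesion protocol manipulates one layer at a time;
  simultaneous multi-layer manipulation is unsupported.
* Arousal-dimension tuning and finer emotion taxonomies are out of scope.
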