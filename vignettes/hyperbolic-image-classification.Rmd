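---
title: "Hybrid Euclidean-Lorentz image classifiers: model, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid Euclidean-Lorentz image classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Medical image collections are implicitly hierarchical: scans split by
modality (CT vs MRI), then by sequence, then by disease and its subtype.
Hyperbolic space embeds tree-like structure with far less distortion than
Euclidean space of the same dimension, which motivates classifiers whose
decision space is a hyperbolic manifold. `lorentznet` implements the hybrid
architecture used in that line of work — a conventional convolutional
encoder whose penultimate features are clipped, exp-mapped onto the Lorentz
model of hyperbolic space, and classified by hyperbolic multinomial logistic
regression with a learnable curvature — together with its exactly matched
Euclidean twin, and the full evaluation battery used to compare them:
embedding-organization statistics against a known class taxonomy,
projected-gradient-descent (PGD) adversarial robustness sweeps, and
out-of-sample / zero-shot rules with patient-level aggregation.

Everything runs on synthetic image datasets whose class taxonomy is known by
construction, so the whole analysis is reproducible without any data
download.

## The Lorentz model and the decoder

We use the hyperboloid (Lorentz) model: points \(x \in \mathbb{R}^{d+1}\)
with time coordinate first, satisfying
\(\langle x, x\rangle_L = -1/k\), \(x_0 > 0\), where
\(\langle x, y\rangle_L = -x_0 y_0 + \sum_{i\ge1} x_i y_i\)
and \(k > 0\) is the curvature magnitude. The origin is
\(o = (1/\sqrt{k}, 0, \dots, 0)\). The package provides the exact maps:

* `expmap0(v, m)`: \(\exp_o(v) = \cosh(\sqrt k\|v\|)\,o +
  \frac{\sinh(\sqrt k \|v\|)}{\sqrt k \|v\|}(0, v)\), with a Taylor branch of
  \(\sinh(t)/t\) below \(t = 10^{-6}\);
* `logmap0`, its exact inverse;
* `geodesic_distance(x, y, m)` \(= \frac{1}{\sqrt k}
  \operatorname{arccosh}(-k\langle x, y\rangle_L)\), the arccosh argument
  floored at 1 so rounding can never produce `NaN` for near-coincident
  points;
* `clip_features(v, r)` \(= v\min(1, r/\|v\|)\), the norm-bounding
  stabilizer applied before the exponential map;
* `project_to_hyperboloid`, which recomputes the time coordinate after
  numerical drift, and `riemannian_step`, the manifold-update contract
  (metric correction, tangent projection, exp-map retraction).

The Lorentz head scores class \(j\) by the norm-scaled signed geodesic
distance of the embedded point to a learnable hyperbolic hyperplane. With
\(s = \sqrt k\), direction \(z_j \in \mathbb{R}^d\) and offset
\(a_j \in \mathbb{R}\), the hyperplane normal is the spacelike vector
\(v_j = (\sinh(s a_j)\|z_j\|,\ \cosh(s a_j) z_j)\) and the logit is

\[
\ell_j(x) = \frac{\|z_j\|}{s}\,
\operatorname{asinh}\!\left(\frac{s\,\langle v_j, x\rangle_L}{\|z_j\|}\right).
\]

This parameterization has exactly \(d + 1\) scalars per class — the same as
an affine Euclidean head — so the only extra trainable parameter of the
Lorentz variant is the curvature, stored as \(\log k\) so no optimizer step
can violate \(k > 0\). The exact +1 parameter delta is asserted for every
configuration in the test suite. The signed-distance form above is the one
used in the Lorentz-model neural-network literature; it is the natural
analogue of "logit = scaled signed distance to a class hyperplane".

All trainable parameters therefore live in flat Euclidean coordinates
(encoder weights, head directions/offsets, \(\log k\)), and plain SGD with
momentum realizes the Riemannian scheme through these reparameterizations;
`riemannian_step` is provided (and tested) for genuinely manifold-valued
parameters, which this architecture deliberately avoids.

## The encoder and why it has no batch norm

Both geometries share one residual convolutional encoder, built and
initialized identically from the same seed so the twins differ only in the
head. Two scales exist:

* `tiny`: stride-2 3x3 stem (width 16), one residual block at width 16, one
  stride-2 block at width 32, global average pooling, then a linear layer to
  the embedding dimension. This is the desk-scale workhorse: it trains to
  high accuracy on the synthetic task in seconds on one CPU.
* `resnet18`: the ResNet-18 width/depth layout (3x3 stem at 64, stages
  64/128/256/512 with two blocks each), retained for fidelity experiments.

The blocks use plain convolutions with biases and no batch normalization;
each block's second convolution is zero-initialized so every block starts as
an identity. Together with a global gradient-norm cap (default 5) and a
cosine-decayed learning rate (default 0.02, momentum 0.9), this makes
BN-free training stable across seeds. Batch norm was left out deliberately:
it roughly doubles the backward-pass machinery while the scientific content
of the comparison — identical encoder, different decoder geometry — is
unchanged, and parameter-count parity (+1) holds either way.

The embedding dimension defaults to the class count, matching the convention
that the evaluation embedding space has one dimension per class (penultimate
layer, before softmax).

## The synthetic generator: what it emulates and what it does not

`build_taxonomy(branching)` defines a balanced tree of categorical
descriptors (default levels: modality / category / disease / subtype).
`generate_dataset()` gives every class a prototype image

\[
\text{prototype} = 0.5 + \sum_{\text{level } l} A_l P_{\text{anc}(l)} +
A_{\text{leaf}} P_{\text{leaf}},
\]

where each \(P\) is a smooth random pattern (an 8x8 Gaussian grid bilinearly
upsampled to the image size) shared by all classes under the same ancestor
at that level, and each image is its prototype plus i.i.d. Gaussian pixel
noise, clamped to \([0, 1]\). Defaults — 32x32 grayscale, 100 images per
class, level amplitudes \(0.3 \cdot 0.6^{l-1}\), leaf amplitude 0.15, noise
sd 0.1 — were chosen once so that (i) the class structure is comfortably
learnable by the tiny encoder, and (ii) sibling classes are visibly more
alike than cross-branch classes, mimicking how two MRI sequences of one
disease resemble each other more than a CT class. 32x32 resolution is used
because the patterns are band-limited (nothing above the 8x8 pattern grid
survives), so a larger canvas adds cost without information.

The zero-shot cohort emulates the emergency-stroke setting: each synthetic
patient is an ordered stack of slices of the trained "normal" class, and
positive slices add a localized hyperdense blob — a lesion class never seen
in training. Patient truth is the OR of slice truths, and every positive
patient is guaranteed at least one positive slice.

What the generator does **not** emulate: anatomical structure, scanner
intensity distributions, class imbalance, label noise, or inter-site
variation. Passing the directional tests on this generator shows that the
pipeline's statistics behave as designed and that the geometric effect
exists under controlled hierarchy and noise; it does not by itself certify
the effect on real neuroimaging data.

## Augmentation and normalization

The augmentation operations from the training protocol (normalization,
random rotation, horizontal flip) are implemented and tested; for the
synthetic study conditions the geometric augmentations default to off,
because the generative model has no orientation invariance — a flipped
pattern is simply a different pattern, unlike a flipped brain slice.
Normalization statistics are always computed from the training split at fit
time, never hard-coded, and the fitted model stores them.

## The evaluation battery

* **Metrics**: cross-entropy, Top-1/Top-5 (ties broken toward the lowest
  class index, documented in `topk_accuracy`).
* **Hierarchy alignment**: per-class centroids of the evaluation embeddings
  (Euclidean: penultimate features with L2 distances; Lorentz: post-clip
  tangent features averaged in the tangent space, exp-mapped, geodesic
  distances — the tangent mean is deterministic and cheap, which is why it
  is preferred to a Fréchet mean). Both the model matrix and the
  descriptor-mismatch ground-truth matrix (level weights default
  \(L, L-1, \dots, 1\), coarse to fine) are normalized by their largest
  off-diagonal entry; the comparison statistics are the mean absolute
  difference over class pairs (with a percentile bootstrap over pairs,
  n = 1000) and the tie-corrected Spearman rank correlation, plus a Welch
  two-sample t-test between the two models' per-pair absolute-difference
  vectors. Centroids are estimated over the full dataset — the lowest-noise
  estimate of the mean class position. Dendrograms use average linkage on
  the model distance matrix.
* **Robustness**: sup-norm PGD (default: step = epsilon/4, 20 iterations,
  random start), run in normalized input units with the valid raw pixel
  range mapped through the same normalization. The protocol's two epsilon
  presets are both shipped (`pgd_epsilon_presets`: 0.03/0.06/0.12 and
  0.003/0.006/0.012), since both scales are in common use; the sweep is
  always configuration-driven. A zero budget is the identity attack (used
  for clean baseline rows).
* **Generalization**: class-to-outcome mappings with an explicit policy for
  unmapped predictions (default: count as error, since a prediction into an
  unrelated class is a diagnostic failure), image-level zero-shot accuracy
  (TP + TN over all images), the at-least-one-true-positive patient rule,
  and seeded percentile bootstrap intervals (patients resampled for
  patient-level metrics, images for image-level ones).

## Numerical choices

* arccosh argument floored at 1; \(\sinh(t)/t\) Taylor branch below
  \(10^{-6}\); its derivative branch below \(10^{-4}\).
* On-manifold validation uses the constraint residual scaled by
  \(\max(1, k x_0^2)\) — the conditioning of the
  \(-x_0^2 + \|x_s\|^2\) cancellation — so the check is meaningful at any
  distance from the origin representable in double precision.
* Head direction norms are floored at \(10^{-12}\) before division.
* Convolutions are exact GEMM (im2col) computations via RcppArmadillo;
  everything is double precision and single-threaded, so fixed seeds give
  bitwise-reproducible training.
* Degenerate inputs error early and descriptively: off-manifold points,
  all-zero distance matrices, constant rank vectors, empty evaluation
  splits, manifests with duplicated paths.

## Problem sizes

The packaged study conditions are deliberately desk-scale: 12 classes on a
2x3x2 taxonomy, 100 images per class at 32x32, the tiny encoder (~20k
parameters), 14 epochs — about 20 s per fitted model on one CPU. The
directional replication in the acceptance suite repeats the full comparison
over ten seeds; the experiment driver (`run_experiment`) performs one full
pipeline run per seed. The `resnet18` scale is available for larger
experiments but is not exercised by the default suite beyond construction
and parameter accounting.

## Known limitations

* The head algebra follows the Lorentz neural-network literature; published
  alignment and robustness statistics obtained on real compiled image sets
  are not expected to reproduce numerically here — only the directional
  findings are.
* The tangent-space class mean is not the intrinsic (Fréchet) barycenter;
  for clipped features (norm at most 1) the two are close, but they differ
  in principle.
* BN-free residual training needs the gradient cap; very deep configurations
  (the `resnet18` scale) have not been tuned for stability.
* The synthetic generator's additive-pattern model makes hierarchy recovery
  easier than in real data; absolute alignment values are not comparable to
  values obtained on real image sets.
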