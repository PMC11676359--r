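# lorentznet

Hybrid Euclidean–Lorentz convolutional image classifiers and the evaluation
battery for comparing them with their Euclidean twins.

## The problem

Medical image collections are implicitly hierarchical — scans divide by
modality, then sequence, then disease and subtype — and hyperbolic space
represents tree-like structure with far less distortion than Euclidean space
of equal dimension. This package implements the hybrid architecture proposed
for that setting: a conventional residual convolutional encoder whose
penultimate features are **norm-clipped**, **exp-mapped onto the Lorentz
model** of hyperbolic space (curvature `k` learnable through `log k`), and
classified by **hyperbolic multinomial logistic regression** — together with
an exactly matched Euclidean classifier that shares the same encoder
initialization and has exactly one fewer trainable parameter (the
curvature).

With `s = √k`, class direction `z_j ∈ R^d` and offset `a_j`, the Lorentz
head scores a hyperboloid point `x` by the norm-scaled signed geodesic
distance to a learnable hyperplane with spacelike normal
`v_j = (sinh(s a_j)‖z_j‖, cosh(s a_j) z_j)`:

    logit_j(x) = (‖z_j‖ / s) · asinh( s · ⟨v_j, x⟩_L / ‖z_j‖ )

where `⟨·,·⟩_L` is the Lorentz inner product. Everything is trained by SGD
with momentum under cross-entropy, using Euclidean reparameterizations of
all manifold-attached quantities.

The comparison battery implements:

* **hierarchy alignment** — class-centroid geodesic/L2 distance matrices vs
  a ground-truth taxonomy distance matrix: normalized mean absolute
  difference (bootstrap CI), tie-corrected Spearman rank correlation, Welch
  t-test between models, average-linkage dendrograms;
* **adversarial robustness** — sup-norm PGD sweeps over epsilon with
  Top-1/Top-5 reporting;
* **generalization** — class-to-outcome mappings, zero-shot image accuracy,
  the at-least-one-true-positive patient rule, percentile bootstrap CIs;
* **synthetic data** — hierarchical image datasets with a known class
  taxonomy, plus patient-series cohorts with an unseen lesion class, so the
  entire analysis runs without any data download.

## Worked example

```r
library(lorentznet)

tax  <- build_taxonomy(c(2, 3, 2))          # 12 classes over 3 levels
ds   <- generate_dataset(tax, synthetic_spec(), seed = 101)
tr   <- dataset_split(ds, "train")
va   <- dataset_split(ds, "val")

fit  <- hcnn(tr$images, tr$labels, geometry = "lorentz", seed = 101)
fit
evaluate(fit, va$images, va$labels)

desc <- taxonomy_ground_truth_labels(tax)
ha   <- hierarchy_alignment(fit, ds$images, ds$labels, desc, seed = 1)
round(c(mad = ha$mad, rho = ha$rho), 3)
```

which prints (one CPU, ~20 s for the fit):

```
Euclidean-Lorentz hybrid classifier (tiny encoder, 32x32 input, 12 classes, 12-dim embedding)
trainable parameters: 19785; curvature k = 17.48 (learnable), clip radius 1
fitted: 14 epochs, final training loss 0.1661, Top-1 100.0%
n = 120: cross-entropy 0.1669, Top-1 100.00%, Top-5 100.00%
  mad   rho 
0.245 0.455 
```

The fitted Lorentz model classifies the 120 held-out validation images
perfectly; its class-centroid geodesic distance matrix sits at mean absolute
difference 0.245 from the normalized taxonomy ground truth with Spearman
rank correlation 0.455. The same call with `geometry = "euclidean"` gives
the twin model (one parameter fewer), whose alignment is worse (MAD 0.325,
rho 0.407 for this seed) — the directional finding the acceptance suite
checks over ten seeds, together with PGD robustness at the middle epsilon.

`run_experiment(experiment_config(seed = 1))` drives the whole pipeline —
generation, both fits, evaluation, hierarchy alignment, the PGD sweep, and
the zero-shot patient cohort — and returns a report object that
`write_report()` serializes as JSON + CSV.

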