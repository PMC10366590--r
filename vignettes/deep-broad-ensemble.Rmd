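---
title: "The deep-broad ensemble model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The deep-broad ensemble model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(broadvol)
```

## The model

`broadvol` implements a two-stage classifier for 3D volumetric images,
aimed at staging tasks such as distinguishing Alzheimer's disease (AD),
mild cognitive impairment (MCI) and normal controls (NC) from structural
brain MRI.

**Stage 1 — a frozen random convolutional backbone.** A 3D residual
convolutional network is initialised once from a seeded RNG and never
trained. Its stages are a 7×7×7 stem convolution (64 kernels) followed by
3×3×3 average pooling; a residual module of 3 bottleneck blocks with 256
output channels; and a second residual module of 4 bottleneck blocks with
512 output channels. Global average pooling of the two module outputs gives
a shallow feature vector $X_d \in \mathbb{R}^{256}$ and a deep vector
$X_e \in \mathbb{R}^{512}$ per volume, with the deep module consuming the
shallow module's pre-pooling tensor:

$$X_{base} = \lambda_{conv\text{-}pool}(X), \qquad
  X_d = \lambda_d(X_{base}), \qquad X_e = \lambda_e(\lambda_d(X_{base})).$$

Random (untrained) convolutional features preserve coarse spatial contrast
structure; the point of the design is that all *learning* happens in the
cheap closed-form stage, so no backpropagation, GPU, or pre-training is
needed.

**Stage 2 — a Broad Learning System (BLS).** The feature nodes apply a
random affine map with selectable activation $\varphi$ to $X_d$,

$$d_i = \varphi_i(X_d W_{e} + \beta_{e}), \qquad D = [d_1, \dots, d_n],$$

and the enhancement nodes apply a non-linear random map $\delta$ to the
*deep* vector (this re-wiring of the enhancement input is what makes the
system an ensemble of the two depths; in the original BLS the enhancement
layer reads $D$ itself, available here as `mode = "classic"`):

$$e_j = \delta_j(X_e W_{h} + \beta_{h}), \qquad E = [e_1, \dots, e_m].$$

With the state matrix $G = [D \mid E]$ and one-hot labels $Y$, the only
trained parameters are the output weights, the ridge minimizer of
$\lVert Y - GW\rVert_2^2 + \lambda \lVert W \rVert_2^2$:

$$W = G^{+} Y, \qquad
  G^{+} = \lim_{\lambda\to 0}\,(\lambda I + G^{\top}G)^{-1}G^{\top}.$$

`ridge_pinv()`/`fit_output_weights()` compute this by a stable linear
solve, switching to the algebraically identical dual form
$G^{\top}(\lambda I + G G^{\top})^{-1}$ whenever there are fewer samples
than nodes — the common regime here, where a few hundred scans meet
thousands of nodes.

## Preprocessing

Inputs are NIfTI volumes of heterogeneous size and spacing. The chain is:

1. **Resample** to isotropic voxels (default 1.5 mm). The output grid is
   `round(shape × spacing / target)`, preserving physical extent to within
   one voxel; interpolation is trilinear with voxel-center alignment
   (nearest-neighbour is available for label maps). Trilinear is the common
   default for intensity images and avoids ringing.
2. **Min–max scale** intensities to (0, 1), globally over the volume. A
   constant volume is returned as all-zeros with a warning rather than NaN.
   Optional percentile clipping is off by default.
3. **Center crop** to 224×224×128 voxels (336×336×192 mm at 1.5 mm), with
   offsets `floor((in − out)/2)`; this reproduces the canonical
   256×256×160 → 224×224×128 crop exactly. Axes smaller than the target
   are symmetrically zero-padded so the pipeline is total on any input.

Volumes are used in their native voxel order; a `canonical = TRUE` flag
reorients to RAS for datasets with mixed orientations.

## Stride scheme of the backbone

The printed architecture lists a 224×224×128 input producing 224×112×64
after the stem convolution — halving two axes only — then 112×56×32 after
pooling, unchanged through module 1, and 56×28×16 after module 2. These
sizes are mutually consistent only under one stride assignment, which is
the package default (`stride_scheme = "table1"`): stem conv stride
(1,2,2), pool stride (2,2,2), module 1 stride 1, module 2 first-block
stride (2,2,2). A `"uniform"` scheme (stem stride 2 on all axes) is
selectable. Padding is "same"-style everywhere, so spatial sizes depend
only on strides.

Further backbone choices where the design was open:

* **No normalisation layers.** The network is never trained, so batch
  statistics have no calibration role; variance is controlled by He-style
  initialisation (`he_normal`, sd $=\sqrt{2/\text{fan-in}}$) instead. This
  also preserves exact zero-propagation (zero input, zero biases → zero
  features), which the tests exploit.
* **ReLU activations** inside bottleneck blocks, with the standard
  1×1×1 → 3×3×3 → 1×1×1 structure, internal width a quarter of the output
  channels, and a 1×1×1 projection shortcut exactly where channel count or
  spatial shape changes.
* **Double precision** throughout; convolution accumulates in C++ doubles
  and every stage is validated against a nested-loop R reference on small
  tensors (tolerance 1e-5; observed agreement is far tighter).

## BLS parameters

| parameter | default | meaning |
|---|---|---|
| `n_feature_nodes` | 1000 | width of the feature-node block (sweep range 500–4000) |
| `n_enh_nodes` | 500 | width of the enhancement block (sweep range 100–1000) |
| `phi` / `delta` | identity / tanh | node activations (conventional BLS choices) |
| `lam` | 1e-8 | ridge coefficient; the pseudo-inverse is the λ→0 limit, and a tiny positive value keeps the solve safe |
| `sparsity` | 0 (off) | ℓ1 coefficient of sparse auto-coding of mapping weights (sweep range 0.4–0.7) |
| `seed` | 1 | seed of the random node weights (uniform on [−1, 1]) |

Sparse auto-coding, when enabled, refines each feature-node group's random
mapping by solving $\min_W \lVert ZW - X\rVert^2 + s\lVert W\rVert_1$ with
$Z$ the group's raw node output, via ISTA (soft-thresholding, ≤50
iterations, tolerance 1e-6; non-convergence returns the best iterate with
a warning). At $s = 0$ this reduces to minimum-norm least squares, solved
through the SVD because $Z$ typically has more columns than the input has
dimensions. Node groups are equal-width; group count is configurable and
totals are validated against the sweep ranges only in sweep mode.

The "probability" output of `predict()` is a softmax over the linear
scores — a monotone convenience view, not a calibrated probability; ROC
analysis uses the raw scores.

## Evaluation protocol

Tasks are binary (AD vs NC, AD vs MCI, MCI vs NC) or three-class, split
0.7:0.3 stratified by class. Because real cohorts carry several scans per
patient, the default split is **grouped at the subject level** — an
image-level split leaks subject identity across the sets and inflates test
accuracy; `split_level = "image"` reproduces the plain protocol for
comparison. The positive class is AD in the AD tasks and MCI in MCI vs NC.
Reported metrics are ACC, SEN, SPEC, PREC, F1 from the confusion matrix
(zero denominators reported as 0 with a warning), plus a threshold-sweep
ROC with trapezoidal AUC. Repeated runs are summarised as mean ± sd over
seeds (default 5), and each seed re-draws both the split and the BLS
weights. Wall-clock time is recorded but deliberately excluded from
serialized reports, so identical runs produce byte-identical artifacts.

## The phantom generator

Testing the full pipeline needs labelled volumes with a controllable
effect. `generate_phantom()` builds an ellipsoidal "brain" (semi-axes 0.4 ×
grid, intensity 1 on background 0) containing a central low-intensity
sphere whose radius is `0.15 × severity × effect_size` of the smallest
semi-axis, severity 1/2/3 for NC/MCI/AD — a crude, directionally correct
analogue of ventricular enlargement/atrophy that creates spatially
structured (not merely global) signal for the convolutional backbone. The
whole structure is jittered by up to one voxel (class-independent, so the
effect ordering is preserved), Gaussian noise is added and intensities are
clipped at 0. Phantoms are written at 2 mm spacing by default so the
resampling stage does real work. Subjects can have multiple "scans"
(shared morphology, fresh noise) to exercise grouped splitting.

What the phantoms do **not** emulate: anatomy (no tissue classes or
template), Rician MRI noise, scanner/site effects, or registration errors.
Passing phantom tests therefore demonstrates that the implementation
learns a spatial class effect end to end — not that clinical-grade
accuracy transfers to real MRI.

At `effect_size = 1`, `noise_sd = 0.05`, a logistic read-out on mean
intensity alone reaches ≥ 95% accuracy, so downstream accuracy targets are
attainable rather than vacuous; at `effect_size = 0` the generator is an
exact null (class labels have no influence on the data).

## Problem sizes used in the tests

The test-suite study conditions are chosen to exercise every contract at
desk scale: phantoms at 16³–32³ voxels with 40 subjects per class, a
reduced-width backbone (stem 8, module outputs 32/64) for pipeline runs,
and the full 224×224×128 spatial grid with reduced internal widths (but
the full 256/512 output channels) for the architecture shape checks. The
solver, convolution and metric components are validated against
independent dense/nested-loop oracles at full precision.

One capacity note: a closed-form ridge learner with node count comparable
to the sample count *interpolates* — on permuted labels its training
accuracy reflects memorisation, not signal. The permuted-label sanity
check therefore uses a deliberately low-capacity configuration (100
identity feature nodes, whose rank is capped by the 20 input dimensions,
20 tanh enhancement nodes, and a large λ in the heavy-shrinkage regime).
Even then the permuted-label training accuracy floors near 0.55 rather
than 0.50: the true class split dominates the top variance direction of
the state matrix, and the magnitude of its alignment with a random
permutation is always positive. The check asserts the mean over ten
permutations stays within ten points of chance.

## Numerical choices and degenerate inputs

* Ridge solves use `solve()` on the primal or dual normal equations,
  whichever is smaller; the explicit dense inverse exists only in test
  oracles. Comparisons against that oracle use overdetermined instances,
  since at λ = 1e-8 the explicit formula is well-conditioned only at full
  column rank.
* Argmax prediction breaks ties toward the first class, deterministically.
* Constant volumes scale to all-`lo`; empty pooling windows cannot occur
  ("same" padding guarantees ≥ 1 in-bounds voxel).
* Average pooling excludes padded voxels from its divisor, so constants
  are preserved exactly.
* All randomness flows through explicit seeds via a private RNG scope that
  restores the caller's RNG state; identical seeds and configs give
  bitwise-identical models, reports and archives.

## Limitations

* The backbone is random: features are generic contrast statistics, not
  disease-tuned representations. A hook accepts externally supplied
  weights, but training them is out of scope by design.
* Incremental node-expansion variants of BLS are not implemented; the
  model is re-solved per configuration (cheap, since features are cached
  across grid points and the solve is closed-form).
* Metrics are reported at the image level; subject-level aggregation is
  available by grouping the exported per-image predictions.
* The phantom generator's caveats above bound what the test suite can
  claim about clinical data.
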