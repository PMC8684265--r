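---
title: "Local-reference semantic codes for breast-ultrasound lesion classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local-reference semantic codes for breast-ultrasound lesion classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrscnet)
```

## The problem and the model

Breast-ultrasound (BUS) computer-aided diagnosis faces two coupled
difficulties: labeled cases are scarce (biopsy-confirmed labels are hard to
collect), and speckle texture varies strongly between scanners, inflating
the within-class variance that any texture feature has to survive. The
classifier implemented here attacks both with a deliberately small,
patch-level architecture:

1. **Local references.** Sliding-window patches (side $m$) from the
   radiologist-delineated lesion ROI of every labeled training image are
   pooled by class. For each class, a set of prototype patches — $k$ benign
   references $\mu_1,\dots,\mu_k$ and $r$ malignant references
   $\vartheta_1,\dots,\vartheta_r$ — is learned by minimizing the
   class-guided sum of squared distances
   $$\sum_{i=1}^{k}\sum_{x \in M_i} \lVert x-\mu_i \rVert_2^2
     \;+\; \sum_{i=1}^{r}\sum_{z \in B_i} \lVert z-\vartheta_i \rVert_2^2,$$
   where $M_i$ ($B_i$) is the set of benign (malignant) patches nearest to
   reference $i$. Class indicators zero out all cross-class terms, so this
   is exactly two independent Lloyd (k-means) iterations whose centroids
   keep their class tags. References are prototypes of *common local tumor
   structures*; averaging pools out scanner-specific speckle realizations.

2. **Learned similarity.** A convolutional backbone $f_\varphi$ — three
   blocks of 3×3 convolution with 32 filters, batch normalization, ReLU and
   2×2 max pooling, closed by global average pooling to a 32-vector — maps
   both patch and reference through *one tied parameter set*. The two
   features are combined by elementwise absolute difference
   $v = \lvert f_\varphi(x) - f_\varphi(l)\rvert$ and scored by a relation
   head: two ReLU fully connected layers and a 2-unit softmax whose
   "related" probability is the similarity $s \in [0,1]$. Because $v$ is
   symmetric, $s(x,l) = s(l,x)$ holds by construction.

3. **Semantic code.** For each patch the similarity vector
   $F_{ls} \in [0,1]^{k+r}$ (benign references first) is condensed to one
   bit: $p$ is the mean over the benign block, and $B = 1$ iff
   $p \ge 0.5$ — bit 1 reads "this patch looks benign". The image's bits,
   in patch order, form its semantic code.

4. **Self-matching.** The label is a training-free vote:
   $l = \tfrac{1}{n}\sum_k B_k$, benign iff $l > 0.5$. The tie $l = 0.5$
   goes to malignant — the conservative reading for a cancer screen, and
   the strict reading of the decision rule. Note the two thresholds are
   deliberately asymmetric: the bit threshold is inclusive
   ($p \ge 0.5 \to 1$), the vote threshold exclusive.

Throughout, **benign is the positive class** (TP = benign called benign).
This mirrors the clinical-tables convention of the source setting and
inverts the more common "positive = disease" convention; the evaluation
module documents it prominently.

## Training the relation head

The similarity module is trained on sampled (patch, reference) pairs with a
*class-agreement* label: 1 when the patch's class equals the reference's
tag, 0 otherwise, balanced 50/50 per epoch. The loss is 2-way
cross-entropy on the relation output, optimized by SGD with momentum —
learning rate 0.001, momentum 0.9, weight decay $10^{-6}$ (weights only;
biases and batch-norm parameters are not decayed). References are frozen
during training: clustering strictly precedes similarity learning in the
pipeline, and no joint refinement is attempted.

The pair-label construction is the natural reading of references "carrying
class information", but it is a design choice of this package: nothing
forces the supervision to be class agreement, and alternatives (e.g.
patch-identity pairs) would change what the similarity means. The choice is
isolated in `make_pairs()`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `m` | 16 px | patch side; small enough to be "local", large enough for 3 pooling stages (minimum 8) |
| `stride` | `m/2` = 8 px | 50% overlap; multiplies patch counts on small datasets |
| `roi_min_frac` | 0.5 | a patch belongs to the lesion when at least half its pixels are inside the delineated boundary |
| `k`, `r` | 25 each | references per class; the method's own tuning curve peaks around 50 total on real data, tests use 10+10 |
| `hidden` | 64, 64 | relation-head widths (unstated in the source; config-overridable) |
| `batch_size` | 64 | pairs per SGD step |
| `epochs` | 30 | training epochs |
| `pairs_per_epoch` | 1024 | freshly sampled balanced pairs per epoch; a convergence pilot on the phantom task showed pair accuracy saturating within a few epochs at this size, so larger values buy nothing here |
| `train_fraction` | 0.8 | stratified train share, the 80/20 protocol |

Every stochastic stage (initialization, pair sampling, splitting, phantom
synthesis) takes an explicit seed; sub-seeds are derived deterministically
from one master seed, so a run is reproducible byte-for-byte from its
config.

## Numerical choices

* **Convergence test.** Lloyd iterations stop when the *assignment* is
  unchanged between consecutive rounds (or after `max_iter = 300`).
  Testing assignments rather than floating-point centroid equality avoids
  a numerically fragile stop rule; the objective is non-increasing across
  iterations either way (asserted as a property test over 100 seeded
  instances).
* **Ties.** Patch-to-reference assignment ties break to the lowest
  reference index; max-pooling ties take the first window element. Both
  rules are deterministic and documented rather than platform-dependent.
* **Empty clusters.** A reference whose cluster empties is replaced by the
  in-class patch farthest from its nearest current reference — the classic
  k-means repair; no reference is ever NaN.
* **Degenerate inputs.** Zero extracted patches (over-restrictive ROI) is
  an explicit error naming the knobs to loosen; a metric with an empty
  denominator is reported `NA` and listed in an `"undefined"` attribute,
  never silently coerced to 0.
* **Similarity output.** The softmax head has 2 output units and the
  similarity is the "related" unit's probability: a softmax over a single
  scalar would be degenerately constant, so the 2-way relation output is
  the standard construction. A zero final layer therefore yields exactly
  0.5 — a useful calibration anchor used by the tests.
* **AUC.** Rank-based (Mann–Whitney) with half-credit ties, computed on
  the *continuous* benign-likelihood score (mean pre-binarization $p$).
  The hard decision always comes from the bit vote; the continuous score
  exists only because an ROC area on near-discrete vote fractions is
  ill-behaved. This score is a package addition, clearly separated from
  the decision path.
* **Batch normalization.** Training uses batch statistics (running
  averages updated with decay 0.9); all inference — including encoding the
  fixed references — uses the stored running statistics, so eval-mode
  outputs are deterministic.

## What the synthetic phantom emulates — and what it does not

Real benign lesions tend to show smoother internal echo texture than
malignant ones, and malignant margins are more irregular. The generator
reproduces exactly these two axes:

* **Fully developed speckle** as the squared magnitude of a
  Gaussian-smoothed circular complex Gaussian field; the smoothing length
  is the class's knob (benign 3.0 px > malignant 1.2 px, so the benign
  class is the smooth one). This is the standard statistical speckle
  emulation — no acoustic physics, no device model.
* A central **hypoechoic lesion** whose interior intensity is scaled by
  $1 - 0.45$, bounded by a radius-perturbed closed curve; the perturbation
  amplitude is 0.25 for malignant margins and one fifth of that for benign
  ones. The mask is emitted as the ROI.
* Additive Gaussian sensor noise (sd 0.02), 8-bit PNG quantization, and a
  seeded stratified 80/20 split column in the manifest.

Class separation deliberately lives in *texture statistics*, not mean
brightness, so the classifier cannot pass by thresholding intensity; an
optional `class_mean_shift` exists for fast smoke tests only. What the
phantom does **not** contain: scanner-specific texture families (the
intra-class variance problem the references exist for), posterior acoustic
shadowing/enhancement, out-of-ROI anatomy, annotation noise, or any
realistic prevalence. Passing the end-to-end tests therefore shows the
pipeline *can learn the texture contrast it was pointed at under the
stated protocol* — it is no evidence of clinical performance.

## Problem sizes used by the tests

The end-to-end protocol mirrors the 80/20 evaluation convention: 100
images per class (160 train / 40 test), $m=16$, $k=r=10$, 30 epochs, three
seeds, asserting accuracy and AUC $\ge$ 0.90 on at least two of three.
Property tests run the clustering oracle on $\le 10$ one-pixel patches
(where exhaustive partition enumeration is the gold standard), similarity
contracts on $\ge 1000$ random draws, and metric exactness on all
$2^8$ four-image confusion tables. These sizes are the package's chosen
desk-scale protocol; the fitted pipeline itself has no size ceiling beyond
memory.

## Known limitations

* Reference learning is a single seeded Lloyd run, as the method
  prescribes (random initialization, iterate to a fixed assignment). Like
  any single-start k-means it can converge to a local minimum of the
  objective; on small unstructured instances this happens for a
  substantial fraction of seeds — the identical behavior is reproduced by
  `stats::kmeans(algorithm = "Lloyd")` started from the same sampled
  centers, which the test suite asserts. The package deliberately does not
  add a best-of-restarts wrapper, since the fitting operation is defined
  with one seed; callers wanting restarts can compare
  `$meta$objective` across seeds themselves.
* The clustering operates on raw flattened pixels, as the centroid-average
  update implies; references are not registered or contrast-normalized, so
  they blur when a cluster mixes misaligned structures.
* With both 0.5 thresholds fixed, heavily imbalanced reference sets (k far
  from r) bias the benign-block mean; the package exposes but does not
  calibrate these thresholds.
* The self-matching vote weights all patches equally; spatial structure
  within the lesion is ignored by design.
* `simulate()`/`residuals()` methods are not provided: a patch-vote
  classifier has no natural data-generating or residual structure at the
  image level.
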