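---
title: "SwarmSeg: models, design choices, and limitations"
author: "SwarmSeg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SwarmSeg: models, design choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SwarmSeg)
```

SwarmSeg compares six intensity-based segmentation pipelines for
bright-ROI medical imagery under one shared preprocessing front-end and
one evaluation suite. This vignette is the package's own account of the
underlying models, the tunable parameters and why their defaults are what
they are, what the synthetic phantoms do and do not emulate, and the
numerical conventions the implementation fixes.

## The segmentation problem

A 2-D 8-bit image contains one compact region of interest (a tumor, a
blast nucleus, a lesion, a nodule) that after enhancement is brighter than
its background. Segmentation must produce a binary foreground mask. The
six scenarios are: fuzzy C-means (FCM), K-means, each hybridized with
particle swarm optimization (PSO) of the cluster centers, and each refined
by a small convolutional network (CNN).

## Shared preprocessing

**Grayscale.** Color input is collapsed with the luma weights
$G = 0.3R + 0.59G + 0.11B$, rounded half-up. The weights sum to 1, so the
8-bit range is preserved.

**Clip-limited adaptive histogram enhancement.** The image is divided into
a `tileRows × tileCols` grid (default 8 × 8). For each tile the `nBins`
(default 256) histogram is clipped at
$\text{clipMultiplier} \times \bar h$, where
$\bar h = \text{tile pixels}/\text{nBins}$ is the average bin occupancy
(`averagePixels()`); the clipped excess is redistributed uniformly, and
the clipped CDF defines a monotone mapping onto $[0, 255]$. Per-pixel
output bilinearly blends the four surrounding tile-center mappings, the
standard construction that avoids tile-boundary seams. The default
multiplier 4 is the conventional compromise: 1 disables enhancement
(uniform mapping), very large values approach plain histogram
equalization, which over-amplifies noise in near-constant tiles. With a
single region the mapping is a pure monotone function of the input value;
with tiling, two pixels of equal value at different positions may
legitimately map differently.

**Hair removal.** Dermoscopic hair is dark, thin (1–3 px), and
curvilinear. Detection is a morphological blackhat (closing with a 7-px
disc minus the image) thresholded by Otsu's method. Otsu alone splits any
unimodal noise distribution, so two guards make hairless-but-noisy images
a near-no-op: an absolute response floor (10 intensity units) and a
noise-adaptive floor of 5 estimated noise standard deviations (robustly
estimated from the median-filter residual). Detected pixels are dilated by
one pixel and filled by iterative neighborhood diffusion; everything
outside the dilated mask is untouched. Masks never pass through hair
removal.

## Clustering cores

Both cores operate on per-pixel grayscale intensity only — a 1-D feature
space matching the intensity-domain formulation of the objectives; spatial
features are deliberately out of scope. Internally, iterations run on the
image's distinct intensity values weighted by pixel counts, which is
algebraically identical to per-pixel updates for 8-bit data and roughly
two orders of magnitude faster; memberships and labels are expanded back
to pixels afterwards.

**FCM** minimizes
$J(\mu, C) = \sum_i \sum_j \mu_{ij}^k (x_i - C_j)^2$ with fuzziness
$k > 1$ by alternating the closed-form membership update and the weighted
center mean. A pixel coinciding with a center takes crisp membership there
(the hard-assignment limit; the raw formula divides by zero). Convergence
is declared when the largest center movement falls below `tol` (default
1e-4) or after `maxIter` (default 100) iterations. Defaults $k = 2$,
conventional for intensity clustering. The recorded objective trace is
non-increasing because each half-step minimizes $J$ in one block of
variables; the final trace entry is evaluated at the returned
(memberships, centers) pair, so the stored objective is exactly consistent
with the stored partition.

**K-means** is Lloyd iteration with the same stopping rule. An empty
cluster is re-seeded to the intensity farthest from the vanished center —
a deterministic, standard repair. Assignment ties break toward the
lower-indexed center. Lloyd fixed points satisfy nearest-center assignment
with centers equal to cluster means; they are not in general optimal
against single-point relabelings (that is Hartigan's stronger criterion),
which is why the test suite asserts the fixed-point conditions plus global
optimality on small instances where exhaustive search is feasible.

**Initialization** for both: `nClusters` *distinct* pixel intensities
drawn from the seeded RNG with probability proportional to pixel
frequency. Requesting more clusters than distinct intensities (or
clustering a constant image) raises a degenerate-input error.

**Mask extraction.** The foreground is the cluster with the brightest
center (fuzzy partitions take per-pixel argmax membership first); a config
flag selects the darkest cluster instead for dark-on-bright modalities.
The largest connected component is kept and its holes filled, reflecting
the single-ROI assumption. Cluster relabeling cannot change the emitted
mask, and an empty selection warns rather than errors.

## PSO hybrids

A particle's position is a candidate center vector, clamped to
$[0, 255]^D$; velocity follows the standard update
$V \leftarrow wV + c_1 r_1 (\text{pbest} - P) + c_2 r_2 (\text{gbest} - P)$
with fresh uniform draws per component, velocity clamped to the intensity
range. Defaults $w = 0.72$, $c_1 = c_2 = 1.49$ (constriction-equivalent
values), 30 particles, 100 iterations. The fitness is the clustering
objective itself — FCM's $J$ or the within-cluster sum of squares — the
only quantity the objective formulation supports. Positions with
components closer than 1e-9 receive the worst-possible finite fitness
(total pixel count × 255²) instead of an exception, so the swarm can move
off the degenerate plateau. Position components are sorted after every
move: the objective is label-permutation invariant, and sorting removes
the resulting plateaus from the search space. After the swarm finishes,
the global-best centers seed a final FCM/Lloyd refinement; since the first
refinement half-step reproduces the swarm's objective value exactly,
refinement can only improve on the swarm's optimum.

## CNN refinement

No deep-learning runtime is required: the refiner is a deliberately small
fully-convolutional network implemented in matrix algebra with
hand-written backpropagation. Architecture: 3×3 convolutions
2 → 8 → 16 → 1 with dilations 1, 2, 4 (receptive field 15 px,
≈ 1.3k parameters), ReLU activations, sigmoid output. The two input
channels are the preprocessed grayscale image scaled to $[0,1]$ and the
clustering proposal mask — making the network a genuine *refiner* of the
clustering stage and keeping it modality-agnostic. The loss is
$0.5\,(1 - \text{softDice}) + 0.5\,\text{BCE}$, the standard combination
for imbalanced masks. Optimization is Adam (default learning rate 0.02,
one image per step, 10 epochs) with a fixed 20 % validation split;
training, initialization and shuffling all derive from one seed, so runs
are reproducible (given a fixed BLAS thread count). Checkpoints round-trip
bit-exactly through `saveRefiner()`/`loadRefiner()`.

The network is small because its job is local: clean up boundary errors,
speckle-induced fragments, and ramp-induced bias in the proposal, guided
by the image. It is emphatically not a general segmentation model, ships
no pretrained weights, and makes no claim of performance on real medical
data.

## Phantoms: what they emulate, and what they do not

`generatePhantom()` renders elliptical blobs (random center, semi-axes
10–22 % of the frame, rotation; rejected if they leave the frame) at a
foreground level on a background level, then corrupts: a linear
left-to-right illumination ramp (fraction `illuminationGradient` of full
scale, emulating uneven lighting), additive Gaussian noise, and optional
dark cubic-Bézier hair curves 1–3 px wide drawn over the image only —
never into the truth mask, which records blob interiors before
corruption. Noise variates are drawn even at σ = 0 so that blob and hair
placement are identical across noise settings of the same seed. Defaults:
256 × 256 canvas, one blob (single-ROI modalities), levels 180/60, σ = 15,
ramp 0.15, no hair. Modality presets (`phantomPreset()`) vary these —
e.g. `skin` adds 5 hairs and a 0.3 ramp; the preset intensity statistics
are the package's own choices and are not claimed to match any real
dataset. Benchmark-set seeds derive from the master seed by a counter
scheme, so a sample depends only on its (set, index) coordinates.

Phantoms exercise exactly the failure modes the methods address —
bimodal-but-overlapping intensity distributions, uneven illumination,
occluding curves — with exact ground truth and no downloads. They do not
emulate anatomy, texture, partial-volume effects, multi-object scenes, or
3-D structure; passing the phantom benchmark demonstrates algorithmic
correctness and the relative behavior of the six methods at desk scale,
not clinical-grade accuracy on real data.

## Evaluation

Confusion counts treat foreground as positive. Scores: precision, recall,
F-measure, accuracy % and error % (complements), MCC, Dice, Jaccard
(`dice = 2J/(1+J)` by construction). Degenerate 0/0 ratios return 0 by a
logged convention, and a zero MCC denominator yields 0, keeping
aggregation total. Elapsed time is measured around the segmentation call
only (never I/O) and is reported but never asserted — it is
hardware-dependent. Aggregation reports per-image means within each
(method, set size) group — per-image means rather than pooled pixels, so
images contribute equally regardless of ROI size — and pivots methods to
columns in the classic sweep-table layout.

## Problem sizes and numerical conventions

The test suite and the acceptance script run at desk scale chosen to keep
a full run in minutes on one CPU: 96 × 96 phantom canvases for benchmarks
(32–64 px for unit tests), 30-image evaluation sets, 50-image CNN training
sets, 10 epochs. The study conditions for the noisy benchmark are noise
σ = 25 and illumination drop 0.3.

Conventions fixed by the implementation:

- every intensity-valued formula rounds half-up (`floor(x + 0.5)`) to an
  integer 8-bit level; outputs clip to $[0, 255]$;
- clustering assignment ties break toward the lower-indexed center;
  membership at a center is crisp; duplicate centers are an error in
  `fcmMembership()` but a finite penalty inside PSO;
- convergence tolerances: `tol = 1e-4` on center movement, membership
  row sums exact to 1e-9;
- all randomness flows through explicit seeds; library calls restore the
  caller's RNG state; derived seeds stay below $2^{31}$.

## Known limitations

- Feature space is 1-D intensity; methods cannot separate regions of
  equal brightness (by design, matching the objective formulations).
- The single-ROI post-processing (largest component) is wrong for
  multi-lesion images; disable with `postprocess = FALSE`.
- The CNN refiner is tiny and trained on phantoms; it transfers the
  *procedure*, not learned weights, to real data.
- PSO on an already-bimodal histogram often converges to the same optimum
  as plain FCM/K-means — its benefit shows on harder, multi-modal
  intensity distributions.
- Wall-time comparisons are indicative only.
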