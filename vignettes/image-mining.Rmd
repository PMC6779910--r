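---
title: "Whole-image mining with imagemine: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-image mining with imagemine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imagemine)
```

`imagemine` treats an image set as a point cloud: an embedding backend maps
every image to a fixed-length feature vector, and all subsequent analysis —
distances, hierarchical clustering, planar projection, classification — is
ordinary multivariate statistics on those vectors. This vignette records
how each stage is defined, which parameters matter, and why the design
decisions that were genuinely open were settled the way they were.

## The embedding model

Transfer-learning embedders reuse a convolutional network trained on a
large generic image corpus: the activation vector of the penultimate layer
(2048 nodes for InceptionV3) serves as a general-purpose description of a
new image, even one from a domain the network never saw. The package keeps
such deep backends behind a deliberately small adapter contract — *given a
decoded image resized to the backend's input size, return the activation
vector from a locally supplied model file* (`register_backend_adapter()`).
No network weights ship with the package, no hosted embedding service is
supported, and none of the package's own tests exercise a deep model:
whether a particular runtime reproduces a particular network is a property
of that runtime, not of this package.

What the package does ship is the `filterbank` backend, a deterministic
hand-crafted profiler in the tradition of classical feature pipelines. The
image is bilinearly resized to 128×128, converted to luminance
($0.299R + 0.587G + 0.114B$), and summarized by 96 numbers in a fixed
order:

| block | length | content |
|---|---|---|
| luminance histogram | 32 | equal-width bins on $[0,1]$, normalized to sum 1 |
| orientation histograms | 16 + 16 | gradient-magnitude-weighted, at full resolution and after 2× block downsampling; all-zero for constant images |
| radial profile | 24 | mean luminance over equal-width annuli from the center to half the diagonal |
| scalars | 8 | mean, population sd, skewness, excess kurtosis, histogram entropy (nats), edge density (fraction of pixels with gradient magnitude > 0.1), ring contrast (max annulus mean − mean annulus mean), normalized centroid offset |

Gradients are central differences with replicated borders. On a constant
image the sd is zero and skewness/kurtosis are defined as 0; the
orientation blocks are all-zero rather than ill-defined. No normalization
is applied to embedding vectors before downstream use — the default cosine
distance is scale-invariant, and any rescaling would silently change
euclidean analyses; this is documented behavior, not an oversight.

Embedding caches (optional) key each vector by the SHA-256 of the file
bytes plus the backend name, so a cache can never serve a vector for an
edited image, and cached vectors are bit-identical to fresh ones.

## Distances and clustering

Cosine distance is the package default throughout, with euclidean as the
alternative. Agglomerative clustering runs the Lance–Williams recurrence
directly on the supplied dissimilarities. Two conventions had to be fixed
where common practice is silent:

- **Ward on non-euclidean dissimilarities.** Ward linkage is
  variance-exact only for squared euclidean distances. Pairing it with
  cosine dissimilarities — standard practice for embedding vectors — is a
  heuristic; the package applies the Ward coefficients to the raw
  dissimilarities as given (no squaring or rooting), which matches
  `stats::hclust(method = "ward.D")`. Heights may occasionally invert on
  such inputs; the merge sequence remains well defined, and Newick export
  tolerates the resulting negative branch lengths.
- **Tie-breaking.** At equal merge dissimilarity the pair with the
  smallest (min node id, max node id) merges first. Ties are measure-zero
  for real embeddings but must be deterministic for byte-reproducible
  artifacts.

Dendrogram nodes are numbered leaves `0..n-1`, internal nodes `n..2n-2`,
so a branch is addressable by a single integer (`select_branch()`), and a
flat cut (`cut_dendrogram()`) labels components in order of first
appearance along the table. Newick branch lengths are parent height minus
child height, leaves at height zero.

## Planar projection

`mds_project()` is metric MDS by SMACOF majorization: from a classical
scaling start (double-centered Gram eigendecomposition; random start
available with a seed), the Guttman transform is iterated, which provably
never increases the raw stress $\sum_{i<j} (d_{ij}(X)-\delta_{ij})^2$.
Iteration stops when the relative stress decrease falls below `tol`
(default $10^{-6}$) or at `max_iter` (default 300). A metric (rather than
non-metric) formulation was chosen because it is directly testable:
configurations that embed exactly in the plane — an equilateral triangle, a
unit square — must reach stress ~0, and do. The all-zero distance matrix
is accepted and yields all points at the origin with zero stress rather
than an error; output dimensionality is fixed at two, since the projection
exists to be looked at.

## Classification and evaluation

The classifier is multinomial (softmax) logistic regression with an L2
penalty of strength $1/C$ on the weights, intercepts unpenalized, fitted
by glmnet's ridge path with `standardize = FALSE` and
$\lambda = 1/(nC)$ — the per-observation scaling under which duplicating
the data set leaves the optimum unchanged. Defaults $C = 1$,
`max_iter = 1000` mirror common library defaults and are recorded in every
saved model and metrics report. Two degenerate inputs are handled in
closed form: a class with a single example (the data are replicated once;
the per-observation penalty scaling makes this a no-op on the optimum) and
all-constant features (intercept-only maximum-likelihood model, giving the
class-frequency probabilities).

Evaluation is stratified $k$-fold cross-validation (default $k = 10$,
shuffle seed 0): within each class the shuffled members are dealt
round-robin with a running offset across classes, so per-class fold counts
are within one of proportional and overall fold sizes stay balanced. Every
sample is predicted exactly once by a model that never saw it. From the
out-of-fold predictions the package reports CA, one-vs-rest
precision/recall/F1 per class, macro and support-weighted F1, and macro
one-vs-rest AUC computed from the out-of-fold probabilities. Because
published tables often quote a single "F1" without defining the average,
the headline `F1` field is the positive-class F1 for binary problems
(positive = the later class in sorted order) and the weighted F1 for
multiclass — with all variants always reported alongside, so any
convention can be checked. `select_cell()` returns the images behind one
confusion-matrix cell, the scriptable form of clicking the cell.

## What the synthetic fixtures emulate — and what they do not

Real phenotyped image sets (the package's motivating use case) cannot ship
with the package, so `generate_ring_diffuse_set()` and
`generate_aggregate_set()` synthesize labelled sets with the *class
structure* of two real studies:

- **ring_diffuse** — a bright nuclear disc (radius 0.35 of the image side,
  jittered center) on a dark field. The `SN` class concentrates extra
  intensity in a thin perinucleolar annulus (Gaussian radial profile,
  center radius 0.15, width 0.03 of the side); the `NSN` class disperses
  the *same total intensity budget* into 6–10 broad Gaussian foci
  (sd 0.08 of the side) in the outer nucleoplasm, clear of the annulus.
  Foci are broad and outward-placed by design: broad, so the dispersed
  class is homogeneous (individual placements average out rather than
  dominating the radial profile); outward of the annulus, because
  "not surrounding the nucleolus" is precisely what distinguishes the
  phenotype — and this keeps the annulus band measurably dimmer than the
  rest of the disc in every dispersed image, not just on average.
- **aggregates** — three morphologies: `STR` (3–5 bright random-walk
  polylines ~2 px wide), `LAG` (20–30 small discs, radius 2–4 px),
  `TAG` (2–4 large discs, radius 0.12 of the side), so connected-component
  structure separates the classes by construction.

Both generators draw all per-image randomness from one seeded stream in
file order and write 8-bit grayscale PNGs, so a fixture spec reproduces
byte-identical files anywhere. Defaults — image side 128 px, noise sd
0.05, 40 images per class for the end-to-end checks — are the package's
chosen study conditions: 128 px matches the filter bank's working
resolution, sd 0.05 is clearly visible noise on a [0,1] scale without
drowning the structure, and 40 per class is a realistic size for a curated
phenotype study while keeping ten-fold stratification comfortable.

What passing tests on these fixtures establishes: the pipeline's stages
compose correctly, preserve row alignment, and recover a class signal that
is genuinely present in pixel space. What they do not establish: anything
about real microscopy — no optics, no uneven illumination, no channel
bleed-through, no within-class biological variability beyond placement
jitter. Accuracy numbers on fixtures are properties of the fixtures.

## Problem sizes and numerical tolerances

The shipped test suite runs the full synthetic pipeline at 40 images per
class (128 px), checks the clustering implementation against a naive
reference agglomerator on over a hundred random 5–8-point instances for
all four linkages, and verifies SMACOF monotonicity on random inputs and
exactness (raw stress below $10^{-6}$) on planar-embeddable
configurations — sizes chosen so the whole suite completes in well under a
minute on one core while still exercising every contract end to end.
Distance computations are checked against a double-loop oracle at
$10^{-12}$; probability rows must sum to 1 within $10^{-9}$.

## Known limitations

- Quadratic memory in the number of images (dense distance matrices): the
  tool targets smaller image sets, not archives.
- Ward-on-cosine is heuristic (above); for variance-exact Ward use
  euclidean distances.
- Deep backends are adapters only; reproducing a specific published
  embedding requires the corresponding model file and runtime.
- Whole-image profiling only: no segmentation, registration, channel
  arithmetic or object-level measurements.
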