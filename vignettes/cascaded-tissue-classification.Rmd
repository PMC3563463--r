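---
title: "Cascaded classification of H&E tissue images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascaded classification of H&E tissue images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histocascade)
```

# The problem

Prostate biopsy tissue is graded by its architecture: the arrangement of
cell nuclei and glands distinguishes benign epithelium (BE) and stroma (BS)
from Gleason grade 3, 4 and 5 cancer (G3, G4, G5), while two confounder
patterns — atrophy (AT) and prostatic intraepithelial neoplasia (PIN) —
mimic cancer and are a major source of diagnostic error. `histocascade`
implements an automated pipeline that classifies a tissue region of
interest (ROI) into one of these seven classes, and compares three
multi-class strategies:

* **OSC** (one-shot): a single multi-leaf decision tree assigns one of the
  seven labels directly.
* **OVA** (one-versus-all): seven independent binary trees, each scoring
  one target class against the pooled rest; each task is evaluated on its
  own, so errors in one class do not affect the others.
* **CAS** (cascaded): six binary decisions over nested class groups —
  cancer vs non-cancer at the root, then {G3,G4} vs G5 and
  confounder {AT,PIN} vs normal {BE,BS}, then singletons. Each node gets
  its own independently trained classifier, so every decision faces two
  relatively homogeneous groups.

The package's claim of interest is directional: when classes form nested
groups of varying similarity, the cascade attains per-class positive
predictive value at least as good as OSC and OVA.

# Pipeline

## Stain separation

An H&E image mixes two dyes: hematoxylin (nuclei) and eosin
(cytoplasm/stroma). Per Beer–Lambert, optical density is linear in stain
amount, so with `a = -log10(max(I, 1) / I0)` per channel and a normalized
3×3 matrix `M` of per-stain OD color vectors, the per-pixel stain amounts
solve `C = a M^{-1}`. The base of the logarithm is a convention (OD is
conventionally base 10; results are invariant to the base up to a global
scale), and intensities are clamped one level above zero so saturated
pixels map to the finite ceiling `log10(I0)`. The default `M` uses the
widely published H&E OD vectors with the residual row completed by the
normalized cross product; any matrix can be supplied via config. The
hematoxylin plane of `C` (clipped at zero) is the nuclear-density image.

## Nuclei detection

Centroids come from a classical watershed chain: Otsu binarization of the
hematoxylin plane (256-bin histogram, foreground on the stain-dense side),
the exact Euclidean distance transform relative to the 8-connected exterior
boundary, and a flood of the negated distance map from its regional maxima.
Numerical choices that the procedure leaves open were fixed as follows:

* maxima are 8-connected regional maxima; equal-valued plateaus collapse to
  a single marker at the plateau centroid;
* markers closer than `min_distance` (default 5 px) merge, keeping the
  member with the largest distance value — this suppresses
  over-segmentation from discretization ridges;
* flooding pops pixels in order of decreasing distance with FIFO
  tie-breaking, so segmentation is deterministic;
* segments below `min_area` (default 30 px²) are discarded, curbing the
  false-positive specks that threshold-based detection produces;
* coordinates are 1-based `(row, col)` with pixel centers at integers, the
  R convention.

## Feature suites

**Architecture (48):** Voronoi tessellation (cells clipped to the image
rectangle so areas sum to the image area), its dual Delaunay triangulation,
the MST on the Delaunay edges, and density statistics. Pools of cell areas,
chord lengths, perimeters, triangle areas/perimeters and MST branch lengths
are reduced to mean, population standard deviation, *disorder*
`1 - 1/(1 + std/mean)`, and min/max ratio; density counts neighbors within
radii 10–50 px and mean distances to the nearest 3/5/7 neighbors, each
reduced to mean/std/disorder. Conventions worth noting: "chord length" is
defined as all pairwise distances between a cell's vertices; the k-nearest
distance feature uses the mean of the k distances; population (divide-by-n)
standard deviations are used everywhere so the disorder statistic behaves
at n = 1; neighbor circles include points exactly at the radius.

**Texture (540):** per pixel on each of the hue, saturation and intensity
planes (hexcone hue/saturation, intensity `(R+G+B)/3`, all rescaled to
0–255): 15 first-order statistic images (window mean/median/std/range,
four Sobel orientations, Kirsch N/NE/E compass responses, central-difference
gradients, their difference, and the diagonal derivative; 3×3 windows,
reflected boundaries), 21 co-occurrence feature images (a symmetric,
normalized 256-level GLCM accumulated over the four distance-1
displacements inside a 9×9 window; the formula sheet is documented in
`src/glcm.cpp`), and a 12-filter Gabor bank (frequency shifts κ ∈ {5, 9}
crossed with six orientations ε·π/6; real and imaginary responses). Every
feature image is aggregated by mean, population std, and the center of the
most populated of 256 equal-width histogram bins (ties to the lowest bin).
That yields 3 × (15+21+24) × 3 = 540 features: 135 first-order,
189 co-occurrence, 216 Gabor.

Gabor details deliberately fixed here: κ is read as cycles across the
kernel width (a literal κ = 5 px⁻¹ carrier would alias); kernels are 17×17
(half-width 8) with σx = σy = 4 and zero-mean-adjusted real parts; the
axis transform is implemented exactly as the printed
`y' = y cosθ + x sinθ` with a `proper_rotation` switch for the conventional
rotation (with σx = σy the envelope differs only for oblique θ).

## Classification and ranking

Each binary task uses a CART-style decision tree with entropy
(information-gain) splits, `cp = 0` (no cost-complexity pruning),
minimum leaf 2 — the closest open analogue to the C5.0 learner, with
hyperparameters exposed. Evaluation is per class from TP/TN/FP/FN:
`ACC = (TP+TN)/total`, `PPV = TP/(TP+FP)`, `NPV = TN/(TN+FN)`; an undefined
ratio is excluded from averaging and counted. Cross-validation is
stratified 3-fold, reshuffled over 20 trials (trial `t` seeds with
`seed + t`); stratification guarantees every class is present in every
cascade training fold.

Feature ranking uses discrete AdaBoost over single-feature threshold stumps
(both polarities searched; ε clamped to `[1e-10, 0.5 − 1e-10]`;
α = ½ ln((1−ε)/ε)). A feature selected at several iterations accumulates
its α's; weights are summed across trials and the final ranking is sorted,
so reported weights are non-increasing in rank by construction (plain
AdaBoost does not guarantee α_t > α_{t+1} iteration-wise). Ties break
lexicographically by feature name.

# The synthetic tissue generator

Clinical slide collections are proprietary, so the package ships a
generator whose ground truth makes every stage testable. Nuclei are
rendered as 2D Gaussian hematoxylin-density blobs (sd = radius/2 — smooth
OD surfaces give the watershed realistic basins) over an eosin background
with a smooth multiplicative field and white noise; densities are pushed
through the forward Beer–Lambert model of the configured stain matrix and
quantized to 8-bit RGB. Noise is applied in stain-density space (sd
`texture_noise_sd/255`) and the post-noise density maps are stored in the
ground truth, so deconvolving a generated image with the same matrix
recovers the planted density exactly (to 1e-6 before quantization).

Arrangements mimic the tissue morphologies: `gland_ring` places nuclei on
jittered circles (radius 13 px), `dense_random` is unconstrained uniform,
`dispersed`/`sparse_random` use rejection sampling with minimum center
distance 1.2 × radius (configurable; the detection-evaluation specs use
2.8 so planted nuclei never overlap). Ring packing relaxes its ring-center
spacing progressively rather than failing when many glands must fit.
Counts are Poisson around the class mean, floored at 8 so the spatial
statistics (which need ≥ 8 points) are always defined.

The class defaults were chosen once, before any evaluation, to encode the
group hierarchy on the numeric parameter vector (count, radius mean/sd,
noise, eosin level, z-scored across classes): cancer classes are dense and
eosin-poor with G3/G4 close and G5 apart; confounders and normals are
sparser and eosin-rich, with within-pair distances (AT–PIN, BE–BS) smaller
than any cancer-to-non-cancer distance. `class_spec_distance_matrix()`
exposes the geometry and the test suite asserts it.

What the generator does *not* emulate: lumen and intra-gland protein,
scanner noise and JPEG artifacts, stain variability between slides, and
nuclear pleomorphism beyond radius jitter. Passing tests therefore
demonstrate the pipeline's mechanics and the relative behavior of the
three strategies under a known hierarchical class structure — not clinical
performance.

# Degenerate inputs and numerical choices

* Constant hematoxylin channels (stain-free tiles) yield an empty centroid
  set with a warning rather than an error.
* Duplicate centroids are deduplicated with a warning before graph
  construction (coincident points break the tessellation).
* Fewer than 4 non-collinear points is a degenerate-geometry error for the
  Voronoi stage; fewer than 8 points is a degenerate-input error for
  density features. When detection on heavily fused tissue (e.g. gland
  rings merging into annular blobs) returns fewer than 8 segments, feature
  extraction retries at finer watershed granularity
  (`min_distance` 3/2/1 with `min_area` 15/8/4) before giving up.
* Disorder is defined as 0 when the mean or the std is 0; min/max ratio is
  1 for an all-zero pool; GLCM correlation is 1 for a zero-variance window;
  the histogram mode of a constant plane is the constant.
* All randomness is seed-scoped: per-image seeds derive from the master
  seed by a counter scheme, and RNG state is restored after generation.

# Problem sizes used by the shipped checks

The test suite exercises the strategy comparison on a 7 × 60-ROI synthetic
cohort of 96 × 96-px tiles (3-fold × 20-trial CV), detection recovery on
40 non-overlapping 128-px tiles, graph features against brute-force
oracles on up to 8-point sets (exhaustive spanning-tree enumeration), and
the deconvolution round trip on 100 random stain matrices. The acceptance
script (`scripts/acceptance.R`) re-runs the same computations at a 7 × 30
cohort. These sizes were chosen so the full evaluation completes in
minutes on a single core while every class contributes dozens of ROIs per
fold.

# Known limitations

* The default stain matrix is a published standard, not a slide-calibrated
  measurement; real slides need their own `M`.
* Watershed on merged nuclear clusters undercounts nuclei (the adaptive
  granularity retry mitigates but does not remove this); architecture
  features on dense cancer classes therefore describe segment geometry
  more than true nucleus geometry — acceptable for discrimination, not for
  counting.
* OVA is scored per binary task by design; the optional fused argmax label
  is provided behind a flag but is not used in the reported comparison.
* The cascade structure is fixed domain knowledge; no data-driven grouping
  is attempted.
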