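---
title: "Distance-field supervision for axon segmentation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-field supervision for axon segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Long-range axons in whole-brain fluorescence microscopy are thin (1–3 voxel
radius), sparsely labeled, and frequently drop to intensities barely above the
background noise. Threshold- or tracer-based reconstruction misses exactly
those weak stretches, and manual repair of the misses dominates annotation
cost. `axonfield` implements a regression-based alternative: instead of a
binary foreground mask, the network learns a *distance field* — a voxel map
that is 1 on the axonal centerline and decays smoothly away from it — and the
predicted field is used either directly (threshold + skeletonize) or as a
contrast enhancement overlaid on the raw image before conventional tracing.

## From skeleton annotation to supervision label

Annotations are SWC skeletons: ordered 3D points with parent links. Label
generation proceeds in three steps (all voxel units, zero-based coordinates,
voxel centers on the integer lattice):

1. **Resampling.** Nodes are linearly interpolated along each parent–child
   edge so adjacent skeleton points are at most `max_spacing = 1` voxel
   apart. Original nodes are never moved.
2. **Region expansion.** The support of the label is the union of open balls
   of radius 3 around every skeleton point: voxel $v$ belongs iff
   $\min_i \lVert v - s_i \rVert < 3$. The inequality is strict as a matter
   of convention (`strict_less` flips it; on the integer lattice the strict
   radius-3 ball contains 93 voxels — squared distances up to 8).
3. **Decay field.** For each in-region voxel $p$, the perpendicular distance
   to the centerline is
   $\mathrm{dist}(p) = \lVert p - s(p) \rVert \,
   \sin(\arccos\langle \widehat{p - s(p)}, \hat u_{s(p)} \rangle)$,
   where $s(p)$ is the nearest skeleton point and $\hat u_{s(p)}$ the unit
   direction from $s(p)$ toward its successor. The label is
   $\exp(-\mathrm{dist}/(2\sigma^2))$, zero outside the region.

Numerical conventions worth stating explicitly:

* The exponent uses the distance to the **first power**. This is deliberate:
  it produces a sharper centerline peak than a conventional Gaussian. A
  `squared_exponent` switch provides the Gaussian variant.
* $\sigma = 2$ voxels by default, giving field value
  $\exp(-3/8) \approx 0.69$ at the region boundary; $\sigma$ is exposed in
  `label_config()`.
* Successor directions: at the tail of a branch the incoming (predecessor)
  direction is reused; at branch nodes the lowest-id child defines the
  direction; a single-node tree falls back to the Euclidean distance;
  $p = s(p)$ gives distance 0.
* Nearest-point ties resolve to the lowest (tree id, node id); each voxel's
  distance is computed against the tree owning its nearest point, and
  overlapping fields from different trees combine by voxel-wise maximum.
* The nearest-point search stamps bounded neighborhoods per skeleton point
  rather than scanning all (voxel, point) pairs; the test suite checks it
  against a brute-force double loop.

## Network and loss

The segmentation network is a 3D U-Net regressor. The reference profile has
six encoder levels with channels doubling 16 → 512, a mirrored decoder with
stride-2 transposed convolutions (kernel 2), and additive residual skip
connections between matching scales; `skip_mode = "concat"` is available
since the fusion style is a genuinely open choice. Each level is two 3×3×3
convolutions, each followed by instance normalization and ReLU. With batch
size 1 (the training default), batch normalization would be degenerate, which
is why instance normalization is used. The output head is a linear 1×1×1
convolution; its output is clamped to [0, 1] at prediction time. During
training the loss is computed on the unclamped output — a hard clamp would
zero the gradient wherever the head saturates on the wrong side.

The loss is a region-weighted sum of four mean absolute errors: over all
voxels; over the weak foreground of the label ($y_g > 3/255$); over the
strong foreground ($y_g > 103/255$); and over the bright region of the
**input image** ($x > 103/255$). The thresholds reference an 8-bit scale, so
all volumes are normalized by their dtype maximum on reading. The three
region terms counter the extreme class imbalance (axonal voxels are a
fraction of a percent of a block), and the input-bright term keeps bright
structures under supervision pressure even where the label is empty. A
region with no voxels contributes 0. Training uses Adam at learning rate
2×10⁻⁴, batch size 1; a single integer seed drives the train/validation
split, initialization, crop positions and data order; the best-validation
parameters are retained.

Training crops patches (default 32³ in the benchmark) biased toward labeled
voxels: when the label has foreground, the crop is centered on a random
foreground voxel. Inference reflect-pads to the divisibility the
architecture needs ($2^{\mathrm{levels}-1}$) and, above `max_untiled` = 128
voxels per edge, processes overlapping tiles whose margin context is taken
from the real data; with margin at least the network's receptive-field
half-width, tiled and untiled outputs agree exactly away from the volume
border, which the suite verifies.

## Enhancement, foreground extraction, skeletonization

Enhancement adds the prediction scaled by the dtype maximum onto the raw
image and clips: `clip(raw + 255·pred, 0, 255)` for 8-bit data. A zero
prediction is the identity.

Foreground extraction thresholds the predicted field. The default threshold
is **half the field value at the region boundary**,
$\tfrac12 e^{-3/8} \approx 0.34$ (`foreground_threshold()`): a voxel counts
as foreground when the network's response reaches at least half of the
weakest value the supervision target takes inside the expanded region. For
raw images (no field), the data-driven `robust_threshold()` — median + 4
MAD — is the appropriate rule and is what the no-enhancement baseline uses.

The default skeletonizer is a Euclidean minimum spanning tree over the
foreground points with edges above 2 voxels removed, spur branches shorter
than 4 voxels pruned, and components below 6 points discarded (isolated
noise). It is deliberately pluggable: any external point-cloud skeletonizer
honoring the SWC contract can replace it, and the human-in-the-loop
`bootstrap` command accepts a directory of revised SWC files that override
the automatic skeletons.

## Evaluation

Reconstructions are scored on skeleton points (resampled to ≤ 1 voxel
spacing, matching the label convention). A point matches when its nearest
counterpart lies strictly within `Thre = 3` voxels — the Euclidean norm is
compared against the threshold; a `squared_norm` switch preserves the
alternative reading in which the squared distance is compared. Recall is the
matched fraction of ground-truth points, precision the matched fraction of
predicted points, F1 their harmonic mean. Two empty sets score 1 by
convention; an empty ground truth yields NaN recall with a warning.

Topology is scored with the Aggregated Jaccard Index on instance maps:
each connected skeleton's radius-3 expansion carries one label (overlap goes
to the nearer skeleton), ground-truth instances are greedily matched to the
unused predicted instance of largest Jaccard index (ascending id, ties to
the lowest id, zero-overlap instances stay unmatched), and matched
intersections are aggregated over matched unions plus unmatched sizes.

## The synthetic phantom generator

The generator emulates the documented diversity of real axon blocks:

* smooth curvilinear paths (persistent random walk with bounded curvature,
  optional single branch) rendered as tubes with a Gaussian radial profile,
  max-combined so crossing tubes do not add;
* per-segment intensity variation with **weak segments**: a configurable
  fraction of each axon is rendered at raw intensity 8–30, i.e. within a few
  noise standard deviations of the background. Configured intensities are
  raw center-voxel values (background included), so tubes are rendered with
  amplitude `intensity − background_mean`;
* Gaussian background noise (mean 12, sd 4 raw units by default) with
  rounding to the 8-bit grid;
* round (blob) and strip-shaped distractors that reuse the tube renderer but
  carry no ground-truth skeleton — realistic false-positive bait;
* optional per-volume SNR calibration: strong-structure amplitudes are
  rescaled by a fixed-point iteration (accounting for 8-bit saturation) so
  the contrast-to-noise ratio over the expanded region hits `snr_target`.
  Weak segments are **excluded** from this rescaling: weak stretches arise
  from labeling deficits and stay near the noise floor no matter how bright
  the rest of the block is, which is exactly the property that makes real
  blocks hard.

Per-sub-block characterization (64³ sub-blocks by default) reports SNR as
(mean signal − background location)/background scale with the background
location and scale estimated by median and MAD — robust statistics, so
bright non-axonal structures in the background do not masquerade as noise —
plus axon density (skeleton points per voxel) and mean skeleton-point
intensity. K-means block selection clusters normalized 256-bin grayscale
histograms and returns the volume nearest each centroid.

What the phantoms do *not* model: the imaging point-spread function and its
anisotropy, autofluorescent tissue texture (the background here is white
noise), vasculature, dendrites and somata, and stitching artifacts. Passing
the synthetic benchmark therefore demonstrates that the pipeline's machinery
learns and evaluates correctly under controlled conditions spanning the
documented SNR range — not that the shipped defaults reach any particular
accuracy on real fMOST or light-sheet data.

## The scaled-down benchmark

`benchmark_synthetic()` is the package's end-to-end study, sized for a
single CPU: 30 volumes of 64³ voxels spanning SNR targets 3–12 with weak
segments and distractors; 25 volumes train a toy-profile network (3 levels,
8 base channels, Adam 2×10⁻⁴, batch 1, 32³ crops, 12 epochs); the 5 held-out
volumes are chosen evenly across the SNR range. Both evaluation arms share
one tracing back end (threshold → skeletonize → score): the network arm
thresholds the predicted field at `foreground_threshold()`, the baseline arm
thresholds the raw image at `robust_threshold()`. The qualitative claim this
reproduces is that field-supervised prediction recovers weak axon stretches
that direct intensity thresholding misses, raising skeleton recall; the
baseline remains genuinely competitive on bright, high-SNR volumes, where
saturated tubes are trivially detectable.

## Known limitations

* The network code is a compact CPU implementation (im2col + BLAS); it is
  not meant for training reference-profile models on full-size corpora.
* The MST skeletonizer produces tube-thick point trees rather than true
  medial axes; precision and AJI on the synthetic benchmark are accordingly
  conservative, and a dedicated point-cloud skeletonizer should be plugged
  in where topology quality matters.
* Anisotropic voxels are not modeled; all distances are in voxel units.
* SWC coordinates are interpreted as voxel indices; files in micrometers
  must be converted before use.
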