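---
title: "Methods: self-supervised particle picking in cryopick"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: self-supervised particle picking in cryopick}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Single-particle cryo-EM starts from micrographs containing hundreds of
low-contrast projections of the specimen, plus contaminants such as
crystalline ice that a naive intensity-based picker happily selects.
`cryopick` implements a self-supervised picking loop that needs no manual
labels: an ab initio shape-based picker proposes candidates, 2D class
averaging filters them by a class-quality score, a small CNN is trained on
the survivors, and the train / pick / classify / select cycle repeats
until the picks stabilize. The converged network is then applied to the
full data set ("production picking").

Three decision rules govern the loop:

* **%/Res selection.** Every 2D class carries a percent class distribution
  (share of all particles assigned to it) and an estimated resolution in
  angstrom. A class is kept iff `distribution_pct / resolution_A > 0.1`
  (strictly). Externally produced class metadata stores distributions as
  fractions; they are converted to percent before the division — with
  typical class counts and resolutions of 10–30 A, only the percent scale
  makes the 0.1 cutoff discriminating.
* **90% initialization stop.** The initial candidate set is re-classified
  and re-selected until at least 90% of a round's input particles survive.
* **70% convergence with a 3-iteration cap.** A training iteration counts
  the fraction of CNN picks that land in selected classes; at `>= 0.70`
  training has converged. If three iterations pass without convergence the
  last model is used anyway.

The number of classes is one per 200 particles (rounded half-up, floor 2).

## The ab initio picker

The picker operates on a micrograph binned by block averaging (default
factor 9) and min–max normalized to [0, 1]. Its detection statistic is the
deviation of each pixel from the mean of a window centered on it
(reflect-101 boundaries), with the window set to twice the binned particle
diameter rounded up to odd. A window of only one particle diameter would
let the particle dominate its own background estimate and cancel most of
its deviation, so the background is estimated on the next-larger scale.

A pixel enters the detection mask when its deviation exceeds
`max(threshold, noise_k * sigma_noise)`. The `threshold` term (default
0.0015) is the user-facing floor familiar from real micrographs, where
normalized contrasts are tiny. The second term is an automatic noise gate:
`sigma_noise` is the median absolute horizontal first difference of the
image divided by `0.6745 * sqrt(2)`, the classic difference-based
estimator of the pixel-noise standard deviation. This estimator is blind
to smooth structure — particles, contaminant plateaus and the wide halos
they create in the deviation image — which would inflate a deviation-based
scale estimate several-fold on contaminated micrographs. `noise_k = 4` is
chosen so that the expected number of Gaussian-tail false features on a
binned micrograph, roughly `N_px * P(z > k)`, stays well below one
(about 0.4 specks on a 113x113 binned image, versus ~3 at `k = 3.5`).
Setting `noise_k = 0` recovers a pure deviation-over-threshold rule.

Masked pixels are labelled with 8-connectivity; each component is reduced
to its deviation-weighted centroid; components whose peak deviation falls
below the threshold are discarded. Centroids are mapped back to the
unbinned frame and thinned greedily so that no two picks are closer than
one particle diameter, larger components winning. By design this stage
*does* pick bright ice — contaminant rejection is the job of the later
stages, and the picker's simplicity (three parameters) is the point.

## 2D class averaging and class quality

The built-in classifier is a correlation-based hard-assignment k-means
over a rotation and integer-shift grid (defaults: 8 in-plane angles,
shifts up to ±2 binned pixels, 6 rounds): each particle joins the (class,
rotation, shift) with the highest normalized cross-correlation, and class
averages are recomputed from the aligned members. Class references are
seeded k-means++-style from single crops under the alignment-correlation
distance, and three restarts are run with the highest mean alignment
correlation winning: with a random even partition every initial average
is dominated by the majority species, and whether a low-correlation junk
class ever separates becomes an accident of the seed — deliberate
far-point seeding makes junk pools form reliably. It is a deterministic,
CPU-cheap stand-in for maximum-likelihood 2D classification — its job is
to rank classes for the %/Res rule, not to produce publication averages.
An adapter (`read_class_metadata()` + `select_classes()`) accepts class
metadata from an external classification program for production use.

Class resolution is the Fourier ring correlation between two half-set
averages, crossing 0.5 with linear interpolation between radial shells.
Two details matter:

* **Gold-standard half-sets.** Members are split even/odd and each half is
  aligned to *its own* running average for three refinement rounds before
  the FRC is computed. If both halves were aligned against one shared
  reference, their noise would correlate and junk classes (aligned noise,
  ice fragments) would report flatteringly high resolutions — the
  well-known "Einstein from noise" effect. Independent refinement makes a
  heterogeneous class collapse to an uncorrelated pair of averages. Two
  further safeguards keep the estimate honest: half-averages are
  per-pixel 20% trimmed means, so a small minority of unrelated members
  (say, a few centered particles inside a contaminant class) cannot
  anchor both halves; and refinement references are low-pass filtered to
  the first 8 shells, the usual guard against alignment noise-fitting —
  correlation beyond the alignment cutoff must come from genuinely shared
  structure.
* **The 999 A unresolved convention.** When the FRC is already below 0.5
  at the first resolvable shell the class carries no resolvable signal;
  the conventional cap of 999 A is reported (class-averaging programs use
  the same sentinel), which drives the %/Res ratio of junk classes toward
  zero. If the FRC never drops below 0.5, the Nyquist resolution
  (2 x pixel size) is returned; classes with fewer than two members are
  unresolved (`Inf`, ratio 0).

## The CNN picker

The network maps a standardized 64x64 crop to a two-way softmax
(background, particle): three 3x3 convolution layers with 32, 64 and 128
filters, each followed by 2x2 max pooling, a 128-unit dense layer, ReLU
activations, cross-entropy loss. The depth (exactly three conv+pool
blocks) and the two-output head are fixed; filter counts and the hidden
width are configurable. Training uses Adam (lr 1e-3, batch 32) for 30
epochs with a stratified 20% validation split. It is implemented in
single-precision C++ (im2col + GEMM) and runs comfortably on one CPU
core; no accelerator is ever required.

Crops are extracted with a box of ~1.2 particle diameters, block-binned so
the binned box lands near 64 px, resampled bilinearly to 64x64 and
standardized per crop to zero mean / unit variance (flat crops map to
zeros). The same extraction code serves training and scanning, so a
training crop and a scan window at the same center are bit-identical.

Positives are the class-selected picks (label 1). Negatives are sampled
uniformly from areas at least one particle diameter from every known
particle (label 0), one per positive by default, re-drawn fresh each
workflow iteration so that stale negatives cannot overlap newly found
particles. Note that contaminated regions are legitimately "empty" under
this rule — ice therefore enters the negative pool, which is part of how
the trained network learns to reject it. Below 100 positives a warning is
emitted; training proceeds but is known to be unreliable.

Augmentation (training portion only, re-drawn every epoch): a rotation
with angle uniform in [-20°, +20°] (reflect-padded, recropped), then a
horizontal and a vertical flip each with probability 0.5. The "rotations
of 20 degrees" are read as the conventional ± range parameterization.

Scanning slides the crop box at a stride of particle_size/4 (any stride
at or below half the non-maximum-suppression radius guarantees that every
true center has a window within `stride * sqrt(2) / 2`); windows scoring
`>= 0.9` particle probability become candidates, and greedy NMS keeps the
higher-probability member of any pair closer than one particle diameter
(ties broken by x, then y — making the result independent of input
order). Each workflow iteration retrains from freshly initialized weights
rather than fine-tuning: reproducible and immune to drift, at a modest
CPU cost.

## The synthetic bench

`generate_micrograph()` emulates the conditions the pipeline is designed
for: unit-variance white Gaussian background noise, many copies of one
soft-edged template (disk, ring or rod) stamped at random orientations
with peak amplitude `snr` (so `snr` is peak contrast over noise sd), and
bright irregular contaminants at 5x the particle amplitude. Contaminant
blobs are unions of anisotropic ellipses 1.5–3x the particle scale:
problematic crystalline ice is large relative to the particle and highly
variable, which is exactly what makes its crops heterogeneous and its 2D
classes unresolvable. Ice is placed first; particles keep one diameter of
clearance from it and 1.25 diameters of spacing from each other (centers
at least one diameter from the edges). Placement is by rejection
sampling; an impossible packing fails with the achievable count.

What the generator does *not* model: CTF oscillations and defocus blur
(low defocus is emulated by a low `snr` knob), ice thickness gradients,
beam-induced motion, detector MTF, or structured backgrounds. Passing
tests therefore demonstrate the decision logic, the learning loop and
contaminant rejection under controlled contrast — not performance on any
real data set.

`evaluate_picks()` matches picks to truth centers greedily by ascending
distance, one-to-one, within a tolerance radius (the field's usual
center-distance criterion, e.g. 20 px); precision = matched/picked,
recall = matched/truth.

## Numerical and bench choices

* Coordinates are 0-based pixel centers in the unbinned frame, x = column,
  y = row; STAR files are written unchanged, with a `one_based` adapter
  flag for software using 1-based conventions.
* Binning is a block mean (deterministic, testable), not a Fourier crop;
  it exists purely for speed.
* Binned centroids map back through `x_unbinned = (x + 0.5) * bin - 0.5`.
* MRC modes 0/1/2 are read, mode 2 written; a zero header voxel size falls
  back to a configurable default with a warning.
* All randomness flows from explicit seeds; per-stage sub-seeds are
  derived from the master seed, so a fixed master seed reproduces the
  entire run ledger bit-for-bit.
* Test-bench problem sizes are chosen for a single CPU core: localpicker
  recovery runs on 1024² scenes with 30 disks of 60 px (the sparse,
  well-separated regime); the end-to-end workflow bench uses 16
  micrographs of 768² with 45 particles of 48 px and 3 ice blobs each,
  giving ~800 initial picks and therefore 4 classes under the
  one-per-200 rule — the smallest scale at which class selection operates
  the way it does on real data sets, where contaminant classes are small
  relative to the cutoff. The selection-loop bench (700 template + 300
  noise crops) uses SNR 1.5 crops so that assignment error of the
  correlation classifier — not the selection rule under test — does not
  dominate the outcome. CNN checks train on 2000 balanced crops for 30
  epochs; the label-shuffle control uses a 600-crop subset for 8 epochs,
  since the property it checks (chance-level validation accuracy) is
  scale-independent.

## Known limitations

* The built-in classifier searches a coarse rotation/shift grid; with
  very anisotropic particles or large shifts it will fragment views into
  several classes. That is harmless for selection (all fragments pass the
  ratio test) but the averages are not publication-grade.
* The %/Res rule's 0.1 cutoff assumes junk classes are a small share of
  the input (on large real data sets a contaminant class holds well under
  2% of particles). On small benches a compact, internally coherent
  contaminant class of a few percent can land just above the cutoff and
  survive selection; and if half the candidate set is junk, no
  class-level rule at this cutoff can clean it.
* Difference-based noise estimation assumes noise dominates at the pixel
  scale; on heavily low-pass-filtered inputs the gate collapses to the
  user threshold.
* The CNN is intentionally small and trained per data set; no transfer
  learning or pretrained weights are provided.
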