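---
title: "Scoring nucleolar maturation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring nucleolar maturation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoshape)
```

## What this package measures

Totipotent-like (2C-like) mouse embryonic stem cells and one- to two-cell
embryos carry immature nucleoli — nucleolar precursor bodies — that look
strikingly different from mature nucleoli: large, round, and often
*ring-like*, with the granular-component marker B23 (Npm1) concentrated
at the rim and a dim interior. Nucleolar maturation coincides with
recruitment of the *Dux* locus to the perinucleolar shell and repression
of the two-cell transcriptional program. nucleoshape implements the
quantitative imaging readouts this biology calls for:

1. **Ring-shape classification** of segmented nucleoli from the radial
   intensity distribution,
2. **FormFactor circularity** with the standard small-object exclusion,
3. **per-cell intensity quantification** (e.g. EU/HPG incorporation,
   Oct4, gag, DAPI),
4. **3D FISH locus scoring**: distances of detected foci to the nearest
   nucleolus surface and to the nuclear border, and categorical
   compartment calls (nucleolar / nucleoplasmic / lamina-proximal),
5. **nascent-transcription focus selection** (two-or-fewer / two
   brightest rule),
6. **siRNA screen statistics**: plate Z-scores with strict hit calling,
   plus the chi-squared (with Bonferroni adjustment) and t-tests
   (with automatic Welch correction) used to compare cell populations.

Because public imaging data for this biology is scarce, the package
ships a first-class synthetic scene generator with exact ground truth;
every stage is validated end-to-end against scenes with known, planted
parameters.

## The ring-shape statistic

A segmented nucleolus mask is partitioned into `n_layers` (default 4)
concentric shells of equal *normalised radial depth*: the interior
Euclidean distance transform of the mask is rescaled to $(0, 1]$ per
object and cut at quantiles ($0.25/0.5/0.75$ for four layers). Layer 1
is the outermost shell touching the boundary; layer $n$ is the core.
The statistic is

$$\mathrm{ring\ ratio} \;=\;
  \frac{\overline{I}_{\text{layer 1}}}{\overline{I}_{\text{layer } n}},$$

and a nucleolus is **RingShape+** when the ratio *strictly* exceeds the
threshold (default 1.4). Two conventions were genuinely open and are
fixed here as follows:

* **Depth-equal, not area-equal shells.** Layers have equal radial-depth
  extent, matching the scaled radial bins used by object
  intensity-distribution profiling in CellProfiler-style pipelines. An
  area-equal alternative would weight the rim more heavily; the
  depth-equal choice makes the generator's rim band (outer quarter of
  radial depth) map exactly onto layer 1, so a noiseless synthetic
  nucleolus of rim contrast $c$ measures a ring ratio of exactly $c$.
* **Proportional outer shell, not boundary pixels only.** The outer
  "layer" is the full outer-quartile shell; a boundary-pixel-only
  variant is obtainable by raising `n_layers`.

Both choices are configurable (`morphology_config()`). Objects whose
radial depth is smaller than the layer count cannot host non-empty
shells and are recorded as skipped, as are objects whose innermost mean
is zero (undefined ratio).

## FormFactor

$$FF = \frac{4\pi \cdot \text{area}}{\text{perimeter}^2},$$

with area the pixel count and perimeter a Crofton (Cauchy) four-direction
estimator: $P = \tfrac{\pi}{4}\bigl(R_0 + R_{90} + (R_{45} +
R_{135})/\sqrt2\bigr)$, where $R_\theta$ counts foreground runs along
scan lines in direction $\theta$ (diagonal lines are spaced $1/\sqrt2$
apart). Naive boundary-pixel counting systematically inflates the
perimeter of digital disks; the Crofton estimator is unbiased for disks
in expectation and keeps a digital disk's $FF$ close to (and just
below) 1. Values can still exceed 1 for small, near-circular digital
objects — exactly the artefact the validity bound addresses — so a
value above `form_factor_max_valid` (default 1) is marked excluded, as
is any object smaller than `min_area_px` (default 100 px, the standard
small-object filter). Exclusions are markers on the record, never
silent drops. Morphology is scored in 2D; a 3D mask is reduced to its
largest-area z-plane first.

## Segmentation

* **Nuclei**: Gaussian smoothing (isotropic in physical units; the
  axial sigma is the lateral sigma scaled by the spacing ratio), global
  Otsu threshold, interior hole filling, then splitting of touching
  objects by seeded watershed on the anisotropic Euclidean distance
  transform. Seeds are distance-transform maxima with a minimum
  separation (default half the largest object radius). Objects below
  `min_size` are removed; border-touching objects are retained but
  flagged (`border_labels` attribute). Connectivity is 8 (2D) / 26 (3D).
* **Nucleoli**: thresholded per nucleus footprint. Inside a nucleus the
  B23 channel has up to three intensity classes — nucleoplasm, filled
  nucleolar signal, and bright rims — so a two-class Otsu can swallow
  the filled class whenever rings are present. The threshold is
  therefore the *lower* cut of a three-class Otsu whenever the middle
  class is signal-like (its mean exceeds the lower class's mean by
  three lower-class SDs), and the upper cut otherwise (the middle class
  is then background noise). A final guard requires the foreground mean
  to exceed the background mean by three background SDs, leaving
  signal-free nuclei empty. Holes are filled before re-clipping to the
  nucleus footprint, so hollow (ring-like) nucleoli yield their full
  disk. Labels are canonicalised by centroid lexicographic order, which
  makes outputs independent of scan order and channel ordering.

All raster primitives (connected components, exact anisotropic squared
EDT via the lower-envelope algorithm, separable Gaussian filtering,
priority-flood watershed, plateau-stable local maxima) are implemented
once in compiled code and shared by the 2D and 3D paths; EBImage
supplies the Otsu criterion. A single unified code path was preferred
over mixing per-frame 2D operations with hand-rolled 3D ones.

## FISH spot detection and distances

Foci are detected with a multiscale Laplacian-of-Gaussian filter whose
scales are specified in micrometres (default 0.2–0.45 µm, bracketing
the diffraction-limited focus size); per-axis voxel sigmas are
`scale / spacing`, which makes the filter anisotropy-aware. Detections
are plateau-stable local maxima of the scale-maximised, scale-normalised
response above `threshold` robust background SDs (MAD). The default
threshold of 10 comes from extreme-value reasoning: across $N \sim 10^6$
voxels the expected maximum of the background response is about
$\sqrt{2\ln N} \approx 5.3$ SDs, and maximising over scales skews the
tail further, so 10 provides a comfortable margin while genuine foci at
the acquisition SNRs this package targets respond at tens of SDs.
Centres are refined to sub-voxel precision by a local centre of mass;
foci outside any nucleus are discarded. Stacks lacking spacing metadata
are refused outright — distances in µm would be meaningless.

Distances are anisotropic Euclidean distances in physical units.
A spot inside a nucleolus scores 0. Otherwise the distance to an object
boundary is estimated symmetrically: the mean of the nearest-neighbour
distances to the inner surface voxels (foreground voxels adjacent to
background) and to the outer shell (background voxels adjacent to
foreground). The true boundary lies between those two voxel-centre
shells, so the average cancels the half-voxel bias either shell alone
would carry; on synthetic spheres the residual error is well below one
voxel diagonal.

Compartments are assigned with documented precedence: **nucleolar** if
the nucleolar distance is $\le$ `assoc_tol` (inclusive; default
0.25 µm, about the confocal lateral resolution), else
**lamina-proximal** if the border distance is $\le$ `lamina_tol`
(default 0.5 µm), else **nucleoplasmic**. No numeric contact criterion
is standard in the literature for "nucleolar-associated", so both
tolerances are configuration, and validation uses tolerances matched to
the generator's. Spots in nuclei without any segmented nucleolus are
classified from the border distance alone and flagged.

Nascent-focus selection flags all foci in nuclei with two or fewer, and
exactly the two brightest in nuclei with more; intensity ties break by
coordinate lexicographic order so the rule is deterministic.

## Screen statistics

A gene's screen value is the mean percent reporter-positive over its
wells. Its Z-score subtracts the mean over *all* well values of the
plate — controls included, "the entire plate" — and divides by the
plate sample SD ($n-1$; the population-SD variant differs by a factor
$\sqrt{(n-1)/n}$ and is not what base R's `sd()` computes, so the
sample SD is declared and used). A hit strictly exceeds the cutoff
(default 1). Chi-squared tests are plain Pearson without continuity
correction (the categorical scores in this domain have large $n$);
Bonferroni adjustment is $\min(1, m\,p)$ over the $m$ tables supplied
together. Group comparisons are two-tailed t-tests; "Welch where
relevant" is made explicit as a variance-ratio trigger (larger/smaller
group variance > 4), and the variant used is always reported.

## The synthetic scene generator

The generator emulates the acquisitions this kind of study performs:
2D confocal snapshots (63×-oil-class sampling, default 0.1 µm/px) of
nuclei with 1–4 nucleoli, either filled or ring-like (rim = outer
quarter of radial depth at `ring_contrast` × interior), and anisotropic
3D z-stacks (defaults 0.25 µm z, 0.12 µm xy) with Gaussian-profile FISH
foci planted at controlled distances from the nucleolar surface and the
nuclear border. Axis order is `(z, y, x)` (`(y, x)` in 2D), 0-based
voxel indices, physical coordinate = index × spacing — one convention
everywhere.

Geometry is exact by construction: nuclei and nucleoli are digital
disks/spheres in physical coordinates, so every ground-truth distance
is analytic. The design allows mild ellipticity in principle; the
implementation keeps circular geometry precisely because exact ground
truth was judged more valuable for validation than marginally more
realistic shapes — a deliberate trade-off.

The noise model is Poisson shot noise on the signal (gain
`photons_per_unit`, default 5 photons per intensity unit) plus a
constant background and Gaussian read noise of SD `level / snr`, so the
background SD equals peak-signal/`snr` exactly and the planted `snr` is
recoverable from the image. `snr = Inf` produces the clean image.
Defaults (`snr = 10`, background 10, peak 100) describe a
good-but-realistic confocal acquisition; the studies this package
models do not publish their noise levels, so these are documented
choices, not calibrated values. Planted spots keep a safety margin
(default one lateral pixel) from the compartment-boundary tolerances
and a minimum pairwise separation (default 1 µm), so voxelisation
cannot flip a spot's true class and planted foci are individually
resolvable. Screen plates are `baseline + effect + N(0, well_sd)`
percent-positive values, clipped to [0, 100], with triplicate gene
wells and dedicated control wells by default.

What the generator deliberately does **not** emulate: optical PSF
convolution beyond Gaussian foci, photobleaching, chromatic aberration,
autofluorescence structure, nuclear-shape irregularity, and
intensity-graded (rather than binary) ring phenotypes. Passing
validation on these scenes therefore demonstrates correctness of the
measurement logic under a known forward model — not robustness to every
artefact of real microscopy.

## Numerical choices and determinism

* Exact squared EDT (per-axis lower-envelope), so layer assignment is
  reproducible to the last bit and matches brute-force recomputation.
* Strict `>` at both decision thresholds (ring ratio, Z cutoff), per the
  conventions the statistics are defined with; boundary cases are
  covered by tests.
* Scenes are bit-reproducible: one seeded generator per scene with
  deterministic per-object sub-streams; segmentation is deterministic
  and invariant to channel order; pipeline reruns with the same config
  and seed produce byte-identical tables.
* Tie-breaks are documented: plateau local maxima keep the
  lowest-index voxel; equal-intensity nascent foci resolve by
  coordinate order; watershed floods in deterministic priority order.

## Problem sizes used in validation

The shipped test-and-validation suite runs scaled scenes chosen to give
tight statistical bounds at interactive runtimes: 1024² snapshots with
34 nuclei (≈ 100 nucleoli) per planted ring fraction for classifier
recovery; 32×160×160 z-stacks (3 nuclei, 9 spots) in batches of 8–10
for the FISH pipeline; 10,000 simulated null tables for chi-squared
calibration. Exact binomial and Bonferroni-adjusted multinomial 99%
intervals are used for all recovery checks, so the sample sizes are the
binding precision constraint, not tolerances chosen after the fact.

## Known limitations

* Nucleolar masks at very high rim contrast dilate by roughly a pixel
  (the smoothed rim tail crosses the local threshold outside the true
  boundary); at extreme contrast two nucleoli separated by only a
  couple of pixels can merge. At the contrasts typical of this biology
  (≤ 3) measured areas stay within a few percent of truth.
* The two-sided surface-distance estimator is unbiased but still
  voxel-limited; sub-voxel accuracy of *distances* (as opposed to spot
  centres) would require a signed-distance interpolation that is out of
  scope.
* Morphology is strictly 2D by design; genuinely 3D shape descriptors
  (sphericity, shell-ness in z) are not computed.
* The screen model treats wells as independent Gaussians; plate-effect
  structure (row/column gradients, edge effects) is not simulated and
  no plate-normalisation beyond the Z-score is provided.
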