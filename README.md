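# nucleoshape

Quantitative image analysis of **nucleolar maturation** for fluorescence
microscopy, with a ground-truthed synthetic scene generator for
end-to-end validation.

Immature nucleoli — the nucleolar precursor bodies of early mouse
embryos and of rare totipotent-like (2C-like) cells in ESC cultures —
are large, round and *ring-like*: the granular-component marker B23
(Npm1) concentrates at the rim around a dim interior. Nucleolar
maturation coincides with recruitment of the *Dux* locus to the
perinucleolar shell and shutdown of the two-cell transcriptional
program, so imaging readouts of nucleolar shape, per-cell biosynthesis,
and locus-to-compartment distances are the workhorse measurements of
this biology. nucleoshape implements them as a tested, reusable R
package:

* **Ring-shape classification.** Each segmented nucleolus is split into
  four concentric layers of equal normalised radial depth (interior
  distance transform scaled to [0, 1]); the mean intensity of the
  outermost layer divided by that of the innermost gives the *ring
  ratio*, and a nucleolus is RingShape+ when the ratio strictly exceeds
  1.4 (configurable).
* **Circularity.** FormFactor = 4π·area/perimeter² with a Crofton
  multi-directional perimeter estimate; nucleoli under 100 px or with
  FormFactor > 1 are marked excluded as unreliable.
* **Segmentation.** Otsu + distance-transform watershed for nuclei
  (2D snapshots and anisotropic 3D stacks); per-nucleus three-class
  Otsu with hole filling for nucleoli, so hollow ring-like nucleoli
  segment as full disks.
* **3D FISH scoring.** Anisotropy-aware multiscale LoG spot detection
  with sub-voxel refinement; per-spot distances (µm) to the nearest
  nucleolus surface and to the nuclear border; compartment calls
  (nucleolar / nucleoplasmic / lamina-proximal) with documented
  precedence; nascent-focus selection (all foci in nuclei with two or
  fewer, else the two brightest).
* **Screen statistics.** Plate Z-scores — (gene value − plate mean) /
  plate SD over all wells — with strict Z > 1 hit calls; Pearson
  chi-squared with Bonferroni adjustment; two-tailed t-tests with an
  explicit Welch trigger.
* **Synthetic scenes.** Digital-disk/sphere nuclei and nucleoli with
  exact analytic ground truth, planted ring fractions, planted spot
  compartments and distances, Poisson + Gaussian noise at a controlled
  SNR, and simulated screen plates with planted hits.

## A worked example

Simulate a snapshot of six nuclei where half the nucleoli are ring-like
(rim contrast 3, SNR 10), segment it, and score nucleolar morphology:

```r
library(nucleoshape)

spec <- scene_spec(n_nuclei = 6, ring_fraction = 0.5, ring_contrast = 3,
                   snr = 10, seed = 42)
sc <- make_cell_scene(spec)
nuclei <- segment_nuclei(sc$stack, "DAPI", min_size = 500)
nucleoli <- segment_nucleoli(sc$stack, "B23", nuclei)
res <- score_population(nucleoli, get_channel(sc$stack, "B23"))
head(res$records[, c("nucleolus_id", "nucleus_id", "area_px",
                     "form_factor", "ring_ratio", "ring_positive")])
#>   nucleolus_id nucleus_id area_px form_factor ring_ratio ring_positive
#> 1            1          1     547   1.0238425  0.9960977         FALSE
#> 2            2          1     416   1.0020910  0.9926702         FALSE
#> 3            3          1     545   0.9875167  1.0066945         FALSE
#> 4            4          1     460   0.9578394  2.5643343          TRUE
#> 5            5          3     477   0.9654334  2.4931773          TRUE
#> 6            6          2     340   0.9622797  2.5360257          TRUE
res$counts
#>     RingShape_pos RingShape_neg
#> all             9             8
```

Filled nucleoli measure ring ratios near 1; planted rings (contrast 3)
measure ≈ 2.5 after segmentation and are called RingShape+ (9 of the 17
segmented nucleoli here, against a planted fraction of 0.5). FormFactor
sits near 1 for these near-circular objects.

Scoring a simulated siRNA miniscreen (Ncl knockdown planted at +5
percentage points of reporter-positive cells):

```r
plate <- make_screen_plate(gene_effects = c(Ncl = 5, Fbl = 3,
                                            Sirt7 = 0.2, Npm3 = -0.5),
                           baseline = 1, well_sd = 0.5, seed = 42)
call_hits(plate_zscores(plate))
#>        gene mean_percent_positive    z_score n_wells   hit
#> 1 siControl             1.1948981 -0.6902808       3 FALSE
#> 2       Ncl             6.1551677  1.4494640       3  TRUE
#> 3       Fbl             4.5725478  0.7667586       3 FALSE
#> 4     Sirt7             1.7881335 -0.4343729       3 FALSE
#> 5      Npm3             0.2646483 -1.0915689       3 FALSE
```

Only the planted Ncl effect crosses the strict Z > 1 hit threshold.

The same stages run from one config via `run_pipeline()` (or the thin
CLI at `inst/scripts/nucleoshape-cli`), which persists every mask and
table with provenance headers and reproduces outputs byte-identically
for a given seed.

## Package layout

* `R/` — scene generation (`synthetic.R`), raster I/O (`io.R`),
  segmentation, morphology, FISH scoring, screen statistics, pipeline
  orchestration.
* `src/` — compiled raster primitives: connected components, exact
  anisotropic Euclidean distance transform, separable Gaussian
  filtering, seeded watershed, local maxima.
* `vignettes/nucleoshape-methods.Rmd` — the model, parameter
  conventions, design decisions and known limitations.
* `tests/testthat/` — unit, property and acceptance suites (all
  fixtures generated in code).
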