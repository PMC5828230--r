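---
title: "Fully automatic kidney segmentation by 3D marker-controlled watershed"
author: "renalws"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fully automatic kidney segmentation by 3D marker-controlled watershed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalws)
```

## The problem

Contrast-enhanced abdominal CT is the workhorse examination of clinical
urology, and kidney delineation is the first step of most downstream tasks
(volumetry, lesion detection, surgical planning). Manual delineation of a
volumetric study is slow; fully automatic methods must cope with both
physiological anatomy and a wide range of pathology — cysts, tumours,
cirrhosis, nephrolithiasis, and surgically or congenitally absent kidneys.

`renalws` implements a fully automatic two-stage pipeline built around the
3D marker-controlled watershed transform (MCWT). A rough, geometry-driven
stage finds a conservative *seed* inside each kidney; the watershed stage
then matches that seed to the true organ boundary on the gradient-magnitude
relief. The package also provides the complete agreement-metric suite used
to score segmentations against reference delineations, and a synthetic CT
phantom generator that stands in for clinical data in the test suite.

## The pipeline, stage by stage

Throughout, volumes are HU-valued grids with axes $(x, y, z)$ — left-right,
anterior-posterior, and the transverse (slice) axis — with anisotropic
voxel spacing in millimetres carried alongside the data.

1. **Body segmentation** (`segment_body`). Air is strongly negative on the
   calibrated HU scale while soft tissue and bone are positive, so the trunk
   is the largest 26-connected component of the voxels above 0 HU after
   small-object removal. Enclosed hypodense regions (e.g. fat) are restored
   by per-slice hole filling.
2. **Skeleton detection** (`detect_skeleton`). Thresholding at the
   cortical-bone level (default 200 HU, separating bone from
   contrast-enhanced soft tissue in the portal venous phase) inside the
   body, followed by a 3D opening and removal of small in-plane components
   in transverse and sagittal planes, leaves the spine and major bones. The
   spine is the anatomical landmark for everything that follows; unlike
   lung-based landmarks it is insensitive to patient positioning.
3. **Posterior crop** (`crop_posterior`). The kidneys sit lateral to the
   spine, so the posterior 30% of the body's anterior-posterior extent —
   spine and back muscles — is removed with one straight cut. The posterior
   direction is *inferred* (spine centroid vs body centroid), never assumed
   from scanner orientation.
4. **Kidney search boxes** (`kidney_boxes`). The bounding box of the cropped
   body is split left/right at the spine's mean lateral position. Each
   sub-box gets a 3D digital diagonal from its medial-posterior corner
   (lowest slice) to its lateral-anterior corner (highest slice); by the
   anatomy this line traverses the kidney.
5. **HU windowing** (`window_kidney_hu`). Enhanced renal parenchyma in the
   portal venous phase lies in a 0–200 HU window; everything outside is set
   to zero and treated as non-kidney. The windowed image $I$ is the
   intensity image of all later stages.
6. **Preliminary segmentation** (`sample_diagonal`, `preliminary_segment`,
   `select_kidney_objects`). The nonzero voxels along the diagonal give
   $h = \bar v + \sigma_v$ (sample sd). The h-maxima transform
   $\mathrm{HMAX}_h(I) = R^{\delta}_I(I - h)$ — morphological reconstruction
   by dilation of $I-h$ under $I$ — flattens intensity maxima of dynamic
   below $h$. The smoothed values on the diagonal voxels form the set $D$,
   and the seed threshold is $th_k = \bar D + \sigma_D$. The binary image
   $I > th_k$ is opened, objects below a physical minimum volume are
   dropped, objects touching the in-plane box borders are removed, and
   the smallest remaining objects are discarded until at most two of
   comparable volume (ratio $\ge$ 0.5) remain. An empty box is a legitimate
   outcome — it is how nephrectomy and renal agenesis present — and
   degrades the run to a single-kidney result rather than an error.
7. **Marker generation** (`make_background_marker`, `make_marker_pair`).
   The seed itself is the *object marker*. For the *background marker*, the
   per-slice bounding rectangle of the seed footprint is filled, the stack
   is extended one slice beyond the seed's z-range, dilated with a ball
   whose radius is 10% of the smallest seed extent (rounded up), and
   inverted. Between the two markers remains an unlabeled corridor that
   contains the true kidney boundary.
8. **Watershed** (`presmooth`, `gradient_magnitude`, `mcwt`). The windowed
   image is box-mean filtered and opened (gradient operators are noise
   sensitive), and the 3D gradient magnitude
   $\|\nabla I\| = \sqrt{I_x^2 + I_y^2 + I_z^2}$ is computed with
   spacing-scaled central differences (HU/mm). Priority-flood watershed then
   floods this relief from exactly the two marker regions; all other minima
   are suppressed, which is what eliminates the classic watershed
   oversegmentation. Voxels where the floods meet become explicit watershed
   lines (dams). The result is a 0/1/2 label image: dam, kidney catchment,
   background catchment.
9. **Post-processing** (`select_kidney_labels`, `smooth_kidney`). The
   kidney is the label-1 catchment (dams are boundary, never kidney).
   Opening, closing and 3D hole filling smooth the edges and close internal
   cavities; a component that smoothing would annihilate entirely is
   restored unsmoothed with a warning, and the final mask always covers the
   object marker.

## Agreement metrics

`compute_metrics` derives the full suite from the voxel contingency table
(TP, TN, FP, FN): sensitivity, specificity, Dice
$D = 2TP/(2TP+FP+FN)$, Jaccard $J = D/(2-D)$, accuracy, random (chance)
accuracy, Cohen's $\kappa = (Acc - randAcc)/(1 - randAcc)$, false positive
volume fraction $FP/(TN+FP)$, and the similarity measure
$1 - |FN-FP|/(2TP+FN+FP)$. All values are proportions internally; percent
rendering happens only at reporting time (`format_metrics`). Indeterminate
ratios (0/0) are reported as `NA`, never as silent zeros. `altman_class`
bands $\kappa$ (in percent) into Very good (80, 100], Good (60, 80],
Moderate (40, 60], Fair (20, 40] and Poor [0, 20] (negative values are
Poor); the bands are half-open so that every real $\kappa$ falls in exactly
one class.

```{r metrics}
r <- compute_metrics(list(tp = 8, fp = 2, fn = 2, tn = 88))
format_metrics(r)
altman_class(100 * r$kappa)
```

## The synthetic phantom

Clinical CT databases cannot ship with a package, so the test bench is a
deterministic phantom (`phantom_spec`, `make_phantom`, `make_suite`): an
elliptic-cylinder trunk (40 HU) in air (−1000 HU), an internal hypodense
fat pocket (−80 HU), a posterior spine column (700 HU), and two kidney
ellipsoids (140 HU, semi-axes 27 × 22 × 50 mm ≈ 125 ml) lateral to the
spine in the anterior part of the trunk, plus zero-mean Gaussian noise
(default sd 10 HU, typical portal-venous noise at these settings). The
default grid is 128 × 128 × 96 voxels at 3 × 3 × 2.5 mm — a clinical
in-plane matrix downsampled fourfold, which keeps a full suite affordable
on one CPU (a 20-phantom suite segments in about two minutes) while
preserving the anatomy/contrast relationships the pipeline relies on.
Pathology modes: a hypodense cyst (−5 HU, outside the kidney window — the
vascular-cavity disagreement mode), a hyperdense tumour (80 HU, inside the
window), and nephrectomy/agenesis (an absent kidney). Lesion voxels stay
part of the kidney ground truth, matching whole-kidney delineation
practice. `make_suite` jitters geometry and tissue HU (kidney ±12% axes,
±20 HU; body ±10 HU) and allocates pathologies deterministically by largest
remainder.

What the phantom does *not* emulate: anatomical texture, ribs and bowel
gas, perirenal fat planes, partial-volume blur, and scanner-specific noise
spectra. Passing the suite therefore demonstrates the pipeline's geometric
and morphological logic under controlled contrast, not clinical-grade
performance; the two are related but not interchangeable.

## Numerical and design choices

* **Unit structuring element.** Grayscale reconstruction iterates geodesic
  dilation with the 6-connected cross — the canonical smallest 3D element.
  Binary object counting uses 26-connectivity throughout.
* **Reconstruction algorithm.** A hybrid raster-scan/FIFO-queue algorithm
  computes reconstruction by dilation; the test suite asserts exact
  equality with the naive fixed-point iteration on random volumes, so the
  efficient path is provably the literal definition.
* **Seed threshold.** $th_k$ is *derived from* the h-maxima-smoothed image
  (whose flattened peaks make the mean+sd statistic stable) but *applied
  to* the windowed image $I$. Applying it to the smoothed image itself
  fails whenever $h$ exceeds the kidney's own dynamic — the smoothed kidney
  then sinks below $th_k$ and the seed vanishes; with the kidney at
  ~130 HU on a ~50 HU background this is not an edge case but an expected
  operating point.
* **Watershed determinism.** Flooding uses 6-connectivity with a priority
  queue ordered by (altitude, FIFO insertion order); marker voxels are
  enqueued in lexicographic voxel order. The labelling is therefore a pure
  function of the input, bit-reproducible, and invariant under adding a
  constant to the relief. Altitudes are quantised to 32-bit floats; no
  discretisation beyond that is applied. Dams are voxel-thick (label 0), so
  label selection can exclude boundaries explicitly; a voxel whose flooded
  neighbours all turned to dams becomes a dam itself, which guarantees
  every voxel is labelled.
* **Degenerate inputs.** All-negative volumes ("no body"), volumes without
  bone ("no skeleton") and boxes without seeds raise typed conditions; only
  the seed condition is caught by the pipeline (the agenesis/nephrectomy
  path). Sample statistics use the n−1 denominator; a diagonal with fewer
  than two nonzero samples cannot yield one and signals "no seed".
* **Tunables.** All thresholds live in `pipeline_config`: the HU window
  (0–200), posterior fraction (0.30), bone threshold (200 HU), comparable
  volume ratio (0.5), marker dilation fraction (0.10), minimum seed volume
  (15 ml — about a tenth of a normal kidney, large enough to reject vessel
  fragments and noise clusters, small enough to keep an atrophic kidney),
  presmoothing radii (1 voxel), and the final smoothing ball, capped at
  2 mm physical radius so thin kidney poles survive (at coarse spacings the
  cap yields radius 0 and smoothing reduces to hole filling).
* **Left/right convention.** Sides are named in image coordinates (low x =
  "left"); the mapping to patient left/right depends on acquisition
  orientation, which the package deliberately does not interpret.

## Worked example

```{r pipeline}
ph <- make_phantom(phantom_spec(seed = 17))
res <- run_pipeline(ph$volume)
res$status
for (side in c("left", "right")) {
  m <- evaluate_segmentation(res$kidneys[[side]], ph$truth[[side]])
  cat(side, format_metrics(m)[c("dice", "kappa")], "\n")
}
```

A 20-phantom suite with mixed pathologies is scored the same way:

```{r suite, eval = FALSE}
suite <- make_suite(20, phantom_spec(), seed = 1)
ev <- evaluate_suite(suite)
cohort_summary(ev$reports)
```

`scripts/acceptance.R` packages exactly this computation — suite
generation, segmentation, per-kidney scoring, cohort means — behind a
`--seed`/`--out` interface.

## Known limitations

* The posterior crop assumes the kidneys lie anterior to the cut; grossly
  ectopic (e.g. pelvic) kidneys would be excluded with the spine.
* The diagonal must traverse enhanced parenchyma; a kidney that is almost
  entirely replaced by hypodense cysts can present as absent.
* Markers derived from a single seed rectangle cannot recover parenchyma
  that lies outside the dilated hull (e.g. a long extrarenal extension of
  a mass).
* Only one volume per run is segmented; multi-phase studies must be reduced
  to the portal venous phase beforehand.
* DICOM reading supports uncompressed little-endian single-frame series
  only, and DICOM writing is out of scope.
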