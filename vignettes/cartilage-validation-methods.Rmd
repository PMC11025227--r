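---
title: "Validating 3D cartilage segmentation models against physical gold standards"
author: "CartilageDice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating 3D cartilage segmentation models against physical gold standards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CartilageDice)
```

## The problem

Automatic (AI) segmentation of knee cartilage from MRI is usually validated
against *other* MRI annotations, which inherit the modality's own errors and
the annotators' subjectivity. A stronger design validates the MRI-derived 3D
cartilage model against physical gold standards obtained when the tibial
plateau is resected during total knee arthroplasty:

* **Track A (2D)** — the resected specimen is photographed top-down on 1 x 1 mm
  calibration grid paper (camera 140 mm above the plane, nominal 1.3x zoom).
  The segmentation model is pose-rectified by PCA and rendered as a silhouette
  under the same geometry; the two binary images are compared by the 2D Dice
  similarity coefficient (DSC).
* **Track B (3D)** — the specimen is scanned by CBCT at 0.2 mm isotropic
  resolution and hand-labelled, giving a reference 3D model. Six anatomical
  landmarks marked in sequence (anterior tibia, 2 x medial plateau, posterior
  tibia, 2 x lateral plateau) initialise a rigid registration that is refined
  by ICP on surface point clouds; 3D DSC and cartilage volumes follow.
* **Cohort level** — per-case DSC triplets and volume pairs are aggregated;
  MRI-model vs CT-model volumes are associated by the Pearson correlation.

The characteristic finding this pipeline is built to detect and quantify is
*thickness underestimation*: an MRI-based model can trace the cartilage
footprint faithfully (high 2D DSC) while systematically underestimating
thickness, which depresses 3D DSC yet leaves the volume correlation strong.

Because no patient data accompany this methodology, the package ships a
synthetic tibial-plateau phantom generator that emulates the paired data, and
every claim the test suite makes is made on those phantoms.

## Dice similarity coefficient

For masks $A$ and $B$ (pixels or voxels),

$$\mathrm{DSC} = \frac{2\,|A \cap B|}{|A| + |B|} \in [0, 1].$$

`dsc2d()` and `dsc3d()` return the counts along with the quotient so any
reported value can be recomputed. Two empty masks raise an error rather than
returning a convention: a 0/0 Dice in this pipeline always means an upstream
failure. 3D DSC is evaluated on the CT grid (0.2 mm), the finer of the two,
after nearest-neighbour resampling of the MRI-frame model through the
registration transform; nearest-neighbour is used because interpolating
labels would fabricate non-label values.

## The synthetic phantom

`phantomParams()` / `generateCase()` build one case from a thickness height
map over an elliptical plateau (default 75 x 50 mm):

* two condylar patches (radius 18 / 16 mm) with a raised-cosine thickness
  profile on a floor of 65% of the 2.2 mm peak — cartilage is centrally
  fairly uniform and ends in an abrupt margin, not a feather edge;
* an intercondylar eminence ridge (2 mm high, Gaussian 6 x 16 mm) and a 12%
  antero-posterior thickness wedge. These give the articular surface the
  relief a real plateau has; without them the surface is so flat that its
  in-plane pose is nearly unobservable to a point-to-point ICP, which is a
  property of a bad phantom, not of the method;
* Gaussian smoothing of the height map (sigma 1.5 mm, fixed), then a 0.25 mm
  floor threshold so the margin is crisp at the voxel-resolvable level;
* optional full-thickness defect disks, punched out after smoothing
  (sharp-edged lesions whose holes must survive the whole 2D pipeline).

The CT gold standard rasterises this field at 0.2 mm in the CT frame. The
MRI-side model is the same field with thickness multiplied by the bias
$\beta \in (0, 1]$ plus a smooth additive boundary-noise field (sd 0.15 mm,
2 mm correlation length), rasterised at 0.4 mm in the MRI frame — the CT
frame mapped through the inverse of a ground-truth rigid transform (drawn up
to 25 degrees / 15 mm in cohorts: large enough that unregistered volumes
barely overlap, small enough that six landmarks plus ICP is well-posed). The
photograph is the top-down foreground projection of the true field at
0.1 mm/px. Landmarks are placed on the anterior/posterior rim and two points
per condylar patch; the MRI-side copies receive 0.5 mm measurement noise
*after* correspondence, emulating imperfectly corresponding key points.

Parameter defaults are chosen once to describe a realistic severe-OA
plateau; $\beta$ is the experiment knob and defaults to 1 (no bias). With no
noise and $\beta = 1$ the MRI/CT volume ratio is 1 within rasterisation
error, and the ratio tracks $\beta$ within 0.08 across $[0.5, 1]$ — both are
tested properties, not assumptions.

What the phantom does **not** emulate: curved subchondral bone under the
cartilage (the base plane is the flat osteotomy cut), MRI/CT imaging physics,
partial-volume intensities, segmentation errors other than thickness bias
and smooth boundary noise, and ligament stumps. Passing tests therefore
demonstrate the *pipeline's* correctness and sensitivity, not any claim
about real-patient accuracy.

## Track A numerics

`pcaRectify()` aligns the vertex-covariance principal axes with x (largest
variance) to z (smallest). Sign conventions make it deterministic: z is
oriented so the majority of surface area has upward outward normals (the
articular surface faces the camera), x so the third central moment of the x
coordinates is non-negative; y completes a right-handed frame. Coplanar
vertex sets are rejected. Rectifying a rectified mesh is the identity within
numerical tolerance.

`renderSilhouette()` defaults to orthographic projection: under grid-paper
calibration both images are expressed in mm via `mmPerPx`, so the absolute
magnification (the "1.3x") cancels, and the parallax error for a <= 5 mm-high
object at 140 mm is below 3% of foreground — the pinhole mode exists to
verify exactly that bound, which is an acceptance test. A pixel is foreground
iff its centre lies in some projected triangle; the rendered pitch of one
grid square is exactly `gridPitchMm / mmPerPx` pixels (10 by default).

`binarizePhoto()` thresholds (fixed value or Otsu), keeps the largest
connected component, and deliberately never fills interior holes — defects
are the morphology of interest.

`alignSilhouettes()` answers a question the photographic procedure leaves
open: how the two binary images are superposed before 2D DSC. Both are
resampled to the finer pixel scale, centroids are superposed, and the 2D
principal axes aligned. Excluding mirrors (a photograph and a top-view render
share handedness), the axis-sign ambiguity leaves exactly two proper
rotations (theta, theta + 180 degrees); the candidate maximising DSC wins,
ties broken by candidate order, and the choice is recorded in the report.
Near-circular foregrounds (anisotropy below 5%) fall back to centroid-only
alignment with a warning rather than trusting an unstable axis.

## Track B numerics

`landmarkAlign()` is the closed-form least-squares rigid fit (cross-covariance
SVD with proper-rotation correction; a reflection-favouring configuration is
forced to a rotation with a warning). Its global optimality is tested against
both a general-purpose iterative minimiser and thousands of random rigid
candidates.

`icpRefine()` is trimmed point-to-point ICP: exact nearest-neighbour
correspondence (uniform-grid index, identical to brute force), discard the
worst `outlierTrimFraction` (default 10%) by distance, closed-form rigid
update on the kept pairs. Three numerical choices deserve explanation:

* **Two-phase trimming.** Trimming from the first iteration discards
  precisely the rim-wall and ridge correspondences that constrain tangential
  motion while the clouds are still far apart; the registration then stalls
  in a flat valley. The iteration therefore first converges untrimmed, and
  only then applies the configured trimming. The robustness purpose of
  trimming (absorbing imperfect correspondences) lives in the second phase.
* **RMS monitoring.** The per-iteration statistic recorded and tested for
  monotone non-increase is the trimmed *root-mean-square* correspondence
  distance: it is the square root of the objective the rigid update
  minimises, hence provably non-increasing at fixed trim count, which the
  arithmetic mean distance is not. Convergence is declared when the RMS
  changes by less than `tolMm` (default 1e-6 mm), with a generous iteration
  cap (default 1000): the tangential pose components converge slowly under
  point-to-point correspondence on quasi-planar anatomy, and a loose cap or
  tolerance returns answers from the middle of the crawl.
* **Asymmetric densities.** Correspondence runs from the evaluated (MRI)
  cloud (default 10000 points) to the reference (CT) cloud sampled
  `dstOversample` = 6 times denser, so nearest-neighbour distances
  approximate true point-to-surface distances; sparser clouds leave a
  tangential sampling-noise floor above the accuracy the registration is
  asked for (recovery within 1.5 degrees / 0.5 mm).

ICP converges to the nearest local optimum by construction; the diagnostics
(final RMS distance, termination reason, iteration trace) are always
reported so a wrong-basin convergence on near-symmetric anatomy is visible
as a large residual rather than a silent success.

## Cohort statistics

`pearsonR()` wraps the definitional Pearson estimate with a two-sided
t-distribution p-value (n - 2 df). p-values are reported, never used to gate
anything inside the pipeline. Degenerate cohorts (constant volumes, fewer
than two volume pairs) yield an NA correlation with a warning instead of an
error: one broken case must not take down a cohort report.

`runCohort()` embeds the configuration hash, master seed, every alignment
candidate chosen and every ICP termination reason in its JSON report, and two
runs with identical configuration and seeds produce bit-identical CSV/JSON —
a tested contract.

## Problem sizes used in the tests

Unit tests run on a scaled-down phantom (36 x 26 mm plateau) where a case
takes about a second; the acceptance-style tests run the full-size default
phantom: 40 seeded cases for ICP recovery, a 6-value bias sweep
(beta = 1.0 ... 0.5, 5 seeds each) for the thickness-bias signature, and a
10-case constant-bias cohort for the volume correlation. These sizes give
stable statistics while keeping the whole suite in the tens of minutes on a
single CPU.

## Known limitations

* Only isotropic, axis-aligned grids are supported; anisotropic input is
  rejected at load rather than silently resampled.
* The world-coordinate convention (mm, voxel-centre at
  `origin + spacing * index`) is this package's choice; exports from
  clinical workstations may differ and should be checked against a known
  landmark.
* The 2D alignment search covers rotations only; if a real photograph were
  mirrored (it should not be), the alignment would report a low DSC rather
  than detect the flip.
* Point-to-point ICP with landmarks is well-posed for the plateau geometry;
  strongly symmetric or featureless shapes can converge to wrong basins,
  flagged only through the residual.
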