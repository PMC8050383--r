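---
title: "Measuring indirect spinal-canal decompression in 3D"
author: "canal3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring indirect spinal-canal decompression in 3D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canal3d)
```

## The measurement model

Percutaneous cement discoplasty (PCD) injects PMMA cement into a collapsed,
vacuum-phenomenon disc. The cement lifts the cranial vertebra of the motion
segment, and that repositioning — not bone removal — enlarges the spinal
canal and both neuroforamina. `canal3d` quantifies this *indirect
decompression* as a volume change inside a fixed measurement region:

* a cylinder of length 90 mm is placed along the coronal axis of the
  neuroforamina, with a radius (typically 10–12 mm) chosen per segment so
  that it covers the central canal and both foramina;
* the free volume of the cylinder — everything not occupied by vertebral
  bone — is measured on the preoperative and the postoperative scan with
  one shared cylinder, after the preoperative segment has been rigidly
  mapped into the postoperative frame;
* the decompression measure is the difference

  $$\Delta V = V_\mathrm{postop} - V_\mathrm{preop} \quad [\mathrm{mm}^3].$$

The free-volume (subtraction) convention matters: each $V$ is the cylinder
volume minus the bone inside it, so both values lie a little below
$\pi r^2 L$ and $\Delta V$ is positive when the lift opens the canal. The
same $\Delta V$ magnitude results if one instead tracks the overlapping
bone volume; the free-space reading is used because it is what the
per-segment result tables report.

The processing chain is: HU segmentation → watertight meshing → landmark
rigid registration → shared-cylinder volumetry, with the Dice similarity
index auditing segmentation repeatability and the Hausdorff distance
auditing alignment.

## Parameters that matter

| Parameter | Default | Unit | Role |
|---|---|---|---|
| bone HU window | [226, ∞) | HU | separates bone from soft tissue; cap the top (e.g. 1200) when cement must stay a separate structure |
| cement HU floor | 1500 | HU | PMMA is far denser than trabecular bone |
| cylinder length | 90 | mm | spans both foramina with margin; fixed by protocol |
| cylinder radius | per segment, 10–12 | mm | fills canal + foramina; recorded as provenance |
| volumetry resolution | 0.3 | mm | sampling step, half a CT voxel |
| smoothing | 6 passes, factor 0.7, shrinkage-compensated | – | mesh-stage default (see below) |
| remeshing | 0.6 mm target edge, 60° sharp angle | mm, ° | uniform triangle quality for downstream use |
| QC gates | HD ≤ 2 mm, landmark RMS ≤ 1 mm | mm | warnings, not failures |

## Numerical design choices

**Isosurface extraction.** Masks and CT fields are contoured with dual
contouring: one vertex per edge-connected inside-corner component of each
grid cell (ambiguous "checkerboard" cells stay manifold), placed by
minimizing a quadratic error function over the cell's edge-crossing points
and field-gradient normals, regularized toward the crossing centroid and
clamped to the cell. The QEF placement reproduces sharp edges instead of
chamfering them; on a voxelized 10 mm sphere the enclosed-volume error is
about 0.005%. Meshes are zero-padded before extraction so they always
close, and are emitted outward-oriented.

**Two contouring routes.** `mask_to_mesh()` contours a binary mask at 0.5
occupancy — surface positions are then quantized to the voxel grid, which
is what a mask stores. `volume_to_mesh()` contours the CT intensity field
itself at a chosen HU level: partial-volume intensities carry sub-voxel
surface information, so this is the default route in the end-to-end
pipeline (`run_config(contour = "field")`). For an unbiased surface the
iso level should be the *half-occupancy* HU — halfway between soft tissue
and the bone plateau — not the segmentation threshold; contouring at the
(lower) threshold systematically inflates every structure by a fraction of
a voxel.

**Smoothing.** `smooth_mesh()` runs uniform Laplacian passes and, with
shrinkage compensation, rescales the mesh about its volume centroid after
every pass so the enclosed volume is preserved (conservation is the
testable essence of the vendor option the protocol names). The pipeline
applies 6 passes to mask-contoured meshes, whose surfaces are terraced,
but none to field-contoured meshes: those are already smooth, and
Laplacian passes would round pedicle corners — which measurably biases
$\Delta V$ wherever a surface leaves the cylinder between the two time
points.

**Cavity filling.** `fill_mask()` offers the protocol's per-slice 2D fill
and a volumetric 3D fill. The pipeline fills volumetrically: at pedicle
level an axial vertebra cross-section is a closed ring (body, two
pedicles, arch), so a per-slice fill would flood the vertebral foramen —
the very space being measured. The 3D fill closes internal cavities while
leaving the canal open, because the canal connects to the outside through
the neuroforamina.

**Volumetry.** Free volumes are computed by sampling the cylinder interior
and classifying each point against every vertebra mesh with a parity
(ray-crossing) test; both the cylinder term and the bone term are counted
on the same sample set, so discretization errors largely cancel in the
pre/post difference. The samples are stratified — one point per grid cell,
jittered uniformly within the cell from a fixed seed — because a regular
grid aliases against surfaces that graze the cylinder (systematic error up
to half a cell per grazing face), while the stratified estimate is
unbiased with ~2 mm³ noise at 0.3 mm. The fixed seed keeps every result
bit-reproducible for identical inputs.

**Registration.** The closed-form Kabsch/SVD fit with a reflection guard;
correspondence is by landmark name and order only (no ICP refinement — the
protocol defines none). The Hausdorff audit is vertex-to-vertex, matching
the way the distance is defined on triangle-mesh vertices; a
point-to-surface variant is deliberately not the default.

**Wilcoxon convention.** The paired signed-rank test uses average ranks
for ties, drops zero differences, and takes its two-sided p-value from the
normal approximation without continuity correction — the convention that
reproduces the published p = 0.0004 on the 16 treated segments (exact
enumeration gives ~3e-5). Exact enumeration is available for n ≤ 12.

**ICC.** Two-way absolute-agreement forms ICC(A,1) and ICC(A,k) per
McGraw–Wong, with F-based 95% bounds; point estimates under the two-way
mixed and two-way random models coincide, which is why one implementation
serves the protocol's "mixed" wording.

## The phantom: what it emulates, and what it does not

`generate_phantom()` builds a fully synthetic motion segment from implicit
solids: a vertebral-body box, a posterior-arch box and two pedicles per
vertebra, enclosing a canal gap and two neuroforamina; an ellipsoidal PMMA
inclusion appears in the postoperative disc space. The cranial vertebra is
lifted by a known rigid transform, each scan is acquired under its own
small random rigid "scanner pose" (rotation 2–6°, translation ≤ 3 mm —
two real scans never share a frame), and voxels are rasterized at 0.6 mm
with partial-volume fractions (2× per-axis supersampling; `supersample =
1` yields an idealized binary phantom whose voxel counts match the
generative geometry exactly). HU levels are background 40, bone 700,
cement 1500, so the default thresholds separate the classes even with
Gaussian noise up to σ ≈ 50 HU. The default is the noiseless reference
condition under which the pipeline's accuracy bounds are stated; noise is
exercised separately in segmentation and registration tests.

Because the solids are implicit, the ground-truth oracle
(`ground_truth_delta_v()`) never touches the mesh pipeline: it classifies
stratified sample points (default 0.1 mm) analytically and subtracts the
occupied count from $\pi r^2 L$. Its noise is below 1 mm³.

Passing the phantom sweep shows that segmentation, meshing, registration
and volumetry compose correctly and that their discretization errors stay
within ~2% of ΔV across lifts of 1–5 mm and radii of 8–12 mm. It does
*not* show robustness to what the phantom lacks: real trabecular texture,
cortical-shell density gradients, osteophytes and endplate sclerosis,
metal or beam-hardening artefacts, rater variability in landmark picking,
or cement in contact with bone (the phantom keeps ≥ 1 mm clearance so the
structures remain separable without manual mask editing, which real
cement–endplate contact generally requires).

## Problem sizes

The shipped tests and the acceptance script use: full-size phantoms of
roughly 90×110×115 voxels (≈ 50–65 mm per side at 0.6 mm), a ten-phantom
sweep, volumetry at 0.3 mm (~1.1 M samples per cylinder), and the analytic
oracle at 0.1 mm (~16 M samples). Unit tests use a smaller phantom
(30×22×18 mm body) for speed; the accuracy bounds are always asserted at
full size.

## Known limitations

* Thresholds are global; no adaptive or learned segmentation (cited only
  as an outlook in the source protocol).
* The Hausdorff audit compares full caudal-vertebra meshes unless the
  caller crops; localized alignment error can hide in a global maximum
  that is dominated by tessellation differences.
* Cylinder placement is caller-supplied. The coronal foraminal axis is a
  manual, rater-dependent choice; the tool records it as provenance rather
  than inferring it.
* The per-face thickness map uses a single perpendicular ray per face (no
  cone averaging); faces whose inward ray escapes report `NA`.
* Published patient-level results that depend on the undeposited CTs and
  raters (DSI means, HD means, ICC values, PMMA–outcome correlations) are
  out of reach by construction; the phantom properties above are the
  package's substitute evidence.
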