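# canal3d

Three-dimensional volumetry of indirect spinal-canal decompression after
percutaneous cement discoplasty (PCD), from paired pre- and postoperative CT.

## The problem and the method

PCD stabilizes a severely degenerated lumbar segment by injecting PMMA bone
cement into the vacuum disc space. The cement lifts the cranial vertebra,
which indirectly enlarges the spinal canal and the neuroforamina. 2D
measurements (disc height, foramen diameter, cross-sectional areas)
undersell this complex 3D change, so `canal3d` measures it volumetrically:

1. **Segmentation** — vertebrae (and cement) are separated from soft tissue
   by Hounsfield-unit thresholding, cavity filling and connected-component
   extraction; agreement between two segmentations is scored with the Dice
   similarity index `DSI = 2 V(I1 ∩ I2) / (V(I1) + V(I2))`.
2. **Meshing** — watertight triangle surfaces via dual-contouring
   isosurface extraction (QEF vertex placement), optional Laplacian
   smoothing with shrinkage compensation (6 passes, factor 0.7) and uniform
   remeshing (0.6 mm target edge, 60° sharp-edge preservation).
3. **Rigid alignment** — the preoperative segment is mapped into the
   postoperative frame by a closed-form (Kabsch/SVD) least-squares fit on
   18 corresponding anatomical landmarks of the caudal vertebra; quality is
   audited with the vertex-to-vertex Hausdorff distance
   `h(A,B) = max_a min_b d(a,b)` (QC gate 2 mm).
4. **Cylinder volumetry** — a measurement cylinder (length 90 mm, radius
   10–12 mm chosen per segment) is placed along the coronal axis of the
   neuroforamina; the free (non-bone) volume inside it is computed for both
   time points with one shared cylinder, and

   **ΔV = V_postop − V_preop**

   is the indirect decompression measure, in mm³.
5. **Statistics** — per-segment descriptive statistics (mean, sample SD,
   CV), paired Wilcoxon signed-rank (normal approximation), Spearman rank
   correlations, and two-way absolute-agreement ICC (single and mean-k
   forms) with 95% CIs.

Because no patient CTs are distributable, the package ships a **synthetic
motion-segment phantom**: two vertebra-like implicit solids (body,
posterior arch, pedicles) around a canal and neuroforamina, a PMMA
inclusion, a known rigid lift, partial-volume rasterization at 0.6 mm, and
an independent analytic fine-grid oracle for ΔV. Every pipeline stage is
verifiable end to end against that ground truth.

## Worked example

```r
library(canal3d)

# a synthetic patient: 3 mm cement lift, 11 mm measurement cylinder
ph  <- generate_phantom(phantom_spec(seed = 7, lift_mm = 3))
cfg <- run_config(bone_hi = 1200, contour_iso = 370,
                  cylinder = ph$truth$cylinder_post)
out <- measure_segment(ph$pre, ph$post,
                       ph$truth$landmarks_pre, ph$truth$landmarks_post, cfg)
out$result
#> <measurement_result> V_preop 29856.28, V_postop 31222.61, delta-V 1366.34 mm^3
#>   cylinder r 11 mm x L 90 mm, sampling 0.3 mm
out$alignment
#> <alignment_report> landmark RMS 5.862e-15 mm, HD 1.452 mm (symmetric 1.452 mm)

truth <- ground_truth_delta_v(ph$truth)   # independent analytic oracle
truth$delta_v
#> [1] 1366.216
```

The measured ΔV (1366.3 mm³) agrees with the analytic truth (1366.2 mm³)
to 0.01%; the landmark RMS is numerically zero (noiseless landmarks) and
the caudal Hausdorff distance sits well under the 2 mm QC gate.

The published per-segment table of the clinical cohort is packaged:

```r
t2 <- pcd_table2()
descriptive(t2$delta_v_mm3)[c("mean", "sd")]
#> $mean [1] 2295.14     $sd [1] 1181.421
wilcoxon_signed_rank(t2$v_pre_mm3, t2$v_post_mm3)
#> Paired Wilcoxon signed-rank (normal approximation, no continuity correction),
#> two-sided: statistic 136, p = 0.0004378 (n = 16)
```

## Layout

- `R/`, `src/` — implementation (geometry kernels in Rcpp)
- `tests/testthat/` — unit, property and acceptance suites
- `vignettes/canal-volumetry.Rmd` — the methods vignette
- `inst/extdata/pcd_table2.csv` — packaged per-segment cohort table
- `inst/cli/canal3d` — command-line interface
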