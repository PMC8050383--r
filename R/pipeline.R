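# End-to-end orchestration of the measurement workflow:
# segment -> mesh -> rigid alignment on the caudal vertebra -> shared-cylinder
# volumetry, with QC gates and provenance.

#' Pipeline run configuration
#'
#' Collects every tunable of the measurement workflow. The configuration is
#' serialisable; its hash is recorded in each result for provenance.
#'
#' @param bone_lo,bone_hi HU window for the vertebra segmentation (226 HU is
#'   a common CT bone preset; cap `bone_hi` when dense cement must stay
#'   separate).
#' @param fill cavity filling mode (see [fill_mask()]). The pipeline
#'   default is `"3d"`: at pedicle levels an axial vertebra cross-section
#'   is a closed ring (body, pedicles, arch), so per-slice filling would
#'   fill the vertebral foramen itself and corrupt the canal volume;
#'   volumetric filling keeps the canal open (it connects to the outside
#'   through the neuroforamina) while still closing internal cavities.
#' @param contour `"field"` (default) isosurfaces the CT intensity field
#'   within each component via [volume_to_mesh()], exploiting
#'   partial-volume information for sub-voxel surfaces; `"mask"` contours
#'   the binary component mask via [mask_to_mesh()].
#' @param contour_iso HU level for field contouring; `NULL` falls back to
#'   `bone_lo`. Set it to the half-occupancy level (halfway between soft
#'   tissue and the bone plateau) for unbiased surface placement.
#' @param presmooth occupancy presmoothing passes before isosurfacing when
#'   `contour = "mask"` (see [mask_to_mesh()]).
#' @param smooth_iterations,smooth_factor,compensate_shrinkage mesh
#'   smoothing stage (see [smooth_mesh()]). `smooth_iterations = NULL`
#'   (default) resolves to 6 passes for `contour = "mask"` (binary-mask
#'   isosurfaces are terraced and need them) and to 0 for
#'   `contour = "field"` (partial-volume interpolation already yields
#'   smooth surfaces, and Laplacian passes would round corners and bias
#'   volumes near grazing geometry).
#' @param remesh run uniform remeshing after smoothing (default off: it
#'   refines triangle quality but leaves enclosed volumes unchanged within
#'   tolerance, so volumetry does not need it).
#' @param remesh_params a [remesh_params()] list.
#' @param cylinder the shared `measurement_cylinder`, in the postoperative
#'   frame.
#' @param resolution volumetry sampling step, mm.
#' @param hd_gate,rms_gate QC warning thresholds (mm) for the caudal
#'   Hausdorff distance and the landmark RMS.
#' @return A `run_config` list with a `hash` field.
#' @export
run_config <- function(bone_lo = 226, bone_hi = Inf,
                       fill = "3d", contour = "field", contour_iso = NULL,
                       presmooth = 1,
                       smooth_iterations = NULL, smooth_factor = 0.7,
                       compensate_shrinkage = TRUE,
                       remesh = FALSE, remesh_params = NULL,
                       cylinder = NULL, resolution = 0.3,
                       hd_gate = 2, rms_gate = 1) {
  cfg <- list(bone_lo = bone_lo, bone_hi = bone_hi, fill = fill,
              contour = contour, contour_iso = contour_iso,
              presmooth = presmooth,
              smooth_iterations = smooth_iterations %||%
                (if (identical(contour, "mask")) 6L else 0L),
              smooth_factor = smooth_factor,
              compensate_shrinkage = compensate_shrinkage,
              remesh = remesh,
              remesh_params = remesh_params %||% canal3d::remesh_params(),
              cylinder = cylinder, resolution = resolution,
              hd_gate = hd_gate, rms_gate = rms_gate)
  cfg$hash <- config_hash(cfg[setdiff(names(cfg), "hash")])
  structure(cfg, class = "run_config")
}

# segment one CT into its two vertebra meshes; caudal identified as the
# component whose centroid is nearest the landmark centroid
segment_to_meshes <- function(ct, landmarks, config, stage) {
  mask <- threshold_mask(ct, config$bone_lo, config$bone_hi)
  if (!any(mask$occupancy))
    stopf("[%s] empty bone mask with HU window [%g, %g]", stage,
          config$bone_lo, config$bone_hi)
  comps <- split_components(mask)
  if (length(comps) < 2)
    stopf("[%s] expected two vertebrae, found %d component(s)", stage, length(comps))
  comps <- comps[1:2]
  if (config$fill != "none")
    comps <- lapply(comps, fill_mask, mode = config$fill)
  meshes <- lapply(comps, function(m) {
    mesh <- if (identical(config$contour, "mask")) {
      mask_to_mesh(m, presmooth = config$presmooth %||% 0)
    } else {
      # other thresholded structures, plus the partial-volume skirt of
      # anything denser than the bone window (e.g. cement touching bone)
      other_occ <- mask$occupancy & !m$occupancy
      if (is.finite(config$bone_hi)) {
        dense <- dilate3(dilate3(ct$voxels > config$bone_hi))
        other_occ <- other_occ | dense
      }
      volume_to_mesh(ct, config$contour_iso %||% config$bone_lo, mask = m,
                     exclude = binary_mask(other_occ, grid = mask),
                     hi = config$bone_hi)
    }
    if (config$smooth_iterations > 0)
      mesh <- smooth_mesh(mesh, config$smooth_iterations, config$smooth_factor,
                          config$compensate_shrinkage)
    if (isTRUE(config$remesh))
      mesh <- remesh_uniform(mesh, config$remesh_params)
    mesh
  })
  lc <- colMeans(landmarks$points)
  d <- vapply(meshes, function(m) vnorm(colMeans(m$vertices) - lc), numeric(1))
  list(caudal = meshes[[which.min(d)]], cranial = meshes[[which.max(d)]])
}

#' Measure one treated segment end to end
#'
#' Runs the full workflow on one motion segment: HU segmentation of both
#' CT scans, watertight meshing with smoothing, landmark-based rigid
#' registration of the preoperative segment into the postoperative frame
#' (fitted on the caudal-vertebra landmarks, applied to the whole
#' segment), Hausdorff-distance QC on the aligned caudal vertebrae, and
#' shared-cylinder volumetry yielding delta-V. QC breaches (Hausdorff or
#' landmark RMS above their gates) set warning flags but do not abort.
#'
#' @param pre_ct,post_ct `ct_volume` scans of the motion segment.
#' @param landmarks_pre,landmarks_post corresponding `landmark_set`s picked
#'   on the caudal vertebra (same names, same order).
#' @param config a [run_config()] whose `cylinder` is set (postop frame).
#' @return List: `result` (a `measurement_result`), `alignment` (an
#'   `alignment_report`), `qc` (named logical flags), `meshes`.
#' @export
measure_segment <- function(pre_ct, post_ct, landmarks_pre, landmarks_post,
                            config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$cylinder))
    stopf("[config] run_config$cylinder must be a measurement_cylinder")
  pre <- segment_to_meshes(pre_ct, landmarks_pre, config, "segment preop")
  post <- segment_to_meshes(post_ct, landmarks_post, config, "segment postop")
  tr <- fit_rigid_landmarks(landmarks_pre, landmarks_post)
  pre_aligned <- lapply(pre, apply_transform, transform = tr)
  align <- alignment_report(tr, pre_aligned$caudal, post$caudal)
  qc <- c(hd_above_gate = align$hausdorff_symmetric > config$hd_gate,
          rms_above_gate = align$landmark_rms > config$rms_gate)
  if (qc["hd_above_gate"])
    warnf("caudal Hausdorff distance %.2f mm exceeds the %.2f mm QC gate",
          align$hausdorff_symmetric, config$hd_gate)
  result <- measure_delta_v(unname(pre_aligned), unname(post), config$cylinder,
                            config$resolution,
                            provenance = list(config_hash = config$hash,
                                              qc = as.list(qc)))
  list(result = result, alignment = align, qc = qc,
       meshes = list(pre = pre_aligned, post = post))
}

#' Batch measurement over a manifest
#'
#' Processes a manifest (CSV path or data.frame) with one row per treated
#' segment and columns `patient`, `segment`, `pre_ct`, `post_ct`,
#' `landmarks_pre`, `landmarks_post`, cylinder placement
#' (`anchor_x/y/z`, `dir_x/y/z`, `radius`, optional `length`, default 90).
#' Rows that fail are logged and skipped; the run continues.
#'
#' @param manifest CSV path or data.frame.
#' @param config a [run_config()] used for every row (its cylinder is
#'   overridden per row).
#' @return List: `results` (data.frame of rows in the clinical table
#'   layout), `failures` (named character), `summary` (delta-V mean/SD/CV
#'   via [descriptive()]).
#' @export
batch_measure <- function(manifest, config = run_config()) {
  if (is.character(manifest)) manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  if (nrow(manifest) == 0) stopf("empty manifest")
  rows <- list()
  failures <- character()
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    res <- tryCatch({
      cyl <- make_cylinder(c(r$anchor_x, r$anchor_y, r$anchor_z),
                           c(r$dir_x, r$dir_y, r$dir_z),
                           length = if ("length" %in% names(r)) r$length else 90,
                           radius = r$radius)
      cfg <- config
      cfg$cylinder <- cyl
      out <- measure_segment(read_ct_volume(r$pre_ct), read_ct_volume(r$post_ct),
                             read_landmarks(r$landmarks_pre, frame = "preop"),
                             read_landmarks(r$landmarks_post, frame = "postop"),
                             cfg)
      result_row(out$result, patient = r$patient, segment = r$segment)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[sprintf("%s %s (row %d)", r$patient, r$segment, i)] <- conditionMessage(res)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else NULL
  summary <- if (length(rows) >= 2) descriptive(results$delta_v_mm3) else NULL
  list(results = results, failures = failures, summary = summary)
}
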