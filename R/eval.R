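#' Dice overlap coefficient between two binary masks
#'
#' \eqn{D = 2|A \cap B| / (|A| + |B|)}: 1 iff the masks are identical
#' (defined as 1 when both are empty), 0 iff they are disjoint.
#'
#' @param a,b binary \linkS4class{ScalarVolume}s or arrays on the same grid.
#' @return a number in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  av <- if (is(a, "ScalarVolume")) a@values else a
  bv <- if (is(b, "ScalarVolume")) b@values else b
  if (!identical(dim(av), dim(bv)))
    stop("precondition error: masks are on different grids")
  if (is(a, "ScalarVolume") && is(b, "ScalarVolume") &&
      (max(abs(a@spacing - b@spacing)) > 1e-6 ||
       max(abs(a@origin - b@origin)) > 1e-6))
    stop("precondition error: masks are on different grids (geometry mismatch)")
  am <- av > 0; bm <- bv > 0
  na <- sum(am); nb <- sum(bm)
  if (na + nb == 0) return(1.0)
  2 * sum(am & bm) / (na + nb)
}

#' Symmetric distance between two centerlines
#'
#' Both polylines are densely resampled (default 0.1 mm) and the
#' point-to-polyline distances are measured in both directions; the
#' symmetric mean and maximum are returned.
#'
#' @param extracted,truth \linkS4class{CenterlineCurve}s.
#' @param sampleStepMm resampling step for the distance estimate (mm).
#' @return named numeric: \code{mean} and \code{max} distance in mm.
#' @export
centerlineDistance <- function(extracted, truth, sampleStepMm = 0.1) {
  stopifnot(is(extracted, "CenterlineCurve"), is(truth, "CenterlineCurve"))
  pa <- densify_polyline(extracted@vertices, sampleStepMm)
  pb <- densify_polyline(truth@vertices, sampleStepMm)
  dab <- cpp_dist_to_polyline(pa, truth@vertices)
  dba <- cpp_dist_to_polyline(pb, extracted@vertices)
  c(mean = (mean(dab) + mean(dba)) / 2, max = max(dab, dba))
}

#' Pipeline configuration
#'
#' Collects every tunable of the segmentation pipeline with its default.
#' The snapshot stored in the run report is exactly this list, so a run can
#' be reproduced from its report.
#'
#' @param vesselness see [vesselnessParams()].
#' @param path see [pathGraphParams()].
#' @param bboxMarginMm graph restriction margin for the centerline search
#'   (mm).
#' @param factor odd super-resolution factor (see [upsampleVolume()]).
#' @param seedRadiusMm exterior-seed radius r (mm); see [seedConfig()].
#' @param roiMarginMm ROI dilation margin; defaults to
#'   \code{seedRadiusMm + 5} so exterior seeds exist inside the ROI.
#' @param connectivity propagation neighbourhood (26 = Moore).
#' @param restrictPropagation run propagation on the undetermined tube plus
#'   its exterior shell instead of the full ROI grid (see
#'   [propagateLabels()]).
#' @param largestComponent keep only the largest connected lumen component.
#' @param surfaceSmoothSigmaMm isosurface pre-smoothing; NULL = one subvoxel.
#' @param flythroughStepMm camera keyframe spacing (mm).
#' @return a configuration list for [runPipeline()].
#' @export
pipelineConfig <- function(vesselness = vesselnessParams(),
                           path = pathGraphParams(),
                           bboxMarginMm = 20,
                           factor = 5L,
                           seedRadiusMm = 10,
                           roiMarginMm = seedRadiusMm + 5,
                           connectivity = 26,
                           restrictPropagation = TRUE,
                           largestComponent = TRUE,
                           surfaceSmoothSigmaMm = NULL,
                           flythroughStepMm = 1) {
  list(vesselness = vesselness, path = path, bboxMarginMm = bboxMarginMm,
       factor = as.integer(factor), seedRadiusMm = seedRadiusMm,
       roiMarginMm = roiMarginMm, connectivity = connectivity,
       restrictPropagation = restrictPropagation,
       largestComponent = largestComponent,
       surfaceSmoothSigmaMm = surfaceSmoothSigmaMm,
       flythroughStepMm = flythroughStepMm)
}

#' Run the full duct segmentation pipeline
#'
#' Executes, in order: tubularity map, optimal-path centerline through the
#' fiducials, ROI crop and super-resolution, seed-map construction,
#' intensity-geodesic label propagation, lumen mask extraction (plus
#' majority-vote downsampling to the original grid), surface
#' reconstruction with Gaussian-curvature map, and fly-through camera path.
#' Per-stage wall-clock times are recorded; when a ground-truth mask (and
#' optionally a truth centerline) is supplied, Dice and centerline-distance
#' metrics are added to the report.
#'
#' @param image a \linkS4class{ScalarVolume} CT image.
#' @param fiducials a \linkS4class{FiducialSet} (duct head first, tail last).
#' @param config see [pipelineConfig()].
#' @param truthMask optional ground-truth lumen mask on the image grid.
#' @param truthCenterline optional ground-truth
#'   \linkS4class{CenterlineCurve}.
#' @param verbose log stage progress and parameters to stderr.
#' @return a list with \code{mask} (original grid), \code{maskRoi}
#'   (super-resolved grid), \code{centerline}, \code{mesh},
#'   \code{cameraPath}, \code{vesselness}, \code{roi}, \code{labels}
#'   and \code{report} (metrics, per-stage runtimes, config snapshot).
#' @export
runPipeline <- function(image, fiducials, config = pipelineConfig(),
                        truthMask = NULL, truthCenterline = NULL,
                        verbose = FALSE) {
  stopifnot(is(image, "ScalarVolume"), is(fiducials, "FiducialSet"))
  say <- function(...) if (verbose) message("[DuctScope] ", ...)
  times <- c()
  stage <- function(name, expr) {
    say(name, " ...")
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    times[[name]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  V <- stage("vesselness", computeVesselness(image, config$vesselness))
  cl <- stage("centerline",
              extractCenterline(V, fiducials, config$path, config$bboxMarginMm))
  crop <- stage("crop", cropRoi(image, cl, config$roiMarginMm))
  roi <- stage("upsample",
               upsampleVolume(crop$volume, config$factor, crop$indexOffset))
  seeds <- stage("seeds",
                 buildSeedMap(roi, cl, seedConfig(config$seedRadiusMm)))
  labels <- stage("propagate",
                  propagateLabels(roi, seeds, config$connectivity,
                                  config$restrictPropagation))
  masks <- stage("mask",
                 lumenMask(labels, roi, image, config$largestComponent))
  mesh <- stage("surface", {
    m <- extractSurface(masks$mask, config$surfaceSmoothSigmaMm)
    gaussianCurvatureMap(m)
  })
  cam <- stage("flythrough", cameraPath(cl, config$flythroughStepMm))

  report <- list(parameters = config, runtime_s = as.list(times),
                 n_lumen_voxels = sum(masks$mask@values > 0),
                 n_lumen_voxels_original = sum(masks$maskOriginal@values > 0))
  if (!is.null(truthMask)) {
    report$dice <- diceCoefficient(masks$maskOriginal, truthMask)
    say(sprintf("Dice vs truth: %.4f", report$dice))
  }
  if (!is.null(truthCenterline)) {
    cd <- centerlineDistance(cl, truthCenterline)
    report$mean_centerline_distance_mm <- cd[["mean"]]
    report$hausdorff_mm <- cd[["max"]]
  }
  list(mask = masks$maskOriginal, maskRoi = masks$mask, centerline = cl,
       mesh = mesh, cameraPath = cam, vesselness = V, roi = roi,
       labels = labels, report = report)
}
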