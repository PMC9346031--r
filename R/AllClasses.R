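#' @useDynLib DuctScope, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' ScalarVolume: a 3D scalar image with physical geometry
#'
#' The central image container. Values are stored as a plain 3D array
#' indexed (i, j, k); the physical position (in mm, LPS convention) of the
#' centre of voxel (i, j, k) -- 0-based -- is
#' \code{origin + direction \%*\% (spacing * c(i, j, k))}.
#'
#' @slot values 3D numeric array of voxel values.
#' @slot spacing numeric(3), voxel edge lengths in mm (all > 0).
#' @slot origin numeric(3), physical position of voxel (0,0,0) in mm.
#' @slot direction 3x3 orthonormal direction cosine matrix.
#' @export
setClass("ScalarVolume",
  representation(values = "array", spacing = "numeric",
                 origin = "numeric", direction = "matrix"),
  prototype(values = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0), direction = diag(3)))

setValidity("ScalarVolume", function(object) {
  msgs <- character()
  if (length(dim(object@values)) != 3L)
    msgs <- c(msgs, "values must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be 3 positive finite reals (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msgs <- c(msgs, "origin must be 3 finite reals (mm)")
  D <- object@direction
  if (!all(dim(D) == c(3L, 3L)) ||
      max(abs(crossprod(D) - diag(3))) > 1e-6)
    msgs <- c(msgs, "direction must be a 3x3 orthonormal matrix")
  if (length(msgs)) msgs else TRUE
})

#' FiducialSet: ordered physical-space landmarks
#'
#' An ordered list of user-placed 3D points in mm (LPS). The first point is
#' the duct head and the last point the duct tail; intermediate points are
#' optional waypoints the centerline must pass through.
#'
#' @slot points N x 3 numeric matrix of physical points (mm, LPS).
#' @slot labels character vector of point names (may be empty strings).
#' @export
setClass("FiducialSet",
  representation(points = "matrix", labels = "character"),
  prototype(points = matrix(0, 2, 3), labels = c("F-1", "F-2")))

setValidity("FiducialSet", function(object) {
  msgs <- character()
  if (ncol(object@points) != 3L) msgs <- c(msgs, "points must be N x 3")
  if (nrow(object@points) < 2L) msgs <- c(msgs, "at least 2 fiducials required")
  if (length(object@labels) != nrow(object@points))
    msgs <- c(msgs, "labels must have one entry per point")
  if (any(!is.finite(object@points))) msgs <- c(msgs, "points must be finite")
  if (length(msgs)) msgs else TRUE
})

#' CenterlineCurve: an ordered polyline with arc length and path cost
#'
#' @slot vertices N x 3 numeric matrix of points (mm, LPS).
#' @slot arclength numeric(N), cumulative polyline length from the first
#'   vertex (mm); nondecreasing, starts at 0.
#' @slot cost accumulated optimal-path cost (>= 0; NA when the curve was not
#'   produced by the path optimizer, e.g. ground-truth curves).
#' @slot sectionBreaks integer vector of vertex indices (1-based) where
#'   consecutive fiducial-to-fiducial sections join; tangents are not
#'   computed across these joints.
#' @export
setClass("CenterlineCurve",
  representation(vertices = "matrix", arclength = "numeric",
                 cost = "numeric", sectionBreaks = "integer"),
  prototype(vertices = matrix(0, 1, 3), arclength = 0,
            cost = NA_real_, sectionBreaks = integer()))

setValidity("CenterlineCurve", function(object) {
  msgs <- character()
  n <- nrow(object@vertices)
  if (ncol(object@vertices) != 3L) msgs <- c(msgs, "vertices must be N x 3")
  if (length(object@arclength) != n)
    msgs <- c(msgs, "arclength must have one entry per vertex")
  else {
    if (n > 0 && abs(object@arclength[1]) > 1e-12)
      msgs <- c(msgs, "arclength must start at 0")
    if (n > 1 && any(diff(object@arclength) < -1e-9))
      msgs <- c(msgs, "arclength must be nondecreasing")
  }
  if (length(object@sectionBreaks) &&
      (any(object@sectionBreaks < 1L) || any(object@sectionBreaks > n)))
    msgs <- c(msgs, "sectionBreaks out of range")
  if (length(msgs)) msgs else TRUE
})

#' RoiVolume: a cropped, super-resolved region of interest
#'
#' A \linkS4class{ScalarVolume} on the refined subvoxel grid, together with
#' the bookkeeping needed to map back to the original image grid.
#'
#' @slot indexOffset integer(3), 0-based voxel index of the crop corner in
#'   the original grid.
#' @slot factor integer(1), the odd per-axis refinement factor c applied.
#' @export
setClass("RoiVolume",
  contains = "ScalarVolume",
  representation(indexOffset = "integer", factor = "integer"),
  prototype(indexOffset = c(0L, 0L, 0L), factor = 1L))

setValidity("RoiVolume", function(object) {
  msgs <- character()
  if (length(object@indexOffset) != 3L || any(object@indexOffset < 0L))
    msgs <- c(msgs, "indexOffset must be 3 nonnegative integers")
  if (length(object@factor) != 1L || object@factor < 1L ||
      object@factor %% 2L == 0L)
    msgs <- c(msgs, "factor must be an odd positive integer")
  if (length(msgs)) msgs else TRUE
})

#' SeedLabelMap: a {0,1,2} label volume over the ROI grid
#'
#' Label 1 marks voxels known to be inside the lumen (the rasterized
#' centerline), label 2 voxels known to be outside (farther than the seed
#' radius r from the centerline), and label 0 undetermined voxels awaiting
#' geodesic propagation.
#'
#' @slot labels 3D integer array over {0,1,2}.
#' @slot counts named integer(3): voxels per label, names "0","1","2".
#' @slot spacing,origin,direction grid geometry (as ScalarVolume).
#' @export
setClass("SeedLabelMap",
  representation(labels = "array", counts = "integer", spacing = "numeric",
                 origin = "numeric", direction = "matrix"),
  prototype(labels = array(0L, c(1, 1, 1)), counts = c(`0` = 1L, `1` = 0L, `2` = 0L),
            spacing = c(1, 1, 1), origin = c(0, 0, 0), direction = diag(3)))

setValidity("SeedLabelMap", function(object) {
  msgs <- character()
  if (!all(object@labels %in% 0:2))
    msgs <- c(msgs, "labels must take values in {0, 1, 2}")
  if (sum(object@counts) != length(object@labels))
    msgs <- c(msgs, "counts must sum to the number of voxels")
  if (length(msgs)) msgs else TRUE
})

#' TriangleMesh: a triangulated surface with per-vertex scalars
#'
#' @slot vertices V x 3 numeric matrix (mm, LPS).
#' @slot faces F x 3 integer matrix of 1-based vertex indices, consistently
#'   wound (outward normals).
#' @slot vertexScalars named list of numeric vectors of length V (e.g.
#'   \code{"gaussian_curvature"} in 1/mm^2).
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix",
                 vertexScalars = "list"),
  prototype(vertices = matrix(0, 0, 3),
            faces = matrix(0L, 0, 3), vertexScalars = list()))

setValidity("TriangleMesh", function(object) {
  msgs <- character()
  if (ncol(object@vertices) != 3L) msgs <- c(msgs, "vertices must be V x 3")
  if (ncol(object@faces) != 3L) msgs <- c(msgs, "faces must be F x 3")
  if (nrow(object@faces) &&
      (min(object@faces) < 1L || max(object@faces) > nrow(object@vertices)))
    msgs <- c(msgs, "faces index out-of-range vertices")
  bad <- vapply(object@vertexScalars, function(s)
    length(s) != nrow(object@vertices), logical(1))
  if (any(bad)) msgs <- c(msgs, "vertexScalars must have one value per vertex")
  if (length(msgs)) msgs else TRUE
})

#' CameraPath: fly-through keyframes along the duct
#'
#' @slot positions N x 3 camera positions (mm).
#' @slot viewDirs N x 3 unit view directions (spline tangents).
#' @slot upDirs N x 3 unit up vectors, parallel-transported along the path.
#' @slot stepMm sampling step used (mm).
#' @export
setClass("CameraPath",
  representation(positions = "matrix", viewDirs = "matrix",
                 upDirs = "matrix", stepMm = "numeric"),
  prototype(positions = matrix(0, 0, 3), viewDirs = matrix(0, 0, 3),
            upDirs = matrix(0, 0, 3), stepMm = 1))

setValidity("CameraPath", function(object) {
  msgs <- character()
  n <- nrow(object@positions)
  if (nrow(object@viewDirs) != n || nrow(object@upDirs) != n)
    msgs <- c(msgs, "positions/viewDirs/upDirs must have equal rows")
  if (n) {
    if (max(abs(sqrt(rowSums(object@viewDirs^2)) - 1)) > 1e-6)
      msgs <- c(msgs, "viewDirs must be unit vectors")
    if (max(abs(sqrt(rowSums(object@upDirs^2)) - 1)) > 1e-6)
      msgs <- c(msgs, "upDirs must be unit vectors")
  }
  if (length(msgs)) msgs else TRUE
})

#' PhantomSpec: parameters of the synthetic duct phantom
#'
#' Describes a CT-like block of enhanced parenchyma embedded in darker
#' background, with a hypodense tube (the duct) swept along a smooth curve.
#' Intensities are HU-like configuration values, not scanner physics.
#'
#' @slot shape integer(3) grid size.
#' @slot spacing numeric(3) voxel size, mm.
#' @slot ductPath K x 3 matrix of control points (mm) of the duct curve.
#' @slot ductRadius tube radius, mm.
#' @slot intensityBackground,intensityParenchyma,intensityDuct HU-like values;
#'   the duct must be hypodense (\code{intensityDuct < intensityParenchyma}).
#' @slot parenchymaMargin inset of the parenchyma block from the volume
#'   faces, mm.
#' @slot noiseSigma additive Gaussian noise SD (HU-like).
#' @slot blurSigmaMm partial-volume Gaussian blur SD, mm.
#' @slot seed integer RNG seed (local to the generator call).
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric", ductPath = "matrix",
                 ductRadius = "numeric", intensityBackground = "numeric",
                 intensityParenchyma = "numeric", intensityDuct = "numeric",
                 parenchymaMargin = "numeric", noiseSigma = "numeric",
                 blurSigmaMm = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msgs <- character()
  if (length(object@shape) != 3L || any(object@shape < 4L))
    msgs <- c(msgs, "shape must be 3 integers >= 4")
  if (any(object@spacing <= 0)) msgs <- c(msgs, "spacing must be positive")
  if (ncol(object@ductPath) != 3L || nrow(object@ductPath) < 2L)
    msgs <- c(msgs, "ductPath needs >= 2 control points (K x 3)")
  if (object@ductRadius <= 0) msgs <- c(msgs, "ductRadius must be positive")
  if (object@intensityDuct >= object@intensityParenchyma)
    msgs <- c(msgs, "duct must be hypodense: intensityDuct < intensityParenchyma")
  if (object@noiseSigma < 0 || object@blurSigmaMm < 0)
    msgs <- c(msgs, "noiseSigma and blurSigmaMm must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' PhantomTruth: a generated phantom with exact ground truth
#'
#' @slot image the noisy, blurred CT-like \linkS4class{ScalarVolume}.
#' @slot ductMask exact (un-noised, un-blurred) swept-tube indicator volume.
#' @slot centerline ground-truth \linkS4class{CenterlineCurve}.
#' @slot headTail \linkS4class{FiducialSet} with the duct endpoints.
#' @export
setClass("PhantomTruth",
  representation(image = "ScalarVolume", ductMask = "ScalarVolume",
                 centerline = "CenterlineCurve", headTail = "FiducialSet"))
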