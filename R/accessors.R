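#' @rdname ScalarVolume-class
#' @aliases imageData,ScalarVolume-method
setMethod("imageData", "ScalarVolume", function(x) x@values)

#' @rdname ScalarVolume-class
setMethod("voxelSpacing", "ScalarVolume", function(x) x@spacing)

#' @rdname ScalarVolume-class
setMethod("volumeOrigin", "ScalarVolume", function(x) x@origin)

#' @rdname ScalarVolume-class
setMethod("volumeDirection", "ScalarVolume", function(x) x@direction)

#' @rdname ScalarVolume-class
setMethod("dim", "ScalarVolume", function(x) dim(x@values))

#' @rdname FiducialSet-class
setMethod("fiducialPoints", "FiducialSet", function(x) x@points)

#' @rdname FiducialSet-class
setMethod("fiducialLabels", "FiducialSet", function(x) x@labels)

#' @rdname FiducialSet-class
setMethod("length", "FiducialSet", function(x) nrow(x@points))

#' @rdname CenterlineCurve-class
setMethod("curveVertices", "CenterlineCurve", function(x) x@vertices)

#' @rdname CenterlineCurve-class
setMethod("curveArclength", "CenterlineCurve", function(x) x@arclength)

#' @rdname CenterlineCurve-class
setMethod("curveCost", "CenterlineCurve", function(x) x@cost)

#' @rdname CenterlineCurve-class
setMethod("sectionBreaks", "CenterlineCurve", function(x) x@sectionBreaks)

#' @rdname CenterlineCurve-class
setMethod("length", "CenterlineCurve", function(x) nrow(x@vertices))

#' @rdname TriangleMesh-class
setMethod("meshVertices", "TriangleMesh", function(x) x@vertices)

#' @rdname TriangleMesh-class
setMethod("meshFaces", "TriangleMesh", function(x) x@faces)

#' @rdname TriangleMesh-class
setMethod("vertexScalars", "TriangleMesh", function(x) x@vertexScalars)

#' @rdname SeedLabelMap-class
setMethod("labelData", "SeedLabelMap", function(x) x@labels)

#' @rdname SeedLabelMap-class
setMethod("labelCounts", "SeedLabelMap", function(x) x@counts)

setMethod("show", "ScalarVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("ScalarVolume %d x %d x %d, spacing (%.4g, %.4g, %.4g) mm\n",
              d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  origin (%.4g, %.4g, %.4g) mm [LPS], value range [%.4g, %.4g]\n",
              object@origin[1], object@origin[2], object@origin[3],
              min(object@values), max(object@values)))
})

setMethod("show", "RoiVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "RoiVolume %d x %d x %d (factor %d, crop offset %d,%d,%d), spacing (%.4g, %.4g, %.4g) mm\n",
    d[1], d[2], d[3], object@factor,
    object@indexOffset[1], object@indexOffset[2], object@indexOffset[3],
    object@spacing[1], object@spacing[2], object@spacing[3]))
})

setMethod("show", "FiducialSet", function(object) {
  cat(sprintf("FiducialSet of %d points (mm, LPS)\n", nrow(object@points)))
  df <- data.frame(label = object@labels, object@points)
  colnames(df) <- c("label", "x", "y", "z")
  print(utils::head(df, 6), row.names = FALSE)
  if (nrow(df) > 6) cat(sprintf("  ... and %d more\n", nrow(df) - 6L))
})

setMethod("show", "CenterlineCurve", function(object) {
  n <- nrow(object@vertices)
  cat(sprintf("CenterlineCurve: %d vertices, length %.2f mm, cost %s\n",
              n, if (n) object@arclength[n] else 0,
              if (is.na(object@cost)) "NA" else sprintf("%.4g", object@cost)))
  if (length(object@sectionBreaks))
    cat("  section joints at vertices:",
        paste(object@sectionBreaks, collapse = ", "), "\n")
})

setMethod("show", "SeedLabelMap", function(object) {
  d <- dim(object@labels)
  cat(sprintf("SeedLabelMap %d x %d x %d: %d lumen seeds (1), %d exterior seeds (2), %d undetermined (0)\n",
              d[1], d[2], d[3],
              object@counts[["1"]], object@counts[["2"]], object@counts[["0"]]))
})

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces", nrow(object@vertices),
              nrow(object@faces)))
  if (length(object@vertexScalars))
    cat(", scalars:", paste(names(object@vertexScalars), collapse = ", "))
  cat("\n")
})

setMethod("show", "CameraPath", function(object) {
  cat(sprintf("CameraPath: %d keyframes, step %.3g mm\n",
              nrow(object@positions), object@stepMm))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec %d x %d x %d @ (%.3g, %.3g, %.3g) mm, duct radius %.3g mm\n",
    object@shape[1], object@shape[2], object@shape[3],
    object@spacing[1], object@spacing[2], object@spacing[3],
    object@ductRadius))
  cat(sprintf("  intensities bg/parenchyma/duct = %.4g/%.4g/%.4g, noise %.3g, blur %.3g mm, seed %d\n",
              object@intensityBackground, object@intensityParenchyma,
              object@intensityDuct, object@noiseSigma, object@blurSigmaMm,
              object@seed))
})

setMethod("show", "PhantomTruth", function(object) {
  cat("PhantomTruth containing:\n image: ")
  show(object@image)
  cat(sprintf(" ductMask: %d voxels in mask\n", sum(object@ductMask@values)))
  cat(" centerline: ")
  show(object@centerline)
})
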