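#' @rdname ScalarVolume-class
#' @param object,x a DuctScope S4 object
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))

#' @rdname ScalarVolume-class
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname ScalarVolume-class
#' @export
setGeneric("volumeOrigin", function(x) standardGeneric("volumeOrigin"))

#' @rdname ScalarVolume-class
#' @export
setGeneric("volumeDirection", function(x) standardGeneric("volumeDirection"))

#' @rdname FiducialSet-class
#' @export
setGeneric("fiducialPoints", function(x) standardGeneric("fiducialPoints"))

#' @rdname FiducialSet-class
#' @export
setGeneric("fiducialLabels", function(x) standardGeneric("fiducialLabels"))

#' @rdname CenterlineCurve-class
#' @export
setGeneric("curveVertices", function(x) standardGeneric("curveVertices"))

#' @rdname CenterlineCurve-class
#' @export
setGeneric("curveArclength", function(x) standardGeneric("curveArclength"))

#' @rdname CenterlineCurve-class
#' @export
setGeneric("curveCost", function(x) standardGeneric("curveCost"))

#' @rdname CenterlineCurve-class
#' @export
setGeneric("sectionBreaks", function(x) standardGeneric("sectionBreaks"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("vertexScalars", function(x) standardGeneric("vertexScalars"))

#' @rdname SeedLabelMap-class
#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))

#' @rdname SeedLabelMap-class
#' @export
setGeneric("labelCounts", function(x) standardGeneric("labelCounts"))
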