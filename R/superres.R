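#' Crop a region of interest around a centerline
#'
#' Super-resolving the whole CT volume by a factor c multiplies its size by
#' c^3, so refinement is applied only in the vicinity of the duct: the
#' axis-aligned bounding box of the centerline vertices, dilated by a
#' physical margin (converted per axis to voxels, rounded up) and clamped to
#' the image. The crop origin is updated so physical coordinates of
#' retained voxels are unchanged.
#'
#' @param image a \linkS4class{ScalarVolume}.
#' @param centerline a \linkS4class{CenterlineCurve} inside the image.
#' @param marginMm positive dilation margin in mm. The default used by the
#'   pipeline is the exterior-seed radius r + 5 mm, so that voxels farther
#'   than r from the centerline (the exterior seeds) exist inside the ROI.
#' @return a list with \code{volume} (the cropped \linkS4class{ScalarVolume})
#'   and \code{indexOffset} (integer(3), 0-based crop corner in the original
#'   grid).
#' @export
cropRoi <- function(image, centerline, marginMm) {
  stopifnot(is(image, "ScalarVolume"), is(centerline, "CenterlineCurve"))
  if (nrow(centerline@vertices) == 0)
    stop("precondition error: empty centerline")
  if (marginMm <= 0) stop("precondition error: marginMm must be positive")
  d <- dim(image@values)
  idx <- worldToVoxel(image, centerline@vertices)
  if (any(idx < -0.5) || any(sweep(idx, 2, d - 0.5, ">=")))
    stop("precondition error: centerline extends outside the image")
  dil <- ceiling(marginMm / image@spacing)
  lo <- pmax(0, floor(apply(idx, 2, min) + 0.5 - 1e-9) - dil)
  hi <- pmin(d - 1, floor(apply(idx, 2, max) + 0.5 + 1e-9) + dil)
  list(volume = crop_volume(image, lo, hi), indexOffset = as.integer(lo))
}

#' Super-resolve a volume by an odd subdivision factor
#'
#' Each original voxel is subdivided into \code{factor}^3 subvoxels (output
#' size = input size x factor per axis, spacing divided by factor, origin
#' shifted by s(1 - 1/c)/2 per axis so the subvoxel centres tile the
#' original voxels). Values are obtained by trilinear interpolation of the
#' original grid -- a convex kernel, so every output value lies within the
#' local min/max of the 8 surrounding original samples -- with clamped
#' (nearest) extension beyond the outermost original centres. Because the
#' factor is odd, each original voxel centre coincides with a subvoxel
#' centre and the original value is reproduced there exactly.
#'
#' @param image a \linkS4class{ScalarVolume} (typically a [cropRoi()] crop).
#' @param factor odd positive integer (default 5; a factor of 5 makes the
#'   output exactly 125 times larger).
#' @param indexOffset 0-based crop corner of \code{image} in the grid of the
#'   volume it was cropped from (from [cropRoi()]); kept for mapping the
#'   segmentation back to the original grid.
#' @return a \linkS4class{RoiVolume}.
#' @export
upsampleVolume <- function(image, factor = 5L, indexOffset = c(0L, 0L, 0L)) {
  stopifnot(is(image, "ScalarVolume"))
  factor <- as.integer(factor)
  if (length(factor) != 1L || is.na(factor) || factor < 1L || factor %% 2L == 0L)
    stop("precondition error: factor must be an odd positive integer")
  d <- dim(image@values)
  if (factor == 1L) {
    out_vals <- image@values
    origin <- image@origin
  } else {
    out_vals <- array(cpp_upsample(as.numeric(image@values), as.integer(d),
                                   factor), d * factor)
    shift <- image@spacing * (1 - 1 / factor) / 2
    origin <- image@origin - as.numeric(image@direction %*% shift)
  }
  new("RoiVolume", values = out_vals, spacing = image@spacing / factor,
      origin = origin, direction = image@direction,
      indexOffset = as.integer(indexOffset), factor = factor)
}
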