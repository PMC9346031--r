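#' Seed configuration for lumen label propagation
#'
#' @param radiusRMm exterior-seed radius r in mm: every ROI voxel farther
#'   than r from the centerline is a known-exterior seed (label 2). The
#'   default of 10 mm is the radius the method was designed with; it is
#'   interpreted as a physical distance, honouring anisotropic spacing.
#' @param normalize intensity normalization applied before propagation;
#'   \code{"minmax_roi"} rescales the ROI to [0, 1] by its min-max so each
#'   Moore step cost |I(q) - I(p)| lies in [0, 1].
#' @return a validated configuration list.
#' @export
seedConfig <- function(radiusRMm = 10, normalize = "minmax_roi") {
  if (radiusRMm <= 0) stop("radiusRMm must be positive")
  normalize <- match.arg(normalize, "minmax_roi")
  list(radiusRMm = radiusRMm, normalize = normalize)
}

#' Build the {0,1,2} seed map from the centerline
#'
#' The centerline is rasterized onto the ROI grid: every voxel whose centre
#' lies within half a subvoxel diagonal of the (densely sampled) centerline
#' polyline becomes a known-lumen seed (label 1). Every voxel whose
#' physical Euclidean distance to the centerline exceeds \code{radiusRMm}
#' becomes a known-exterior seed (label 2). All remaining voxels are
#' undetermined (label 0) and are classified by [propagateLabels()].
#'
#' @param roi a \linkS4class{RoiVolume} (or any ScalarVolume).
#' @param centerline a \linkS4class{CenterlineCurve} intersecting the ROI.
#' @param config see [seedConfig()].
#' @return a \linkS4class{SeedLabelMap}.
#' @export
buildSeedMap <- function(roi, centerline, config = seedConfig()) {
  stopifnot(is(roi, "ScalarVolume"), is(centerline, "CenterlineCurve"))
  d <- dim(roi@values)
  # polyline in the grid-local orthonormal frame (distances preserved)
  local_verts <- sweep(centerline@vertices, 2, roi@origin, "-") %*% roi@direction
  dist <- cpp_grid_dist_to_polyline(as.integer(d), roi@spacing, c(0, 0, 0),
                                    local_verts)
  half_diag <- 0.5 * sqrt(sum(roi@spacing^2))
  labels <- integer(length(dist))
  labels[dist <= half_diag] <- 1L
  labels[dist > config$radiusRMm] <- 2L
  if (!any(labels == 1L))
    stop("precondition error: centerline does not intersect the ROI")
  if (!any(labels == 2L))
    stop("configuration error: no exterior seeds in the ROI; enlarge the ROI margin beyond radiusRMm")
  counts <- tabulate(labels + 1L, nbins = 3L)
  new("SeedLabelMap", labels = array(labels, d),
      counts = c(`0` = counts[1], `1` = counts[2], `2` = counts[3]),
      spacing = roi@spacing, origin = roi@origin, direction = roi@direction)
}

#' Moore neighbourhood of a voxel
#'
#' All in-bounds voxels within Chebyshev distance 1 of the given voxel,
#' excluding the voxel itself: 26 neighbours for an interior voxel of a 3D
#' grid, 8 for an interior pixel of a single-slice grid.
#'
#' @param index 0-based integer voxel index (i, j, k).
#' @param shape integer(3) grid dimensions.
#' @return a matrix of 0-based neighbour indices (one row each).
#' @export
mooreNeighbors <- function(index, shape) {
  index <- as.integer(index); shape <- as.integer(shape)
  if (any(index < 0L) || any(index >= shape))
    stop("index outside the grid")
  rng <- function(a) max(index[a] - 1L, 0L):min(index[a] + 1L, shape[a] - 1L)
  nb <- as.matrix(expand.grid(i = rng(1), j = rng(2), k = rng(3)))
  dimnames(nb) <- NULL
  keep <- rowSums(sweep(nb, 2, index, "==")) < 3L
  nb[keep, , drop = FALSE]
}

#' Classify undetermined voxels by intensity-geodesic label propagation
#'
#' Each undetermined voxel p receives the label of the seed l* minimizing,
#' over all paths H(l, p) on the Moore-adjacency graph, the accumulated
#' intensity-difference cost sum |I(q_{i+1}) - I(q_i)|. Note the step cost
#' carries no spatial length factor: the "distance" is purely
#' intensity-geodesic, unlike the length-weighted cost of the centerline
#' stage. The minimization is solved exactly with one multi-source Dijkstra
#' sweep per label class; at exact cost ties the lumen label 1 wins
#' (deterministic output).
#'
#' ROI intensities are min-max normalized to [0, 1] over the ROI before
#' propagation, so each step cost lies in [0, 1]; the labeling is therefore
#' invariant to positive affine rescaling of the intensities.
#'
#' @param roi the \linkS4class{RoiVolume} (or ScalarVolume) holding the
#'   intensities on the seed-map grid.
#' @param seeds a \linkS4class{SeedLabelMap} from [buildSeedMap()].
#' @param connectivity 26 (Moore, default) or 6.
#' @param restrict if TRUE, propagation runs on the undetermined region plus
#'   its one-voxel shell of exterior seeds instead of the whole ROI grid; an
#'   optimal path entering the exterior can always be shortened to start at
#'   the shell, so only exact-tie corridor cases can differ (see the methods
#'   vignette). Default FALSE (exact everywhere).
#' @return a \linkS4class{SeedLabelMap} with no zeros; the minimal costs per
#'   voxel are attached as attribute \code{"cost"} on the label array (the
#'   minimum of the two per-class geodesic distances).
#' @export
propagateLabels <- function(roi, seeds, connectivity = 26, restrict = FALSE) {
  stopifnot(is(roi, "ScalarVolume"), is(seeds, "SeedLabelMap"))
  d <- dim(roi@values)
  if (!all(dim(seeds@labels) == d))
    stop("precondition error: seed map and ROI grids differ")
  labels <- as.integer(seeds@labels)
  if (!any(labels == 0L)) return(seeds)   # nothing to classify

  v <- as.numeric(roi@values)
  rng <- range(v)
  I <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1])
       else numeric(length(v))
  s1 <- which(labels == 1L) - 1L
  s2 <- which(labels == 2L) - 1L
  active <- if (restrict) {
    labels != 2L | cpp_seed_ring(labels, as.integer(d))
  } else logical(0)
  if (restrict) {
    s2 <- which(labels == 2L & active) - 1L
  }
  d1 <- cpp_geodesic_dist(I, as.integer(d), s1, connectivity, active)
  d2 <- cpp_geodesic_dist(I, as.integer(d), s2, connectivity, active)
  out <- labels
  undet <- labels == 0L
  out[undet] <- ifelse(d1[undet] <= d2[undet], 1L, 2L)   # label 1 wins ties
  counts <- tabulate(out + 1L, nbins = 3L)
  lab_arr <- array(out, d)
  attr(lab_arr, "cost") <- array(pmin(d1, d2), d)
  new("SeedLabelMap", labels = lab_arr,
      counts = c(`0` = counts[1], `1` = counts[2], `2` = counts[3]),
      spacing = seeds@spacing, origin = seeds@origin,
      direction = seeds@direction)
}

#' Extract the binary lumen mask from a propagated label map
#'
#' The label-1 region after propagation covers the duct lumen. Optionally
#' the largest 26-connected component is kept (on by default; stray
#' same-intensity pockets far from the duct are discarded) and the mask is
#' majority-vote downsampled back to the original image grid: an original
#' voxel is lumen iff more than half of its factor^3 subvoxels are lumen.
#'
#' @param labels a propagated \linkS4class{SeedLabelMap} (no zeros).
#' @param roi the \linkS4class{RoiVolume} the labels live on (needed for the
#'   subdivision factor and crop offset when downsampling).
#' @param originalImage the uncropped \linkS4class{ScalarVolume}; when
#'   supplied (together with \code{roi}), a mask on the original grid is
#'   returned as well.
#' @param largestComponent keep only the largest 26-connected component.
#' @param fillCavities set enclosed interior pockets (complement voxels not
#'   6-connected to the grid boundary) to lumen. The duct lumen is simply
#'   connected, so cavities are noise artifacts; filling them also
#'   guarantees a single-shell surface mesh.
#' @return a list with \code{mask} (binary \linkS4class{ScalarVolume} on the
#'   label grid) and \code{maskOriginal} (binary ScalarVolume on the
#'   original grid, or NULL).
#' @export
lumenMask <- function(labels, roi = NULL, originalImage = NULL,
                      largestComponent = TRUE, fillCavities = TRUE) {
  stopifnot(is(labels, "SeedLabelMap"))
  if (labels@counts[["0"]] > 0)
    stop("precondition error: propagation incomplete (undetermined voxels remain)")
  d <- dim(labels@labels)
  m <- labels@labels == 1L
  if (!any(m)) stop("degenerate result: empty lumen (no label-1 voxels)")
  if (largestComponent)
    m <- array(cpp_largest_cc(as.logical(m), as.integer(d), 26L), d)
  if (fillCavities) {
    outside <- array(cpp_outside_fill(as.logical(m), as.integer(d)), d)
    m <- m | !outside
  }
  mask_roi <- scalarVolume(array(as.double(m), d), spacing = labels@spacing,
                           origin = labels@origin,
                           direction = labels@direction)
  mask_orig <- NULL
  if (!is.null(roi) && !is.null(originalImage)) {
    stopifnot(is(roi, "RoiVolume"), is(originalImage, "ScalarVolume"))
    cc <- roi@factor
    nr <- d %/% cc
    arr6 <- array(as.double(m), c(cc, nr[1], cc, nr[2], cc, nr[3]))
    counts <- aperm(arr6, c(1, 3, 5, 2, 4, 6))
    dim(counts) <- c(cc^3, prod(nr))
    votes <- array(colSums(counts) > cc^3 / 2, nr)
    dorig <- dim(originalImage@values)
    full <- array(0, dorig)
    off <- roi@indexOffset
    full[(off[1] + 1):(off[1] + nr[1]),
         (off[2] + 1):(off[2] + nr[2]),
         (off[3] + 1):(off[3] + nr[3])] <- as.double(votes)
    mask_orig <- scalarVolume(full, spacing = originalImage@spacing,
                              origin = originalImage@origin,
                              direction = originalImage@direction)
  }
  list(mask = mask_roi, maskOriginal = mask_orig)
}
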