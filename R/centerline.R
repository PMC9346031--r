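#' Voxel-graph parameters for optimal-path centerline extraction
#'
#' @param connectivity 26 (Moore, default) or 6 (face neighbours).
#' @param weightFloor small nonnegative lower bound on edge weights so that
#'   shortest paths stay well defined where the tubularity map reaches 1
#'   (a zero-cost region would otherwise make all paths through it free);
#'   the default 1e-6 also breaks cost ties toward geometrically shorter
#'   paths.
#' @param snapRadiusMm 0 (default) snaps each fiducial to its nearest voxel
#'   centre; a positive radius instead snaps to the highest-tubularity voxel
#'   centre within that physical radius.
#' @return a validated parameter list for [extractCenterline()].
#' @export
pathGraphParams <- function(connectivity = 26, weightFloor = 1e-6,
                            snapRadiusMm = 0) {
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  if (weightFloor < 0) stop("weightFloor must be nonnegative")
  if (snapRadiusMm < 0) stop("snapRadiusMm must be nonnegative")
  list(connectivity = as.integer(connectivity), weightFloor = weightFloor,
       snapRadiusMm = snapRadiusMm)
}

#' Extract the optimal duct centerline through ordered fiducials
#'
#' The centerline is the curve minimizing the tubularity-weighted path
#' integral of (1 - V) |C'(t)| dt, constrained to pass through every
#' fiducial. By Bellman's principle the constrained problem decomposes into
#' independent optimal sections between consecutive fiducials; each section
#' is solved exactly on the voxel graph with Dijkstra's algorithm using edge
#' weights
#' \deqn{w(p,q) = \max(\mathrm{floor},\; 1 - (V(p)+V(q))/2)\;\|x_p - x_q\|,}
#' with physical (anisotropic) edge lengths in mm. Sections are concatenated
#' without smoothing across the joints; tangents are never computed across a
#' joint (see [tangentAt()]).
#'
#' @param vesselness a \linkS4class{ScalarVolume} with values in [0, 1]
#'   (see [computeVesselness()]).
#' @param fiducials a \linkS4class{FiducialSet}; all points must lie inside
#'   the volume.
#' @param params see [pathGraphParams()].
#' @param bboxMarginMm the voxel graph is restricted to the axis-aligned
#'   bounding box of the fiducials dilated by this margin (mm); set to
#'   \code{Inf} to search the whole volume.
#' @return a \linkS4class{CenterlineCurve} whose vertices are voxel centres
#'   in mm; \code{curveCost()} is the accumulated edge cost and
#'   \code{sectionBreaks()} marks the joints at intermediate fiducials.
#' @export
extractCenterline <- function(vesselness, fiducials,
                              params = pathGraphParams(),
                              bboxMarginMm = 20) {
  stopifnot(is(vesselness, "ScalarVolume"), is(fiducials, "FiducialSet"))
  v <- vesselness@values
  if (min(v) < -1e-9 || max(v) > 1 + 1e-9)
    stop("precondition error: vesselness values must lie in [0, 1]")
  d <- dim(v)
  idx <- worldToVoxel(vesselness, fiducials@points)
  if (any(idx < -0.5) || any(sweep(idx, 2, d - 0.5, ">=")))
    stop("precondition error: fiducial outside the volume")

  # restrict the graph to the dilated fiducial bounding box
  if (is.finite(bboxMarginMm)) {
    dil <- ceiling(bboxMarginMm / vesselness@spacing)
    lo <- pmax(0, floor(apply(idx, 2, min)) - dil)
    hi <- pmin(d - 1, ceiling(apply(idx, 2, max)) + dil)
  } else {
    lo <- c(0, 0, 0); hi <- d - 1
  }
  sub <- crop_volume(vesselness, lo, hi)
  subdim <- dim(sub@values)

  snapped <- snap_fiducials(sub, fiducials@points, params$snapRadiusMm)

  verts_idx <- matrix(numeric(0), 0, 3)
  breaks <- integer()
  total_cost <- 0
  for (s in seq_len(nrow(snapped) - 1)) {
    src <- ijk_to_linear(snapped[s, , drop = FALSE], subdim) - 1L
    dst <- ijk_to_linear(snapped[s + 1, , drop = FALSE], subdim) - 1L
    if (src == dst) {
      sec <- snapped[s, , drop = FALSE]
      cost <- 0
    } else {
      res <- cpp_dijkstra_path(as.numeric(sub@values), as.integer(subdim),
                               sub@spacing, src, dst,
                               params$connectivity, params$weightFloor)
      sec <- linear_to_ijk(res$path + 1L, subdim)
      cost <- res$cost
    }
    total_cost <- total_cost + cost
    if (s == 1) {
      verts_idx <- sec
    } else {
      breaks <- c(breaks, nrow(verts_idx))
      verts_idx <- rbind(verts_idx, sec[-1, , drop = FALSE])
    }
  }
  verts <- voxelToWorld(sub, verts_idx)
  new("CenterlineCurve", vertices = verts,
      arclength = polyline_arclength(verts),
      cost = total_cost, sectionBreaks = as.integer(breaks))
}

snap_fiducials <- function(vol, points, snap_radius_mm) {
  d <- dim(vol@values)
  cont <- worldToVoxel(vol, points)
  snapped <- pmin(pmax(round(cont), 0), matrix(d - 1, nrow(cont), 3, byrow = TRUE))
  if (snap_radius_mm > 0) {
    rad_vox <- ceiling(snap_radius_mm / vol@spacing)
    for (t in seq_len(nrow(snapped))) {
      lo <- pmax(0, snapped[t, ] - rad_vox)
      hi <- pmin(d - 1, snapped[t, ] + rad_vox)
      box <- expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3])
      box <- as.matrix(box)
      ctr <- voxelToWorld(vol, box)
      dist <- sqrt(rowSums(sweep(ctr, 2, points[t, ], "-")^2))
      ok <- dist <= snap_radius_mm
      if (any(ok)) {
        vals <- vol@values[ijk_to_linear(box[ok, , drop = FALSE], d)]
        snapped[t, ] <- box[ok, , drop = FALSE][which.max(vals), ]
      }
    }
  }
  storage.mode(snapped) <- "double"
  snapped
}

# crop [lo, hi] (0-based, inclusive) keeping physical coordinates intact
crop_volume <- function(vol, lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  vals <- vol@values[(lo[1] + 1):(hi[1] + 1),
                     (lo[2] + 1):(hi[2] + 1),
                     (lo[3] + 1):(hi[3] + 1), drop = FALSE]
  origin <- as.numeric(voxelToWorld(vol, lo))
  scalarVolume(vals, spacing = vol@spacing, origin = origin,
               direction = vol@direction)
}

#' Discrete tangent of a centerline
#'
#' Central finite difference of the vertex polyline, normalized to unit
#' length; the endpoints use one-sided differences. Tangents are undefined
#' at section joints (the curve is only piecewise smooth there); passing
#' \code{allowJoint = TRUE} returns the one-sided (backward) difference
#' instead of raising an error.
#'
#' @param curve a \linkS4class{CenterlineCurve} with >= 2 vertices.
#' @param index vertex index (1-based).
#' @param allowJoint permit evaluation at a section joint.
#' @return a unit 3-vector.
#' @export
tangentAt <- function(curve, index, allowJoint = FALSE) {
  v <- curve@vertices
  n <- nrow(v)
  if (n < 2) stop("undefined tangent: curve has a single vertex")
  if (index < 1 || index > n) stop("vertex index out of range")
  if (index %in% curve@sectionBreaks && !allowJoint)
    stop("tangent is not computed at a section joint (set allowJoint = TRUE for the one-sided difference)")
  tv <- if (index == 1) v[2, ] - v[1, ]
        else if (index == n) v[n, ] - v[n - 1, ]
        else if (index %in% curve@sectionBreaks) v[index, ] - v[index - 1, ]
        else v[index + 1, ] - v[index - 1, ]
  nrm <- sqrt(sum(tv^2))
  if (nrm == 0) stop("undefined tangent: coincident neighbouring vertices")
  tv / nrm
}

#' Resample a centerline along a cubic spline
#'
#' Fits natural cubic splines componentwise against cumulative arc length
#' and resamples at uniform arc-length steps no larger than \code{stepMm};
#' the endpoints are preserved exactly.
#'
#' @param curve a \linkS4class{CenterlineCurve} with >= 2 vertices.
#' @param stepMm positive target arc-length step (mm).
#' @return a resampled \linkS4class{CenterlineCurve} (cost is carried over;
#'   section joints are dropped since the spline is globally smooth).
#' @export
resampleCurve <- function(curve, stepMm) {
  if (stepMm <= 0) stop("precondition error: stepMm must be positive")
  v <- unique_vertices(curve@vertices)
  if (nrow(v) < 2) stop("precondition error: curve must have >= 2 distinct vertices")
  al <- polyline_arclength(v)
  fx <- stats::splinefun(al, v[, 1], method = "natural")
  fy <- stats::splinefun(al, v[, 2], method = "natural")
  fz <- stats::splinefun(al, v[, 3], method = "natural")
  # arc-length reparameterization on a dense sampling of the spline
  dense_t <- seq(0, al[length(al)], length.out = max(20L * nrow(v), 2000L))
  dense <- cbind(fx(dense_t), fy(dense_t), fz(dense_t))
  dense_al <- polyline_arclength(dense)
  total <- dense_al[length(dense_al)]
  nstep <- max(1L, ceiling(total / stepMm))
  targets <- seq(0, total, length.out = nstep + 1L)
  tpar <- stats::approx(dense_al, dense_t, xout = targets, ties = "ordered")$y
  out <- cbind(fx(tpar), fy(tpar), fz(tpar))
  out[1, ] <- v[1, ]
  out[nrow(out), ] <- v[nrow(v), ]
  new("CenterlineCurve", vertices = out, arclength = polyline_arclength(out),
      cost = curve@cost, sectionBreaks = integer())
}

unique_vertices <- function(v) {
  if (nrow(v) < 2) return(v)
  seg <- sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
  v[c(TRUE, seg > 1e-12), , drop = FALSE]
}

#' Build a CenterlineCurve from a vertex matrix
#'
#' Convenience constructor used for ground-truth curves and tests.
#'
#' @param vertices N x 3 matrix of points (mm).
#' @param cost optional accumulated path cost.
#' @param sectionBreaks optional joint indices.
#' @return a \linkS4class{CenterlineCurve}.
#' @export
centerlineCurve <- function(vertices, cost = NA_real_,
                            sectionBreaks = integer()) {
  vertices <- rbind_points(vertices)
  new("CenterlineCurve", vertices = vertices,
      arclength = polyline_arclength(vertices), cost = cost,
      sectionBreaks = as.integer(sectionBreaks))
}
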