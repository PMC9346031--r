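#' Reconstruct the lumen surface from a binary mask
#'
#' The mask is optionally Gaussian-smoothed (reducing staircase artifacts
#' that would otherwise dominate the curvature map), zero-padded by one
#' voxel so surfaces touching the grid boundary still close, and
#' isosurfaced at level 0.5 by marching tetrahedra on the consistent Kuhn
#' 6-tetrahedra cube split (watertight, consistently wound, outward
#' normals). Vertices are returned in physical mm.
#'
#' @param mask a binary \linkS4class{ScalarVolume}.
#' @param smoothSigmaMm Gaussian pre-smoothing sigma in mm; the default
#'   (NULL) uses one voxel of the mask grid (its smallest spacing).
#' @param keepLargestShell smoothing a thin, noisy mask can pinch off tiny
#'   interior cavity shells or satellites in the isosurface even when the
#'   mask itself is one connected component; with TRUE (default) only the
#'   largest connected shell -- the outer lumen wall -- is returned.
#' @return a \linkS4class{TriangleMesh}.
#' @export
extractSurface <- function(mask, smoothSigmaMm = NULL,
                           keepLargestShell = TRUE) {
  stopifnot(is(mask, "ScalarVolume"))
  if (!any(mask@values > 0)) stop("precondition error: empty mask")
  if (is.null(smoothSigmaMm)) smoothSigmaMm <- min(mask@spacing)
  d <- dim(mask@values)
  field <- array(0, d + 2L)
  field[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask@values
  if (smoothSigmaMm > 0)
    field <- smooth_volume_gaussian(field, mask@spacing, smoothSigmaMm)
  mt <- cpp_marching_tetra(as.numeric(field), as.integer(d + 2L), 0.5)
  if (nrow(mt$vertices) == 0)
    stop("degenerate result: isosurface is empty after smoothing")
  pad_origin <- mask@origin - as.numeric(mask@direction %*% mask@spacing)
  padded <- scalarVolume(array(0, c(1, 1, 1)), spacing = mask@spacing,
                         origin = pad_origin, direction = mask@direction)
  verts <- voxelToWorld(padded, mt$vertices)
  faces <- mt$faces
  if (det(mask@direction) < 0) faces <- faces[, c(1, 3, 2), drop = FALSE]
  if (keepLargestShell && nrow(faces)) {
    comp <- cpp_vertex_components(faces, nrow(verts))
    main <- as.integer(names(which.max(table(comp[comp > 0]))))
    keep_v <- comp == main
    if (!all(keep_v)) {
      remap <- cumsum(keep_v)
      faces <- faces[keep_v[faces[, 1]], , drop = FALSE]
      faces[] <- remap[faces]
      verts <- verts[keep_v, , drop = FALSE]
    }
  }
  new("TriangleMesh", vertices = verts, faces = faces, vertexScalars = list())
}

#' Attach per-vertex Gaussian curvature to a mesh
#'
#' Discrete Gaussian curvature by angle deficit: at each vertex the deficit
#' 2*pi - sum(incident triangle angles) is divided by the mixed Voronoi
#' area (Meyer's scheme, with the obtuse-triangle correction). The mixed
#' areas tile the surface exactly, so for a closed genus-0 mesh the total
#' deficit satisfies the discrete Gauss-Bonnet identity
#' sum(deficit) = 4*pi independently of geometry.
#'
#' @param mesh a manifold, consistently oriented \linkS4class{TriangleMesh}.
#'   Open meshes are accepted (boundary-vertex curvature is not meaningful).
#' @return the mesh with vertex scalars \code{"gaussian_curvature"}
#'   (1/mm^2), \code{"angle_deficit"} (rad) and \code{"mixed_area"} (mm^2)
#'   attached.
#' @export
gaussianCurvatureMap <- function(mesh) {
  stopifnot(is(mesh, "TriangleMesh"))
  v <- mesh@vertices
  f <- mesh@faces
  check_manifold(f)
  A <- v[f[, 1], , drop = FALSE]
  B <- v[f[, 2], , drop = FALSE]
  C <- v[f[, 3], , drop = FALSE]
  e_ab <- B - A; e_ac <- C - A; e_bc <- C - B
  l_ab2 <- rowSums(e_ab^2); l_ac2 <- rowSums(e_ac^2); l_bc2 <- rowSums(e_bc^2)
  cr <- cbind(e_ab[, 2] * e_ac[, 3] - e_ab[, 3] * e_ac[, 2],
              e_ab[, 3] * e_ac[, 1] - e_ab[, 1] * e_ac[, 3],
              e_ab[, 1] * e_ac[, 2] - e_ab[, 2] * e_ac[, 1])
  area2 <- sqrt(rowSums(cr^2))        # twice the triangle area
  ang <- function(u2, w2, opp2) {     # angle between edges of sq.len u2, w2
    cosv <- (u2 + w2 - opp2) / (2 * sqrt(u2 * w2))
    acos(pmin(1, pmax(-1, cosv)))
  }
  angA <- ang(l_ab2, l_ac2, l_bc2)
  angB <- ang(l_ab2, l_bc2, l_ac2)
  angC <- pi - angA - angB
  nv <- nrow(v)
  vid <- c(f[, 1], f[, 2], f[, 3])
  accum <- function(x) {   # per-vertex sum, robust to vertices unused by faces
    agg <- rowsum(x, group = vid)
    out <- numeric(nv)
    out[as.integer(rownames(agg))] <- agg[, 1]
    out
  }
  angle_sum <- accum(c(angA, angB, angC))

  # Meyer mixed areas: Voronoi for non-obtuse triangles, else area/2 at the
  # obtuse corner and area/4 at the others
  cot <- function(a) cos(a) / sin(a)
  cotA <- cot(angA); cotB <- cot(angB); cotC <- cot(angC)
  area <- area2 / 2
  obtuse <- cbind(angA > pi / 2, angB > pi / 2, angC > pi / 2)
  any_obtuse <- rowSums(obtuse) > 0
  vorA <- (l_ab2 * cotC + l_ac2 * cotB) / 8
  vorB <- (l_ab2 * cotC + l_bc2 * cotA) / 8
  vorC <- (l_ac2 * cotB + l_bc2 * cotA) / 8
  mixA <- ifelse(any_obtuse, ifelse(obtuse[, 1], area / 2, area / 4), vorA)
  mixB <- ifelse(any_obtuse, ifelse(obtuse[, 2], area / 2, area / 4), vorB)
  mixC <- ifelse(any_obtuse, ifelse(obtuse[, 3], area / 2, area / 4), vorC)
  mixed <- accum(c(mixA, mixB, mixC))
  mixed[mixed <= 0] <- NA_real_

  deficit <- 2 * pi - angle_sum
  mesh@vertexScalars[["gaussian_curvature"]] <- deficit / mixed
  mesh@vertexScalars[["angle_deficit"]] <- deficit
  mesh@vertexScalars[["mixed_area"]] <- mixed
  mesh
}

check_manifold <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  bad <- names(tab)[tab > 2]
  if (length(bad))
    stop("topology error: non-manifold edges (shared by > 2 faces): ",
         paste(utils::head(bad, 5), collapse = "; "),
         if (length(bad) > 5) " ..." else "")
  invisible(TRUE)
}

# undirected edge count (for Euler characteristic checks)
mesh_edge_count <- function(mesh) {
  e <- rbind(mesh@faces[, c(1, 2)], mesh@faces[, c(2, 3)], mesh@faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  length(unique(key))
}

#' Fly-through camera path along the centerline spline
#'
#' The centerline is spline-resampled at the requested step
#' ([resampleCurve()]); at each keyframe the camera looks along the discrete
#' curve tangent, and the up vector is carried along by parallel transport
#' (double-reflection method) from an initial up orthogonal to the first
#' tangent, so the camera never rolls abruptly at vertical tangents.
#'
#' @param centerline a \linkS4class{CenterlineCurve} with >= 2 vertices.
#' @param stepMm positive keyframe spacing (mm).
#' @return a \linkS4class{CameraPath}.
#' @export
cameraPath <- function(centerline, stepMm) {
  stopifnot(is(centerline, "CenterlineCurve"))
  if (nrow(unique_vertices(centerline@vertices)) < 2)
    stop("precondition error: degenerate (zero-length) centerline")
  rs <- resampleCurve(centerline, stepMm)
  p <- rs@vertices
  n <- nrow(p)
  tang <- matrix(0, n, 3)
  for (t in seq_len(n)) {
    tv <- if (t == 1) p[2, ] - p[1, ]
          else if (t == n) p[n, ] - p[n - 1, ]
          else p[t + 1, ] - p[t - 1, ]
    tang[t, ] <- tv / sqrt(sum(tv^2))
  }
  up <- matrix(0, n, 3)
  seedv <- c(0, 0, 1)
  if (abs(sum(seedv * tang[1, ])) > 0.9) seedv <- c(0, 1, 0)
  u <- seedv - sum(seedv * tang[1, ]) * tang[1, ]
  up[1, ] <- u / sqrt(sum(u^2))
  for (t in seq_len(n - 1)) {   # double-reflection parallel transport
    v1 <- p[t + 1, ] - p[t, ]
    c1 <- sum(v1 * v1)
    uL <- if (c1 > 0) up[t, ] - (2 / c1) * sum(v1 * up[t, ]) * v1 else up[t, ]
    tL <- if (c1 > 0) tang[t, ] - (2 / c1) * sum(v1 * tang[t, ]) * v1 else tang[t, ]
    v2 <- tang[t + 1, ] - tL
    c2 <- sum(v2 * v2)
    u2 <- if (c2 > 0) uL - (2 / c2) * sum(v2 * uL) * v2 else uL
    u2 <- u2 - sum(u2 * tang[t + 1, ]) * tang[t + 1, ]
    up[t + 1, ] <- u2 / sqrt(sum(u2^2))
  }
  new("CameraPath", positions = p, viewDirs = tang, upDirs = up,
      stepMm = stepMm)
}

#' Simulate a nodule (cyst) on the lumen surface
#'
#' Adds a smooth Gaussian bump protruding into the lumen, emulating an
#' intraductal nodule, so the curvature map can be exercised on pathology.
#' The mesh method displaces vertices inward (against the outward normal)
#' by \code{height * exp(-4.5 d^2 / radius^2)} with hard compact support at
#' \code{d > 3 * radius} from the centre. The mask method carves the
#' equivalent indentation: a ball of the given radius whose centre is
#' retracted so the maximum intrusion depth is \code{height}.
#'
#' @param x a \linkS4class{TriangleMesh} or a binary mask
#'   \linkS4class{ScalarVolume}.
#' @param center 3D point on/near the lumen surface (mm).
#' @param radius bump radius (mm).
#' @param height maximum inward displacement (mm); 0 is the identity.
#' @return the deformed object, same class as \code{x}.
#' @export
setGeneric("simulateNodule",
           function(x, center, radius, height) standardGeneric("simulateNodule"))

#' @rdname simulateNodule
setMethod("simulateNodule", "TriangleMesh", function(x, center, radius, height) {
  if (radius <= 0) stop("radius must be positive")
  if (height == 0) return(x)
  nearest <- which.min(rowSums(sweep(x@vertices, 2, center, "-")^2))
  local_r <- sqrt(sum((x@vertices[nearest, ] - center)^2))
  if (local_r > radius)
    warning("geometry warning: bump centre is ", signif(local_r, 3),
            " mm from the surface (radius ", radius, " mm); proceeding")
  nrm <- vertex_normals(x)
  dvec <- sweep(x@vertices, 2, center, "-")
  dist <- sqrt(rowSums(dvec^2))
  amp <- height * exp(-4.5 * dist^2 / radius^2)
  amp[dist > 3 * radius] <- 0
  x@vertices <- x@vertices - nrm * amp
  x
})

#' @rdname simulateNodule
setMethod("simulateNodule", "ScalarVolume", function(x, center, radius, height) {
  if (radius <= 0) stop("radius must be positive")
  if (height == 0) return(x)
  m <- x@values > 0
  if (!any(m)) stop("precondition error: empty mask")
  ctr_all <- all_voxel_centers(x)
  centroid <- colMeans(ctr_all[as.vector(m), , drop = FALSE])
  u <- centroid - center
  nu <- sqrt(sum(u^2))
  u <- if (nu > 0) u / nu else c(0, 0, 1)
  ball_center <- center - u * max(radius - height, 0)
  inside <- sqrt(rowSums(sweep(ctr_all, 2, ball_center, "-")^2)) <= radius
  vals <- x@values
  vals[array(inside, dim(vals)) & m] <- 0
  scalarVolume(vals, spacing = x@spacing, origin = x@origin,
               direction = x@direction)
})

# area-weighted outward vertex normals
vertex_normals <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nv <- nrow(v)
  acc <- matrix(0, nv, 3)
  idx <- c(f[, 1], f[, 2], f[, 3])
  for (ax in 1:3) {
    agg <- rowsum(rep(fn[, ax], 3), group = idx)
    acc[as.integer(rownames(agg)), ax] <- agg[, 1]
  }
  len <- sqrt(rowSums(acc^2))
  len[len == 0] <- 1
  acc / len
}

#' Unit icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere: a closed genus-0 mesh
#' with near-uniform triangles, used as analytic reference geometry (the
#' Gaussian curvature of a sphere of radius R is 1/R^2 everywhere).
#'
#' @param radius sphere radius (mm).
#' @param subdivisions number of 4-to-1 face subdivisions (3 gives 1280
#'   faces).
#' @param center sphere centre.
#' @return a \linkS4class{TriangleMesh} with outward-wound faces.
#' @export
icosphereMesh <- function(radius = 1, subdivisions = 3L, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (it in seq_len(subdivisions)) {
    midcache <- new.env(hash = TRUE)
    nf <- matrix(0L, 0, 3)
    vv <- v
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- midcache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (vv[a, ] + vv[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      vv <<- rbind(vv, m)
      id <- nrow(vv)
      midcache[[key]] <- id
      id
    }
    newf <- vector("list", nrow(f))
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c0 <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c0); ca <- midpoint(c0, a)
      newf[[t]] <- rbind(c(a, ab, ca), c(b, bc, ab), c(c0, ca, bc),
                         c(ab, bc, ca))
    }
    f <- do.call(rbind, newf)
    v <- vv
  }
  # enforce outward winding
  for (t in seq_len(nrow(f))) {
    a <- v[f[t, 1], ]; b <- v[f[t, 2], ]; c0 <- v[f[t, 3], ]
    n <- c((b - a)[2] * (c0 - a)[3] - (b - a)[3] * (c0 - a)[2],
           (b - a)[3] * (c0 - a)[1] - (b - a)[1] * (c0 - a)[3],
           (b - a)[1] * (c0 - a)[2] - (b - a)[2] * (c0 - a)[1])
    if (sum(n * (a + b + c0)) < 0) f[t, ] <- f[t, c(1, 3, 2)]
  }
  verts <- sweep(v * radius, 2, center, "+")
  new("TriangleMesh", vertices = verts, faces = f, vertexScalars = list())
}

#' Write a mesh to ASCII PLY or legacy VTK
#'
#' Per-vertex scalar arrays are embedded (PLY: extra vertex properties;
#' VTK: POINT_DATA scalars), so standard viewers can colour the surface by
#' the curvature map directly.
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param path output path ending in .ply or .vtk.
#' @return invisibly, \code{path}.
#' @export
writeMesh <- function(mesh, path) {
  stopifnot(is(mesh, "TriangleMesh"))
  v <- mesh@vertices; f <- mesh@faces
  scalars <- mesh@vertexScalars
  if (grepl("\\.ply$", tolower(path))) {
    propnames <- gsub("[^A-Za-z0-9_]", "_", names(scalars))
    header <- c("ply", "format ascii 1.0",
                paste("element vertex", nrow(v)),
                "property float x", "property float y", "property float z",
                paste("property float", propnames),
                paste("element face", nrow(f)),
                "property list uchar int vertex_indices", "end_header")
    vdata <- cbind(v, do.call(cbind, unname(scalars)))
    vl <- apply(vdata, 1, function(r) paste(sprintf("%.8g", r), collapse = " "))
    fl <- apply(f - 1L, 1, function(r) paste(c(3L, r), collapse = " "))
    writeLines(c(header, vl, fl), path)
  } else if (grepl("\\.vtk$", tolower(path))) {
    lines <- c("# vtk DataFile Version 3.0", "DuctScope mesh", "ASCII",
               "DATASET POLYDATA",
               paste("POINTS", nrow(v), "float"),
               apply(v, 1, function(r) paste(sprintf("%.8g", r), collapse = " ")),
               paste("POLYGONS", nrow(f), nrow(f) * 4L),
               apply(f - 1L, 1, function(r) paste(c(3L, r), collapse = " ")))
    if (length(scalars)) {
      lines <- c(lines, paste("POINT_DATA", nrow(v)))
      for (nm in names(scalars)) {
        lines <- c(lines,
                   paste("SCALARS", gsub("[^A-Za-z0-9_]", "_", nm), "float 1"),
                   "LOOKUP_TABLE default",
                   sprintf("%.8g", scalars[[nm]]))
      }
    }
    writeLines(lines, path)
  } else stop("unsupported mesh format (use .ply or .vtk): ", path)
  invisible(path)
}

#' Write a camera path as JSON keyframes
#'
#' @param path a \linkS4class{CameraPath}.
#' @param file output JSON path.
#' @return invisibly, \code{file}.
#' @export
writeCameraPath <- function(path, file) {
  stopifnot(is(path, "CameraPath"))
  jsonlite::write_json(list(
    step_mm = path@stepMm,
    keyframes = lapply(seq_len(nrow(path@positions)), function(t) list(
      position = path@positions[t, ],
      view = path@viewDirs[t, ],
      up = path@upDirs[t, ]))),
    file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}
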