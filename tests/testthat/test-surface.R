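# Surface reconstruction, discrete Gaussian curvature, fly-through path and
# nodule simulation.

solid_cube_mask <- function(n = 10L, pad = 4L) {
  d <- rep(n + 2L * pad, 3L)
  m <- array(0, d)
  m[(pad + 1):(pad + n), (pad + 1):(pad + n), (pad + 1):(pad + n)] <- 1
  scalarVolume(m)
}

test_that("a solid cube mask yields a closed genus-0 mesh", {
  mesh <- extractSurface(solid_cube_mask(), smoothSigmaMm = 0)
  V <- nrow(meshVertices(mesh))
  F <- nrow(meshFaces(mesh))
  E <- DuctScope:::mesh_edge_count(mesh)
  expect_identical(V - E + F, 2L)
  expect_identical(3L * F, 2L * E)   # closed: every edge shared by 2 faces
})

test_that("a digital ball's mesh area approaches the analytic sphere area", {
  d <- c(21L, 21L, 21L)
  ijk <- as.matrix(expand.grid(0:20, 0:20, 0:20))
  ball <- array(as.double(sqrt(rowSums(sweep(ijk, 2, c(10, 10, 10), "-")^2)) <= 8), d)
  mesh <- extractSurface(scalarVolume(ball), smoothSigmaMm = 1)
  v <- meshVertices(mesh); f <- meshFaces(mesh)
  e1 <- v[f[, 2], ] - v[f[, 1], ]; e2 <- v[f[, 3], ] - v[f[, 1], ]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- sum(sqrt(rowSums(cr^2))) / 2
  expect_lt(abs(area - 4 * pi * 64) / (4 * pi * 64), 0.05)
  # vertices localize near the mask boundary
  dist_to_ctr <- sqrt(rowSums(sweep(v, 2, c(10, 10, 10), "-")^2))
  expect_lt(max(abs(dist_to_ctr - 8)), sqrt(3))
  expect_error(extractSurface(scalarVolume(array(0, c(4, 4, 4)))), "empty")
})

test_that("interior cavity shells are dropped so the lumen wall is one closed surface", {
  d <- c(15L, 15L, 15L)
  ijk <- as.matrix(expand.grid(0:14, 0:14, 0:14))
  r <- sqrt(rowSums(sweep(ijk, 2, c(7, 7, 7), "-")^2))
  hollow <- array(as.double(r <= 5 & r > 1.8), d)   # ball with a cavity
  both <- extractSurface(scalarVolume(hollow), smoothSigmaMm = 0,
                         keepLargestShell = FALSE)
  chi_both <- nrow(meshVertices(both)) - DuctScope:::mesh_edge_count(both) +
    nrow(meshFaces(both))
  expect_identical(chi_both, 4L)                    # two nested shells
  outer <- extractSurface(scalarVolume(hollow), smoothSigmaMm = 0)
  chi <- nrow(meshVertices(outer)) - DuctScope:::mesh_edge_count(outer) +
    nrow(meshFaces(outer))
  expect_identical(chi, 2L)
})

test_that("total angle deficit of closed genus-0 meshes is exactly 4*pi", {
  for (mesh in list(extractSurface(solid_cube_mask(), smoothSigmaMm = 0),
                    icosphereMesh(radius = 3, subdivisions = 2))) {
    curv <- gaussianCurvatureMap(mesh)
    expect_equal(sum(vertexScalars(curv)$angle_deficit), 4 * pi,
                 tolerance = 1e-6 / (4 * pi))
  }
})

test_that("icosphere per-vertex curvature matches 1/R^2 within 5%", {
  mesh <- gaussianCurvatureMap(icosphereMesh(radius = 2, subdivisions = 3))
  k <- vertexScalars(mesh)$gaussian_curvature
  expect_true(all(abs(k - 0.25) / 0.25 < 0.05))
})

test_that("interior vertices of a flat triangulated rectangle have zero curvature", {
  # regular grid triangulation of a 6 x 5 planar patch
  nx <- 6L; ny <- 5L
  verts <- as.matrix(expand.grid(x = 0:(nx - 1), y = 0:(ny - 1)))
  verts <- cbind(verts, 0)
  vid <- function(i, j) i + (j - 1L) * nx
  faces <- NULL
  for (j in 1:(ny - 1)) for (i in 1:(nx - 1)) {
    faces <- rbind(faces,
                   c(vid(i, j), vid(i + 1, j), vid(i + 1, j + 1)),
                   c(vid(i, j), vid(i + 1, j + 1), vid(i, j + 1)))
  }
  mesh <- gaussianCurvatureMap(new("TriangleMesh", vertices = verts,
                                   faces = faces, vertexScalars = list()))
  interior <- verts[, 1] > 0 & verts[, 1] < nx - 1 &
              verts[, 2] > 0 & verts[, 2] < ny - 1
  expect_true(all(abs(vertexScalars(mesh)$gaussian_curvature[interior]) < 1e-9))
})

test_that("non-manifold meshes are rejected with the offending edges named", {
  verts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  faces <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))   # edge 1-2 in 3 faces
  mesh <- new("TriangleMesh", vertices = verts, faces = faces,
              vertexScalars = list())
  expect_error(gaussianCurvatureMap(mesh), "non-manifold.*1 2")
})

test_that("camera paths look along the tangent with transported up vectors", {
  straight <- centerlineCurve(rbind(c(0, 0, 0), c(0, 0, 10)))
  cam <- cameraPath(straight, 1)
  expect_identical(nrow(cam@positions), 11L)   # floor(arclength / step) + 1
  expect_true(all(abs(sweep(cam@viewDirs, 2, c(0, 0, 1), "-")) < 1e-9))
  expect_true(all(abs(cam@positions[, 1:2]) < 1e-9))
  # circular arc: view orthogonal to the radius everywhere
  th <- seq(0, pi, length.out = 200)
  arc <- centerlineCurve(cbind(20 * cos(th), 20 * sin(th), 0))
  cam2 <- cameraPath(arc, 1)
  radial <- cam2@positions / 20
  dots <- abs(rowSums(cam2@viewDirs * radial))
  expect_lt(max(dots[2:(nrow(radial) - 1)]), 1e-3)
  # parallel transport: no roll flips between consecutive keyframes
  consec <- rowSums(cam2@upDirs[-1, ] * cam2@upDirs[-nrow(cam2@upDirs), ])
  expect_gt(min(consec), 0.9)
  expect_error(cameraPath(centerlineCurve(rbind(c(1, 1, 1), c(1, 1, 1))), 1),
               "degenerate")
})

test_that("simulated nodules bend the surface with compact support and high curvature", {
  mesh <- icosphereMesh(radius = 5, subdivisions = 3)
  expect_identical(simulateNodule(mesh, c(0, 0, 5), 2, 0), mesh)
  bumped <- simulateNodule(mesh, c(0, 0, 5), radius = 1.5, height = 1)
  moved <- sqrt(rowSums((meshVertices(bumped) - meshVertices(mesh))^2))
  d_center <- sqrt(rowSums(sweep(meshVertices(mesh), 2, c(0, 0, 5), "-")^2))
  expect_true(all(moved[d_center > 3 * 1.5] == 0))
  expect_gt(max(moved), 0.9)                       # apex displaced ~height
  # the bump pushes inward (toward the sphere centre)
  apex <- which.max(moved)
  expect_lt(sqrt(sum(meshVertices(bumped)[apex, ]^2)), 5)
  # curvature at the bump exceeds the healthy surface's 95th percentile
  k0 <- vertexScalars(gaussianCurvatureMap(mesh))$gaussian_curvature
  k1 <- vertexScalars(gaussianCurvatureMap(bumped))$gaussian_curvature
  sel <- d_center <= 3 * 1.5
  expect_gt(max(k1[sel]), quantile(k0, 0.95))
})

test_that("nodule carving on a mask removes a bounded pocket of lumen", {
  d <- c(20L, 20L, 20L)
  ijk <- as.matrix(expand.grid(0:19, 0:19, 0:19))
  ball <- array(as.double(sqrt(rowSums(sweep(ijk, 2, c(10, 10, 10), "-")^2)) <= 7), d)
  mask <- scalarVolume(ball)
  expect_identical(simulateNodule(mask, c(10, 10, 3), 3, 0), mask)
  carved <- simulateNodule(mask, c(10, 10, 3), radius = 3, height = 2)
  removed <- imageData(mask) - imageData(carved)
  expect_true(all(removed >= 0))
  expect_gt(sum(removed), 0)
  # removal is local to the bump site
  rem_idx <- which(array(removed > 0, d), arr.ind = TRUE) - 1L
  expect_true(all(sqrt(rowSums(sweep(rem_idx, 2, c(10, 10, 3), "-")^2)) <= 3 * 3))
})

test_that("meshes and camera paths export to standard text formats", {
  mesh <- gaussianCurvatureMap(icosphereMesh(radius = 1, subdivisions = 1))
  ply <- tempfile(fileext = ".ply"); vtk <- tempfile(fileext = ".vtk")
  writeMesh(mesh, ply); writeMesh(mesh, vtk)
  expect_identical(readLines(ply, 1), "ply")
  expect_true(any(grepl("gaussian_curvature", readLines(ply, 10))))
  expect_true(any(grepl("POLYGONS", readLines(vtk))))
  cam <- cameraPath(centerlineCurve(rbind(c(0, 0, 0), c(0, 0, 5))), 1)
  cj <- tempfile(fileext = ".json")
  writeCameraPath(cam, cj)
  doc <- jsonlite::fromJSON(cj, simplifyVector = FALSE)
  expect_identical(length(doc$keyframes), 6L)
  unlink(c(ply, vtk, cj))
})
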