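# Optimal-path centerline extraction, tangents and spline resampling.

test_that("coincident endpoints give a degenerate single-vertex curve of cost 0", {
  V <- scalarVolume(array(0.5, c(5, 5, 5)))
  fid <- fiducialSet(rbind(c(2.1, 2, 2), c(1.9, 2, 2)))
  cl <- extractCenterline(V, fid)
  expect_identical(length(cl), 1L)
  expect_equal(curveCost(cl), 0)
})

test_that("a perfect-vesselness row is followed exactly at zero cost", {
  v <- array(0, c(5, 5, 1))
  v[, 3, 1] <- 1                      # middle row (j = 2, 0-based)
  V <- scalarVolume(v)
  fid <- fiducialSet(rbind(c(0, 2, 0), c(4, 2, 0)))
  cl <- extractCenterline(V, fid, pathGraphParams(weightFloor = 0),
                          bboxMarginMm = Inf)
  expect_equal(curveCost(cl), 0)
  expect_equal(curveVertices(cl),
               cbind(0:4, rep(2, 5), rep(0, 5)))
})

test_that("uniform vesselness makes the straight path optimal with cost (1-V)*length", {
  V <- scalarVolume(array(0.5, c(9, 5, 5)))
  fid <- fiducialSet(rbind(c(2, 2, 2), c(6, 2, 2)))
  cl <- extractCenterline(V, fid)
  expect_equal(curveCost(cl), 0.5 * 4, tolerance = 1e-9)
  expect_identical(length(cl), 5L)
  expect_true(all(curveVertices(cl)[, 2] == 2))
})

test_that("swapping head and tail reverses the curve and preserves the cost", {
  set.seed(31)
  V <- scalarVolume(array(runif(6 * 6 * 6), c(6, 6, 6)))
  f1 <- fiducialSet(rbind(c(0, 0, 0), c(5, 5, 5)))
  f2 <- fiducialSet(rbind(c(5, 5, 5), c(0, 0, 0)))
  a <- extractCenterline(V, f1, bboxMarginMm = Inf)
  b <- extractCenterline(V, f2, bboxMarginMm = Inf)
  expect_equal(curveCost(a), curveCost(b), tolerance = 1e-9)
  expect_equal(curveVertices(a), curveVertices(b)[length(b):1, ])
})

test_that("an intermediate fiducial on the optimal path leaves the cost unchanged", {
  set.seed(32)
  V <- scalarVolume(array(runif(7 * 6 * 5), c(7, 6, 5)))
  ends <- fiducialSet(rbind(c(0, 0, 0), c(6, 5, 4)))
  base <- extractCenterline(V, ends, bboxMarginMm = Inf)
  mid <- curveVertices(base)[ceiling(length(base) / 2), ]
  with_mid <- extractCenterline(
    V, fiducialSet(rbind(c(0, 0, 0), mid, c(6, 5, 4))), bboxMarginMm = Inf)
  expect_equal(curveCost(with_mid), curveCost(base), tolerance = 1e-9)
  expect_identical(length(sectionBreaks(with_mid)), 1L)
})

test_that("the easy phantom centerline is captured within a voxel diagonal", {
  ph <- generatePhantom(defaultDuctSpec("easy"))
  V <- computeVesselness(ph@image)
  cl <- extractCenterline(V, ph@headTail)
  cd <- centerlineDistance(cl, ph@centerline)
  expect_lte(cd[["mean"]], sqrt(3))
})

test_that("fiducials outside the volume are rejected", {
  V <- scalarVolume(array(0.5, c(5, 5, 5)))
  expect_error(
    extractCenterline(V, fiducialSet(rbind(c(0, 0, 0), c(40, 2, 2)))),
    "outside")
})

test_that("tangents are unit central differences with one-sided endpoints", {
  cl <- centerlineCurve(cbind(0, 0, seq(0, 10, by = 0.5)))
  for (t in seq_len(length(cl)))
    expect_equal(tangentAt(cl, t), c(0, 0, 1))
  # quarter circle sampled at 1 degree: tangent orthogonal to the radius
  th <- seq(0, pi / 2, by = pi / 180)
  circ <- centerlineCurve(cbind(10 * cos(th), 10 * sin(th), 0))
  for (t in c(2, 25, 60, 90)) {
    tv <- tangentAt(circ, t)
    expect_lt(abs(sum(tv * curveVertices(circ)[t, ])) / 10, 1e-3)
  }
})

test_that("reversing vertex order negates every tangent", {
  set.seed(33)
  pts <- cbind(cumsum(runif(8)), cumsum(runif(8)), cumsum(runif(8)))
  a <- centerlineCurve(pts)
  b <- centerlineCurve(pts[8:1, ])
  for (t in 2:7)
    expect_equal(tangentAt(a, t), -tangentAt(b, 9 - t))
})

test_that("tangents at section joints require explicit opt-in", {
  cl <- new("CenterlineCurve",
            vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 2, 0)),
            arclength = c(0, 1, 2, 3), cost = 0, sectionBreaks = 2L)
  expect_error(tangentAt(cl, 2), "joint")
  expect_equal(tangentAt(cl, 2, allowJoint = TRUE), c(1, 0, 0))
  expect_error(tangentAt(centerlineCurve(matrix(0, 1, 3)), 1), "single vertex")
})

test_that("resampling a straight 10 mm segment at 1 mm gives 11 collinear vertices", {
  cl <- centerlineCurve(rbind(c(0, 0, 0), c(0, 0, 10)))
  rs <- resampleCurve(cl, 1)
  expect_identical(length(rs), 11L)
  expect_equal(curveVertices(rs), cbind(0, 0, 0:10))
  # idempotency on the uniform case
  rs2 <- resampleCurve(rs, 1)
  expect_lt(max(abs(curveVertices(rs2) - curveVertices(rs))), 1e-6)
})

test_that("fine resampling preserves curve length within 1%", {
  th <- seq(0, pi, length.out = 40)
  cl <- centerlineCurve(cbind(8 * cos(th), 8 * sin(th), th))
  orig_len <- max(curveArclength(cl))
  rs <- resampleCurve(cl, 0.5)
  expect_lt(abs(max(curveArclength(rs)) - orig_len) / orig_len, 0.01)
  expect_equal(curveVertices(rs)[1, ], unname(curveVertices(cl)[1, ]))
  expect_equal(curveVertices(rs)[length(rs), ], unname(curveVertices(cl)[40, ]))
  expect_error(resampleCurve(cl, 0), "positive")
})
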