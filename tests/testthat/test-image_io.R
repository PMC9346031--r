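# Volume and fiducial I/O: geometry-preserving round trips and the
# RAS/LPS coordinate conventions.

rand_vol <- function(dims = c(10L, 12L, 14L), seed = 1) {
  set.seed(seed)
  scalarVolume(array(rnorm(prod(dims)), dims),
               spacing = c(0.8, 0.8, 2.5), origin = c(-10.5, 4.25, 3))
}

test_that("volume round trips preserve values, shape and geometry in every format", {
  vol <- rand_vol()
  for (ext in c(".nii", ".nii.gz", ".nrrd", ".mha", ".mhd")) {
    f <- tempfile(fileext = ext)
    writeVolume(vol, f, datatype = "double")
    back <- readVolume(f)
    expect_identical(dim(back), c(10L, 12L, 14L))
    expect_lt(max(abs(imageData(back) - imageData(vol))), 1e-6)
    expect_equal(voxelSpacing(back), c(0.8, 0.8, 2.5), tolerance = 1e-6)
    expect_equal(volumeOrigin(back), volumeOrigin(vol), tolerance = 1e-6)
    expect_equal(volumeDirection(back), diag(3), tolerance = 1e-6)
    unlink(f)
  }
})

test_that("label volumes written as uint8 reread exactly", {
  set.seed(2)
  lab <- scalarVolume(array(sample(0:2, 8 * 7 * 6, replace = TRUE), c(8, 7, 6)),
                      spacing = c(1, 1, 2))
  for (ext in c(".nii.gz", ".nrrd", ".mha")) {
    f <- tempfile(fileext = ext)
    writeVolume(lab, f, datatype = "uint8")
    expect_identical(imageData(readVolume(f)), imageData(lab))
    unlink(f)
  }
})

test_that("non-identity orientation survives the round trip", {
  D <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)  # 90 deg about z
  vol <- scalarVolume(array(runif(4 * 5 * 6), c(4, 5, 6)),
                      spacing = c(1, 1.5, 2), origin = c(3, -2, 7),
                      direction = D)
  for (ext in c(".nii", ".nrrd", ".mha")) {
    f <- tempfile(fileext = ext)
    writeVolume(vol, f, datatype = "double")
    back <- readVolume(f)
    expect_equal(volumeDirection(back), D, tolerance = 1e-6)
    # physical coordinate of an arbitrary voxel is unchanged
    expect_equal(voxelToWorld(back, c(2, 3, 4)), voxelToWorld(vol, c(2, 3, 4)),
                 tolerance = 1e-6)
    unlink(f)
  }
})

test_that("unsupported or missing files raise clear errors", {
  expect_error(readVolume(tempfile(fileext = ".nii")), "not found")
  bad <- tempfile(fileext = ".xyz")
  writeLines("x", bad)
  expect_error(readVolume(bad), "extension")
  unlink(bad)
  f <- tempfile(fileext = ".nrrd")
  writeLines("not a nrrd", f)
  expect_error(readVolume(f))
})

test_that("fcsv fiducials are converted from RAS to LPS with order preserved", {
  f <- tempfile(fileext = ".fcsv")
  writeLines(c(
    "# Markups fiducial file version = 4.11",
    "# CoordinateSystem = 0",
    "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID",
    "vtkMRMLMarkupsFiducialNode_0,10,-20,5,0,0,0,1,1,1,0,F-1,,",
    "vtkMRMLMarkupsFiducialNode_1,1.5,2.5,-3,0,0,0,1,1,1,0,F-2,,"), f)
  fid <- readFiducials(f)
  expect_identical(length(fid), 2L)
  expect_equal(fiducialPoints(fid)[1, ], c(-10, 20, 5))   # RAS -> LPS
  expect_identical(fiducialLabels(fid), c("F-1", "F-2"))
  unlink(f)
})

test_that("fiducial round trip is an involution and order is preserved", {
  pts <- rbind(c(1.25, -2.5, 3), c(-4, 5.75, -6), c(7, 8, -9.5), c(0, 1, 2))
  fid <- fiducialSet(pts)
  for (ext in c(".fcsv", ".json")) {
    f <- tempfile(fileext = ext)
    writeFiducials(fid, f)
    back <- readFiducials(f)
    expect_equal(fiducialPoints(back), pts)
    expect_identical(length(back), 4L)
    unlink(f)
  }
})

test_that("malformed or too-short fiducial files are rejected", {
  f <- tempfile(fileext = ".fcsv")
  writeLines(c("# header", "id,1,2,3,0,0,0,1,1,1,0,A,,"), f)
  expect_error(readFiducials(f), "at least 2")
  writeLines(c("id,1,oops,3,0,0,0,1,1,1,0,A,,",
               "id,1,2,3,0,0,0,1,1,1,0,B,,"), f)
  expect_error(readFiducials(f), "parse error")
  unlink(f)
})

test_that("centerline JSON round trips vertices, cost and joints", {
  cl <- centerlineCurve(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)),
                        cost = 1.25, sectionBreaks = 2L)
  f <- tempfile(fileext = ".json")
  writeCenterline(cl, f)
  back <- readCenterline(f)
  expect_equal(curveVertices(back), curveVertices(cl))
  expect_equal(curveCost(back), 1.25)
  expect_identical(sectionBreaks(back), 2L)
  unlink(f)
})
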