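# ROI cropping and convex subdivision upsampling.

test_that("crop around a straight centerline has the expected extent and geometry", {
  vol <- scalarVolume(array(seq_len(50^3), c(50, 50, 50)))
  cl <- centerlineCurve(rbind(c(25, 25, 10), c(25, 25, 40)))
  crop <- cropRoi(vol, cl, 10)
  expect_identical(dim(crop$volume)[1:2], c(21L, 21L))   # 1 + 2*10 voxels
  expect_identical(crop$indexOffset[1:2], c(15L, 15L))
  # physical coordinates of retained voxels are unchanged
  p_orig <- voxelToWorld(vol, c(20, 18, 12))
  p_crop <- voxelToWorld(crop$volume, c(20, 18, 12) - crop$indexOffset)
  expect_equal(p_crop, p_orig, tolerance = 1e-9)
  # values come from the right place
  expect_equal(imageData(crop$volume)[1, 1, 1],
               imageData(vol)[16, 16, 1])
})

test_that("a margin covering the whole image returns the input grid", {
  vol <- scalarVolume(array(runif(8^3), c(8, 8, 8)))
  cl <- centerlineCurve(rbind(c(3, 3, 1), c(4, 4, 6)))
  crop <- cropRoi(vol, cl, 500)
  expect_identical(dim(crop$volume), dim(vol))
  expect_identical(crop$indexOffset, c(0L, 0L, 0L))
  expect_identical(imageData(crop$volume), imageData(vol))
})

test_that("factor 1 upsampling is the identity", {
  vol <- scalarVolume(array(runif(5 * 6 * 7), c(5, 6, 7)),
                      spacing = c(0.8, 1, 1.5), origin = c(1, 2, 3))
  up <- upsampleVolume(vol, 1L)
  expect_identical(imageData(up), imageData(vol))
  expect_equal(volumeOrigin(up), volumeOrigin(vol))
})

test_that("factor 5 multiplies the voxel count by exactly 125", {
  vol <- scalarVolume(array(runif(6 * 5 * 4), c(6, 5, 4)))
  up <- upsampleVolume(vol, 5L)
  expect_identical(length(imageData(up)), 125L * (6L * 5L * 4L))
  expect_identical(dim(up), c(30L, 25L, 20L))
  expect_equal(voxelSpacing(up), c(1, 1, 1) / 5)
})

test_that("even factors are rejected", {
  vol <- scalarVolume(array(0, c(4, 4, 4)))
  expect_error(upsampleVolume(vol, 2L), "odd")
  expect_error(upsampleVolume(vol, 4L), "odd")
})

test_that("odd factors reproduce original voxel centres exactly and convexly", {
  set.seed(7)
  d <- c(6L, 5L, 4L)
  vol <- scalarVolume(array(rnorm(prod(d)), d), spacing = c(1, 2, 0.5))
  cc <- 3L
  up <- upsampleVolume(vol, cc)
  uv <- imageData(up)
  # original centres: output index c*i + (c-1)/2 (0-based)
  orig_at <- uv[cc * (0:(d[1] - 1)) + (cc - 1) / 2 + 1,
                cc * (0:(d[2] - 1)) + (cc - 1) / 2 + 1,
                cc * (0:(d[3] - 1)) + (cc - 1) / 2 + 1]
  expect_identical(orig_at, imageData(vol))
  # physical alignment: subvoxel centres tile the original voxels
  expect_equal(voxelToWorld(up, c((cc - 1) / 2, (cc - 1) / 2, (cc - 1) / 2)),
               voxelToWorld(vol, c(0, 0, 0)), tolerance = 1e-9)
  # convexity: each output value lies within the local min/max of the
  # 8 enclosing original samples (independently recomputed mapping)
  iv <- imageData(vol)
  set.seed(8)
  for (probe in seq_len(200)) {
    out_idx <- c(sample(0:(d[1] * cc - 1), 1), sample(0:(d[2] * cc - 1), 1),
                 sample(0:(d[3] * cc - 1), 1))
    u <- pmin(pmax((out_idx + 0.5) / cc - 0.5, 0), d - 1)
    lo <- pmax(floor(u), 0); hi <- pmin(lo + 1, d - 1)
    corners <- iv[unique(c(lo[1], hi[1])) + 1,
                  unique(c(lo[2], hi[2])) + 1,
                  unique(c(lo[3], hi[3])) + 1]
    val <- uv[out_idx[1] + 1, out_idx[2] + 1, out_idx[3] + 1]
    expect_gte(val, min(corners) - 1e-12)
    expect_lte(val, max(corners) + 1e-12)
  }
})

test_that("constant and trilinear fields are reproduced exactly", {
  d <- c(5L, 5L, 5L)
  const <- upsampleVolume(scalarVolume(array(3.25, d)), 5L)
  expect_true(all(imageData(const) == 3.25))
  # a linear ramp is in the span of trilinear interpolation
  ramp_fun <- function(p) 2 * p[, 1] - 3 * p[, 2] + 0.5 * p[, 3] + 1
  ijk <- as.matrix(expand.grid(0:4, 0:4, 0:4))
  ramp <- array(0, d)
  ramp[ijk + 1] <- ramp_fun(ijk)
  volr <- scalarVolume(ramp, spacing = c(1, 1, 1))
  up <- upsampleVolume(volr, 3L)
  # interior subvoxels (clamped boundary extension is constant, not linear)
  interior <- 2:(dim(up)[1] - 1)
  pts <- as.matrix(expand.grid(interior - 1, interior - 1, interior - 1))
  world <- voxelToWorld(up, pts)
  got <- imageData(up)[pts + 1]
  expect_equal(got, ramp_fun(world), tolerance = 1e-9)
})

test_that("cropping then upsampling matches upsampling then cropping away from the boundary", {
  set.seed(9)
  d <- c(10L, 10L, 8L)
  vol <- scalarVolume(array(rnorm(prod(d)), d))
  cl <- centerlineCurve(rbind(c(4, 4, 2), c(6, 5, 5)))
  cc <- 3L
  crop <- cropRoi(vol, cl, 2)
  a <- upsampleVolume(crop$volume, cc, crop$indexOffset)
  b_full <- upsampleVolume(vol, cc)
  off <- crop$indexOffset * cc
  da <- dim(a)
  sub_b <- imageData(b_full)[(off[1] + 1):(off[1] + da[1]),
                             (off[2] + 1):(off[2] + da[2]),
                             (off[3] + 1):(off[3] + da[3])]
  trim <- function(x) x[(cc + 1):(dim(x)[1] - cc),
                        (cc + 1):(dim(x)[2] - cc),
                        (cc + 1):(dim(x)[3] - cc)]
  expect_lt(max(abs(trim(imageData(a)) - trim(sub_b))), 1e-6)
})
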