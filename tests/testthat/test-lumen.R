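# Seed map construction, Moore neighbourhoods and intensity-geodesic label
# propagation.

test_that("Moore neighbourhood sizes follow the 2D/3D boundary rules", {
  expect_identical(nrow(mooreNeighbors(c(3, 3, 3), c(7, 7, 7))), 26L)
  expect_identical(nrow(mooreNeighbors(c(0, 0, 0), c(7, 7, 7))), 7L)
  expect_identical(nrow(mooreNeighbors(c(3, 3, 0), c(7, 7, 1))), 8L)
  expect_identical(nrow(mooreNeighbors(c(0, 3, 0), c(7, 7, 1))), 5L)
  expect_error(mooreNeighbors(c(7, 3, 3), c(7, 7, 7)), "outside")
  # neighbours differ by at most 1 per coordinate and exclude the centre
  nb <- mooreNeighbors(c(2, 2, 2), c(5, 5, 5))
  expect_true(all(abs(sweep(nb, 2, c(2, 2, 2), "-")) <= 1))
  expect_false(any(rowSums(sweep(nb, 2, c(2, 2, 2), "==")) == 3))
})

test_that("the seed map realizes the centerline / radius-r partition", {
  # 60 x 60 x 5 grid at 0.5 mm: straight line through the middle
  d <- c(60L, 60L, 5L)
  vol <- scalarVolume(array(0, d), spacing = c(0.5, 0.5, 0.5))
  roi <- upsampleVolume(vol, 1L)
  cl <- centerlineCurve(rbind(c(14.8, 14.8, 0), c(14.8, 14.8, 2)))
  seeds <- buildSeedMap(roi, cl, seedConfig(radiusRMm = 10))
  lab <- labelData(seeds)
  ctr <- worldToVoxel(vol, rbind(c(14.8, 14.8, 1)))[1, 1:2]
  # every rasterized centerline voxel is a label-1 seed
  expect_identical(lab[ctr[1] + 1, ctr[2] + 1, 3], 1L)
  # 12 mm away -> exterior seed; 5 mm away -> undetermined
  vox_12 <- round(worldToVoxel(vol, rbind(c(14.8 + 12, 14.8, 1))))[1, ]
  vox_5 <- round(worldToVoxel(vol, rbind(c(14.8 + 5, 14.8, 1))))[1, ]
  expect_identical(lab[vox_12[1] + 1, vox_12[2] + 1, vox_12[3] + 1], 2L)
  expect_identical(lab[vox_5[1] + 1, vox_5[2] + 1, vox_5[3] + 1], 0L)
  # counts partition the grid
  expect_identical(sum(labelCounts(seeds)), as.integer(prod(d)))
})

test_that("a too-small ROI margin is reported as a configuration error", {
  vol <- scalarVolume(array(0, c(10, 10, 10)))
  roi <- upsampleVolume(vol, 1L)
  cl <- centerlineCurve(rbind(c(4, 4, 2), c(4, 4, 7)))
  expect_error(buildSeedMap(roi, cl, seedConfig(radiusRMm = 50)),
               "configuration error.*margin")
})

test_that("constant ROI with one seed of each label resolves ties to the lumen", {
  vol <- scalarVolume(array(1, c(4, 4, 1)))
  lab <- array(0L, c(4, 4, 1))
  lab[1, 1, 1] <- 1L
  lab[4, 4, 1] <- 2L
  seeds <- make_seed_map(lab)
  out <- propagateLabels(vol, seeds)
  expect_identical(sum(labelData(out) == 1L), 15L)   # all ties -> label 1
  expect_identical(labelData(out)[4, 4, 1], 2L)      # seeds keep their label
})

test_that("a step edge on a 6-voxel chain is classified by intensity geodesics", {
  vol <- scalarVolume(array(c(0, 0, 0, 1, 1, 1), c(6, 1, 1)))
  lab <- array(0L, c(6, 1, 1)); lab[1, 1, 1] <- 1L; lab[6, 1, 1] <- 2L
  seeds <- make_seed_map(lab)
  out <- propagateLabels(vol, seeds)
  expect_identical(as.integer(labelData(out)), c(1L, 1L, 1L, 2L, 2L, 2L))
  cost <- attr(labelData(out), "cost")
  expect_equal(as.numeric(cost), c(0, 0, 0, 0, 0, 0))  # each side reaches its seed free
})

test_that("piecewise-constant two-region images are recovered exactly", {
  set.seed(21)
  for (rep in 1:5) {
    d <- c(sample(4:7, 1), sample(4:7, 1), sample(2:4, 1))
    split <- sample(seq_len(d[1] - 1), 1)
    vals <- array(0, d)
    vals[(split + 1):d[1], , ] <- runif(1, 0.3, 1)
    region <- array(1L, d); region[(split + 1):d[1], , ] <- 2L
    lab <- array(0L, d)
    pick1 <- function(x) x[sample.int(length(x), 1)]
    s1 <- c(pick1(seq_len(split)), sample(d[2], 1), sample(d[3], 1))
    s2 <- c(pick1((split + 1):d[1]), sample(d[2], 1), sample(d[3], 1))
    lab[s1[1], s1[2], s1[3]] <- 1L
    lab[s2[1], s2[2], s2[3]] <- 2L
    seeds <- make_seed_map(lab)
    out <- propagateLabels(scalarVolume(vals), seeds)
    expect_identical(labelData(out)[seq_along(region)], as.integer(region))
  }
})

test_that("labeling is invariant to positive affine intensity rescaling", {
  set.seed(22)
  d <- c(6L, 5L, 3L)
  vals <- array(runif(prod(d)), d)
  lab <- array(0L, d); lab[2, 2, 2] <- 1L; lab[5, 4, 2] <- 2L
  seeds <- make_seed_map(lab)
  base <- propagateLabels(scalarVolume(vals), seeds)
  shifted <- propagateLabels(scalarVolume(vals + 42), seeds)
  scaled <- propagateLabels(scalarVolume(3.5 * vals - 1), seeds)
  expect_identical(as.integer(labelData(base)), as.integer(labelData(shifted)))
  expect_identical(as.integer(labelData(base)), as.integer(labelData(scaled)))
})

test_that("propagation is deterministic and restriction does not change labels", {
  set.seed(23)
  d <- c(12L, 12L, 6L)
  vol <- scalarVolume(array(runif(prod(d)), d))
  roi <- upsampleVolume(vol, 1L)
  cl <- centerlineCurve(rbind(c(5, 5, 1), c(6, 6, 4)))
  seeds <- buildSeedMap(roi, cl, seedConfig(radiusRMm = 4))
  a <- propagateLabels(roi, seeds)
  b <- propagateLabels(roi, seeds)
  expect_identical(labelData(a)[], labelData(b)[])
  r <- propagateLabels(roi, seeds, restrict = TRUE)
  expect_identical(as.integer(labelData(a)), as.integer(labelData(r)))
})

test_that("an all-seed map is returned unchanged", {
  vol <- scalarVolume(array(runif(8), c(2, 2, 2)))
  lab <- array(c(1L, 2L), c(2, 2, 2))
  seeds <- make_seed_map(lab)
  expect_identical(propagateLabels(vol, seeds), seeds)
})

test_that("lumen mask keeps seeds, majority-downsamples and screens components", {
  # all-ones c^3 block downsamples to a single positive voxel
  d <- c(6L, 6L, 6L)
  vol <- scalarVolume(array(0, c(2L, 2L, 2L)), spacing = c(1, 1, 1))
  roi <- upsampleVolume(vol, 3L)
  lab <- array(2L, d)
  lab[1:3, 1:3, 1:3] <- 1L                 # exactly the first original voxel
  seeds <- make_seed_map(lab)
  res <- lumenMask(seeds, roi, vol)
  expect_equal(sum(imageData(res$mask)), 27)
  expect_identical(imageData(res$maskOriginal)[1, 1, 1], 1)
  expect_equal(sum(imageData(res$maskOriginal)), 1)
  # incomplete propagation is rejected
  lab0 <- lab; lab0[6, 6, 6] <- 0L
  bad <- make_seed_map(lab0, spacing = voxelSpacing(roi))
  expect_error(lumenMask(bad, roi, vol), "incomplete")
})

test_that("enclosed cavities are filled (the lumen is simply connected)", {
  d <- c(9L, 9L, 9L)
  lab <- array(2L, d)
  lab[2:8, 2:8, 2:8] <- 1L
  lab[5, 5, 5] <- 2L                         # isolated interior pocket
  seeds <- make_seed_map(lab)
  filled <- lumenMask(seeds)$mask
  expect_equal(imageData(filled)[5, 5, 5], 1)
  open_mask <- lumenMask(seeds, fillCavities = FALSE)$mask
  expect_equal(imageData(open_mask)[5, 5, 5], 0)
})
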