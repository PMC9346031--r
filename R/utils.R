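#' Construct a ScalarVolume
#'
#' @param values 3D numeric array.
#' @param spacing numeric(3) voxel size in mm.
#' @param origin numeric(3) physical position of voxel (0,0,0) in mm (LPS).
#' @param direction 3x3 orthonormal direction matrix.
#' @return a \linkS4class{ScalarVolume}.
#' @export
scalarVolume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         direction = diag(3)) {
  storage.mode(values) <- "double"
  vol <- new("ScalarVolume", values = values, spacing = as.numeric(spacing),
             origin = as.numeric(origin), direction = direction)
  if (!axis_aligned(direction))
    warning("volume orientation is not axis-aligned; distances use physical coordinates")
  vol
}

#' Construct a FiducialSet
#'
#' @param points N x 3 matrix of physical points (mm, LPS); first row is the
#'   duct head, last row the tail.
#' @param labels optional character names per point.
#' @return a \linkS4class{FiducialSet}.
#' @export
fiducialSet <- function(points, labels = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (is.null(labels)) labels <- paste0("F-", seq_len(nrow(points)))
  new("FiducialSet", points = points, labels = as.character(labels))
}

# is a direction matrix a signed permutation (axis-aligned)?
axis_aligned <- function(D, tol = 1e-6) {
  all(abs(abs(D) - round(abs(D))) < tol)
}

#' Map 0-based voxel indices to physical coordinates
#'
#' @param vol a \linkS4class{ScalarVolume}.
#' @param ijk N x 3 matrix (or length-3 vector) of 0-based, possibly
#'   fractional voxel indices.
#' @return N x 3 matrix of physical points (mm, LPS).
#' @export
voxelToWorld <- function(vol, ijk) {
  ijk <- rbind_points(ijk)
  scaled <- sweep(ijk, 2, vol@spacing, "*")
  sweep(scaled %*% t(vol@direction), 2, vol@origin, "+")
}

#' Map physical coordinates to continuous 0-based voxel indices
#'
#' @inheritParams voxelToWorld
#' @param xyz N x 3 matrix (or length-3 vector) of physical points (mm, LPS).
#' @return N x 3 matrix of continuous 0-based voxel indices.
#' @export
worldToVoxel <- function(vol, xyz) {
  xyz <- rbind_points(xyz)
  local <- sweep(xyz, 2, vol@origin, "-") %*% vol@direction
  sweep(local, 2, vol@spacing, "/")
}

rbind_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  stopifnot(ncol(p) == 3L)
  p
}

# physical coordinates of every voxel centre, in linear-index order
all_voxel_centers <- function(vol) {
  d <- dim(vol@values)
  ijk <- cbind(
    rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  voxelToWorld(vol, ijk)
}

# linear 1-based index from 0-based ijk matrix
ijk_to_linear <- function(ijk, dims) {
  as.integer(ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3]) + 1)
}

linear_to_ijk <- function(idx, dims) {
  idx0 <- idx - 1L
  cbind(idx0 %% dims[1],
        (idx0 %/% dims[1]) %% dims[2],
        idx0 %/% (dims[1] * dims[2]))
}

# run expr with a local RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# sampled Gaussian (order 0/1/2 derivative) kernel, sigma in voxels
gaussian_kernel <- function(sigma, order = 0L, radius = NULL) {
  if (sigma <= 0) {
    if (order == 0L) return(1)
    # central finite differences at unit voxel step
    return(switch(order + 1L, 1, c(-0.5, 0, 0.5), c(1, -2, 1)))
  }
  if (is.null(radius)) radius <- max(1L, ceiling(4 * sigma))
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(order + 1L,
         g,
         -x / sigma^2 * g,
         (x^2 - sigma^2) / sigma^4 * g)
}

# separable Gaussian smoothing with physical sigma (mm), spacing-aware
smooth_volume_gaussian <- function(values, spacing, sigma_mm) {
  if (sigma_mm <= 0) return(values)
  d <- dim(values)
  out <- as.numeric(values)
  for (axis in 0:2) {
    sig_vox <- sigma_mm / spacing[axis + 1]
    if (sig_vox > 1e-8)
      out <- cpp_conv_axis(out, as.integer(d), gaussian_kernel(sig_vox), axis)
  }
  array(out, d)
}

# cumulative polyline arc length
polyline_arclength <- function(verts) {
  n <- nrow(verts)
  if (n < 2) return(rep(0, n))
  seg <- sqrt(rowSums((verts[-1, , drop = FALSE] - verts[-n, , drop = FALSE])^2))
  c(0, cumsum(seg))
}

# sample a polyline at a uniform arc-length step (always includes endpoints)
densify_polyline <- function(verts, step) {
  al <- polyline_arclength(verts)
  total <- al[length(al)]
  if (total == 0) return(verts[1, , drop = FALSE])
  nseg <- max(1L, ceiling(total / step))
  targets <- seq(0, total, length.out = nseg + 1L)
  apply_interp <- function(col) stats::approx(al, verts[, col], xout = targets,
                                              ties = "ordered")$y
  cbind(apply_interp(1), apply_interp(2), apply_interp(3))
}
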