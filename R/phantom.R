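#' Phantom specifications with sensible defaults
#'
#' Builds a \linkS4class{PhantomSpec} describing a CT-like block of
#' contrast-enhanced parenchyma containing a hypodense tubular duct with
#' known geometry. Two presets are provided:
#' \describe{
#'   \item{easy}{straight axial duct, radius 2 mm, isotropic 1 mm voxels,
#'     high contrast, no noise, no blur -- for exact geometric checks.}
#'   \item{realistic}{curved (cubic-spline) duct of radius 1.5 mm on an
#'     anisotropic grid of (0.8, 0.8, 1.5) mm -- in-plane the duct occupies
#'     roughly 3-5 voxels across its diameter, the regime that makes thin
#'     ducts hard to segment at native resolution -- with 70 HU
#'     duct/parenchyma contrast, additive Gaussian noise (sigma 10) and
#'     0.8 mm partial-volume blur.}
#' }
#'
#' @param difficulty "easy" or "realistic".
#' @param seed RNG seed stored in the spec (the generator is deterministic
#'   given the spec).
#' @return a \linkS4class{PhantomSpec}.
#' @export
defaultDuctSpec <- function(difficulty = c("easy", "realistic"), seed = 7L) {
  difficulty <- match.arg(difficulty)
  if (difficulty == "easy") {
    new("PhantomSpec",
        shape = c(40L, 40L, 40L), spacing = c(1, 1, 1),
        ductPath = rbind(c(20.4, 19.7, 6), c(20.4, 19.7, 34)),
        ductRadius = 2,
        intensityBackground = -50, intensityParenchyma = 90,
        intensityDuct = 15,
        parenchymaMargin = 3, noiseSigma = 0, blurSigmaMm = 0,
        seed = as.integer(seed))
  } else {
    new("PhantomSpec",
        shape = c(48L, 48L, 36L), spacing = c(0.8, 0.8, 1.5),
        ductPath = rbind(c(12, 14, 7), c(18, 23, 19),
                         c(25, 16, 31), c(19, 22, 46)),
        ductRadius = 1.5,
        intensityBackground = -50, intensityParenchyma = 90,
        intensityDuct = 20,
        parenchymaMargin = 3, noiseSigma = 10, blurSigmaMm = 0.8,
        seed = as.integer(seed))
  }
}

#' Generate a synthetic duct phantom with exact ground truth
#'
#' The duct path (control points) is interpolated by a natural cubic spline
#' and swept with the duct radius. The tube is rasterized with
#' anti-aliasing: each voxel is supersampled 3x per axis and the 27
#' occupancy fractions are box-averaged, giving partial-volume voxels
#' fractional pre-noise intensities at the boundary. The image is then
#' Gaussian-blurred by \code{blurSigmaMm} and corrupted with additive
#' Gaussian noise (seeded locally by \code{spec@seed}; the caller's RNG
#' state is untouched). The ground-truth mask is the exact un-noised,
#' un-blurred swept-tube indicator at voxel centres, and the ground-truth
#' centerline is the duct path sampled at no more than half the minimum
#' spacing.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return a \linkS4class{PhantomTruth}.
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  d <- spec@shape
  s <- spec@spacing

  # dense ground-truth centerline along the (spline-interpolated) duct path
  ctrl <- centerlineCurve(spec@ductPath)
  curve <- resampleCurve(ctrl, stepMm = min(s) / 2)
  verts <- curve@vertices

  # clearance from the volume faces (centres span [0, (n-1)s]; faces +/- s/2)
  clearance <- spec@ductRadius + 3 * spec@blurSigmaMm
  lo_face <- -s / 2
  hi_face <- (d - 1) * s + s / 2
  if (any(sweep(verts, 2, lo_face + clearance, "<")) ||
      any(sweep(verts, 2, hi_face - clearance, ">")))
    stop("geometry error: duct curve runs within ", signif(clearance, 3),
         " mm of a volume face")

  # anti-aliased occupancy: 3x supersampling then box average
  dist_sub <- cpp_grid_dist_to_polyline(as.integer(d * 3L), s / 3, -s / 3,
                                        verts)
  sub <- array(dist_sub <= spec@ductRadius, d * 3L)
  sub6 <- array(as.double(sub), c(3L, d[1], 3L, d[2], 3L, d[3]))
  occ <- aperm(sub6, c(1, 3, 5, 2, 4, 6))
  dim(occ) <- c(27L, prod(d))
  frac <- array(colMeans(occ), d)

  # parenchyma block inset from the faces
  centers_ax <- function(a) (seq_len(d[a]) - 1) * s[a]
  inbox <- function(a) centers_ax(a) >= (lo_face[a] + spec@parenchymaMargin) &
    centers_ax(a) <= (hi_face[a] - spec@parenchymaMargin)
  box <- outer(outer(inbox(1), inbox(2), "&"), inbox(3), "&")

  img <- array(spec@intensityBackground, d)
  img[box] <- spec@intensityParenchyma
  img <- img + frac * (spec@intensityDuct - spec@intensityParenchyma)

  if (spec@blurSigmaMm > 0)
    img <- smooth_volume_gaussian(img, s, spec@blurSigmaMm)
  if (spec@noiseSigma > 0)
    img <- img + with_local_seed(spec@seed,
      array(stats::rnorm(prod(d), sd = spec@noiseSigma), d))

  dist_ctr <- cpp_grid_dist_to_polyline(as.integer(d), s, c(0, 0, 0), verts)
  mask <- array(as.double(dist_ctr <= spec@ductRadius), d)

  head_tail <- fiducialSet(rbind(verts[1, ], verts[nrow(verts), ]),
                           c("F-1", "F-2"))
  new("PhantomTruth",
      image = scalarVolume(img, spacing = s),
      ductMask = scalarVolume(mask, spacing = s),
      centerline = curve,
      headTail = head_tail)
}
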