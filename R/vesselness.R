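#' Parameters of the multiscale Hessian line filter
#'
#' The tubularity (vesselness) measure is the classical multiscale Hessian
#' eigenvalue line filter: at each scale the image is convolved with
#' Gaussian second-derivative kernels (physical, spacing-aware sigmas), the
#' Hessian eigenvalues are sorted by magnitude, and line-like structures are
#' scored by the plate/line ratio (alpha), the blobness ratio (beta) and the
#' structure-to-noise term (gamma). The response is maximized over scales.
#'
#' @param scalesMm strictly increasing positive Gaussian scales in mm.
#'   Defaults cover duct radii of roughly 1-3 mm.
#' @param alpha plate-vs-line discrimination weight (default 0.5).
#' @param beta blob discrimination weight (default 0.5).
#' @param gamma structure-to-noise weight; \code{"auto"} (default) resolves,
#'   per scale, to half the maximum Hessian Frobenius norm over the image.
#' @param polarity \code{"dark_tube"} (hypodense duct in enhanced
#'   parenchyma; requires both large eigenvalues positive) or
#'   \code{"bright_tube"}.
#' @return a validated parameter list for [computeVesselness()].
#' @export
vesselnessParams <- function(scalesMm = c(1, 1.5, 2, 3), alpha = 0.5,
                             beta = 0.5, gamma = "auto",
                             polarity = c("dark_tube", "bright_tube")) {
  polarity <- match.arg(polarity)
  if (!length(scalesMm) || any(scalesMm <= 0) ||
      (length(scalesMm) > 1 && any(diff(scalesMm) <= 0)))
    stop("scalesMm must be nonempty, positive and strictly increasing")
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  if (!identical(gamma, "auto") && (!is.numeric(gamma) || gamma <= 0))
    stop("gamma must be a positive number or \"auto\"")
  list(scalesMm = scalesMm, alpha = alpha, beta = beta, gamma = gamma,
       polarity = polarity)
}

#' Compute a tubularity (vesselness) map
#'
#' Produces a \linkS4class{ScalarVolume} on the same grid as the input,
#' normalized to [0, 1] by division by the global maximum (a constant image
#' yields an all-zero map). Voxels failing the eigenvalue sign condition for
#' the requested polarity get response 0. Hessians are computed with
#' scale-normalized Gaussian derivatives (response multiplied by sigma^2) so
#' responses are comparable across scales; image boundaries use
#' nearest-neighbour extension.
#'
#' @param image a \linkS4class{ScalarVolume} with at least 5 voxels per axis.
#' @param params see [vesselnessParams()].
#' @return a \linkS4class{ScalarVolume} holding V in [0, 1].
#' @export
computeVesselness <- function(image, params = vesselnessParams()) {
  stopifnot(is(image, "ScalarVolume"))
  d <- dim(image@values)
  if (any(d < 5L)) stop("precondition error: image must have >= 5 voxels per axis")
  gamma <- if (identical(params$gamma, "auto")) -1 else params$gamma
  best <- numeric(prod(d))
  for (sigma in params$scalesMm) {
    H <- hessian_components(image@values, image@spacing, sigma)
    resp <- cpp_line_filter(H$xx, H$yy, H$zz, H$xy, H$xz, H$yz,
                            params$alpha, params$beta, gamma,
                            params$polarity == "dark_tube")
    best <- pmax(best, resp)
  }
  mx <- max(best)
  if (mx > 0) best <- best / mx
  scalarVolume(array(best, d), spacing = image@spacing,
               origin = image@origin, direction = image@direction)
}

# six scale-normalized Hessian components (d^2 I / dx_a dx_b, in 1/mm^2,
# multiplied by sigma^2) via separable Gaussian derivative convolution
hessian_components <- function(values, spacing, sigma_mm) {
  d <- dim(values)
  x <- as.numeric(values)
  deriv <- function(orders) {
    out <- x
    for (axis in 0:2) {
      sig_vox <- sigma_mm / spacing[axis + 1]
      k <- gaussian_kernel(sig_vox, order = orders[axis + 1])
      out <- cpp_conv_axis(out, as.integer(d), k, axis)
      if (orders[axis + 1] > 0)           # voxel-unit derivative -> per mm
        out <- out / spacing[axis + 1]^orders[axis + 1]
    }
    out * sigma_mm^2
  }
  list(xx = deriv(c(2, 0, 0)), yy = deriv(c(0, 2, 0)), zz = deriv(c(0, 0, 2)),
       xy = deriv(c(1, 1, 0)), xz = deriv(c(1, 0, 1)), yz = deriv(c(0, 1, 1)))
}
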