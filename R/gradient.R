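# Structure-tensor orientation of grayscale micrographs: the robust form of
# per-pixel gradient-based fibre orientation used on fluorescence images.
# Gradients are derivative-of-Gaussian filtered; the tensor components are
# window-smoothed; the local fibre axis is the eigenvector of least
# intensity variation (perpendicular to the dominant gradient) and the
# eigenvalue contrast (l1 - l2)/(l1 + l2) gives a [0, 1] coherence weight.

gaussian_kernel_1d <- function(sigma, deriv = FALSE) {
  r <- max(1L, ceiling(3 * sigma))
  u <- (-r):r
  g <- exp(-u^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (deriv) -u / sigma^2 * g else g
}

filter_sep <- function(img, ky, kx) {
  EBImage::filter2(img, outer(ky, kx), boundary = "replicate")
}

#' Structure-tensor orientation field of a grayscale image
#'
#' @param image 2D numeric matrix (grayscale intensities).
#' @param sigma_gradient Gaussian derivative scale in pixels (default 1).
#' @param sigma_window Tensor smoothing window scale in pixels (default 2).
#' @return An `orientation_field`: `theta_deg` (axial, `[-90, 90)`; NaN where
#'   invalid), `coherence` in `[0, 1]`, `valid` mask. Pixels with no local
#'   gradient energy and a border of width `3 * (sigma_gradient +
#'   sigma_window)` (filter support) are invalid.
#' @examples
#' x <- outer(rep(1, 32), sin(2 * pi * (1:32) / 8))  # vertical stripes
#' f <- structure_tensor_orientation(x)
#' median(f$theta_deg[f$valid])  # 90: structure runs along y
#' @export
structure_tensor_orientation <- function(image, sigma_gradient = 1,
                                         sigma_window = 2) {
  if (!is.matrix(image)) stop("'image' must be a 2D matrix")
  stopifnot(sigma_gradient > 0, sigma_window > 0)
  g_g <- gaussian_kernel_1d(sigma_gradient)
  g_d <- gaussian_kernel_1d(sigma_gradient, deriv = TRUE)
  ix <- filter_sep(image, g_g, g_d)   # d/dx: derivative along columns
  iy <- filter_sep(image, g_d, g_g)   # d/dy: derivative along rows
  g_w <- gaussian_kernel_1d(sigma_window)
  j11 <- filter_sep(ix * ix, g_w, g_w)
  j22 <- filter_sep(iy * iy, g_w, g_w)
  j12 <- filter_sep(ix * iy, g_w, g_w)
  trace <- j11 + j22
  # dominant gradient axis, then +90 degrees for the structure axis
  psi <- 0.5 * atan2(2 * j12, j11 - j22)
  theta <- canonical_axial(rad2deg(psi) + 90)
  coherence <- matrix(0, nrow(image), ncol(image))
  # gradient-energy floor relative to the image scale, so FFT round-off on
  # flat images does not register as structure
  floor_energy <- 1e-12 * max(mean(image^2), .Machine$double.xmin)
  pos <- trace > floor_energy
  coherence[pos] <- sqrt((j11 - j22)[pos]^2 + 4 * j12[pos]^2) / trace[pos]
  coherence <- pmin(pmax(coherence, 0), 1)
  valid <- pos
  border <- ceiling(3 * (sigma_gradient + sigma_window))
  h <- nrow(image); w <- ncol(image)
  if (2 * border >= min(h, w)) {
    valid[] <- FALSE
  } else {
    valid[c(seq_len(border), h - seq_len(border) + 1), ] <- FALSE
    valid[, c(seq_len(border), w - seq_len(border) + 1)] <- FALSE
  }
  theta[!valid] <- NaN
  structure(list(theta_deg = theta, coherence = coherence, valid = valid),
            class = "orientation_field")
}

#' Pool an orientation field into an orientation sample
#'
#' Valid pixels with coherence at or above `coherence_min`, weighted by
#' coherence, ready for the axial circular statistics.
#'
#' @param field An `orientation_field` (e.g. from
#'   [structure_tensor_orientation()]).
#' @param coherence_min Coherence cutoff in `[0, 1]` (default 0).
#' @return An [orientation_sample()]; if no pixel qualifies, an empty sample
#'   with `n = 0` (for which [axial_resultant()] returns NaN rather than
#'   failing).
#' @export
field_to_sample <- function(field, coherence_min = 0) {
  stopifnot(inherits(field, "orientation_field"),
            coherence_min >= 0, coherence_min <= 1)
  sel <- field$valid & field$coherence >= coherence_min &
    is.finite(field$theta_deg)
  if (!any(sel))
    return(structure(list(angles_deg = numeric(0), weights = numeric(0),
                          n = 0L),
                     class = "orientation_sample"))
  w <- field$coherence[sel]
  if (sum(w) <= 0) w <- rep(1, sum(sel))
  orientation_sample(field$theta_deg[sel], w)
}
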