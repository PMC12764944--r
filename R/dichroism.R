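# Stokes-parameter mapping of linear dichroism from four-angle amplitude
# stacks:
#   I = p0 + p90,  Q = p0 - p90,  U = p45 - p135
#   DoLD = sqrt(Q^2 + U^2) / I
#   AoLD = (1/2) atan2(U, Q)   (degrees, axial range [-90, 90))
# Under the isotropic-plus-Malus forward model p_theta = a + b cos^2(theta -
# phi) these invert exactly: I = 2a + b, Q = b cos 2phi, U = b sin 2phi, so
# DoLD = b/(2a + b) and AoLD = phi. atan2 (not a plain arctangent) is used so
# that phi and phi + 90 are distinguished and Q = 0 is well-defined.

FLAG_OK <- 0L
FLAG_LOW_SIGNAL <- 1L
FLAG_UNDEFINED_ANGLE <- 2L
FLAG_MODEL_INCONSISTENT <- 3L

canonical_angle_set <- c(0, 45, 90, 135)

#' Stokes parameter maps from a four-angle stack
#'
#' @param stack A [pol_stack()] holding exactly the canonical polarization
#'   states 0/45/90/135 degrees (after axial reduction). Other angle sets are
#'   rejected; use [dense_fit_oracle()] for those.
#' @return A `stokes_maps` list with matrices `I`, `Q`, `U`.
#' @export
stokes_maps <- function(stack) {
  stopifnot(inherits(stack, "pol_stack"))
  ang <- stack$meta$angles_deg
  if (length(ang) != 4 || !setequal(ang, canonical_angle_set))
    stop("Stokes mapping requires exactly the polarization states 0/45/90/135 degrees")
  p <- function(theta) stack$images[[match(theta, ang)]]
  structure(list(I = p(0) + p(90), Q = p(0) - p(90), U = p(45) - p(135)),
            class = "stokes_maps")
}

#' Automatic low-signal threshold
#'
#' Five times the robust (median-absolute-deviation based) spread of the
#' intensity map, a conservative floor separating tissue from background in
#' background-dominated fields of view.
#'
#' @param I Intensity (Stokes I) matrix.
#' @return Scalar threshold.
#' @export
auto_min_signal <- function(I) 5 * mad(I, na.rm = TRUE)

#' Degree of linear dichroism map
#'
#' `sqrt(Q^2 + U^2) / I` wherever `I >= min_signal`. Values above 1 violate
#' the two-parameter dichroism model (noise or model breakdown); they are
#' flagged, not clamped.
#'
#' @param s A `stokes_maps` from [stokes_maps()].
#' @param min_signal Low-signal threshold on `I`; `"auto"` (default) uses
#'   [auto_min_signal()].
#' @return List with `dold` (NaN where low-signal) and integer `flags`.
#' @export
dold_map <- function(s, min_signal = "auto") {
  stopifnot(inherits(s, "stokes_maps"))
  min_signal <- resolve_min_signal(min_signal, s$I)
  dold <- sqrt(s$Q^2 + s$U^2) / s$I
  flags <- matrix(FLAG_OK, nrow(s$I), ncol(s$I))
  flags[!is.na(dold) & dold > 1] <- FLAG_MODEL_INCONSISTENT
  low <- s$I < min_signal
  dold[low] <- NaN
  flags[low] <- FLAG_LOW_SIGNAL
  list(dold = dold, flags = flags, min_signal = min_signal)
}

#' Orientation angle of linear dichroism map
#'
#' `(1/2) atan2(U, Q)` in degrees, wrapped to `[-90, 90)`. Pixels with
#' `Q = U = 0` have no defined axis and are flagged `undefined_angle`;
#' low-signal pixels are flagged and set to NaN.
#'
#' @inheritParams dold_map
#' @return List with `aold_deg` and integer `flags`.
#' @export
aold_map <- function(s, min_signal = "auto") {
  stopifnot(inherits(s, "stokes_maps"))
  min_signal <- resolve_min_signal(min_signal, s$I)
  aold <- canonical_axial(rad2deg(atan2(s$U, s$Q) / 2))
  flags <- matrix(FLAG_OK, nrow(s$I), ncol(s$I))
  undef <- s$Q == 0 & s$U == 0
  aold[undef] <- NaN
  flags[undef] <- FLAG_UNDEFINED_ANGLE
  low <- s$I < min_signal
  aold[low] <- NaN
  flags[low] <- FLAG_LOW_SIGNAL
  list(aold_deg = aold, flags = flags, min_signal = min_signal)
}

resolve_min_signal <- function(min_signal, I) {
  if (identical(min_signal, "auto")) return(auto_min_signal(I))
  if (!is.numeric(min_signal) || min_signal < 0)
    stop("'min_signal' must be non-negative or \"auto\"")
  min_signal
}

#' Full dichroism mapping of a four-angle stack
#'
#' Convenience wrapper: Stokes maps, DoLD, AoLD, a combined validity mask and
#' per-pixel flag codes (0 ok, 1 low_signal, 2 undefined_angle,
#' 3 model_inconsistent; low signal takes precedence).
#'
#' @param stack A [pol_stack()] with the canonical four states. Apply
#'   [fluence_normalize()] first if per-state fluence drift is present.
#' @inheritParams dold_map
#' @return A `dichroism_result`: `dold`, `aold_deg`, `valid_mask`, `flags`,
#'   `stokes`, `min_signal`.
#' @examples
#' ph <- make_stack(phantom_spec(16, 16, orientation_field = 30,
#'                               iso_map = 1, dichroic_map = 1))
#' res <- dichroism_map(ph$stack, min_signal = 0)
#' res$dold[1, 1]      # b / (2a + b) = 1/3
#' res$aold_deg[1, 1]  # 30
#' @export
dichroism_map <- function(stack, min_signal = "auto") {
  s <- stokes_maps(stack)
  min_signal <- resolve_min_signal(min_signal, s$I)
  d <- dold_map(s, min_signal)
  a <- aold_map(s, min_signal)
  flags <- pmax(d$flags, a$flags)
  flags[d$flags == FLAG_LOW_SIGNAL | a$flags == FLAG_LOW_SIGNAL] <- FLAG_LOW_SIGNAL
  valid <- flags == FLAG_OK | flags == FLAG_MODEL_INCONSISTENT
  structure(
    list(dold = d$dold, aold_deg = a$aold_deg, valid_mask = valid,
         flags = flags, stokes = s, min_signal = min_signal),
    class = "dichroism_result")
}

#' @export
print.dichroism_result <- function(x, ...) {
  cat(sprintf("<dichroism_result> %d x %d px, %.1f%% valid, min_signal = %.4g\n",
              nrow(x$dold), ncol(x$dold), 100 * mean(x$valid_mask),
              x$min_signal))
  invisible(x)
}

#' Dense-angle least-squares dichroism estimator
#'
#' Independent of the four-angle Stokes formulas: fits
#' `p_theta = c0 + c1 cos 2 theta + c2 sin 2 theta` per pixel by least
#' squares over any K >= 3 angles spanning at least 90 degrees, and converts
#' to the model parameters `b = 2 sqrt(c1^2 + c2^2)`, `a = c0 - b/2`,
#' `phi = (1/2) atan2(c2, c1)`. On noiseless canonical four-angle input this
#' reproduces the Stokes-based DoLD and AoLD exactly, which makes it the
#' verification oracle for [dichroism_map()].
#'
#' @param images List of per-angle amplitude matrices, or a [pol_stack()].
#' @param angles_deg Angles of the images (ignored for a `pol_stack`).
#' @return List of matrices `a_hat`, `b_hat`, `phi_hat_deg` (NaN where
#'   `b_hat` is numerically zero), `dold_hat = b_hat / (2 a_hat + b_hat)`.
#' @export
dense_fit_oracle <- function(images, angles_deg = NULL) {
  if (inherits(images, "pol_stack")) {
    angles_deg <- images$meta$angles_deg
    images <- images$images
  }
  stopifnot(is.list(images), length(images) == length(angles_deg))
  k <- length(angles_deg)
  if (k < 3) stop("need at least 3 angles for the least-squares fit")
  th2 <- 2 * deg2rad(angles_deg)
  X <- cbind(1, cos(th2), sin(th2))
  xtx <- crossprod(X)
  if (rcond(xtx) < 1e-10)
    stop("angles are collinear modulo 180 degrees (rank-deficient design)")
  d <- dim(images[[1]])
  P <- vapply(images, as.numeric, numeric(prod(d)))   # npix x K
  C <- P %*% X %*% solve(xtx)                          # npix x 3
  b_hat <- 2 * sqrt(C[, 2]^2 + C[, 3]^2)
  a_hat <- C[, 1] - b_hat / 2
  phi <- canonical_axial(rad2deg(atan2(C[, 3], C[, 2]) / 2))
  scale_ref <- pmax(abs(C[, 1]), .Machine$double.eps)
  phi[b_hat / scale_ref < 1e-12] <- NaN
  denom <- 2 * a_hat + b_hat
  dold_hat <- ifelse(denom != 0, b_hat / denom, NaN)
  list(a_hat = matrix(a_hat, d[1], d[2]),
       b_hat = matrix(b_hat, d[1], d[2]),
       phi_hat_deg = matrix(phi, d[1], d[2]),
       dold_hat = matrix(dold_hat, d[1], d[2]))
}
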