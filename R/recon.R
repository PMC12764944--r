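# From A-line time series to per-state maximum-amplitude-projection (MAP)
# images. The envelope is the magnitude of the analytic signal, a
# phase-invariant amplitude estimate; the MAP is its per-pixel maximum over
# time, so it is invariant to time shifts and sign flips.

#' Analytic-signal envelope of time series
#'
#' Computes the magnitude of the analytic signal (FFT half-spectrum
#' doubling). Columns of a matrix are treated as independent signals.
#'
#' @param x Numeric vector, or matrix with one signal per column; at least 8
#'   samples, no NA.
#' @return Non-negative envelope, same shape as `x`.
#' @export
envelope <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (n < 8) stop("envelope needs at least 8 samples")
  if (anyNA(x)) stop("envelope input contains NA")
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  env <- Mod(mvfft(mvfft(x) * h, inverse = TRUE)) / n
  if (vec) drop(env) else env
}

#' Maximum-amplitude projection of an A-line volume
#'
#' @param volume An `aline_volume` (fields `signals` = `y x x x t` array,
#'   `sample_rate`, `angle_deg`), e.g. from [make_aline_volume()].
#' @return A `map_image`: list with `amplitude` (per-pixel envelope maximum,
#'   `>= 0`) and `angle_deg`.
#' @export
map_project <- function(volume) {
  stopifnot(inherits(volume, "aline_volume"))
  d <- dim(volume$signals)
  if (length(d) != 3 || d[3] < 8) stop("A-line volume needs a time axis of >= 8 samples")
  sig <- matrix(aperm(volume$signals, c(3, 1, 2)), nrow = d[3])
  amp <- matrix(apply(envelope(sig), 2, max), d[1], d[2])
  structure(list(amplitude = amp, angle_deg = volume$angle_deg),
            class = "map_image")
}

#' Reconstruct a polarization stack from per-state A-line volumes
#'
#' @param volumes Named list of `aline_volume`s, one per polarization state.
#' @param fluence Per-state fluence for the stack metadata.
#' @param pixel_size_um Pixel pitch for the metadata.
#' @return A [pol_stack()] of MAP images.
#' @export
reconstruct_stack <- function(volumes, fluence = 1, pixel_size_um = 1) {
  maps <- lapply(volumes, map_project)
  pol_stack(lapply(maps, `[[`, "amplitude"),
            angles = vapply(maps, `[[`, 0, "angle_deg"),
            fluence = fluence, pixel_size_um = pixel_size_um,
            provenance = "reconstructed from A-line volumes")
}

#' Fluence-normalize a polarization stack
#'
#' Divides each state's image by that state's laser fluence, pixel by pixel,
#' removing per-state illumination drift. Only fluence ratios matter: the
#' result is invariant to rescaling any state's image and fluence together.
#' Normalized fluence metadata is set to 1.
#'
#' @param stack A [pol_stack()].
#' @param fluence Optional override of the per-state fluence values stored in
#'   the stack metadata.
#' @return A [pol_stack()] with drift removed.
#' @export
fluence_normalize <- function(stack, fluence = NULL) {
  stopifnot(inherits(stack, "pol_stack"))
  if (is.null(fluence)) fluence <- stack$meta$fluence
  fluence <- rep_len(as.numeric(fluence), length(stack$images))
  if (any(!is.finite(fluence)) || any(fluence <= 0))
    stop("fluence must be positive and finite for every state")
  images <- Map(function(img, g) img / g, stack$images, fluence)
  pol_stack(images, stack$meta$angles_deg, fluence = 1,
            pixel_size_um = stack$meta$pixel_size_um,
            provenance = stack$meta$provenance)
}

#' Average MAP image across polarization states
#'
#' The per-pixel arithmetic mean over all states; with the four canonical
#' angles under the Malus model this equals `a + b/2`, i.e. `I/2` of the
#' Stokes maps.
#'
#' @param stack A [pol_stack()] with at least one state.
#' @return Numeric matrix.
#' @export
average_map <- function(stack) {
  stopifnot(inherits(stack, "pol_stack"), length(stack$images) >= 1)
  Reduce(`+`, stack$images) / length(stack$images)
}
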