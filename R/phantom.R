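# Synthetic fibrous phantoms: polarization-resolved amplitude stacks with a
# known orientation field, A-line volumes, and voltage-dye wave movies.
#
# Forward model for the amplitude at incident polarization theta:
#   p_theta(x, y) = g_theta * [ a(x, y) + b(x, y) * cos^2(theta - phi(x, y)) ] + eps
# with a the isotropic and b the dichroic absorption amplitude, phi the local
# fibre axis, g_theta a per-state fluence drift, and eps additive Gaussian
# noise clipped at zero (amplitudes are envelope maxima, hence non-negative).

#' Specify a dichroic fibrous phantom
#'
#' Bundles the per-pixel maps and acquisition parameters that define a
#' synthetic polarization-resolved stack. Scalar `orientation_field`,
#' `iso_map` and `dichroic_map` are recycled to full `height x width`
#' matrices.
#'
#' @param width,height Image size in pixels.
#' @param orientation_field Per-pixel fibre axis phi in degrees (axial,
#'   period 180); scalar or `height x width` matrix. Stored reduced to
#'   `[-90, 90)`.
#' @param iso_map Isotropic absorption amplitude `a >= 0` (arbitrary units);
#'   scalar or matrix.
#' @param dichroic_map Dichroic absorption amplitude `b >= 0`; scalar or
#'   matrix.
#' @param noise_sigma Standard deviation of additive amplitude noise (same
#'   units as `a`, `b`); non-negative.
#' @param fluence_factors Per-state multiplicative fluence drift `g > 0`,
#'   recycled to one value per polarization angle.
#' @param seed Integer RNG seed; generation is bit-reproducible for a fixed
#'   seed.
#' @param angles Incident polarization angles in degrees.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(width, height,
                         orientation_field = 0,
                         iso_map = 1,
                         dichroic_map = 1,
                         noise_sigma = 0,
                         fluence_factors = 1,
                         seed = 1L,
                         angles = c(0, 45, 90, 135)) {
  stopifnot(width >= 1, height >= 1)
  as_map <- function(x, what) {
    if (length(x) == 1) x <- matrix(x, height, width)
    if (!is.matrix(x) || !all(dim(x) == c(height, width)))
      stop(sprintf("'%s' must be a scalar or a %d x %d matrix", what, height, width))
    x
  }
  phi <- canonical_axial(as_map(orientation_field, "orientation_field"))
  a <- as_map(iso_map, "iso_map")
  b <- as_map(dichroic_map, "dichroic_map")
  if (any(a < 0) || any(b < 0)) stop("absorption maps must be non-negative")
  if (noise_sigma < 0) stop("'noise_sigma' must be non-negative")
  g <- rep_len(fluence_factors, length(angles))
  if (any(g <= 0)) stop("'fluence_factors' must be positive")
  structure(
    list(width = as.integer(width), height = as.integer(height),
         orientation_field = phi, iso_map = a, dichroic_map = b,
         noise_sigma = noise_sigma, fluence_factors = g,
         seed = as.integer(seed), angles = as.numeric(angles)),
    class = "phantom_spec")
}

# Noise-free Malus amplitudes for one polarization state (no fluence drift).
malus_amplitude <- function(spec, theta_deg) {
  spec$iso_map +
    spec$dichroic_map * cos(deg2rad(theta_deg - spec$orientation_field))^2
}

#' Generate a polarization-resolved amplitude stack with ground truth
#'
#' Evaluates the isotropic-plus-Malus-law forward model at each incident
#' polarization angle, applies per-state fluence drift and additive Gaussian
#' noise (clipped at zero), and emits the ground truth alongside.
#'
#' @param spec A [phantom_spec()].
#' @return A list with components `stack` (a [pol_stack()] whose metadata
#'   carries the fluence factors) and `truth` (a `phantom_truth` list with
#'   `orientation_field`, `dold_true = b / (2 a + b)`, and `foreground_mask`
#'   where `a + b > 0`).
#' @examples
#' ph <- make_stack(phantom_spec(8, 8, orientation_field = 30))
#' sapply(ph$stack$images, mean)
#' @export
make_stack <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  images <- with_local_seed(spec$seed, {
    lapply(seq_along(spec$angles), function(i) {
      p <- spec$fluence_factors[i] * malus_amplitude(spec, spec$angles[i])
      if (spec$noise_sigma > 0)
        p <- p + matrix(rnorm(length(p), 0, spec$noise_sigma), nrow(p), ncol(p))
      pmax(p, 0)
    })
  })
  names(images) <- format_angle(spec$angles)
  stack <- pol_stack(images, angles = spec$angles,
                     fluence = spec$fluence_factors,
                     provenance = "dichropam phantom")
  denom <- 2 * spec$iso_map + spec$dichroic_map
  dold_true <- ifelse(denom > 0, spec$dichroic_map / denom, NaN)
  truth <- structure(
    list(orientation_field = spec$orientation_field,
         dold_true = dold_true,
         foreground_mask = (spec$iso_map + spec$dichroic_map) > 0),
    class = "phantom_truth")
  list(stack = stack, truth = truth)
}

#' Orientation field around anchoring pins
#'
#' Emulates the fibre geometry of an engineered tissue stretched between
#' anchoring pins: circumferential (tangent to circles) near each pin, where
#' the anchor imposes a local mechanical constraint, relaxing to a uniform
#' longitudinal direction between the pins, where axial tension aligns the
#' fibres. Pin influence decays as `exp(-d / blend_length)` with distance `d`
#' and is blended with a fixed-weight longitudinal component in
#' doubled-angle vector space, so a few blend lengths away from any pin the
#' field is longitudinal.
#'
#' @param width,height Canvas size in pixels.
#' @param pin_positions Matrix or list of `(x, y)` pin coordinates
#'   (1-based pixel units); at least one pin inside the canvas.
#' @param blend_length E-folding distance (pixels) of pin influence.
#' @param longitudinal_deg Axis of the longitudinal component, degrees
#'   (default 0: along +x, the usual pin-to-pin axis).
#' @return `height x width` matrix of axial angles in `[-90, 90)`.
#' @export
make_pin_field <- function(width, height, pin_positions, blend_length,
                           longitudinal_deg = 0) {
  if (is.list(pin_positions)) pin_positions <- do.call(rbind, pin_positions)
  pin_positions <- matrix(as.numeric(pin_positions), ncol = 2)
  if (nrow(pin_positions) < 1) stop("at least one pin is required")
  inside <- pin_positions[, 1] >= 1 & pin_positions[, 1] <= width &
    pin_positions[, 2] >= 1 & pin_positions[, 2] <= height
  if (!all(inside)) stop("pins must lie inside the canvas")
  stopifnot(blend_length > 0)
  xs <- matrix(rep(seq_len(width), each = height), height, width)
  ys <- matrix(rep(seq_len(height), times = width), height, width)
  # longitudinal component gets a constant weight; pins dominate only nearby
  z <- 0.2 * exp(2i * deg2rad(longitudinal_deg))
  for (k in seq_len(nrow(pin_positions))) {
    dx <- xs - pin_positions[k, 1]
    dy <- ys - pin_positions[k, 2]
    d <- sqrt(dx^2 + dy^2)
    tangent <- atan2(dy, dx) + pi / 2
    z <- z + exp(-d / blend_length) * exp(2i * tangent)
  }
  canonical_axial(rad2deg(Arg(z) / 2))
}

#' Synthesize A-line volumes for each polarization state
#'
#' Builds the time-domain input of maximum-amplitude-projection
#' reconstruction: each pixel's A-line is a Gaussian-modulated sinusoid whose
#' envelope peak equals that pixel's amplitude `p_theta` (same forward model
#' and noise realisation as [make_stack()]), placed at a per-pixel random
#' depth within `depth_jitter`.
#'
#' @param spec A [phantom_spec()].
#' @param pulse_center_freq Carrier frequency in Hz (default 30 MHz, a
#'   typical photoacoustic detection band).
#' @param pulse_bandwidth Fractional FWHM bandwidth of the pulse (default
#'   0.6).
#' @param samples Number of time samples per A-line.
#' @param sample_rate Sampling rate in Hz; must exceed twice the carrier.
#' @param depth_jitter Peak-to-peak spread of the per-pixel pulse delay, in
#'   seconds.
#' @param jitter_seed Seed for the depth jitter stream (defaults to
#'   `spec$seed + 1000` so amplitude noise and depth are independent).
#' @return Named list of `aline_volume` objects, one per polarization state;
#'   each has `signals` (`height x width x samples` array), `sample_rate`,
#'   and `angle_deg`.
#' @export
make_aline_volume <- function(spec, pulse_center_freq = 30e6,
                              pulse_bandwidth = 0.6,
                              samples = 256, sample_rate = 250e6,
                              depth_jitter = 0, jitter_seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), samples >= 16)
  if (sample_rate <= 2 * pulse_center_freq)
    stop("sampling rate must exceed twice the pulse center frequency")
  if (is.null(jitter_seed)) jitter_seed <- spec$seed + 1000L
  amp_images <- make_stack(spec)$stack$images
  sigma_f <- pulse_bandwidth * pulse_center_freq / (2 * sqrt(2 * log(2)))
  sigma_t <- 1 / (2 * pi * sigma_f)
  t <- (seq_len(samples) - 1) / sample_rate
  t_mid <- t[samples %/% 2]
  delays <- with_local_seed(jitter_seed, {
    lapply(seq_along(spec$angles), function(i)
      matrix(runif(spec$width * spec$height, -depth_jitter / 2, depth_jitter / 2),
             spec$height, spec$width))
  })
  vols <- lapply(seq_along(spec$angles), function(i) {
    amp <- amp_images[[i]]
    t0 <- t_mid + delays[[i]]
    sig <- array(0, c(spec$height, spec$width, samples))
    for (j in seq_len(samples)) {
      dt <- t[j] - t0
      sig[, , j] <- amp * exp(-dt^2 / (2 * sigma_t^2)) * cos(2 * pi * pulse_center_freq * dt)
    }
    structure(list(signals = sig, sample_rate = sample_rate,
                   angle_deg = spec$angles[i]),
              class = "aline_volume")
  })
  names(vols) <- format_angle(spec$angles)
  vols
}

#' Synthesize a planar activation-wave movie
#'
#' Emulates a voltage-dye recording of one action-potential transit: a
#' fluorescence upstroke travels along +x at constant speed, so the column at
#' `x` activates (crosses half its upstroke) at `t = x / speed`. Pixels in
#' `block_mask` activate with an added delay and/or reduced amplitude,
#' standing in for fibrotic tissue.
#'
#' @param width,height Frame size in pixels.
#' @param speed_px_per_s Wavefront speed in pixels per second.
#' @param fps Frames per second (default 100).
#' @param n_frames Number of frames; must cover the full transit.
#' @param upstroke_ms 10--90 percent rise time of the logistic upstroke, ms.
#' @param amplitude Upstroke amplitude (fluorescence units above baseline).
#' @param baseline Resting fluorescence intensity `F0 > 0`.
#' @param block_mask Optional logical `height x width` matrix of blocked
#'   (fibrotic) pixels.
#' @param block_delay_ms Extra activation delay inside the mask, ms.
#' @param block_amp_factor Amplitude multiplier inside the mask.
#' @param t0_ms Quiescent lead time before the wave enters the frame, ms
#'   (default 0); gives every pixel a resting baseline segment, as a
#'   triggered recording would.
#' @return List with `movie` (a `voltage_movie`: `frames` array
#'   `height x width x n_frames`, `fps`, `roi_mask = NULL`) and
#'   `t_act_true` (`height x width` matrix of true activation times, ms).
#' @export
make_wave_movie <- function(width, height, speed_px_per_s, fps = 100,
                            n_frames = 100, upstroke_ms = 20,
                            amplitude = 1, baseline = 1,
                            block_mask = NULL, block_delay_ms = 0,
                            block_amp_factor = 1, t0_ms = 0) {
  stopifnot(speed_px_per_s > 0, fps > 0, amplitude >= 0, baseline > 0,
            n_frames >= 2, t0_ms >= 0)
  transit_s <- width / speed_px_per_s + (block_delay_ms + t0_ms) / 1000 +
    2 * upstroke_ms / 1000
  if (n_frames / fps < transit_s)
    stop("n_frames too small to contain the wave transit")
  if (is.null(block_mask)) block_mask <- matrix(FALSE, height, width)
  stopifnot(all(dim(block_mask) == c(height, width)))
  xs <- matrix(rep(seq_len(width), each = height), height, width)
  t_act <- t0_ms + xs / speed_px_per_s * 1000  # ms
  t_act[block_mask] <- t_act[block_mask] + block_delay_ms
  amp <- matrix(amplitude, height, width)
  amp[block_mask] <- amp[block_mask] * block_amp_factor
  tau <- upstroke_ms / (2 * log(9))            # logistic 10-90% rise time
  frames <- array(0, c(height, width, n_frames))
  tt <- (seq_len(n_frames) - 1) / fps * 1000   # ms
  for (j in seq_len(n_frames))
    frames[, , j] <- baseline + amp / (1 + exp(-(tt[j] - t_act) / tau))
  movie <- structure(list(frames = frames, fps = fps, roi_mask = NULL),
                     class = "voltage_movie")
  t_act_true <- t_act
  t_act_true[amp == 0] <- NaN
  list(movie = movie, t_act_true = t_act_true)
}

# Evaluate expr with a temporarily-seeded RNG, restoring the caller's state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

format_angle <- function(theta) paste0("p", gsub("-", "m", format(theta, trim = TRUE)))
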