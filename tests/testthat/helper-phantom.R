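# Shared fixture builders: everything is generated in code at test time.

# Noiseless Malus amplitude images at arbitrary angles (closed form, used as
# the independent route around make_stack).
malus_images <- function(angles_deg, a, b, phi_deg) {
  lapply(angles_deg, function(th)
    a + b * cos((th - phi_deg) * pi / 180)^2)
}

# Uniform-orientation noiseless canonical stack with scalar maps.
scalar_stack <- function(a = 1, b = 1, phi = 30, n = 4, noise = 0, g = 1,
                         seed = 1) {
  make_stack(phantom_spec(n, n, orientation_field = phi, iso_map = a,
                          dichroic_map = b, noise_sigma = noise,
                          fluence_factors = g, seed = seed))
}

# Sinusoidal grating whose *structure* (stripe axis) lies along theta_deg.
grating_image <- function(n, theta_deg, wavelength = 8) {
  wave_dir <- (theta_deg + 90) * pi / 180   # wave vector perpendicular to stripes
  xs <- matrix(rep(seq_len(n), each = n), n, n)
  ys <- matrix(rep(seq_len(n), times = n), n, n)
  sin(2 * pi * (xs * cos(wave_dir) + ys * sin(wave_dir)) / wavelength)
}

# Proper 90-degree (clockwise) rotation of a matrix: axes map theta -> theta + 90.
rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

expect_axial_equal <- function(actual, expected, tol = 1e-9) {
  expect_lt(max(abs(dichropam::axial_diff(actual, expected))), tol)
}
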