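test_that("Stokes maps follow the four-angle definitions", {
  stk <- pol_stack(list(matrix(3, 2, 2), matrix(2, 2, 2), matrix(1, 2, 2),
                        matrix(2, 2, 2)), angles = c(0, 45, 90, 135))
  s <- stokes_maps(stk)
  expect_equal(s$I[1, 1], 4)
  expect_equal(s$Q[1, 1], 2)
  expect_equal(s$U[1, 1], 0)
  # all states equal c -> I = 2c, Q = U = 0
  stk2 <- pol_stack(rep(list(matrix(5, 2, 2)), 4), angles = c(0, 45, 90, 135))
  s2 <- stokes_maps(stk2)
  expect_equal(s2$I[1, 1], 10); expect_equal(s2$Q[1, 1], 0)
  expect_equal(s2$U[1, 1], 0)
})

test_that("Stokes mapping rejects non-canonical angle sets", {
  stk3 <- pol_stack(rep(list(matrix(1, 2, 2)), 3), angles = c(0, 60, 120))
  expect_error(stokes_maps(stk3), "0/45/90/135")
})

test_that("DoLD follows Eq. definition and flags model violations", {
  stk <- pol_stack(list(matrix(3, 2, 2), matrix(2, 2, 2), matrix(1, 2, 2),
                        matrix(2, 2, 2)), angles = c(0, 45, 90, 135))
  d <- dold_map(stokes_maps(stk), min_signal = 0)
  expect_equal(d$dold[1, 1], 0.5)
  # p0=1, p90=0, p45=1, p135=0 -> DoLD = sqrt(2), model-inconsistent
  stk2 <- pol_stack(list(matrix(1, 2, 2), matrix(1, 2, 2), matrix(0, 2, 2),
                         matrix(0, 2, 2)), angles = c(0, 45, 90, 135))
  d2 <- dold_map(stokes_maps(stk2), min_signal = 0)
  expect_equal(d2$dold[1, 1], sqrt(2))
  expect_true(all(d2$flags == 3L))
  res <- dichroism_map(stk2, min_signal = 0)
  expect_true(all(res$valid_mask))  # flagged, not masked
})

test_that("AoLD uses quadrant-aware halving and wraps to [-90, 90)", {
  mk <- function(p0, p45, p90, p135)
    stokes_maps(pol_stack(list(matrix(p0, 1, 1), matrix(p45, 1, 1),
                               matrix(p90, 1, 1), matrix(p135, 1, 1)),
                          angles = c(0, 45, 90, 135)))
  expect_equal(aold_map(mk(3, 2, 1, 2), 0)$aold_deg[1, 1], 0)      # Q>0, U=0
  expect_equal(aold_map(mk(1, 2, 3, 2), 0)$aold_deg[1, 1], -90)    # Q<0 -> 90 wraps
  expect_equal(aold_map(mk(2, 3, 2, 1), 0)$aold_deg[1, 1], 45)     # U>0
  a <- aold_map(mk(2, 2, 2, 2), 0)
  expect_true(is.nan(a$aold_deg[1, 1]))                            # Q=U=0
  expect_equal(a$flags[1, 1], 2L)
})

test_that("noiseless inversion is exact over an (a, b, phi) grid", {
  for (a in c(0.5, 2)) for (b in c(0, 0.75, 2)) for (phi in c(-88, -30, 0, 44, 89)) {
    ph <- scalar_stack(a = a, b = b, phi = phi, n = 2)
    res <- dichroism_map(ph$stack, min_signal = 0)
    expect_lt(abs(res$dold[1, 1] - b / (2 * a + b)), 1e-9)
    if (b > 0) expect_axial_equal(res$aold_deg[1, 1], phi, tol = 1e-9)
  }
})

test_that("DoLD and AoLD are invariant to a global amplitude scale", {
  ph <- scalar_stack(a = 1.3, b = 0.9, phi = -52, n = 3)
  r1 <- dichroism_map(ph$stack, min_signal = 0)
  scaled <- ph$stack
  scaled$images <- lapply(scaled$images, function(m) 7.3 * m)
  r2 <- dichroism_map(scaled, min_signal = 0)
  expect_equal(r2$dold, r1$dold, tolerance = 1e-12)
  expect_equal(r2$aold_deg, r1$aold_deg, tolerance = 1e-12)
})

test_that("AoLD is equivariant under rotation of the orientation field", {
  set.seed(3)
  f <- matrix(runif(64, -90, 90), 8, 8)
  for (delta in c(10, 37.5, 90, 155)) {
    r1 <- dichroism_map(make_stack(phantom_spec(8, 8, orientation_field = f,
                                                dichroic_map = 0.7))$stack,
                        min_signal = 0)
    r2 <- dichroism_map(make_stack(phantom_spec(8, 8,
                                                orientation_field = f + delta,
                                                dichroic_map = 0.7))$stack,
                        min_signal = 0)
    expect_axial_equal(r2$aold_deg, r1$aold_deg + delta, tol = 1e-9)
  }
})

test_that("relabelling states by 90 degrees negates Q and U", {
  ph <- scalar_stack(a = 1, b = 0.8, phi = 25, n = 3)
  img <- ph$stack$images
  swapped <- pol_stack(list(img[["p90"]], img[["p135"]], img[["p0"]],
                            img[["p45"]]), angles = c(0, 45, 90, 135))
  s1 <- stokes_maps(ph$stack); s2 <- stokes_maps(swapped)
  expect_equal(s2$Q, -s1$Q, tolerance = 1e-12)
  expect_equal(s2$U, -s1$U, tolerance = 1e-12)
  r1 <- dichroism_map(ph$stack, 0); r2 <- dichroism_map(swapped, 0)
  expect_equal(r2$dold, r1$dold, tolerance = 1e-12)
  expect_axial_equal(r2$aold_deg, r1$aold_deg + 90, tol = 1e-9)
})

test_that("low-signal pixels are masked by the MAD-based auto threshold", {
  iso <- matrix(0.001, 16, 16); iso[6:11, 6:11] <- 5
  dic <- matrix(0, 16, 16); dic[6:11, 6:11] <- 2
  ph <- make_stack(phantom_spec(16, 16, orientation_field = 15, iso_map = iso,
                                dichroic_map = dic, noise_sigma = 0.01,
                                seed = 5))
  res <- dichroism_map(ph$stack)
  expect_true(all(res$valid_mask[6:11, 6:11]))
  expect_true(all(!res$valid_mask[1:4, 1:4]))
  expect_true(all(is.nan(res$aold_deg[1:4, 1:4])))
})

test_that("dense least-squares oracle recovers (a, b, phi) and matches Eqs on
           canonical stacks", {
  angles <- seq(0, 180, by = 5)
  imgs <- lapply(malus_images(angles, a = 2, b = 1, phi = -40),
                 function(v) matrix(v, 3, 3))
  o <- dense_fit_oracle(imgs, angles)
  expect_lt(max(abs(o$a_hat - 2)), 1e-9)
  expect_lt(max(abs(o$b_hat - 1)), 1e-9)
  expect_axial_equal(o$phi_hat_deg, -40, tol = 1e-9)
  # four canonical angles: oracle == Stokes inversion, exactly
  set.seed(7)
  f <- matrix(runif(36, -90, 90), 6, 6)
  ph <- make_stack(phantom_spec(6, 6, orientation_field = f,
                                iso_map = matrix(runif(36, 0.5, 3), 6, 6),
                                dichroic_map = matrix(runif(36, 0.1, 2), 6, 6)))
  res <- dichroism_map(ph$stack, min_signal = 0)
  o2 <- dense_fit_oracle(ph$stack)
  expect_lt(max(abs(o2$dold_hat - res$dold)), 1e-9)
  expect_axial_equal(o2$phi_hat_deg, res$aold_deg, tol = 1e-9)
  # b = 0: no dichroism, angle undefined
  o3 <- dense_fit_oracle(lapply(malus_images(angles, 1, 0, 0),
                                function(v) matrix(v, 2, 2)), angles)
  expect_lt(max(o3$b_hat), 1e-12)
  expect_true(all(is.nan(o3$phi_hat_deg)))
  expect_error(dense_fit_oracle(rep(list(matrix(1, 2, 2)), 3), c(0, 90, 180)),
               "collinear")
})

test_that("AoLD error shrinks as SNR grows under additive noise", {
  rmse <- vapply(c(0.4, 0.1, 0.02), function(sg) {
    ph <- make_stack(phantom_spec(100, 100, orientation_field = 35,
                                  iso_map = 1, dichroic_map = 1,
                                  noise_sigma = sg, seed = 99))
    res <- dichroism_map(ph$stack, min_signal = 0)
    sqrt(mean(axial_diff(res$aold_deg, 35)^2, na.rm = TRUE))
  }, 0)
  expect_true(all(diff(rmse) <= 0))
  expect_lt(rmse[3], 2)   # near-noiseless case is tight
})
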