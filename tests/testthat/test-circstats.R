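test_that("axial resultant handles aligned, antipodal and empty samples", {
  r <- axial_resultant(orientation_sample(rep(40, 5)))
  expect_equal(r$resultant_length, 1)
  expect_equal(r$mean_angle_deg, 40)
  # 0 and 90 are antipodal after doubling: no mean axis
  r0 <- axial_resultant(orientation_sample(c(0, 90)))
  expect_lt(r0$resultant_length, 1e-12)
  expect_true(is.nan(r0$mean_angle_deg))
  # weighted: weight 0 observations do not count
  rw <- axial_resultant(orientation_sample(c(10, 80), weights = c(1, 0)))
  expect_equal(rw$mean_angle_deg, 10)
  expect_error(orientation_sample(numeric(0)), "empty")
  expect_error(orientation_sample(c(1, NaN)), "finite")
  expect_error(orientation_sample(c(1, 2), weights = c(0, 0)), "zero")
})

test_that("branch choice of axial angles does not affect the statistics", {
  set.seed(21)
  th <- runif(200, -90, 90)
  branch <- th + 180 * sample(0:1, 200, replace = TRUE)
  r1 <- axial_resultant(orientation_sample(th))
  r2 <- axial_resultant(orientation_sample(branch))
  expect_equal(r1$resultant_length, r2$resultant_length, tolerance = 1e-12)
  expect_axial_equal(r1$mean_angle_deg, r2$mean_angle_deg, tol = 1e-9)
})

test_that("R is rotation invariant and the mean axis is equivariant", {
  set.seed(22)
  th <- raxial_vonmises(500, 10, 3)
  r1 <- axial_resultant(orientation_sample(th))
  for (delta in c(25, 90, 140)) {
    r2 <- axial_resultant(orientation_sample(th + delta))
    expect_equal(r2$resultant_length, r1$resultant_length, tolerance = 1e-12)
    expect_axial_equal(r2$mean_angle_deg, r1$mean_angle_deg + delta, tol = 1e-9)
  }
})

test_that("uniform axial samples have near-zero R, von Mises matches the
           Bessel ratio, and R grows with concentration", {
  set.seed(23)
  expect_lt(axial_resultant(orientation_sample(
    raxial_vonmises(1e4, 0, 0)))$resultant_length, 0.02)
  s <- orientation_sample(raxial_vonmises(1e5, 20, 2))
  expect_lt(abs(axial_resultant(s)$resultant_length -
                  besselI(2, 1) / besselI(2, 0)), 0.01)
  rs <- vapply(c(0.5, 1, 2, 4, 8), function(k)
    axial_resultant(orientation_sample(
      raxial_vonmises(1e4, -30, k)))$resultant_length, 0)
  expect_true(all(diff(rs) > 0))
})

test_that("bootstrap CI is deterministic, degenerate at zero dispersion, and
           contains the point estimate", {
  set.seed(24)
  samp <- orientation_sample(raxial_vonmises(150, -20, 4))
  ci1 <- mean_angle_ci95(samp, "bootstrap", seed = 5)
  ci2 <- mean_angle_ci95(samp, "bootstrap", seed = 5)
  expect_identical(ci1, ci2)
  est <- axial_resultant(samp)$mean_angle_deg
  expect_lte(ci1[["low"]], est); expect_gte(ci1[["high"]], est)
  cif <- mean_angle_ci95(samp, "fisher")
  expect_lt(cif[["low"]], est); expect_gt(cif[["high"]], est)
  cid <- mean_angle_ci95(orientation_sample(rep(33, 20)), "bootstrap")
  expect_equal(unname(cid), c(33, 33))
  expect_error(mean_angle_ci95(orientation_sample(c(0, 90))), "undefined|zero")
})

test_that("CI width shrinks with sample size at fixed dispersion", {
  set.seed(25)
  widths <- vapply(c(50, 500, 5000), function(n)
    diff(mean_angle_ci95(orientation_sample(raxial_vonmises(n, 0, 4)),
                         "fisher")), 0)
  expect_true(all(diff(widths) < 0))
})

test_that("polar histogram partitions [-90, 90) and conserves mass", {
  grid <- seq(-90, 89, by = 1)
  h <- polar_histogram(orientation_sample(grid), n_bins = 18)
  expect_equal(nrow(h), 18)
  expect_true(all(h$count == 10))
  set.seed(26)
  th <- runif(321, -90, 90); w <- runif(321)
  h2 <- polar_histogram(orientation_sample(th, w), n_bins = 7)
  expect_equal(sum(h2$count), sum(w), tolerance = 1e-12)
  perm <- sample(321)
  h3 <- polar_histogram(orientation_sample(th[perm], w[perm]), n_bins = 7)
  expect_equal(h2$count, h3$count, tolerance = 1e-12)
  expect_error(polar_histogram(orientation_sample(1), n_bins = 1), "at least 2")
})

test_that("ROI summaries report DoLD/AoLD statistics and handle empty ROIs", {
  f <- matrix(15, 12, 12)
  ph <- make_stack(phantom_spec(12, 12, orientation_field = f, iso_map = 1,
                                dichroic_map = 1))
  res <- dichroism_map(ph$stack, min_signal = 0)
  rois <- list(left = cbind(matrix(TRUE, 12, 6), matrix(FALSE, 12, 6)),
               nothing = matrix(FALSE, 12, 12))
  tab <- roi_summary(res, rois)
  expect_equal(tab$region, c("left", "nothing"))
  expect_equal(tab$n_pixels, c(72L, 0L))
  expect_equal(tab$mean_dold[1], 1 / 3, tolerance = 1e-9)
  expect_equal(tab$sd_dold[1], 0)
  expect_equal(tab$mean_aold_deg[1], 15, tolerance = 1e-9)
  expect_equal(tab$resultant_length[1], 1, tolerance = 1e-12)
  expect_true(is.na(tab$mean_dold[2]))
})

test_that("pooling two disjoint ROIs matches the direct complex-sum union", {
  set.seed(27)
  f <- matrix(raxial_vonmises(400, 10, 1.5), 20, 20)
  ph <- make_stack(phantom_spec(20, 20, orientation_field = f,
                                dichroic_map = 0.9, noise_sigma = 0.03))
  res <- dichroism_map(ph$stack, min_signal = 0)
  top <- rbind(matrix(TRUE, 10, 20), matrix(FALSE, 10, 20))
  rois <- list(top = top, bottom = !top,
               union = matrix(TRUE, 20, 20))
  tab <- roi_summary(res, rois)
  # brute-force pooled complex sum of the two halves
  zsum <- function(mask) {
    sel <- mask & res$valid_mask & is.finite(res$aold_deg)
    sum(exp(2i * res$aold_deg[sel] * pi / 180))
  }
  n1 <- sum(top & res$valid_mask); n2 <- sum(!top & res$valid_mask)
  pooled_R <- Mod(zsum(top) + zsum(!top)) / (n1 + n2)
  expect_equal(tab$resultant_length[tab$region == "union"], pooled_R,
               tolerance = 1e-9)
  expect_gte(pooled_R + 1e-12, 0)
  expect_lte(pooled_R, max(tab$resultant_length[1:2]) + 1e-12)
})

test_that("amplitude and DoLD weight modes change the pooled statistics", {
  iso <- matrix(1, 10, 10); dic <- matrix(0.2, 10, 10)
  dic[, 6:10] <- 1.5   # right half strongly dichroic, different axis
  f <- matrix(0, 10, 10); f[, 6:10] <- 60
  ph <- make_stack(phantom_spec(10, 10, orientation_field = f, iso_map = iso,
                                dichroic_map = dic))
  res <- dichroism_map(ph$stack, min_signal = 0)
  t_none <- roi_summary(res, weight_mode = "none")
  t_dold <- roi_summary(res, weight_mode = "dold")
  # dold-weighting pulls the mean axis toward the dichroic half at 60 deg
  expect_gt(t_dold$mean_aold_deg, t_none$mean_aold_deg)
})
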