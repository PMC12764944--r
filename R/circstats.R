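# Axial circular statistics. Fibre orientations have period 180 degrees, so
# every statistic is computed on doubled angles (2 theta, period 360) and
# mapped back: the mean axis is arg(m)/2 and the resultant vector length
# R = |m| of m = sum(w exp(i 2 theta)) / sum(w). R = 1 means perfect
# alignment, R -> 0 means no preferred axis ("orientation uniformity").

#' Construct an orientation sample
#'
#' @param angles_deg Finite axial angles in degrees (any branch; stored
#'   reduced to `[-90, 90)`).
#' @param weights Non-negative per-angle weights, recycled; not all zero.
#' @return An `orientation_sample` list with `angles_deg`, `weights`, `n`.
#' @export
orientation_sample <- function(angles_deg, weights = 1) {
  angles_deg <- as.numeric(angles_deg)
  if (length(angles_deg) == 0) stop("empty orientation sample")
  if (any(!is.finite(angles_deg))) stop("orientation angles must be finite")
  weights <- rep_len(as.numeric(weights), length(angles_deg))
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) <= 0) stop("weights must not all be zero")
  structure(list(angles_deg = canonical_axial(angles_deg), weights = weights,
                 n = length(angles_deg)),
            class = "orientation_sample")
}

axial_complex_mean <- function(sample) {
  w <- sample$weights
  sum(w * exp(2i * deg2rad(sample$angles_deg))) / sum(w)
}

#' Axial mean angle and resultant vector length
#'
#' @param sample An [orientation_sample()].
#' @return List with `mean_angle_deg` (in `[-90, 90)`; NaN when `R = 0`,
#'   where the mean axis is undefined) and `resultant_length` in `[0, 1]`.
#' @examples
#' axial_resultant(orientation_sample(c(40, 40, 40)))
#' axial_resultant(orientation_sample(c(0, 90)))  # antipodal after doubling
#' @export
axial_resultant <- function(sample) {
  stopifnot(inherits(sample, "orientation_sample"))
  if (sample$n == 0)
    return(list(mean_angle_deg = NaN, resultant_length = NA_real_))
  m <- axial_complex_mean(sample)
  R <- min(Mod(m), 1)
  mean_deg <- if (R < .Machine$double.eps^0.5 * 10) NaN
              else canonical_axial(rad2deg(Arg(m) / 2))
  list(mean_angle_deg = mean_deg, resultant_length = R)
}

#' Circular standard deviation on the axial scale
#'
#' `sqrt(-2 log R)` radians on the doubled-angle scale, halved and converted
#' to degrees.
#'
#' @param R Resultant vector length in `(0, 1]`.
#' @return Degrees; `Inf` for `R = 0`.
#' @export
axial_circ_sd <- function(R) rad2deg(sqrt(-2 * log(pmin(pmax(R, 0), 1)))) / 2

#' 95% confidence interval for the axial mean angle
#'
#' Percentile bootstrap (default) resamples the weighted sample and takes
#' quantiles of the wrapped deviations of the bootstrap mean axes from the
#' point estimate; `"fisher"` uses the large-sample circular standard error
#' on the doubled angles. Endpoints are reported unwrapped so that
#' `low <= mean <= high`; reduce with [canonical_axial()] for display.
#'
#' @param sample An [orientation_sample()] with `R > 0`.
#' @param method `"bootstrap"` or `"fisher"`.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (deterministic given the seed).
#' @param conf Confidence level (default 0.95).
#' @return Named numeric `c(low, high)` in degrees.
#' @export
mean_angle_ci95 <- function(sample, method = c("bootstrap", "fisher"),
                            n_boot = 1000, seed = 1, conf = 0.95) {
  stopifnot(inherits(sample, "orientation_sample"))
  method <- match.arg(method)
  est <- axial_resultant(sample)
  if (!is.finite(est$mean_angle_deg))
    stop("mean axis undefined (resultant length is zero)")
  alpha <- 1 - conf
  if (method == "bootstrap") {
    if (sample$n < 10) stop("bootstrap CI needs at least 10 observations")
    w <- sample$weights
    z <- exp(2i * deg2rad(sample$angles_deg))
    dev <- with_local_seed(seed, {
      idx <- matrix(sample.int(sample$n, sample$n * n_boot, replace = TRUE,
                               prob = if (all(w == w[1])) NULL else w),
                    n_boot, sample$n)
      zb <- matrix(z[idx], n_boot, sample$n)
      means <- rad2deg(Arg(rowMeans(zb)) / 2)
      axial_diff(means, est$mean_angle_deg)
    })
    q <- quantile(dev, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
    ci <- est$mean_angle_deg + q
  } else {
    w <- sample$weights
    n_eff <- sum(w)^2 / sum(w^2)
    a <- 2 * deg2rad(sample$angles_deg)
    mu2 <- 2 * deg2rad(est$mean_angle_deg)
    rho2 <- sum(w * cos(2 * (a - mu2))) / sum(w)
    se2 <- sqrt((1 - rho2) / (2 * n_eff * est$resultant_length^2))
    hw <- rad2deg(qnorm(1 - alpha / 2) * se2) / 2
    ci <- est$mean_angle_deg + c(-hw, hw)
  }
  names(ci) <- c("low", "high")
  ci
}

#' Weighted polar histogram over the axial range
#'
#' @param sample An [orientation_sample()].
#' @param n_bins Number of equal-width bins partitioning `[-90, 90)`
#'   (default 18, i.e. 10-degree bins).
#' @return Tibble with `bin_low_deg`, `bin_high_deg`, `bin_mid_deg`,
#'   `count` (weighted; sums to the total weight).
#' @export
polar_histogram <- function(sample, n_bins = 18) {
  stopifnot(inherits(sample, "orientation_sample"))
  if (n_bins < 2) stop("'n_bins' must be at least 2")
  width <- 180 / n_bins
  idx <- pmin(floor((sample$angles_deg + 90) / width) + 1, n_bins)
  counts <- vapply(seq_len(n_bins),
                   function(b) sum(sample$weights[idx == b]), 0)
  lows <- -90 + (seq_len(n_bins) - 1) * width
  structure(
    tibble::tibble(bin_low_deg = lows, bin_high_deg = lows + width,
                   bin_mid_deg = lows + width / 2, count = counts),
    class = c("polar_histogram", "tbl_df", "tbl", "data.frame"))
}

#' Summarise dichroism maps over regions of interest
#'
#' For each ROI: mean and SD of DoLD over valid pixels, the axial mean and
#' circular SD of AoLD, the resultant vector length, and a confidence
#' interval for the mean axis.
#'
#' @param result A `dichroism_result` from [dichroism_map()].
#' @param roi_masks Named list of logical matrices matching the map shape;
#'   `NULL` summarises the whole image as region `"all"`.
#' @param weight_mode Weights for the axial statistics: `"none"` (default),
#'   `"amplitude"` (average MAP, i.e. Stokes `I/2`), or `"dold"`.
#' @param ci_method Passed to [mean_angle_ci95()]; `"fisher"` default keeps
#'   the summary deterministic without a seed.
#' @param seed Seed for a bootstrap CI.
#' @return Tibble with one row per ROI: `region`, `n_pixels`, `mean_dold`,
#'   `sd_dold`, `mean_aold_deg`, `sd_aold_deg`, `resultant_length`,
#'   `ci95_low_deg`, `ci95_high_deg`. An ROI with no valid pixels yields a
#'   row with `n_pixels = 0` and NA statistics.
#' @export
roi_summary <- function(result, roi_masks = NULL,
                        weight_mode = c("none", "amplitude", "dold"),
                        ci_method = "fisher", seed = 1) {
  stopifnot(inherits(result, "dichroism_result"))
  weight_mode <- match.arg(weight_mode)
  if (is.null(roi_masks))
    roi_masks <- list(all = matrix(TRUE, nrow(result$dold), ncol(result$dold)))
  if (is.null(names(roi_masks)) && length(roi_masks) > 0)
    names(roi_masks) <- paste0("roi", seq_along(roi_masks))
  wmap <- switch(weight_mode,
                 none = NULL,
                 amplitude = result$stokes$I / 2,
                 dold = result$dold)
  empty <- tibble::tibble(region = character(0), n_pixels = integer(0),
                          mean_dold = numeric(0), sd_dold = numeric(0),
                          mean_aold_deg = numeric(0), sd_aold_deg = numeric(0),
                          resultant_length = numeric(0),
                          ci95_low_deg = numeric(0), ci95_high_deg = numeric(0))
  if (length(roi_masks) == 0) return(empty)
  rows <- lapply(names(roi_masks), function(nm) {
    m <- roi_masks[[nm]]
    if (!all(dim(m) == dim(result$dold)))
      stop("ROI '", nm, "' does not match the map shape")
    sel <- m & result$valid_mask & is.finite(result$aold_deg) &
      is.finite(result$dold)
    n <- sum(sel)
    if (n == 0)
      return(tibble::tibble(region = nm, n_pixels = 0L, mean_dold = NA_real_,
                            sd_dold = NA_real_, mean_aold_deg = NA_real_,
                            sd_aold_deg = NA_real_, resultant_length = NA_real_,
                            ci95_low_deg = NA_real_, ci95_high_deg = NA_real_))
    dv <- result$dold[sel]
    w <- if (is.null(wmap)) rep(1, n) else pmax(wmap[sel], 0)
    samp <- orientation_sample(result$aold_deg[sel], w)
    res <- axial_resultant(samp)
    ci <- if (is.finite(res$mean_angle_deg) && n >= 10)
      tryCatch(mean_angle_ci95(samp, method = ci_method, seed = seed),
               error = function(e) c(low = NA_real_, high = NA_real_))
      else c(low = NA_real_, high = NA_real_)
    tibble::tibble(region = nm, n_pixels = as.integer(n),
                   mean_dold = mean(dv), sd_dold = sd(dv),
                   mean_aold_deg = res$mean_angle_deg,
                   sd_aold_deg = axial_circ_sd(res$resultant_length),
                   resultant_length = res$resultant_length,
                   ci95_low_deg = unname(ci[1]), ci95_high_deg = unname(ci[2]))
  })
  do.call(rbind, rows)
}

#' Sample from an axial von Mises distribution
#'
#' Draws directional von Mises variates by the Best-Fisher (1979) rejection
#' method on the doubled-angle scale and halves back, giving axial angles
#' concentrated around `mu_deg` with concentration `kappa`. `kappa = 0` is
#' the uniform axial distribution. The expected resultant length is the
#' Bessel ratio `I_1(kappa) / I_0(kappa)`.
#'
#' @param n Number of draws.
#' @param mu_deg Mean axis in degrees.
#' @param kappa Concentration parameter `>= 0` (on the doubled scale).
#' @return Axial angles in degrees, `[-90, 90)`.
#' @export
raxial_vonmises <- function(n, mu_deg = 0, kappa = 1) {
  canonical_axial(rad2deg(rvonmises_rad(n, 2 * deg2rad(mu_deg), kappa)) / 2)
}

# Best & Fisher (1979) von Mises sampler (radians, directional scale).
rvonmises_rad <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa == 0) return((runif(n) * 2 * pi + mu) %% (2 * pi))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 32L)
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    keep <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    th <- sign(u3 - 0.5) * acos(pmax(pmin(f, 1), -1))
    out <- c(out, th[keep])
  }
  (out[seq_len(n)] + mu) %% (2 * pi)
}
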