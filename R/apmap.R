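# Optical-mapping analysis of voltage-dye movies: F/F0 normalization,
# single-cycle extraction, and per-pixel activation times. Activation is the
# moment a pixel's fluorescence crosses a fixed fraction of its own upstroke
# (default 50%), located with sub-frame linear interpolation; the maximum
# temporal derivative is available as an alternative criterion.

#' F/F0 normalization of a voltage-dye movie
#'
#' Divides each pixel's trace by its resting intensity F0. Baselines:
#' `"percentile"` (default) uses the per-pixel 10th percentile, robust when
#' the rest period is short; `"first_k"` averages the first `k` frames.
#' Pixels with `F0 <= 0` are marked invalid (NaN trace).
#'
#' @param movie A `voltage_movie` (fields `frames` = `y x x x t` array,
#'   `fps`, optional `roi_mask`).
#' @param baseline_mode `"percentile"` or `"first_k"`.
#' @param k Frames averaged in `"first_k"` mode (default 5).
#' @param prob Percentile for `"percentile"` mode (default 0.1).
#' @return A `voltage_movie` of F/F0 ratios (resting level 1).
#' @export
dff <- function(movie, baseline_mode = c("percentile", "first_k"),
                k = 5, prob = 0.1) {
  stopifnot(inherits(movie, "voltage_movie"))
  baseline_mode <- match.arg(baseline_mode)
  d <- dim(movie$frames)
  if (d[3] < 2) stop("movie needs at least 2 frames")
  tr <- matrix(movie$frames, d[1] * d[2], d[3])   # pixels x time
  f0 <- if (baseline_mode == "first_k") {
    if (d[3] < k) stop("'first_k' baseline needs at least ", k, " frames")
    rowMeans(tr[, seq_len(k), drop = FALSE])
  } else {
    apply(tr, 1, quantile, probs = prob, names = FALSE)
  }
  if (all(!is.finite(f0) | f0 <= 0)) stop("no pixel has a positive baseline")
  bad <- !is.finite(f0) | f0 <= 0
  norm <- tr / f0
  norm[bad, ] <- NaN
  structure(list(frames = array(norm, d), fps = movie$fps,
                 roi_mask = movie$roi_mask),
            class = "voltage_movie")
}

#' Extract one activation cycle from a movie
#'
#' Locates the first upstroke of the smoothed spatial-mean trace and returns
#' the frame window spanning that cycle: from the last near-baseline frame
#' before the rise to the last frame before a second rise begins (or the end
#' of the movie). Deterministic.
#'
#' @param movie A `voltage_movie`, typically F/F0 normalized.
#' @param smooth_frames Moving-average width for the mean trace (default 3).
#' @return List with `movie` (frames restricted to the window), `start`,
#'   `end` (frame indices into the input).
#' @export
extract_cycle <- function(movie, smooth_frames = 3) {
  stopifnot(inherits(movie, "voltage_movie"))
  d <- dim(movie$frames)
  sel <- if (is.null(movie$roi_mask)) rep(TRUE, d[1] * d[2])
         else as.vector(movie$roi_mask)
  tr <- matrix(movie$frames, d[1] * d[2], d[3])[sel, , drop = FALSE]
  trace <- colMeans(tr, na.rm = TRUE)
  trace <- moving_average(trace, smooth_frames)
  lo <- min(trace); hi <- max(trace)
  if (!is.finite(lo) || !is.finite(hi) || (hi - lo) <= 1e-6 * max(abs(hi), 1))
    stop("no detectable activation cycle in the movie")
  level <- lo + 0.5 * (hi - lo)
  rest <- lo + 0.1 * (hi - lo)
  ups <- which(diff(trace >= level) == 1) + 1
  if (length(ups) == 0) stop("no detectable activation cycle in the movie")
  pre <- which(trace[seq_len(ups[1])] <= rest)
  start <- if (length(pre)) max(pre) else 1L
  end <- if (length(ups) >= 2) {
    pre2 <- which(trace[seq_len(ups[2] - 1)] <= rest)
    if (length(pre2)) max(pre2) else ups[2] - 1L
  } else d[3]
  out <- movie
  out$frames <- movie$frames[, , start:end, drop = FALSE]
  list(movie = out, start = as.integer(start), end = as.integer(end))
}

#' Per-pixel activation-time map
#'
#' For an F/F0-normalized single-cycle movie, finds when each pixel crosses
#' `threshold_frac` of its upstroke amplitude (`"half_max"`, linear
#' interpolation between frames) or reaches its maximum temporal derivative
#' (`"dvdt"`, parabolic sub-frame refinement on a smoothed trace). Pixels
#' whose upstroke amplitude (peak F/F0 - 1) is below `min_amp`, or outside
#' `roi_mask`, get NaN.
#'
#' @param movie An F/F0 `voltage_movie` (resting level 1).
#' @param method `"half_max"` (default) or `"dvdt"`.
#' @param threshold_frac Fraction of the upstroke for `"half_max"`, in (0, 1).
#' @param min_amp Amplitude noise floor on peak F/F0 - 1 (default 0.05).
#' @param smooth_frames Moving-average width before the derivative.
#' @return An `activation_map`: `t_act` (ms from the first frame of the
#'   window), `amp` (peak F/F0 - 1), `fps`.
#' @export
activation_map <- function(movie, method = c("half_max", "dvdt"),
                           threshold_frac = 0.5, min_amp = 0.05,
                           smooth_frames = 3) {
  stopifnot(inherits(movie, "voltage_movie"))
  method <- match.arg(method)
  if (method == "half_max" && (threshold_frac <= 0 || threshold_frac >= 1))
    stop("'threshold_frac' must be in (0, 1)")
  d <- dim(movie$frames)
  tr <- matrix(movie$frames, d[1] * d[2], d[3])
  peak <- apply(tr, 1, max)
  amp <- peak - 1
  t_act <- rep(NaN, nrow(tr))
  ok <- is.finite(amp) & amp >= min_amp
  if (!is.null(movie$roi_mask)) ok <- ok & as.vector(movie$roi_mask)
  frame_ms <- 1000 / movie$fps
  for (i in which(ok)) {
    y <- tr[i, ]
    if (method == "half_max") {
      thr <- 1 + threshold_frac * amp[i]
      j <- which(y[-1] >= thr & y[-length(y)] < thr)
      if (length(j) == 0) next
      j <- j[1]
      frac <- (thr - y[j]) / (y[j + 1] - y[j])
      t_act[i] <- (j - 1 + frac) * frame_ms
    } else {
      ys <- moving_average(y, smooth_frames)
      dv <- diff(ys)
      j <- which.max(dv)
      t_sub <- j - 0.5   # derivative sample sits between frames j and j+1
      if (j > 1 && j < length(dv)) {
        denom <- dv[j - 1] - 2 * dv[j] + dv[j + 1]
        if (denom < 0) t_sub <- t_sub + 0.5 * (dv[j - 1] - dv[j + 1]) / denom
      }
      t_act[i] <- t_sub * frame_ms
    }
  }
  structure(list(t_act = matrix(t_act, d[1], d[2]),
                 amp = matrix(amp, d[1], d[2]), fps = movie$fps),
            class = "activation_map")
}

moving_average <- function(x, k) {
  if (k <= 1) return(x)
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2)) |>
    (\(y) ifelse(is.na(y), x, y))()
}
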