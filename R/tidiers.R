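# broom-style accessors and ggplot2 visualisations for the result objects.
# The numeric files written by the pipeline are the contract; these are
# conveniences for interactive work.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a dichroism result into a per-pixel tibble
#'
#' @param x A `dichroism_result`.
#' @param ... Unused.
#' @return Tibble with `x`, `y` (1-based pixel coordinates), `dold`,
#'   `aold_deg`, `valid`, `flag`.
#' @export
tidy.dichroism_result <- function(x, ...) {
  obj <- x
  d <- dim(obj$dold)
  tibble::tibble(
    x = rep(seq_len(d[2]), each = d[1]),
    y = rep(seq_len(d[1]), times = d[2]),
    dold = as.vector(obj$dold),
    aold_deg = as.vector(obj$aold_deg),
    valid = as.vector(obj$valid_mask),
    flag = c("ok", "low_signal", "undefined_angle",
             "model_inconsistent")[as.vector(obj$flags) + 1L])
}

#' One-row summary of a dichroism result
#'
#' @param x A `dichroism_result`.
#' @param ... Unused.
#' @return Tibble with pixel counts, mean/SD DoLD, axial mean AoLD and
#'   resultant length over valid pixels.
#' @export
glance.dichroism_result <- function(x, ...) {
  s <- roi_summary(x)
  tibble::tibble(n_pixels = s$n_pixels, pct_valid = 100 * mean(x$valid_mask),
                 mean_dold = s$mean_dold, sd_dold = s$sd_dold,
                 mean_aold_deg = s$mean_aold_deg,
                 resultant_length = s$resultant_length,
                 min_signal = x$min_signal)
}

#' Tidy an orientation summary from a sample
#'
#' @param x An `orientation_sample`.
#' @param ... Unused.
#' @return One-row tibble with `n`, `mean_angle_deg`, `resultant_length`,
#'   `circ_sd_deg`.
#' @export
glance.orientation_sample <- function(x, ...) {
  r <- axial_resultant(x)
  tibble::tibble(n = x$n, mean_angle_deg = r$mean_angle_deg,
                 resultant_length = r$resultant_length,
                 circ_sd_deg = axial_circ_sd(r$resultant_length))
}

#' Tidy an activation map into a per-pixel tibble
#'
#' @param x An `activation_map`.
#' @param ... Unused.
#' @return Tibble with `x`, `y`, `t_act_ms`, `amp`.
#' @export
tidy.activation_map <- function(x, ...) {
  obj <- x
  d <- dim(obj$t_act)
  tibble::tibble(
    x = rep(seq_len(d[2]), each = d[1]),
    y = rep(seq_len(d[1]), times = d[2]),
    t_act_ms = as.vector(obj$t_act),
    amp = as.vector(obj$amp))
}

need_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("install 'ggplot2' for plotting")
}

#' Plot DoLD and AoLD maps
#'
#' @param object A `dichroism_result`.
#' @param which `"dold"` or `"aold"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dichroism_result <- function(object, which = c("dold", "aold"), ...) {
  need_ggplot2()
  which <- match.arg(which)
  df <- tidy.dichroism_result(object)
  df <- df[df$valid, ]
  if (which == "dold")
    ggplot2::ggplot(df, ggplot2::aes(x = x, y = y,
                                     fill = dold)) +
      ggplot2::geom_raster() + ggplot2::scale_y_reverse() +
      ggplot2::scale_fill_viridis_c(name = "DoLD") +
      ggplot2::coord_equal() + ggplot2::theme_minimal()
  else
    ggplot2::ggplot(df, ggplot2::aes(x = x, y = y,
                                     fill = aold_deg)) +
      ggplot2::geom_raster() + ggplot2::scale_y_reverse() +
      ggplot2::scale_fill_gradientn(
        name = "AoLD (deg)", limits = c(-90, 90),
        colours = grDevices::hcl.colors(13, "Spectral")) +
      ggplot2::coord_equal() + ggplot2::theme_minimal()
}

#' Polar histogram of an orientation distribution
#'
#' @param object A `polar_histogram` tibble from [polar_histogram()].
#' @param ... Unused.
#' @return A ggplot object in polar coordinates (axial: each bin is drawn at
#'   its angle and its antipode).
#' @exportS3Method ggplot2::autoplot
autoplot.polar_histogram <- function(object, ...) {
  need_ggplot2()
  df <- rbind(as.data.frame(object),
              transform(as.data.frame(object),
                        bin_mid_deg = bin_mid_deg + 180))
  ggplot2::ggplot(df, ggplot2::aes(x = bin_mid_deg, y = count)) +
    ggplot2::geom_col(width = 180 / nrow(object), fill = "steelblue") +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(-90, 270),
                                breaks = seq(-90, 240, 30)) +
    ggplot2::labs(x = "orientation (deg)", y = "weight") +
    ggplot2::theme_minimal()
}

#' Plot an activation-time map
#'
#' @param object An `activation_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.activation_map <- function(object, ...) {
  need_ggplot2()
  df <- tidy.activation_map(object)
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y,
                                   fill = t_act_ms)) +
    ggplot2::geom_raster() + ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "activation (ms)") +
    ggplot2::coord_equal() + ggplot2::theme_minimal()
}
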