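# Polarization stacks on disk: multi-page float TIFF (one page per incident
# polarization state) plus a JSON or YAML sidecar naming the angle, fluence
# and pixel pitch of each page. Fluence units are arbitrary: only per-state
# ratios enter the analysis.

#' Construct a polarization-resolved image stack
#'
#' @param images List of co-registered `height x width` amplitude matrices,
#'   one per incident polarization state.
#' @param angles Incident polarization angles in degrees (unique modulo 180).
#' @param fluence Per-state laser fluence, arbitrary units `> 0`.
#' @param pixel_size_um Physical pixel pitch, micrometres.
#' @param provenance Free-text description of the stack's origin.
#' @return A `pol_stack`: list with `images` (named `p<angle>`) and `meta`.
#' @export
pol_stack <- function(images, angles, fluence = 1, pixel_size_um = 1,
                      provenance = "") {
  stopifnot(is.list(images), length(images) == length(angles))
  dims <- lapply(images, dim)
  if (length(unique(dims)) != 1)
    stop("all pages of a polarization stack must share one shape")
  angles <- as.numeric(angles) %% 180
  if (anyDuplicated(angles))
    stop("polarization angles must be unique modulo 180")
  fluence <- rep_len(as.numeric(fluence), length(angles))
  if (any(fluence <= 0)) stop("fluence must be positive for every state")
  if (pixel_size_um <= 0) stop("'pixel_size_um' must be positive")
  ord <- order(angles)
  images <- images[ord]
  names(images) <- format_angle(angles[ord])
  structure(
    list(images = images,
         meta = list(angles_deg = angles[ord], fluence = fluence[ord],
                     pixel_size_um = pixel_size_um,
                     provenance = provenance)),
    class = "pol_stack")
}

#' @export
print.pol_stack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("<pol_stack> %d x %d px, states at %s deg, pixel %.3g um\n",
              d[1], d[2], paste(x$meta$angles_deg, collapse = "/"),
              x$meta$pixel_size_um))
  invisible(x)
}

sidecar_path <- function(path) {
  base <- sub("\\.[^.]*$", "", path)
  for (ext in c(".json", ".yaml", ".yml")) {
    cand <- paste0(base, ext)
    if (file.exists(cand)) return(cand)
  }
  paste0(base, ".json")
}

read_sidecar <- function(path) {
  if (grepl("\\.(yaml|yml)$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path)
}

#' Read a polarization stack from TIFF plus sidecar
#'
#' Pages whose sidecar angles differ by 180 degrees describe the same axial
#' polarization state and are merged (averaged) under the equivalent angle in
#' `[0, 180)`.
#'
#' @param path Multi-page TIFF file.
#' @param sidecar Sidecar path; by default the TIFF path with a
#'   `.json`/`.yaml` extension.
#' @return A [pol_stack()].
#' @export
read_stack <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sidecar_path(path)
  if (!file.exists(sidecar))
    stop("missing sidecar for ", path, " (looked for ", sidecar, ")")
  meta <- read_sidecar(sidecar)
  if (is.null(meta$angles_deg)) stop("sidecar must name 'angles_deg'")
  pages <- read_tiff_float(path)
  angles_raw <- as.numeric(meta$angles_deg)
  if (length(pages) != length(angles_raw))
    stop(sprintf("sidecar names %d angles but the TIFF has %d pages",
                 length(angles_raw), length(pages)))
  if (anyDuplicated(angles_raw)) stop("duplicate angles in sidecar")
  fluence <- if (is.null(meta$fluence)) rep(1, length(angles_raw))
             else as.numeric(meta$fluence)
  ax <- angles_raw %% 180
  # merge axial-equivalent pages (theta and theta + 180)
  if (anyDuplicated(ax)) {
    grp <- split(seq_along(ax), ax)
    pages <- lapply(grp, function(i) Reduce(`+`, pages[i]) / length(i))
    fluence <- vapply(grp, function(i) mean(fluence[i]), 0)
    ax <- as.numeric(names(grp))
  }
  pol_stack(pages, ax, fluence,
            pixel_size_um = if (is.null(meta$pixel_size_um)) 1
                            else meta$pixel_size_um,
            provenance = if (is.null(meta$provenance)) "" else meta$provenance)
}

#' Write a polarization stack as TIFF plus JSON sidecar
#'
#' @param stack A [pol_stack()].
#' @param path Output TIFF path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "pol_stack"))
  write_tiff_float(unname(stack$images), path)
  jsonlite::write_json(stack$meta, sidecar_path_for_write(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path_for_write <- function(path) paste0(sub("\\.[^.]*$", "", path), ".json")

#' Write dichroism result maps and ROI summaries
#'
#' Writes `dold.tif`, `aold.tif` (degrees; invalid pixels as NaN),
#' `mask.tif` (1 valid / 0 invalid), `flags.tif` (0 ok, 1 low_signal,
#' 2 undefined_angle, 3 model_inconsistent) and `summary.csv`.
#'
#' @param result A `dichroism_result` from [dichroism_map()].
#' @param summaries Tibble of ROI summaries as produced by [roi_summary()];
#'   may have zero rows.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
write_results <- function(result, summaries, dir) {
  stopifnot(inherits(result, "dichroism_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  aold <- result$aold_deg
  aold[!result$valid_mask] <- NaN
  files <- c(dold = file.path(dir, "dold.tif"),
             aold = file.path(dir, "aold.tif"),
             mask = file.path(dir, "mask.tif"),
             flags = file.path(dir, "flags.tif"),
             summary = file.path(dir, "summary.csv"))
  write_tiff_float(result$dold, files["dold"])
  write_tiff_float(aold, files["aold"])
  write_tiff_float(result$valid_mask + 0, files["mask"])
  write_tiff_float(result$flags + 0, files["flags"])
  cols <- c("region", "n_pixels", "mean_dold", "sd_dold", "mean_aold_deg",
            "sd_aold_deg", "resultant_length", "ci95_low_deg", "ci95_high_deg")
  tab <- as.data.frame(summaries)[, intersect(cols, names(summaries)), drop = FALSE]
  for (miss in setdiff(cols, names(tab))) tab[[miss]] <- numeric(nrow(tab))
  write.csv(tab[, cols, drop = FALSE], files["summary"], row.names = FALSE)
  invisible(files)
}
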