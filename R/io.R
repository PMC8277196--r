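#' Write a multi-channel z-stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are channel-major: all slices of channel 1, then all slices of
#' channel 2, and so on. Intensities are stored as 16-bit after division by
#' a recorded `intensity_max`; the spatial calibration, channel names, slice
#' count and intensity scale live in a `<path>.meta.json` sidecar (the TIFF
#' writer available here does not expose resolution tags).
#'
#' @param channels Named list; each element a list of `calibrated_image`
#'   slices (one channel), or a single `calibrated_image`.
#' @param path Output `.tif` path.
#' @param ground_truth Optional `ground_truth` written as a second sidecar
#'   `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(channels, path, ground_truth = NULL) {
  if (is_calibrated_image(channels)) channels <- list(ch1 = list(channels))
  if (is_calibrated_image(channels[[1]])) channels <- list(ch1 = channels)
  if (is.null(names(channels)) || any(names(channels) == "")) {
    names(channels) <- paste0("ch", seq_along(channels))
  }
  slices <- unlist(channels, recursive = FALSE)
  upx <- slices[[1]]$um_per_pixel
  vmax <- max(1e-12, max(vapply(slices, function(s) max(s$pixels), 1)))
  pages <- lapply(slices, function(s) s$pixels / vmax)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(
    um_per_pixel = upx,
    intensity_max = vmax,
    channels = names(channels),
    n_slices = vapply(channels, length, 1L),
    page_order = "channel_major"
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(ground_truth)) {
    write_ground_truth(ground_truth, paste0(path, ".truth.json"))
  }
  invisible(path)
}

#' Read a multi-channel z-stack written by [write_image_stack()]
#'
#' @param path `.tif` path with its `.meta.json` sidecar.
#' @param um_per_pixel Optional override of the sidecar calibration; a
#'   warning reports the override when both are present and differ.
#' @return Named list of channels, each a list of `calibrated_image` slices.
#' @export
read_image_stack <- function(path, um_per_pixel = NULL) {
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) abort(sprintf("missing sidecar %s.", meta_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  upx <- meta$um_per_pixel
  if (!is.null(um_per_pixel)) {
    if (!isTRUE(all.equal(um_per_pixel, upx))) {
      warn(sprintf("calibration override: using %g um/px over sidecar %g.",
                   um_per_pixel, upx))
    }
    upx <- um_per_pixel
  }
  if (is.null(upx) || upx <= 0) abort("calibration missing: supply um_per_pixel.")
  pages <- tiff::readTIFF(path, all = TRUE)
  vmax <- meta$intensity_max %||% 1
  n_slices <- meta$n_slices
  chs <- meta$channels
  out <- list()
  k <- 0L
  for (i in seq_along(chs)) {
    out[[chs[i]]] <- lapply(seq_len(n_slices[i]), function(s) {
      k_local <- k + s
      calibrate(pages[[k_local]] * vmax, upx, chs[i])
    })
    k <- k + n_slices[i]
  }
  out
}

write_ground_truth <- function(truth, path) {
  payload <- list(
    puncta = as.data.frame(as_tibble(truth)),
    cell_center_um = as.list(attr(truth, "cell_center_um")),
    cell_radius_um = attr(truth, "cell_radius_um"),
    nucleus_center_um = as.list(attr(truth, "nucleus_center_um")),
    nucleus_radius_um = attr(truth, "nucleus_radius_um"),
    seed = attr(truth, "seed")
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a ground-truth sidecar
#'
#' @param path `.truth.json` path.
#' @return A `ground_truth` tibble.
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- as_tibble(raw$puncta)
  structure(tr,
            cell_center_um = unlist(raw$cell_center_um),
            cell_radius_um = raw$cell_radius_um,
            nucleus_center_um = unlist(raw$nucleus_center_um),
            nucleus_radius_um = raw$nucleus_radius_um,
            seed = raw$seed,
            class = c("ground_truth", class(tibble())))
}

#' Experiment run configuration
#'
#' Validated bundle of every parameter of an end-to-end run. Unknown keys
#' are rejected by name, and the full configuration is echoed verbatim into
#' the run manifest.
#'
#' @param cells Data frame with columns `cell_id`, `group`, `path` (one
#'   TIFF per cell; one cell per image).
#' @param um_per_pixel Optional calibration override (microns per pixel).
#' @param channels Character vector of channel names to analyse (default:
#'   every channel in each file's sidecar).
#' @param pipeline A [pipeline_params()].
#' @param scheme_name Built-in size-scheme name (see [size_scheme()]).
#' @param band_width_um Peripheral band width.
#' @param min_large_area_um2 Large-punctum cutoff for periphery and
#'   punctum-restricted colocalization.
#' @param reference Reference group for normalization.
#' @param coloc_channels Length-2 channel names to correlate, or `NULL` to
#'   skip colocalization.
#' @param seed Integer seed (recorded; analysis is deterministic anyway).
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(cells, out_dir, reference,
                       um_per_pixel = NULL,
                       channels = NULL,
                       pipeline = pipeline_params(),
                       scheme_name = "lc3b",
                       band_width_um = 10,
                       min_large_area_um2 = 10,
                       coloc_channels = NULL,
                       seed = 1L) {
  cells <- as_tibble(cells)
  need <- c("cell_id", "group", "path")
  if (!all(need %in% names(cells))) {
    abort("`cells` needs columns cell_id, group, path.")
  }
  if (anyDuplicated(cells$cell_id)) abort("cell_id values must be unique.")
  if (!reference %in% cells$group) abort("`reference` must be one of the groups.")
  structure(list(cells = cells, out_dir = out_dir, reference = reference,
                 um_per_pixel = um_per_pixel, channels = channels,
                 pipeline = pipeline, scheme_name = scheme_name,
                 band_width_um = band_width_um,
                 min_large_area_um2 = min_large_area_um2,
                 coloc_channels = coloc_channels, seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file. Recognised keys: `cells` (list of
#'   `cell_id`/`group`/`path` records), `out_dir`, `reference`,
#'   `um_per_pixel`, `channels`, `pipeline` (sub-keys as in
#'   [pipeline_params()]), `scheme_name`, `band_width_um`,
#'   `min_large_area_um2`, `coloc_channels`, `seed`. Unknown keys raise an
#'   error naming the key.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("cells", "out_dir", "reference", "um_per_pixel", "channels",
             "pipeline", "scheme_name", "band_width_um",
             "min_large_area_um2", "coloc_channels", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    abort(sprintf("unknown config key(s): %s.", paste(bad, collapse = ", ")))
  }
  pknown <- names(formals(pipeline_params))
  pbad <- setdiff(names(raw$pipeline), pknown)
  if (length(pbad) > 0) {
    abort(sprintf("unknown pipeline key(s): %s.", paste(pbad, collapse = ", ")))
  }
  pl <- do.call(pipeline_params, raw$pipeline %||% list())
  cells <- bind_rows(lapply(raw$cells, as_tibble))
  args <- raw[setdiff(names(raw), c("cells", "pipeline"))]
  do.call(run_config, c(list(cells = cells, pipeline = pl), args))
}
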