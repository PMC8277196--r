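#' Pipeline parameters
#'
#' Parameters of the puncta measurement chain. The threshold is a fixed 8-bit
#' value by default; keep it constant across experimental groups within a
#' replicate when comparing groups. `"otsu"` is accepted for exploratory runs
#' and recorded in provenance.
#'
#' @param tophat_radius_px Disc radius of the white top-hat, pixels.
#' @param threshold Integer in `[0, 255]`, or `"otsu"`.
#' @param connectivity 4 or 8.
#' @param min_area_um2 Minimum particle area retained, square microns.
#' @param projection `"max"` or `"sum"` overlay of the z-stack.
#' @return A `pipeline_params` list.
#' @export
pipeline_params <- function(tophat_radius_px = 15, threshold = 20,
                            connectivity = 8, min_area_um2 = 0,
                            projection = c("max", "sum")) {
  projection <- match.arg(projection)
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  if (min_area_um2 < 0) abort("`min_area_um2` must be non-negative.")
  structure(list(tophat_radius_px = tophat_radius_px, threshold = threshold,
                 connectivity = connectivity, min_area_um2 = min_area_um2,
                 projection = projection),
            class = "pipeline_params")
}

#' Run the full puncta measurement chain on one z-stack
#'
#' Composition of the measurement stages for one cell and channel:
#' overlay of the z-stack into a single image, 8-bit conversion, white
#' top-hat background suppression, fixed-value thresholding, and particle
#' analysis. Every parameter, plus the 8-bit rescale range, is recorded in
#' the returned table's provenance attribute.
#'
#' @param stack A calibrated z-stack: list of `calibrated_image` slices (or a
#'   single `calibrated_image`).
#' @param params A [pipeline_params()] object.
#' @param image_id Optional identifier recorded in provenance.
#' @return A `puncta_table` (see [analyze_particles()]).
#' @examples
#' sim <- generate_cell(puncta_spec(n = c(5, 2), lower_um2 = c(0.2, 1),
#'                                  upper_um2 = c(0.5, 1.767)),
#'                      acquisition_params(image_size_px = c(256, 256),
#'                                         noise_model = "none"),
#'                      seed = 1)
#' tab <- run_pipeline(sim$stack, pipeline_params(threshold = 120))
#' nrow(tab)
#' @export
run_pipeline <- function(stack, params = pipeline_params(), image_id = NULL) {
  if (!inherits(params, "pipeline_params")) {
    abort("`params` must come from `pipeline_params()`.")
  }
  flat <- overlay_stack(stack, method = params$projection)
  rng <- range(flat$pixels)
  img8 <- to_eight_bit(flat)
  th <- white_top_hat(img8, params$tophat_radius_px)
  thr_value <- params$threshold
  if (is.character(thr_value)) thr_value <- otsu_threshold(th$pixels)
  mask <- threshold_image(th, thr_value)
  tab <- analyze_particles(mask, params$connectivity, params$min_area_um2)
  prov <- list(
    image_id = image_id,
    channel_id = flat$channel_id,
    um_per_pixel = flat$um_per_pixel,
    n_slices = if (is_calibrated_image(stack)) 1L else length(stack),
    projection = params$projection,
    eight_bit_rescale_range = rng,
    tophat_radius_px = params$tophat_radius_px,
    threshold_requested = params$threshold,
    threshold_applied = thr_value,
    connectivity = params$connectivity,
    min_area_um2 = params$min_area_um2
  )
  attr(tab, "provenance") <- prov
  tab
}
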