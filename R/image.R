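#' Calibrated single-channel image
#'
#' A `calibrated_image` wraps a 2-D intensity matrix together with the spatial
#' calibration (microns per pixel) and a channel label, so that every
#' downstream area is reported in square microns (pixel count times
#' `um_per_pixel^2`).
#'
#' @param pixels Numeric matrix of non-negative intensities. Rows index y,
#'   columns index x.
#' @param um_per_pixel Positive scalar, microns per pixel (isotropic).
#' @param channel_id Character label for the imaged channel/marker
#'   (e.g. `"LC3B"`, `"LAMP1"`).
#' @param bit_depth Either `"native"` (arbitrary intensity units) or
#'   `"eight_bit"` (integers in `[0, 255]`).
#'
#' @return An object of class `calibrated_image`: a list with fields
#'   `pixels`, `um_per_pixel`, `channel_id`, `bit_depth`.
#' @examples
#' img <- calibrate(matrix(runif(64), 8, 8), um_per_pixel = 0.5)
#' img$um_per_pixel
#' @export
calibrate <- function(pixels, um_per_pixel, channel_id = "ch1",
                      bit_depth = c("native", "eight_bit")) {
  bit_depth <- match.arg(bit_depth)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.")
  }
  if (!is.numeric(um_per_pixel) || length(um_per_pixel) != 1L ||
      is.na(um_per_pixel) || um_per_pixel <= 0) {
    abort("`um_per_pixel` must be a single positive number.")
  }
  if (any(pixels < 0, na.rm = TRUE)) {
    abort("`pixels` must be non-negative.")
  }
  if (bit_depth == "eight_bit" &&
      (any(pixels > 255) || any(pixels != round(pixels)))) {
    abort("eight_bit images must hold integers in [0, 255].")
  }
  structure(
    list(pixels = pixels, um_per_pixel = as.numeric(um_per_pixel),
         channel_id = as.character(channel_id), bit_depth = bit_depth),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf(
    "<calibrated_image> %d x %d px, %.4g um/px, channel '%s', %s\n",
    nrow(x$pixels), ncol(x$pixels), x$um_per_pixel, x$channel_id, x$bit_depth
  ))
  invisible(x)
}

is_calibrated_image <- function(x) inherits(x, "calibrated_image")

stopifnot_image <- function(img, arg = "img") {
  if (!is_calibrated_image(img)) {
    abort(sprintf("`%s` must be a calibrated_image (see `calibrate()`).", arg))
  }
}

#' Overlay a z-stack into a single image
#'
#' Collapses an ordered list of calibrated slices into one 2-D image. The
#' default is a per-pixel maximum-intensity projection, the standard overlay
#' for sparse bright puncta; a sum projection is available behind the
#' `method` flag.
#'
#' @param stack List of `calibrated_image` slices sharing shape, scale and
#'   channel.
#' @param method `"max"` (default) or `"sum"`.
#' @return A single `calibrated_image` with the input scale and channel.
#' @export
overlay_stack <- function(stack, method = c("max", "sum")) {
  method <- match.arg(method)
  if (is_calibrated_image(stack)) stack <- list(stack)
  if (!is.list(stack) || length(stack) == 0L) {
    abort("`stack` must be a non-empty list of calibrated_image slices.")
  }
  walk(stack, stopifnot_image, arg = "stack[[i]]")
  ref <- stack[[1L]]
  for (s in stack[-1L]) {
    if (!identical(dim(s$pixels), dim(ref$pixels))) {
      abort("all slices must share the same pixel dimensions.")
    }
    if (!isTRUE(all.equal(s$um_per_pixel, ref$um_per_pixel))) {
      abort("all slices must share the same um_per_pixel scale.")
    }
    if (!identical(s$channel_id, ref$channel_id)) {
      abort("all slices must belong to the same channel.")
    }
  }
  arr <- vapply(stack, function(s) s$pixels, ref$pixels)
  dim(arr) <- c(dim(ref$pixels), length(stack))
  px <- if (method == "max") apply(arr, c(1, 2), max) else
    apply(arr, c(1, 2), sum)
  calibrate(px, ref$um_per_pixel, ref$channel_id, bit_depth = "native")
}

#' Convert an image to 8-bit grayscale
#'
#' Linear min-max rescale of a native-depth image to integers in `[0, 255]`,
#' rounded half-up. A constant image maps to all zeros. An image that already
#' holds integers spanning exactly `[0, 255]` is returned unchanged. The
#' rescale is per-image, which matters when a fixed threshold is compared
#' across images; the conversion is therefore recorded in pipeline provenance.
#'
#' @param img A `calibrated_image`.
#' @return An 8-bit `calibrated_image`.
#' @export
to_eight_bit <- function(img) {
  stopifnot_image(img)
  px <- img$pixels
  rng <- range(px)
  if (rng[1] == rng[2]) {
    out <- array(0, dim = dim(px))
  } else {
    out <- round_half_up((px - rng[1]) / (rng[2] - rng[1]) * 255)
  }
  dim(out) <- dim(px)
  calibrate(out, img$um_per_pixel, img$channel_id, bit_depth = "eight_bit")
}

# round half away from zero, as ImageJ's 8-bit conversion does
round_half_up <- function(x) floor(x + 0.5)
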