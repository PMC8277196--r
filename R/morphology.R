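#' Disc structuring element
#'
#' Flat disc brush of the given pixel radius (a `(2r+1) x (2r+1)` 0/1 matrix),
#' shared by the white top-hat and its brute-force oracle so both operate on
#' the same neighbourhood.
#'
#' @param radius_px Positive integer radius in pixels.
#' @return 0/1 matrix structuring element.
#' @export
disc_kernel <- function(radius_px) {
  if (!is.numeric(radius_px) || length(radius_px) != 1L || radius_px < 1 ||
      radius_px != round(radius_px)) {
    abort("`radius_px` must be a positive integer.")
  }
  makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
}

#' White top-hat filter
#'
#' Background suppression for puncta detection: the image minus its
#' morphological opening with a flat disc structuring element. Structures that
#' cannot contain the disc (puncta) are retained; broader structures
#' (cytoplasmic background, the cell body) are removed. The result is
#' non-negative and pointwise no greater than the input.
#'
#' @param img An 8-bit `calibrated_image` (native-depth input is accepted and
#'   filtered as-is).
#' @param radius_px Disc radius in pixels; must exceed the radius of the
#'   largest punctum that should survive. Default 15.
#' @return A `calibrated_image` of the same depth flag as the input.
#' @export
white_top_hat <- function(img, radius_px = 15) {
  stopifnot_image(img)
  kern <- disc_kernel(radius_px)
  px <- img$pixels
  # EBImage grayscale morphology expects intensities in [0, 1]
  scale <- if (img$bit_depth == "eight_bit") 255 else max(px, 1)
  opened <- opening(px / scale, kern) * scale
  out <- px - opened
  out[out < 0] <- 0  # guard against floating-point dust
  if (all(px == round(px))) out <- round(out)  # keep integer images integer
  calibrate(out, img$um_per_pixel, img$channel_id, bit_depth = img$bit_depth)
}

#' Binary foreground mask with calibration
#'
#' @param mask Logical (or 0/1) matrix.
#' @param um_per_pixel Positive scalar, microns per pixel.
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(mask, um_per_pixel) {
  if (!is.matrix(mask)) abort("`mask` must be a matrix.")
  m <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (any(is.na(m))) abort("`mask` must not contain NA.")
  if (!is.numeric(um_per_pixel) || um_per_pixel <= 0) {
    abort("`um_per_pixel` must be a single positive number.")
  }
  structure(list(mask = m, um_per_pixel = as.numeric(um_per_pixel)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %.4g um/px, %d foreground px\n",
              nrow(x$mask), ncol(x$mask), x$um_per_pixel, sum(x$mask)))
  invisible(x)
}

#' Threshold an 8-bit image
#'
#' Foreground is every pixel with intensity greater than or equal to the
#' threshold (ImageJ default-dark convention, bright puncta). The fixed-value
#' mode is the one used for group comparisons; thresholds must be kept
#' consistent across experimental groups within a replicate. `"otsu"` is
#' provided for exploratory runs only and is recorded in provenance when used
#' through [run_pipeline()].
#'
#' @param img An 8-bit `calibrated_image`.
#' @param value Integer in `[0, 255]`, or the string `"otsu"`.
#' @return A `binary_mask`.
#' @export
threshold_image <- function(img, value = 20) {
  stopifnot_image(img)
  if (is.character(value)) {
    if (!identical(value, "otsu")) abort("auto method must be \"otsu\".")
    value <- otsu_threshold(img$pixels)
  }
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value > 255) {
    abort("threshold `value` must lie in [0, 255].")
  }
  binary_mask(img$pixels >= value, img$um_per_pixel)
}

# Otsu on the 8-bit histogram; returns the value such that `>= value` keeps
# the bright class (EBImage's otsu returns the boundary on [0,1])
otsu_threshold <- function(px) {
  t01 <- otsu(px / 255, range = c(0, 1), levels = 256L)
  ceiling(t01 * 255)
}

#' Label connected components of a binary mask
#'
#' Iterative breadth-first labeling supporting both 4- and 8-connectivity
#' (EBImage's `bwlabel` is 8-connected only). Labels are assigned in raster
#' order of each component's first pixel, starting at 1.
#'
#' @param mask Logical matrix (or `binary_mask`).
#' @param connectivity 4 or 8 (default 8, the ImageJ Analyze Particles
#'   behaviour).
#' @return Integer matrix of the same shape; 0 is background.
#' @export
label_components <- function(mask, connectivity = 8) {
  if (inherits(mask, "binary_mask")) mask <- mask$mask
  if (!is.matrix(mask)) abort("`mask` must be a logical matrix.")
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (length(fg) == 0L) return(labels)
  # raster order = column-major in R; sort by (col, row) to mimic row-major
  # raster scanning is unnecessary for correctness; first-seen order suffices
  offsets <- if (connectivity == 4) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  }
  lab <- 0L
  for (seed in fg) {
    if (labels[seed] != 0L) next
    lab <- lab + 1L
    labels[seed] <- lab
    frontier <- seed
    while (length(frontier) > 0L) {
      fr <- ((frontier - 1L) %% nr) + 1L
      fc <- ((frontier - 1L) %/% nr) + 1L
      nxt <- integer(0)
      for (off in offsets) {
        rr <- fr + off[1L]; cc <- fc + off[2L]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        if (!any(ok)) next
        idx <- (cc[ok] - 1L) * nr + rr[ok]
        idx <- idx[mask[idx] & labels[idx] == 0L]
        if (length(idx) > 0L) {
          labels[idx] <- lab
          nxt <- c(nxt, idx)
        }
      }
      frontier <- unique(nxt)
    }
  }
  labels
}
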