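#' No-threshold Pearson colocalization of two channels
#'
#' Pearson correlation of per-pixel intensities across two co-registered
#' channels, with no intensity gating. If top-hat radii are supplied, the
#' white top-hat is applied to each channel first (the filtered channels are
#' what gets correlated); the radii are recorded in the result. The ROI
#' defaults to the whole frame; restricting it to the cell mask avoids
#' background pixels outside the cell inflating the correlation.
#'
#' @param ch1,ch2 `calibrated_image`s of the same shape and scale.
#' @param roi Optional logical matrix / `binary_mask` / `cell_geometry`
#'   restricting the pixels used.
#' @param tophat_radius_px `NULL` (no filtering), a single radius applied to
#'   both channels, or a length-2 vector of per-channel radii.
#' @return A `coloc_result`: one-row tibble with `pearson_r`, `n_pixels`,
#'   `roi`, `tophat_radius_ch1`, `tophat_radius_ch2`. `pearson_r` is `NA`
#'   when either channel is constant over the ROI.
#' @export
pearson_no_threshold <- function(ch1, ch2, roi = NULL,
                                 tophat_radius_px = NULL) {
  stopifnot_image(ch1, "ch1"); stopifnot_image(ch2, "ch2")
  if (!identical(dim(ch1$pixels), dim(ch2$pixels))) {
    abort("channels must share pixel dimensions.")
  }
  if (!isTRUE(all.equal(ch1$um_per_pixel, ch2$um_per_pixel))) {
    abort("channels must share the um_per_pixel scale.")
  }
  radii <- c(NA_real_, NA_real_)
  if (!is.null(tophat_radius_px)) {
    radii <- rep(tophat_radius_px, length.out = 2)
    ch1 <- white_top_hat(ch1, radii[1])
    ch2 <- white_top_hat(ch2, radii[2])
  }
  roi_label <- "frame"
  sel <- TRUE
  if (!is.null(roi)) {
    if (inherits(roi, "cell_geometry")) {
      sel <- roi$cell_mask; roi_label <- "cell"
    } else if (inherits(roi, "binary_mask")) {
      sel <- roi$mask; roi_label <- "mask"
    } else {
      sel <- as.logical(roi); dim(sel) <- dim(roi); roi_label <- "mask"
    }
    if (!identical(dim(sel), dim(ch1$pixels))) {
      abort("ROI must match the channel dimensions.")
    }
  }
  a <- ch1$pixels[sel]; b <- ch2$pixels[sel]
  n <- length(a)
  if (n < 2L) abort("ROI must contain more than one pixel.")
  r <- if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
  structure(
    tibble(pearson_r = r, n_pixels = n, roi = roi_label,
           tophat_radius_ch1 = radii[1], tophat_radius_ch2 = radii[2]),
    class = c("coloc_result", class(tibble())))
}

#' Percent reduction between two correlation coefficients
#'
#' `100 * (r_control - r_treated) / r_control`, signed: an increase over the
#' control yields a negative percentage. Rounding to the nearest integer is
#' applied only in printed summaries, not to the returned value.
#'
#' @param r_control Reference-group coefficient (non-zero).
#' @param r_treated Treated-group coefficient.
#' @return Percentage (bare number, e.g. 38 for a 38\% reduction).
#' @examples
#' percent_reduction(0.829, 0.515)
#' @export
percent_reduction <- function(r_control, r_treated) {
  if (!is.finite(r_control) || r_control == 0) {
    abort("`r_control` must be finite and non-zero.")
  }
  100 * (r_control - r_treated) / r_control
}

#' Colocalization restricted to large puncta
#'
#' Pearson correlation over the union of pixel masks of puncta exceeding
#' `min_area_um2` (strictly), taken from a puncta table derived from one
#' reference channel. Quantifies dual-labeling inside large
#' amphisome-candidate structures rather than over the whole cell.
#'
#' @param ch1,ch2 `calibrated_image`s (same shape/scale as the table's source
#'   image).
#' @param table A `puncta_table` carrying its label matrix (as produced by
#'   [analyze_particles()]/[run_pipeline()]).
#' @param min_area_um2 Large-punctum cutoff (default 10).
#' @param tophat_radius_px Passed to [pearson_no_threshold()].
#' @return A `coloc_result`; `pearson_r` is `NA` when no punctum exceeds the
#'   cutoff (empty ROI).
#' @export
coloc_in_large_puncta <- function(ch1, ch2, table, min_area_um2 = 10,
                                  tophat_radius_px = NULL) {
  lm <- attr(table, "label_matrix")
  if (is.null(lm)) abort("`table` must carry its label matrix.")
  big <- table$label[table$area_um2 > min_area_um2]
  if (length(big) == 0L) {
    return(structure(
      tibble(pearson_r = NA_real_, n_pixels = 0L, roi = "large_puncta",
             tophat_radius_ch1 = NA_real_, tophat_radius_ch2 = NA_real_),
      class = c("coloc_result", class(tibble()))))
  }
  roi <- matrix(lm %in% big, nrow(lm), ncol(lm))
  out <- pearson_no_threshold(ch1, ch2, roi = roi,
                              tophat_radius_px = tophat_radius_px)
  out$roi <- "large_puncta"
  out
}
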