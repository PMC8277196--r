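#' Cell geometry: mask, centroid, equivalent radius, peripheral band
#'
#' Construct geometry from an explicit mask (the override path). See
#' [estimate_cell_mask()] for automatic estimation from the image.
#'
#' @param mask Logical matrix, the cell mask (one cell).
#' @param um_per_pixel Positive scalar, microns per pixel.
#' @return A `cell_geometry`: list with `cell_mask`, `um_per_pixel`,
#'   `centroid_um`, `equivalent_radius_um`, and (after [peripheral_band()])
#'   `band_mask` and `band_width_um`.
#' @export
cell_geometry <- function(mask, um_per_pixel) {
  bm <- binary_mask(mask, um_per_pixel)
  m <- bm$mask
  if (!any(m)) abort("cell mask is empty.")
  fg <- which(m)
  nr <- nrow(m)
  rows <- ((fg - 1L) %% nr) + 1L
  cols <- ((fg - 1L) %/% nr) + 1L
  area_um2 <- length(fg) * um_per_pixel^2
  structure(
    list(cell_mask = m,
         um_per_pixel = um_per_pixel,
         centroid_um = c(x = (mean(cols) - 1) * um_per_pixel,
                         y = (mean(rows) - 1) * um_per_pixel),
         equivalent_radius_um = sqrt(area_um2 / pi),
         band_mask = NULL, band_width_um = NULL),
    class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf(
    "<cell_geometry> r_eq = %.2f um, centroid (%.1f, %.1f) um%s\n",
    x$equivalent_radius_um, x$centroid_um[["x"]], x$centroid_um[["y"]],
    if (is.null(x$band_mask)) "" else
      sprintf(", band %.1f um", x$band_width_um)))
  invisible(x)
}

#' Circular cell geometry on a pixel grid
#'
#' Analytic helper: a disc mask of the given radius, used by tests and by
#' workflows where the cell outline is fitted rather than segmented.
#'
#' @param center_um Disc centre `(x, y)` in microns.
#' @param radius_um Disc radius in microns.
#' @param um_per_pixel Microns per pixel.
#' @param image_size_px `c(rows, cols)` of the grid.
#' @return A `cell_geometry`.
#' @export
circular_cell_geometry <- function(center_um, radius_um, um_per_pixel,
                                   image_size_px) {
  nr <- image_size_px[1]; nc <- image_size_px[2]
  xs <- (seq_len(nc) - 1) * um_per_pixel
  ys <- (seq_len(nr) - 1) * um_per_pixel
  d2 <- outer(ys - center_um[2], xs - center_um[1],
              function(dy, dx) dx^2 + dy^2)
  cell_geometry(d2 <= radius_um^2, um_per_pixel)
}

#' Estimate the cell mask from a single-cell image
#'
#' Otsu threshold of a Gaussian-smoothed copy (default sigma 2 um), keep the
#' largest connected component, fill holes. The diffuse cytoplasmic signal of
#' the analysed channel is usually enough to segment the cell body; supply
#' your own mask via [cell_geometry()] to override.
#'
#' @param img A `calibrated_image` containing exactly one cell.
#' @param sigma_um Gaussian smoothing sigma in microns before thresholding.
#' @return A `cell_geometry`.
#' @export
estimate_cell_mask <- function(img, sigma_um = 2) {
  stopifnot_image(img)
  px <- img$pixels
  if (max(px) == min(px)) abort("blank image: no foreground found.")
  sm <- gblur(px, sigma = sigma_um / img$um_per_pixel)
  # clip bright puncta so Otsu separates background from the cell body
  # rather than puncta from everything else
  sm <- pmin(sm, stats::quantile(sm, 0.90))
  dim(sm) <- dim(px)
  if (max(sm) == min(sm)) abort("no foreground found above the Otsu threshold.")
  sm01 <- (sm - min(sm)) / (max(sm) - min(sm))
  thr <- otsu(sm01, range = c(0, 1), levels = 256L)
  fgmask <- sm01 > thr
  if (!any(fgmask)) abort("no foreground found above the Otsu threshold.")
  labels <- label_components(fgmask, 8)
  sizes <- tabulate(labels[labels > 0L])
  big <- which.max(sizes)
  others <- sizes[-big]
  if (length(others) > 0 && any(others > 0.5 * sizes[big])) {
    abort("ambiguous field: multiple similar-size components.")
  }
  mask <- labels == big
  mask <- fillHull(mask) > 0
  cell_geometry(mask, img$um_per_pixel)
}

#' Peripheral band of a cell
#'
#' The outermost `width_um` of the cell: the cell mask minus its erosion by a
#' disc of radius `width_um` (rounded to the nearest pixel radius). For a
#' circular cell this is the annulus between radii `R - width` and `R`.
#'
#' @param geom A `cell_geometry`.
#' @param width_um Band width in microns (default 10, the outer 10 um of the
#'   cell).
#' @return The `cell_geometry` with `band_mask` and `band_width_um` filled
#'   in.
#' @export
peripheral_band <- function(geom, width_um = 10) {
  if (!inherits(geom, "cell_geometry")) abort("`geom` must be a cell_geometry.")
  if (width_um <= 0) abort("`width_um` must be positive.")
  if (width_um >= geom$equivalent_radius_um) {
    abort("band width must be smaller than the cell's equivalent radius.")
  }
  r_px <- round(width_um / geom$um_per_pixel)
  if (r_px < 1) {
    band <- matrix(FALSE, nrow(geom$cell_mask), ncol(geom$cell_mask))
  } else {
    kern <- disc_kernel(r_px)
    eroded <- erode(geom$cell_mask * 1, kern) > 0
    band <- geom$cell_mask & !eroded
  }
  geom$band_mask <- band
  geom$band_width_um <- width_um
  geom
}

#' Fraction of large puncta in the peripheral band
#'
#' Selects puncta with area above `min_area_um2` (strictly, matching the
#' ">10 um^2" convention) and reports how many have their centroid inside the
#' outer band. With no large puncta the fraction is undefined and reported as
#' `NA`, never as 0.
#'
#' @param table A `puncta_table` for the same image/calibration.
#' @param geom A `cell_geometry`; the band is computed at `band_width_um` if
#'   not already present.
#' @param min_area_um2 Large-punctum area cutoff (default 10).
#' @param band_width_um Band width used when `geom` has no band yet.
#' @param rule `"centroid"` (default) counts a punctum by its centroid;
#'   `"any_pixel"` counts it if any of its pixels lie in the band (requires
#'   the table's label matrix).
#' @return A one-row tibble: `n_large`, `n_in_band`, `fraction`,
#'   `band_width_um`, `cell_radius_um`.
#' @export
peripheral_fraction <- function(table, geom, min_area_um2 = 10,
                                band_width_um = 10,
                                rule = c("centroid", "any_pixel")) {
  rule <- match.arg(rule)
  if (!inherits(geom, "cell_geometry")) abort("`geom` must be a cell_geometry.")
  if (is.null(geom$band_mask)) geom <- peripheral_band(geom, band_width_um)
  large <- table[table$area_um2 > min_area_um2, , drop = FALSE]
  n_large <- nrow(large)
  if (n_large == 0L) {
    return(tibble(n_large = 0L, n_in_band = NA_integer_,
                  fraction = NA_real_,
                  band_width_um = geom$band_width_um,
                  cell_radius_um = geom$equivalent_radius_um))
  }
  in_band <- if (rule == "centroid") {
    centroid_in_mask(large, geom$band_mask, geom$um_per_pixel)
  } else {
    lm <- attr(table, "label_matrix")
    if (is.null(lm)) abort("any_pixel rule needs the table's label matrix.")
    vapply(large$label, function(l) any(geom$band_mask[lm == l]), logical(1))
  }
  tibble(n_large = n_large, n_in_band = sum(in_band),
         fraction = sum(in_band) / n_large,
         band_width_um = geom$band_width_um,
         cell_radius_um = geom$equivalent_radius_um)
}

# map centroids (um) to their containing pixel and look the mask up
centroid_in_mask <- function(table, mask, um_per_pixel) {
  rr <- pmin(pmax(round(table$centroid_y_um / um_per_pixel) + 1L, 1L),
             nrow(mask))
  cc <- pmin(pmax(round(table$centroid_x_um / um_per_pixel) + 1L, 1L),
             ncol(mask))
  mask[cbind(rr, cc)]
}
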