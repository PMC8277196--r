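#' Particle analysis of a thresholded mask
#'
#' One row per connected component of the foreground, with its area in square
#' microns, intensity-free centroid in microns from the image origin (pixel
#' centres; origin at the centre of pixel `[1, 1]` is `(0, 0)`), and the
#' equivalent circular diameter `2 * sqrt(area / pi)`.
#'
#' @param mask A `binary_mask` (see [threshold_image()]).
#' @param connectivity 4 or 8 (default 8).
#' @param min_area_um2 Components below this area are dropped. Default 0
#'   (keep everything, as the size-class schemes bin even the smallest
#'   puncta).
#' @return A `puncta_table`: a tibble with columns `label`, `area_um2`,
#'   `centroid_x_um`, `centroid_y_um`, `equivalent_diameter_um` and an
#'   attached `label_matrix` attribute mapping pixels to rows (used by
#'   punctum-restricted colocalization).
#' @export
analyze_particles <- function(mask, connectivity = 8, min_area_um2 = 0) {
  if (!inherits(mask, "binary_mask")) {
    abort("`mask` must be a binary_mask (see `threshold_image()`).")
  }
  if (min_area_um2 < 0) abort("`min_area_um2` must be non-negative.")
  labels <- label_components(mask$mask, connectivity)
  upx <- mask$um_per_pixel
  n_lab <- max(labels)
  if (n_lab == 0L) {
    return(new_puncta_table(empty_puncta_rows(), labels, upx, connectivity,
                            min_area_um2))
  }
  fg <- which(labels > 0L)
  lab <- labels[fg]
  nr <- nrow(labels)
  px_row <- ((fg - 1L) %% nr) + 1L
  px_col <- ((fg - 1L) %/% nr) + 1L
  n_px <- tabulate(lab, nbins = n_lab)
  # x along columns, y along rows; pixel centre (r, c) -> ((c-1)*s, (r-1)*s)
  cx <- (tapply(px_col, lab, sum) / n_px - 1) * upx
  cy <- (tapply(px_row, lab, sum) / n_px - 1) * upx
  tab <- tibble(
    label = seq_len(n_lab),
    area_um2 = n_px * upx^2,
    centroid_x_um = as.numeric(cx),
    centroid_y_um = as.numeric(cy),
    equivalent_diameter_um = 2 * sqrt(n_px * upx^2 / pi)
  )
  keep <- tab$area_um2 >= min_area_um2
  if (!all(keep)) {
    labels[labels %in% tab$label[!keep]] <- 0L
    tab <- tab[keep, , drop = FALSE]
    tab$label <- seq_len(nrow(tab))
    labels <- relabel_sequential(labels)
  }
  new_puncta_table(tab, labels, upx, connectivity, min_area_um2)
}

empty_puncta_rows <- function() {
  tibble(label = integer(), area_um2 = numeric(),
         centroid_x_um = numeric(), centroid_y_um = numeric(),
         equivalent_diameter_um = numeric())
}

relabel_sequential <- function(labels) {
  u <- sort(unique(labels[labels > 0L]))
  if (length(u) == 0L) return(labels)
  lut <- integer(max(u)); lut[u] <- seq_along(u)
  out <- labels
  out[out > 0L] <- lut[out[out > 0L]]
  out
}

new_puncta_table <- function(tab, label_matrix, um_per_pixel, connectivity,
                             min_area_um2, provenance = NULL) {
  structure(
    tab,
    label_matrix = label_matrix,
    um_per_pixel = um_per_pixel,
    connectivity = connectivity,
    min_area_um2 = min_area_um2,
    provenance = provenance,
    class = c("puncta_table", class(tibble())))
}

#' Write a puncta table as CSV with a provenance sidecar
#'
#' @param table A `puncta_table`.
#' @param path Output CSV path; a `<path>.provenance.json` sidecar records
#'   the parameters that produced the table.
#' @return `path`, invisibly.
#' @export
write_puncta_csv <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  prov <- attr(table, "provenance")
  meta <- list(
    um_per_pixel = attr(table, "um_per_pixel"),
    connectivity = attr(table, "connectivity"),
    min_area_um2 = attr(table, "min_area_um2"),
    provenance = prov
  )
  jsonlite::write_json(meta, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
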