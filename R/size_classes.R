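#' Convert punctum diameter to projected area
#'
#' `pi * (d/2)^2`, linking the conventional vesicle diameters to the areas a
#' 2-D projection reports: a 0.5-1.5 um diameter autophagosome corresponds to
#' 0.196-1.767 um^2 of projected area.
#'
#' @param diameter_um Positive diameter(s), microns.
#' @return Area(s) in square microns.
#' @examples
#' round(diameter_to_area(c(0.5, 1.5)), 3)
#' @export
diameter_to_area <- function(diameter_um) {
  if (any(!is.finite(diameter_um)) || any(diameter_um <= 0)) {
    abort("`diameter_um` must be positive and finite.")
  }
  pi * (diameter_um / 2)^2
}

#' @rdname diameter_to_area
#' @param area_um2 Positive area(s), square microns.
#' @export
area_to_diameter <- function(area_um2) {
  if (any(!is.finite(area_um2)) || any(area_um2 <= 0)) {
    abort("`area_um2` must be positive and finite.")
  }
  2 * sqrt(area_um2 / pi)
}

#' Vesicle size-class schemes
#'
#' A size-class scheme is an ordered, non-overlapping set of area bins whose
#' union covers `(0, Inf)`; each puncta table row falls in exactly one class.
#' Bin-edge convention: named ranges quoted with a dash (0.196-1.767,
#' 0.03-0.5) include both printed bounds; ">x" classes are strictly open
#' below; all other (ladder) bins are half-open `(lower, upper]` so that the
#' scheme is an exact partition.
#'
#' Built-in schemes, per marker context:
#' \describe{
#'   \item{`lc3b`, `becn1`}{phagophore `(0, 0.196)`, autophagosome
#'     `[0.196, 1.767]` (0.5-1.5 um diameter), a 1-um^2 ladder up to 10, and
#'     amphisome-candidate `> 10`.}
#'   \item{`lamp1`}{`(0, 0.03)`, lysosome `[0.03, 0.5]`, a 0.1-um^2 ladder up
#'     to 1, and `> 1`.}
#'   \item{`ladder1`}{plain 1-um^2 ladder `(0,1], (1,2], ..., > 10`.}
#'   \item{`ladder01`}{plain 0.1-um^2 ladder up to `> 1`.}
#' }
#'
#' @param name One of `"lc3b"`, `"becn1"`, `"lamp1"`, `"ladder1"`,
#'   `"ladder01"`.
#' @return A `size_scheme`: a tibble with columns `class`, `lower_um2`,
#'   `upper_um2` (`Inf` for the open terminal class), `lower_closed`,
#'   `upper_closed`, plus a `marker_context` attribute.
#' @examples
#' size_scheme("lc3b")
#' @export
size_scheme <- function(name = c("lc3b", "becn1", "lamp1", "ladder1",
                                 "ladder01")) {
  name <- match.arg(name)
  sch <- switch(
    name,
    lc3b = ,
    becn1 = {
      ladder <- ladder_bins(1.767, 10, 1)
      bind_rows(
        bin_row("phagophore", 0, 0.196, FALSE, FALSE),
        bin_row("autophagosome", 0.196, 1.767, TRUE, TRUE),
        ladder,
        bin_row("amphisome_candidate", 10, Inf, FALSE, FALSE)
      )
    },
    lamp1 = {
      ladder <- ladder_bins(0.5, 1, 0.1)
      bind_rows(
        bin_row("sub_lysosome", 0, 0.03, FALSE, FALSE),
        bin_row("lysosome", 0.03, 0.5, TRUE, TRUE),
        ladder,
        bin_row("gt_1", 1, Inf, FALSE, FALSE)
      )
    },
    ladder1 = bind_rows(ladder_bins(0, 10, 1),
                        bin_row("gt_10", 10, Inf, FALSE, FALSE)),
    ladder01 = bind_rows(ladder_bins(0, 1, 0.1),
                         bin_row("gt_1", 1, Inf, FALSE, FALSE))
  )
  new_size_scheme(sch, marker_context = toupper(name))
}

bin_row <- function(class, lower, upper, lc, uc) {
  tibble(class = class, lower_um2 = lower, upper_um2 = upper,
         lower_closed = lc, upper_closed = uc)
}

# half-open (a, b] ladder bins of the given width between `from` and `to`
ladder_bins <- function(from, to, width) {
  lows <- seq(from, to - width, by = width)
  # guard against floating-point shortfall of seq()
  lows <- round(lows, 10)
  ups <- round(lows + width, 10)
  ups[length(ups)] <- to
  tibble(class = sprintf("(%g,%g]", lows, ups),
         lower_um2 = lows, upper_um2 = ups,
         lower_closed = FALSE, upper_closed = TRUE)
}

#' Build a custom size-class scheme
#'
#' @param bins Data frame with columns `class`, `lower_um2`, `upper_um2` and
#'   optionally `lower_closed`/`upper_closed` (default half-open
#'   `(lower, upper]`).
#' @param marker_context Free-form marker label recorded with the scheme.
#' @return A validated `size_scheme`.
#' @export
size_scheme_custom <- function(bins, marker_context = "custom") {
  bins <- as_tibble(bins)
  if (!"lower_closed" %in% names(bins)) bins$lower_closed <- FALSE
  if (!"upper_closed" %in% names(bins)) bins$upper_closed <- TRUE
  bins$upper_closed[is.infinite(bins$upper_um2)] <- FALSE
  new_size_scheme(bins[, c("class", "lower_um2", "upper_um2",
                           "lower_closed", "upper_closed")],
                  marker_context)
}

new_size_scheme <- function(bins, marker_context) {
  bins <- arrange(bins, .data$lower_um2)
  validate_size_scheme(bins)
  structure(bins, marker_context = marker_context,
            class = c("size_scheme", class(tibble())))
}

# partition check: ordered bins must tile (0, Inf) with no gap or overlap
validate_size_scheme <- function(bins) {
  need <- c("class", "lower_um2", "upper_um2", "lower_closed", "upper_closed")
  if (!all(need %in% names(bins))) {
    abort("scheme needs columns class, lower_um2, upper_um2, lower_closed, upper_closed.")
  }
  if (anyDuplicated(bins$class)) abort("class names must be unique.")
  if (any(bins$upper_um2 <= bins$lower_um2)) {
    abort("every bin needs lower_um2 < upper_um2.")
  }
  if (bins$lower_um2[1] != 0 || bins$lower_closed[1]) {
    abort("the first bin must open at (0, ...: areas are strictly positive.")
  }
  n <- nrow(bins)
  if (!is.infinite(bins$upper_um2[n])) {
    abort("the last bin must be open-ended (upper_um2 = Inf).")
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      if (!isTRUE(all.equal(bins$upper_um2[i], bins$lower_um2[i + 1]))) {
        abort(sprintf("gap or overlap between bins %d and %d.", i, i + 1))
      }
      # exactly one of the touching edges may be closed
      if (bins$upper_closed[i] == bins$lower_closed[i + 1]) {
        abort(sprintf(
          "edge %g must be claimed by exactly one of bins %d and %d.",
          bins$upper_um2[i], i, i + 1))
      }
    }
  }
  invisible(bins)
}

#' Read size-class schemes from YAML
#'
#' Each document maps a scheme name to a list of bins
#' (`class`, `lower_um2`, `upper_um2`, optional closedness flags).
#'
#' @param path YAML file path.
#' @return Named list of `size_scheme` objects.
#' @export
read_schemes_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(sch) {
    bins <- bind_rows(lapply(sch$bins, function(b) {
      tibble(class = b$class,
             lower_um2 = b$lower_um2,
             upper_um2 = if (is.null(b$upper_um2)) Inf else b$upper_um2,
             lower_closed = isTRUE(b$lower_closed),
             upper_closed = if (is.null(b$upper_closed)) NA else
               isTRUE(b$upper_closed))
    }))
    bins$upper_closed[is.na(bins$upper_closed)] <-
      !is.infinite(bins$upper_um2[is.na(bins$upper_closed)])
    size_scheme_custom(bins, marker_context = sch$marker_context %||% "custom")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign puncta to size classes
#'
#' Bins every punctum area into exactly one class of a partitioning scheme
#' and returns the per-class counts (a size profile).
#'
#' @param table A `puncta_table` (or any data frame with an `area_um2`
#'   column).
#' @param scheme A `size_scheme`.
#' @param cell_id Optional cell identifier carried into the profile.
#' @return A `size_profile` tibble: columns `class`, `lower_um2`,
#'   `upper_um2`, `n`; attributes `total` and `cell_id`.
#' @export
classify_puncta <- function(table, scheme = size_scheme("lc3b"),
                            cell_id = NA_character_) {
  if (!inherits(scheme, "size_scheme")) {
    abort("`scheme` must be a size_scheme.")
  }
  areas <- table$area_um2
  if (any(areas <= 0)) abort("punctum areas must be strictly positive.")
  idx <- assign_bins(areas, scheme)
  if (any(is.na(idx))) abort("punctum area outside scheme coverage.")
  counts <- tabulate(idx, nbins = nrow(scheme))
  out <- tibble(class = scheme$class,
                lower_um2 = scheme$lower_um2,
                upper_um2 = scheme$upper_um2,
                n = counts)
  structure(out, total = length(areas), cell_id = cell_id,
            marker_context = attr(scheme, "marker_context"),
            class = c("size_profile", class(tibble())))
}

assign_bins <- function(areas, scheme) {
  idx <- rep(NA_integer_, length(areas))
  for (i in seq_len(nrow(scheme))) {
    lo <- scheme$lower_um2[i]; up <- scheme$upper_um2[i]
    in_lo <- if (scheme$lower_closed[i]) areas >= lo else areas > lo
    in_up <- if (scheme$upper_closed[i]) areas <= up else areas < up
    idx[is.na(idx) & in_lo & in_up] <- i
  }
  idx
}

#' Count puncta in an area range
#'
#' Default closedness follows the reporting conventions: a bounded range
#' `[lower, upper)` is closed below and open above, while an unbounded range
#' (`upper = Inf`) is strictly open below, matching ">x um^2" classes.
#'
#' @param table A `puncta_table` or data frame with `area_um2`.
#' @param lower_um2,upper_um2 Range bounds; `upper_um2 = Inf` for ">lower".
#' @param lower_closed,upper_closed Override the edge conventions.
#' @return Integer count.
#' @examples
#' tab <- tibble::tibble(area_um2 = c(9.9, 10.1, 12))
#' count_in_range(tab, 10)          # "> 10": 2
#' @export
count_in_range <- function(table, lower_um2, upper_um2 = Inf,
                           lower_closed = is.finite(upper_um2),
                           upper_closed = FALSE) {
  if (lower_um2 >= upper_um2) abort("need lower_um2 < upper_um2.")
  a <- table$area_um2
  in_lo <- if (lower_closed) a >= lower_um2 else a > lower_um2
  in_up <- if (upper_closed) a <= upper_um2 else a < upper_um2
  sum(in_lo & in_up)
}

#' @export
print.size_profile <- function(x, ...) {
  cat(sprintf("<size_profile> %s, cell %s, %d puncta\n",
              attr(x, "marker_context") %||% "?", attr(x, "cell_id"),
              attr(x, "total")))
  NextMethod()
}

#' Plot a size profile
#'
#' Bar chart of puncta counts per size class, mirroring size-distribution
#' figures.
#'
#' @param object A `size_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.size_profile <- function(object, ...) {
  df <- as_tibble(object)
  df$class <- factor(df$class, levels = df$class)
  ggplot(df, aes(x = .data$class, y = .data$n)) +
    geom_col(fill = "grey35") +
    labs(x = "size class (um^2)", y = "puncta count",
         title = sprintf("Puncta size profile (%s)",
                         attr(object, "marker_context") %||% "")) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
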