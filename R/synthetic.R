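#' Acquisition parameters for synthetic confocal stacks
#'
#' Defaults reproduce the imaging setup the package emulates: a 15-slice
#' z-stack at 1 um spacing through the cell. The pixel grid (0.15 um/px,
#' 640 x 640 px = 96 x 96 um) comfortably holds a 75-um oocyte. The lateral
#' PSF sigma defaults to 0.05 um — tighter than a diffraction-limited 60x
#' objective (~0.09 um) — so rendered puncta stay area-true; raise it for
#' optically softer fixtures. Noise defaults to Poisson shot noise plus
#' Gaussian read noise; `"none"` gives noiseless fixtures.
#'
#' @param um_per_pixel Microns per pixel.
#' @param image_size_px `c(rows, cols)` of each slice.
#' @param n_slices Number of z slices.
#' @param slice_spacing_um Axial spacing, microns.
#' @param psf_sigma_um Lateral Gaussian blur sigma, microns.
#' @param axial_sigma_um Axial attenuation sigma for off-home slices,
#'   microns.
#' @param background_level Background intensity, arbitrary units.
#' @param noise_model `"both"`, `"gaussian"`, `"poisson"` or `"none"`.
#' @param noise_scale Gaussian read-noise standard deviation.
#' @return An `acquisition_params` list.
#' @export
acquisition_params <- function(um_per_pixel = 0.15,
                               image_size_px = c(640, 640),
                               n_slices = 15,
                               slice_spacing_um = 1,
                               psf_sigma_um = 0.05,
                               axial_sigma_um = 0.75,
                               background_level = 5,
                               noise_model = c("both", "gaussian", "poisson",
                                               "none"),
                               noise_scale = 2) {
  noise_model <- match.arg(noise_model)
  if (um_per_pixel <= 0) abort("`um_per_pixel` must be positive.")
  if (any(image_size_px < 8)) abort("`image_size_px` must be positive (>= 8).")
  if (n_slices < 1 || slice_spacing_um <= 0) {
    abort("need n_slices >= 1 and positive slice spacing.")
  }
  if (noise_scale < 0) abort("`noise_scale` must be non-negative.")
  structure(list(um_per_pixel = um_per_pixel,
                 image_size_px = as.integer(image_size_px),
                 n_slices = as.integer(n_slices),
                 slice_spacing_um = slice_spacing_um,
                 psf_sigma_um = psf_sigma_um,
                 axial_sigma_um = axial_sigma_um,
                 background_level = background_level,
                 noise_model = noise_model,
                 noise_scale = noise_scale),
            class = "acquisition_params")
}

#' Punctum population specification
#'
#' A mixture over area ranges: each row plants `n` puncta with areas drawn
#' log-uniformly from `[lower_um2, upper_um2]` at the given peak intensity.
#' The default emulates the observed vesicle populations: many small
#' lysosome-sized puncta (0.03-0.5 um^2), a band of autophagosome-sized
#' puncta (0.196-1.767 um^2), and a few large (>10 um^2) structures. The
#' peak intensity is constant by default so that a single fixed threshold
#' means the same thing for every punctum.
#'
#' @param n Integer vector, puncta per mixture component.
#' @param lower_um2,upper_um2 Area range per component, square microns.
#' @param peak_intensity Peak intensity per component (recycled).
#' @return A `puncta_spec` tibble.
#' @export
puncta_spec <- function(n = c(120, 40, 3),
                        lower_um2 = c(0.03, 0.196, 10.5),
                        upper_um2 = c(0.5, 1.767, 14),
                        peak_intensity = 200) {
  if (any(n < 0) || any(n != round(n))) abort("`n` must be non-negative integers.")
  if (any(lower_um2 <= 0) || any(upper_um2 < lower_um2)) {
    abort("need 0 < lower_um2 <= upper_um2.")
  }
  structure(tibble(n = as.integer(n), lower_um2 = lower_um2,
                   upper_um2 = upper_um2,
                   peak_intensity = rep(peak_intensity, length.out = length(n))),
            class = c("puncta_spec", class(tibble())))
}

# run expr with a local, restorable RNG state
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Uniform points in a disc
#'
#' @param n Number of points.
#' @param radius Disc radius.
#' @param center Disc centre `(x, y)`.
#' @return Tibble with columns `x`, `y`.
#' @export
sample_disc_uniform <- function(n, radius, center = c(0, 0)) {
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  tibble(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
}

# uniform point in the annulus [r0, r1] around `center`
sample_annulus <- function(n, r0, r1, center = c(0, 0)) {
  r <- sqrt(runif(n, r0^2, r1^2))
  th <- runif(n, 0, 2 * pi)
  tibble(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
}

#' Generate a synthetic single-cell z-stack with ground truth
#'
#' Renders a disc-shaped cell body (default diameter 75 um) with a nucleus
#' and bright cytoplasmic puncta on a noisy background, as a z-stack. Each
#' punctum is a Gaussian-blurred hard disc of known equivalent area assigned
#' to a home slice, with intensity attenuating in neighbouring slices by the
#' axial PSF — so the overlay-projection stage is exercised nontrivially.
#' The returned ground truth records, per punctum, both the analytic area
#' `pi r^2` and the rendered pixel area (which differ by discretization).
#'
#' @param truth_spec A [puncta_spec()].
#' @param acq An [acquisition_params()].
#' @param seed Integer seed; identical `(spec, seed)` give bit-identical
#'   output.
#' @param cell_diameter_um,nucleus_diameter_um Cell and nucleus diameters.
#' @param cell_intensity Added intensity of the cell body over background.
#' @param channel_id Channel label on the rendered slices.
#' @param placement `"cytoplasm"` (default: puncta fit between nucleus and
#'   cell edge), or `"uniform"` (centroids uniform over the whole cell disc,
#'   for spatial-statistics fixtures).
#' @param min_separation_um Minimum edge-to-edge distance between puncta.
#' @return List with `stack` (list of `calibrated_image` slices) and `truth`
#'   (a `ground_truth` tibble with cell geometry attributes).
#' @export
generate_cell <- function(truth_spec = puncta_spec(),
                          acq = acquisition_params(),
                          seed = 1L,
                          cell_diameter_um = 75,
                          nucleus_diameter_um = 25,
                          cell_intensity = 10,
                          channel_id = "ch1",
                          placement = c("cytoplasm", "uniform"),
                          min_separation_um = 0.5) {
  placement <- match.arg(placement)
  with_local_seed(seed, {
    truth <- sample_truth(truth_spec, acq, cell_diameter_um,
                          nucleus_diameter_um, channel_id, placement,
                          min_separation_um, seed)
    rendered <- render_stack(truth, acq, cell_intensity, channel_id)
    list(stack = rendered$slices, truth = rendered$truth)
  })
}

sample_truth <- function(truth_spec, acq, cell_diameter_um,
                         nucleus_diameter_um, channel_id, placement,
                         min_separation_um, seed) {
  if (cell_diameter_um <= nucleus_diameter_um) {
    abort("cell diameter must exceed nucleus diameter.")
  }
  fov <- (acq$image_size_px - 1) * acq$um_per_pixel
  center <- c(x = fov[2] / 2, y = fov[1] / 2)
  cell_r <- cell_diameter_um / 2
  nuc_r <- nucleus_diameter_um / 2
  if (2 * cell_r > min(fov)) abort("cell does not fit in the field of view.")
  rows <- as_tibble(truth_spec)[rep(seq_len(nrow(truth_spec)),
                                    truth_spec$n), ]
  n_tot <- nrow(rows)
  if (n_tot == 0L) {
    return(new_ground_truth(empty_truth_rows(), center, cell_r, nuc_r, seed,
                            acq))
  }
  radius <- sqrt(exp(runif(n_tot, log(rows$lower_um2), log(rows$upper_um2))) /
                   pi)
  if (placement == "cytoplasm" && any(nuc_r + radius > cell_r - radius)) {
    abort("a requested punctum cannot fit between nucleus and cell edge.")
  }
  if (placement == "uniform" && any(radius >= cell_r)) {
    abort("a requested punctum cannot fit inside the cell.")
  }
  pts <- place_puncta(radius, center, cell_r, nuc_r, placement,
                      min_separation_um)
  tr <- tibble(
    id = seq_len(n_tot),
    x_um = pts$x, y_um = pts$y,
    radius_um = radius,
    area_um2 = pi * radius^2,
    rendered_area_um2 = NA_real_,
    peak_intensity = rows$peak_intensity,
    channel_id = channel_id,
    home_slice = sample.int(acq$n_slices, n_tot, replace = TRUE),
    shared = FALSE,
    in_band = NA
  )
  new_ground_truth(tr, center, cell_r, nuc_r, seed, acq)
}

# rejection-sample punctum centres; largest first so crowding resolves
place_puncta <- function(radius, center, cell_r, nuc_r, placement,
                         min_sep, max_tries = 5000L) {
  ord <- order(radius, decreasing = TRUE)
  n <- length(radius)
  x <- numeric(n); y <- numeric(n)
  placed <- integer(0)
  for (i in ord) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      p <- if (placement == "cytoplasm") {
        sample_annulus(1, nuc_r + radius[i], cell_r - radius[i],
                       c(center[["x"]], center[["y"]]))
      } else {
        sample_disc_uniform(1, cell_r, c(center[["x"]], center[["y"]]))
      }
      if (length(placed) > 0) {
        d <- sqrt((p$x - x[placed])^2 + (p$y - y[placed])^2)
        if (any(d < radius[i] + radius[placed] + min_sep)) next
      }
      x[i] <- p$x; y[i] <- p$y; ok <- TRUE; break
    }
    if (!ok) abort("could not place all puncta without overlap; reduce counts or sizes.")
    placed <- c(placed, i)
  }
  tibble(x = x, y = y)
}

empty_truth_rows <- function() {
  tibble(id = integer(), x_um = numeric(), y_um = numeric(),
         radius_um = numeric(), area_um2 = numeric(),
         rendered_area_um2 = numeric(), peak_intensity = numeric(),
         channel_id = character(), home_slice = integer(),
         shared = logical(), in_band = logical())
}

new_ground_truth <- function(tr, center, cell_r, nuc_r, seed, acq) {
  structure(tr,
            cell_center_um = center,
            cell_radius_um = cell_r,
            nucleus_center_um = center,
            nucleus_radius_um = nuc_r,
            seed = seed,
            acquisition = acq,
            class = c("ground_truth", class(tibble())))
}

# render slices: cell body + puncta discs, lateral blur, then noise
render_stack <- function(truth, acq, cell_intensity, channel_id) {
  nr <- acq$image_size_px[1]; nc <- acq$image_size_px[2]
  upx <- acq$um_per_pixel
  center <- attr(truth, "cell_center_um")
  cell_r <- attr(truth, "cell_radius_um")
  xs <- (seq_len(nc) - 1) * upx
  ys <- (seq_len(nr) - 1) * upx
  cell_disc <- outer(ys - center[["y"]], xs - center[["x"]],
                     function(dy, dx) dx^2 + dy^2 <= cell_r^2)
  base <- acq$background_level + cell_intensity * cell_disc
  sigma_px <- acq$psf_sigma_um / upx
  # per-punctum hard-disc pixel sets (local windows); at least one pixel
  disc_px <- vector("list", nrow(truth))
  if (nrow(truth) > 0) {
    for (i in seq_len(nrow(truth))) {
      disc_px[[i]] <- punctum_pixels(truth$x_um[i], truth$y_um[i],
                                     truth$radius_um[i], upx, nr, nc)
    }
    truth$rendered_area_um2 <- vapply(disc_px, nrow, 1L) * upx^2
  }
  slices <- vector("list", acq$n_slices)
  for (s in seq_len(acq$n_slices)) {
    px <- base
    if (nrow(truth) > 0) {
      dz <- (s - truth$home_slice) * acq$slice_spacing_um
      att <- exp(-dz^2 / (2 * acq$axial_sigma_um^2))
      for (i in which(att > 1e-4)) {
        idx <- disc_px[[i]]
        px[cbind(idx$row, idx$col)] <-
          px[cbind(idx$row, idx$col)] + truth$peak_intensity[i] * att[i]
      }
    }
    if (sigma_px > 0) px <- gblur(px, sigma = sigma_px)
    px <- add_noise(px, acq)
    px[px < 0] <- 0
    slices[[s]] <- calibrate(px, upx, channel_id)
  }
  attr(slices, "cell_mask") <- cell_disc
  list(slices = slices, truth = truth)
}

punctum_pixels <- function(x_um, y_um, r_um, upx, nr, nc) {
  c0 <- x_um / upx + 1; r0 <- y_um / upx + 1
  rad <- r_um / upx
  rows <- max(1L, floor(r0 - rad - 1)):min(nr, ceiling(r0 + rad + 1))
  cols <- max(1L, floor(c0 - rad - 1)):min(nc, ceiling(c0 + rad + 1))
  grid <- expand.grid(row = rows, col = cols)
  inside <- (grid$row - r0)^2 + (grid$col - c0)^2 <= rad^2
  if (!any(inside)) {
    # sub-pixel punctum: light the nearest pixel so it is still rendered
    grid <- grid[which.min((grid$row - r0)^2 + (grid$col - c0)^2), ,
                 drop = FALSE]
  } else {
    grid <- grid[inside, , drop = FALSE]
  }
  as_tibble(grid)
}

add_noise <- function(px, acq) {
  switch(acq$noise_model,
         none = px,
         gaussian = px + rnorm(length(px), 0, acq$noise_scale),
         poisson = matrix(rpois(length(px), pmax(px, 0)), nrow(px), ncol(px)),
         both = matrix(rpois(length(px), pmax(px, 0)), nrow(px), ncol(px)) +
           rnorm(length(px), 0, acq$noise_scale))
}

#' Generate a two-channel stack with a controlled colocalized fraction
#'
#' A fraction of the puncta is placed at identical coordinates in both
#' channels ("shared"); the remainder is placed independently per channel.
#' The ground truth tags each punctum as shared or channel-private, so the
#' Pearson response to the colocalized fraction can be benchmarked.
#'
#' @param coloc_fraction Fraction in `[0, 1]` of puncta shared across
#'   channels.
#' @param truth_spec A [puncta_spec()] for the total per-channel population.
#' @param acq An [acquisition_params()].
#' @param seed Integer seed.
#' @inheritParams generate_cell
#' @return List with `channels` (named list of two slice lists) and `truth`
#'   (rows for both channels; shared puncta appear once per channel at the
#'   same coordinates).
#' @export
generate_correlated_pair <- function(coloc_fraction,
                                     truth_spec = puncta_spec(),
                                     acq = acquisition_params(),
                                     seed = 1L,
                                     cell_diameter_um = 75,
                                     nucleus_diameter_um = 25,
                                     cell_intensity = 10,
                                     min_separation_um = 0.5) {
  if (!is.numeric(coloc_fraction) || coloc_fraction < 0 ||
      coloc_fraction > 1) {
    abort("`coloc_fraction` must lie in [0, 1].")
  }
  with_local_seed(seed, {
    full <- sample_truth(truth_spec, acq, cell_diameter_um,
                         nucleus_diameter_um, "ch1", "cytoplasm",
                         min_separation_um, seed)
    n <- nrow(full)
    n_shared <- round(coloc_fraction * n)
    shared_ids <- if (n_shared > 0) sort(sample.int(n, n_shared)) else
      integer(0)
    # channel-private replacements for the non-shared puncta of channel 2
    priv2 <- sample_truth(truth_spec, acq, cell_diameter_um,
                          nucleus_diameter_um, "ch2", "cytoplasm",
                          min_separation_um, seed)
    t1 <- full
    t1$shared <- t1$id %in% shared_ids
    t2 <- priv2
    t2$shared <- FALSE
    if (n_shared > 0) {
      keep <- t1$id %in% shared_ids
      t2[keep, c("x_um", "y_um", "radius_um", "area_um2", "peak_intensity",
                 "home_slice")] <-
        t1[keep, c("x_um", "y_um", "radius_um", "area_um2", "peak_intensity",
                   "home_slice")]
      t2$shared[keep] <- TRUE
    }
    r1 <- render_stack(t1, acq, cell_intensity, "ch1")
    r2 <- render_stack(t2, acq, cell_intensity, "ch2")
    truth <- bind_rows(as_tibble(r1$truth), as_tibble(r2$truth))
    truth <- new_ground_truth(truth, attr(full, "cell_center_um"),
                              attr(full, "cell_radius_um"),
                              attr(full, "nucleus_radius_um"), seed, acq)
    list(channels = list(ch1 = r1$slices, ch2 = r2$slices), truth = truth)
  })
}

#' Generate a cell with peripherally biased large puncta
#'
#' Plants `n_large_puncta` large (>10 um^2) puncta; each has probability
#' `peripheral_bias` of being placed with its centroid inside the outer
#' `band_width_um` of the cell, emulating the peripheral accumulation of
#' large puncta seen in aged cells. Small background puncta are added from
#' `small_spec`. Ground truth records band membership per punctum.
#'
#' @param n_large_puncta Number of large puncta.
#' @param peripheral_bias Probability in `[0, 1]` that a large punctum is
#'   peripheral.
#' @param acq An [acquisition_params()].
#' @param seed Integer seed.
#' @param band_width_um Peripheral band width (default 10 um).
#' @param large_area_um2 Area range for the large puncta.
#' @param small_spec A [puncta_spec()] for background puncta (default a
#'   small lysosome-sized population); use `puncta_spec(n = 0)` for none.
#' @inheritParams generate_cell
#' @return List with `stack` and `truth` (column `in_band` filled for every
#'   punctum).
#' @export
generate_peripheral_cohort <- function(n_large_puncta, peripheral_bias,
                                       acq = acquisition_params(),
                                       seed = 1L,
                                       band_width_um = 10,
                                       large_area_um2 = c(10.5, 14),
                                       small_spec = puncta_spec(n = 30,
                                                               lower_um2 = 0.1,
                                                               upper_um2 = 0.5),
                                       cell_diameter_um = 75,
                                       nucleus_diameter_um = 25,
                                       cell_intensity = 10,
                                       min_separation_um = 0.5) {
  if (peripheral_bias < 0 || peripheral_bias > 1) {
    abort("`peripheral_bias` must lie in [0, 1].")
  }
  cell_r <- cell_diameter_um / 2
  if (band_width_um >= cell_r) {
    abort("band width must be smaller than the cell radius.")
  }
  with_local_seed(seed, {
    base <- sample_truth(small_spec, acq, cell_diameter_um,
                         nucleus_diameter_um, "ch1", "cytoplasm",
                         min_separation_um, seed)
    center <- attr(base, "cell_center_um")
    radius <- sqrt(exp(runif(n_large_puncta, log(large_area_um2[1]),
                             log(large_area_um2[2]))) / pi)
    is_band <- runif(n_large_puncta) < peripheral_bias
    pts <- vector("list", n_large_puncta)
    for (i in seq_len(n_large_puncta)) {
      # keep the whole punctum inside the cell; centroid inside/outside band
      pts[[i]] <- if (is_band[i]) {
        sample_annulus(1, cell_r - band_width_um,
                       cell_r - radius[i], c(center[["x"]], center[["y"]]))
      } else {
        sample_annulus(1, nucleus_diameter_um / 2 + radius[i],
                       cell_r - band_width_um, c(center[["x"]], center[["y"]]))
      }
    }
    pts <- bind_rows(pts)
    large <- tibble(
      id = max(base$id, 0L) + seq_len(n_large_puncta),
      x_um = pts$x, y_um = pts$y, radius_um = radius,
      area_um2 = pi * radius^2, rendered_area_um2 = NA_real_,
      peak_intensity = 200, channel_id = "ch1",
      home_slice = sample.int(acq$n_slices, n_large_puncta, replace = TRUE),
      shared = FALSE, in_band = is_band)
    dist_c <- sqrt((base$x_um - center[["x"]])^2 +
                     (base$y_um - center[["y"]])^2)
    base$in_band <- dist_c > cell_r - band_width_um
    truth <- new_ground_truth(bind_rows(as_tibble(base), large), center,
                              cell_r, nucleus_diameter_um / 2, seed, acq)
    rendered <- render_stack(truth, acq, cell_intensity, "ch1")
    list(stack = rendered$slices, truth = rendered$truth)
  })
}
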