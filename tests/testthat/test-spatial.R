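test_that("cell-mask estimation recovers a planted disc geometry", {
  sim <- small_cell(seed = 19)
  geom <- estimate_cell_mask(overlay_stack(sim$stack))
  expect_equal(geom$equivalent_radius_um, 20, tolerance = 0.02)
  cc <- attr(sim$truth, "cell_center_um")
  expect_equal(unname(geom$centroid_um[["x"]]), unname(cc[["x"]]),
               tolerance = 0.05)
  # blank image errors
  expect_error(estimate_cell_mask(calibrate(matrix(3, 32, 32), 1)), "blank")
  # user-supplied mask is honoured verbatim
  g <- circular_cell_geometry(c(20, 20), 10, 0.5, c(80, 80))
  expect_equal(g$equivalent_radius_um, 10, tolerance = 0.02)
})

test_that("the peripheral band matches the analytic annulus and stays inside the cell", {
  g <- circular_cell_geometry(c(30, 30), 20, 0.25, c(240, 240))
  gb <- peripheral_band(g, 10)
  band_area <- sum(gb$band_mask) * 0.25^2
  expect_equal(band_area, pi * (20^2 - 10^2), tolerance = 0.03)
  expect_true(all(g$cell_mask[gb$band_mask]))      # band subset of cell
  # band via erosion equals band via distance transform (oracle)
  dist_px <- EBImage::distmap(g$cell_mask * 1)
  band_dt <- g$cell_mask & dist_px <= 10 / 0.25
  expect_gt(sum(gb$band_mask & band_dt) / sum(gb$band_mask | band_dt), 0.98)
  # limits: tiny width -> near-empty band; width ~ radius rejected
  tiny <- peripheral_band(g, 0.05)
  expect_equal(sum(tiny$band_mask), 0)
  expect_error(peripheral_band(g, 25), "radius")
  wide <- peripheral_band(g, 19.9)
  expect_gt(sum(wide$band_mask) / sum(g$cell_mask), 0.98)
})

test_that("peripheral fraction handles degenerate and missing cases", {
  g <- peripheral_band(circular_cell_geometry(c(20, 20), 15, 0.5, c(80, 80)),
                       10)
  # all large puncta planted in the band -> fraction 1
  ring <- tibble::tibble(label = 1:4, area_um2 = rep(12, 4),
                         centroid_x_um = c(20, 20, 6.5, 33.5),
                         centroid_y_um = c(6.5, 33.5, 20, 20),
                         equivalent_diameter_um = rep(2, 4))
  res <- peripheral_fraction(ring, g)
  expect_equal(res$fraction, 1)
  # no large puncta -> NA, never zero
  small <- tibble::tibble(label = 1L, area_um2 = 0.4,
                          centroid_x_um = 20, centroid_y_um = 20,
                          equivalent_diameter_um = 0.7)
  expect_true(is.na(peripheral_fraction(small, g)$fraction))
  # centre punctum is not peripheral
  centre <- tibble::tibble(label = 1L, area_um2 = 12, centroid_x_um = 20,
                           centroid_y_um = 20, equivalent_diameter_um = 4)
  expect_equal(peripheral_fraction(centre, g)$fraction, 0)
})

test_that("peripheral fraction is invariant to translation and 90-degree rotation", {
  set.seed(33)
  pts <- sample_disc_uniform(60, 14, c(20, 20))
  tab <- tibble::tibble(label = 1:60, area_um2 = rep(12, 60),
                        centroid_x_um = pts$x, centroid_y_um = pts$y,
                        equivalent_diameter_um = 4)
  g <- peripheral_band(circular_cell_geometry(c(20, 20), 15, 0.5, c(90, 90)),
                       5)
  f0 <- peripheral_fraction(tab, g)$fraction
  # translate field and geometry together
  tab_t <- dplyr::mutate(tab, centroid_x_um = centroid_x_um + 3,
                         centroid_y_um = centroid_y_um + 2)
  g_t <- peripheral_band(circular_cell_geometry(c(23, 22), 15, 0.5,
                                                c(90, 90)), 5)
  expect_equal(peripheral_fraction(tab_t, g_t)$fraction, f0)
  # rotate 90 degrees about the cell centre: (x, y) -> (cy + (y-cy'), ...)
  tab_r <- tibble::tibble(label = 1:60, area_um2 = rep(12, 60),
                          centroid_x_um = 20 + (pts$y - 20),
                          centroid_y_um = 20 - (pts$x - 20),
                          equivalent_diameter_um = 4)
  expect_equal(peripheral_fraction(tab_r, g)$fraction, f0)
})

test_that("pooled uniform placement lands inside the annulus-law confidence interval", {
  # 2000 uniformly placed large puncta in a 37.5-um cell, 10-um band
  set.seed(97)
  R <- 37.5; w <- 10; n <- 2000
  g <- peripheral_band(circular_cell_geometry(c(45, 45), R, 0.15,
                                              c(601, 601)), w)
  pts <- sample_disc_uniform(n, R, c(45, 45))
  tab <- tibble::tibble(label = seq_len(n), area_um2 = rep(12, n),
                        centroid_x_um = pts$x, centroid_y_um = pts$y,
                        equivalent_diameter_um = 4)
  res <- peripheral_fraction(tab, g)
  p <- 1 - ((R - w) / R)^2
  ci <- p + c(-1, 1) * 1.96 * sqrt(p * (1 - p) / n)
  expect_gt(res$fraction, ci[1])
  expect_lt(res$fraction, ci[2])
})
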