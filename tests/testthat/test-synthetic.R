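test_that("the generator handles the empty case and is bit-identical under a fixed seed", {
  acq <- small_acq()
  empty <- generate_cell(puncta_spec(n = 0), acq, seed = 2,
                         cell_diameter_um = 40, nucleus_diameter_um = 12)
  expect_equal(nrow(empty$truth), 0)
  expect_length(empty$stack, 15)
  # pure background + cell body: nothing brighter than cell + background
  expect_lte(max(empty$stack[[1]]$pixels), 5 + 10 + 1e-6)
  a <- small_cell(seed = 7)
  b <- small_cell(seed = 7)
  expect_identical(lapply(a$stack, function(s) s$pixels),
                   lapply(b$stack, function(s) s$pixels))
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  c2 <- small_cell(seed = 8)
  expect_false(identical(as.data.frame(a$truth), as.data.frame(c2$truth)))
})

test_that("ground truth respects the cell geometry invariants", {
  sim <- small_cell(puncta_spec(n = c(25, 10, 1)), seed = 12)
  tr <- sim$truth
  cc <- attr(tr, "cell_center_um"); cr <- attr(tr, "cell_radius_um")
  d <- sqrt((tr$x_um - cc[["x"]])^2 + (tr$y_um - cc[["y"]])^2)
  expect_true(all(d < cr))
  expect_true(all(tr$radius_um > 0))
  expect_gt(cr, attr(tr, "nucleus_radius_um"))
  expect_equal(nrow(tr), 36)
  # rejections: puncta too large for the cytoplasm, bad scale
  expect_error(generate_cell(puncta_spec(n = 1, lower_um2 = 2000,
                                         upper_um2 = 2100),
                             small_acq(), seed = 1,
                             cell_diameter_um = 40),
               "fit")
  expect_error(acquisition_params(um_per_pixel = 0), "positive")
})

test_that("a rendered punctum's pixel area approaches pi r^2 on a fine grid", {
  # radius 0.75 um -> pi * 0.75^2 = 1.767 um^2; fine pixel grid, noiseless
  acq <- acquisition_params(um_per_pixel = 0.05, image_size_px = c(512, 512),
                            n_slices = 1, noise_model = "none")
  sim <- generate_cell(puncta_spec(n = 1, lower_um2 = 1.767, upper_um2 = 1.767),
                       acq, seed = 3, cell_diameter_um = 20,
                       nucleus_diameter_um = 5)
  expect_equal(sim$truth$rendered_area_um2, pi * 0.75^2, tolerance = 0.05)
  # discretization error shrinks with pixel size: coarse grid does worse
  acq2 <- acquisition_params(um_per_pixel = 0.3, image_size_px = c(128, 128),
                             n_slices = 1, noise_model = "none")
  sim2 <- generate_cell(puncta_spec(n = 1, lower_um2 = 1.767,
                                    upper_um2 = 1.767),
                        acq2, seed = 3, cell_diameter_um = 20,
                        nucleus_diameter_um = 5)
  err_fine <- abs(sim$truth$rendered_area_um2 - pi * 0.75^2)
  err_coarse <- abs(sim2$truth$rendered_area_um2 - pi * 0.75^2)
  expect_lt(err_fine, err_coarse + 1e-9)
})

test_that("correlated-pair generation splits shared and private puncta deterministically", {
  acq <- small_acq()
  spec <- puncta_spec(n = c(16, 8), lower_um2 = c(0.1, 0.5),
                      upper_um2 = c(0.5, 1.5))
  pr <- generate_correlated_pair(0.5, spec, acq, seed = 21,
                                 cell_diameter_um = 40,
                                 nucleus_diameter_um = 12)
  t1 <- pr$truth[pr$truth$channel_id == "ch1", ]
  t2 <- pr$truth[pr$truth$channel_id == "ch2", ]
  expect_equal(sum(t1$shared), round(0.5 * nrow(t1)))
  shared1 <- t1[t1$shared, c("x_um", "y_um", "radius_um")]
  shared2 <- t2[t2$shared, c("x_um", "y_um", "radius_um")]
  expect_equal(as.data.frame(shared1), as.data.frame(shared2))
  pr2 <- generate_correlated_pair(0.5, spec, acq, seed = 21,
                                  cell_diameter_um = 40,
                                  nucleus_diameter_um = 12)
  expect_identical(as.data.frame(pr$truth), as.data.frame(pr2$truth))
  expect_error(generate_correlated_pair(1.2, spec, acq, 1), "\\[0, 1\\]")
})

test_that("peripheral bias places large puncta as requested", {
  acq <- small_acq()
  all_in <- generate_peripheral_cohort(5, 1, acq, seed = 4,
                                       cell_diameter_um = 40,
                                       nucleus_diameter_um = 12,
                                       large_area_um2 = c(10.5, 12),
                                       small_spec = puncta_spec(n = 0))
  expect_true(all(all_in$truth$in_band))
  none_in <- generate_peripheral_cohort(5, 0, acq, seed = 4,
                                        cell_diameter_um = 40,
                                        nucleus_diameter_um = 12,
                                        large_area_um2 = c(10.5, 12),
                                        small_spec = puncta_spec(n = 0))
  expect_false(any(none_in$truth$in_band))
  expect_error(generate_peripheral_cohort(2, 0.5, acq, 1, band_width_um = 30,
                                          cell_diameter_um = 40),
               "band width")
})

test_that("uniform placement reproduces the analytic annulus fraction", {
  # P(centroid in outer w of radius-R disc) = 1 - ((R - w)/R)^2
  set.seed(123)
  R <- 37.5; w <- 10; n <- 2000
  pts <- sample_disc_uniform(n, R)
  frac <- mean(sqrt(pts$x^2 + pts$y^2) > R - w)
  p <- 1 - ((R - w) / R)^2
  ci <- p + c(-1, 1) * 1.96 * sqrt(p * (1 - p) / n)
  expect_gt(frac, ci[1])
  expect_lt(frac, ci[2])
})
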