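test_that("Pearson fixtures: identity, inversion, independence", {
  set.seed(3)
  px <- matrix(runif(64 * 64, 0, 255), 64, 64)
  a <- calibrate(px, 0.2)
  expect_equal(pearson_no_threshold(a, a)$pearson_r, 1, tolerance = 1e-9)
  b <- calibrate(max(px) - px, 0.2)
  expect_equal(pearson_no_threshold(a, b)$pearson_r, -1, tolerance = 1e-9)
  # independent noise, 10^4 pixels: |r| < 0.05
  n1 <- calibrate(matrix(runif(1e4, 0, 100), 100, 100), 0.2)
  n2 <- calibrate(matrix(runif(1e4, 0, 100), 100, 100), 0.2)
  expect_lt(abs(pearson_no_threshold(n1, n2)$pearson_r), 0.05)
  # constant channel -> missing, shape mismatch -> error
  flatc <- calibrate(matrix(7, 64, 64), 0.2)
  expect_true(is.na(pearson_no_threshold(a, flatc)$pearson_r))
  expect_error(pearson_no_threshold(a, calibrate(matrix(1, 3, 3), 0.2)),
               "dimensions")
})

test_that("Pearson matches the two-pass covariance oracle and affine laws", {
  set.seed(8)
  for (rep in 1:5) {
    p1 <- matrix(runif(48 * 48, 0, 255), 48, 48)
    p2 <- 0.4 * p1 + matrix(rnorm(48 * 48, 0, 30), 48, 48)
    p2 <- pmax(p2, 0)
    r_pkg <- pearson_no_threshold(calibrate(p1, 1), calibrate(p2, 1))$pearson_r
    expect_equal(r_pkg, oracle_pearson(as.vector(p1), as.vector(p2)),
                 tolerance = 1e-12)
    # invariant under positive affine gain, sign-flipped under negative gain
    r_gain <- pearson_no_threshold(calibrate(3 * p1 + 10, 1),
                                   calibrate(p2, 1))$pearson_r
    expect_equal(r_gain, r_pkg, tolerance = 1e-9)
    neg <- calibrate(max(p2) - 2 * p2 + 2 * max(p2), 1) # gain -2 + offset
    r_neg <- pearson_no_threshold(calibrate(p1, 1), neg)$pearson_r
    expect_equal(r_neg, -r_pkg, tolerance = 1e-9)
  }
})

test_that("percent reduction reproduces the control-vs-treated arithmetic", {
  expect_equal(round(percent_reduction(0.829, 0.515)), 38)
  expect_equal(percent_reduction(0.6, 0.6), 0)
  expect_equal(percent_reduction(0.5, 0.75), -50)
  expect_error(percent_reduction(0, 0.5), "non-zero")
})

test_that("colocalization is monotone in the generated shared fraction", {
  acq <- small_acq()
  spec <- puncta_spec(n = c(20, 10), lower_um2 = c(0.1, 0.5),
                      upper_um2 = c(0.5, 1.5))
  rs <- vapply(c(0, 0.5, 1), function(f) {
    pr <- generate_correlated_pair(f, spec, acq, seed = 11,
                                   cell_diameter_um = 40,
                                   nucleus_diameter_um = 12)
    f1 <- overlay_stack(pr$channels$ch1)
    f2 <- overlay_stack(pr$channels$ch2)
    g <- estimate_cell_mask(f1)
    pearson_no_threshold(f1, f2, roi = g)$pearson_r
  }, 1)
  expect_equal(rs[3], 1, tolerance = 1e-6)   # identical channels
  expect_true(all(diff(rs) > 0))             # non-decreasing in fraction
})

test_that("large-puncta colocalization restricts the ROI correctly", {
  acq <- small_acq()
  spec <- puncta_spec(n = c(10, 1), lower_um2 = c(0.2, 11),
                      upper_um2 = c(0.8, 13))
  pr <- generate_correlated_pair(1, spec, acq, seed = 13,
                                 cell_diameter_um = 40,
                                 nucleus_diameter_um = 12)
  f1 <- to_eight_bit(overlay_stack(pr$channels$ch1))
  f2 <- to_eight_bit(overlay_stack(pr$channels$ch2))
  tab <- run_pipeline(pr$channels$ch1, half_max_params())
  res <- coloc_in_large_puncta(f1, f2, tab)
  expect_equal(res$pearson_r, 1, tolerance = 1e-6)  # fully shared punctum
  expect_identical(res$roi, "large_puncta")
  expect_gt(res$n_pixels, 10 / acq$um_per_pixel^2 * 0.5)
  # no puncta over the cutoff -> missing result
  none <- coloc_in_large_puncta(f1, f2, tab, min_area_um2 = 1e4)
  expect_true(is.na(none$pearson_r))
  expect_equal(none$n_pixels, 0L)
})
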