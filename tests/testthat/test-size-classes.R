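test_that("diameter-area conversion reproduces the autophagosome bounds", {
  expect_equal(round(diameter_to_area(0.5), 3), 0.196)
  expect_equal(round(diameter_to_area(1.5), 3), 1.767)
  d <- c(0.1, 0.5, 1.5, 3, 10)
  expect_equal(area_to_diameter(diameter_to_area(d)), d, tolerance = 1e-9)
  expect_true(all(diff(diameter_to_area(seq(0.1, 5, by = 0.1))) > 0))
  expect_equal(diameter_to_area(d), pi * (d / 2)^2)
  expect_error(diameter_to_area(0), "positive")
  expect_error(area_to_diameter(-1), "positive")
})

test_that("built-in schemes partition (0, Inf) and classify by marker context", {
  for (nm in c("lc3b", "becn1", "lamp1", "ladder1", "ladder01")) {
    sch <- size_scheme(nm)
    expect_s3_class(sch, "size_scheme")
    expect_true(is.infinite(sch$upper_um2[nrow(sch)]))
  }
  tab <- tibble::tibble(area_um2 = c(0.1, 0.5, 11.0))
  prof <- classify_puncta(tab, size_scheme("lc3b"))
  expect_equal(prof$n[prof$class == "phagophore"], 1)
  expect_equal(prof$n[prof$class == "autophagosome"], 1)
  expect_equal(prof$n[prof$class == "amphisome_candidate"], 1)
  # empty table -> all-zero profile
  empty <- classify_puncta(tibble::tibble(area_um2 = numeric()),
                           size_scheme("lamp1"))
  expect_true(all(empty$n == 0))
  expect_equal(attr(empty, "total"), 0)
})

test_that("class counts conserve the total for random areas (partition property)", {
  set.seed(77)
  areas <- exp(runif(1000, log(0.01), log(40)))
  for (nm in c("lc3b", "lamp1", "ladder1")) {
    prof <- classify_puncta(tibble::tibble(area_um2 = areas), size_scheme(nm))
    expect_equal(sum(prof$n), 1000)
  }
})

test_that("boundary areas follow the documented edge conventions", {
  sch <- size_scheme("lc3b")
  # exactly 0.196 falls in the autophagosome class, not the phagophore class
  p <- classify_puncta(tibble::tibble(area_um2 = 0.196), sch)
  expect_equal(p$n[p$class == "autophagosome"], 1)
  expect_equal(p$n[p$class == "phagophore"], 0)
  # exactly 1.767 still autophagosome; exactly 10 is not an amphisome (">10")
  p2 <- classify_puncta(tibble::tibble(area_um2 = c(1.767, 10)), sch)
  expect_equal(p2$n[p2$class == "autophagosome"], 1)
  expect_equal(p2$n[p2$class == "amphisome_candidate"], 0)
  # lamp1: 0.03 and 0.5 both inside the lysosome class
  pl <- classify_puncta(tibble::tibble(area_um2 = c(0.03, 0.5)),
                        size_scheme("lamp1"))
  expect_equal(pl$n[pl$class == "lysosome"], 2)
})

test_that("range counting uses a strict lower bound for open-ended ranges", {
  tab <- tibble::tibble(area_um2 = c(9.9, 10.1, 12))
  expect_equal(count_in_range(tab, 10), 2)
  tab2 <- tibble::tibble(area_um2 = c(0.02, 0.03, 0.49, 0.5))
  expect_equal(count_in_range(tab2, 0.03, 0.5), 2)
  full <- tibble::tibble(area_um2 = runif(50, 0.01, 20))
  expect_equal(count_in_range(full, 0), 50)
  expect_error(count_in_range(tab, 5, 5), "lower")
})

test_that("schemes round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c(
    "my_scheme:",
    "  marker_context: LC3B",
    "  bins:",
    "    - {class: small, lower_um2: 0, upper_um2: 1}",
    "    - {class: large, lower_um2: 1}"
  ), path)
  schemes <- read_schemes_yaml(path)
  expect_named(schemes, "my_scheme")
  prof <- classify_puncta(tibble::tibble(area_um2 = c(0.5, 1, 2)),
                          schemes$my_scheme)
  expect_equal(prof$n, c(2, 1))
  # invalid schemes are rejected
  expect_error(size_scheme_custom(
    tibble::tibble(class = c("a", "b"), lower_um2 = c(0, 2),
                   upper_um2 = c(1, Inf))), "gap")
})
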