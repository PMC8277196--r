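test_that("reference normalization follows the ratio convention", {
  df <- tibble::tibble(group = c("young", "young", "aged", "aged"),
                       value = c(4, 4, 2, 6))
  out <- normalize_to_reference(df, "young")
  expect_equal(out$normalized, c(1, 1, 0.5, 1.5))
  # reference group all equal -> normalized all 1
  cc <- tibble::tibble(group = rep("ctrl", 3), value = c(7, 7, 7))
  expect_equal(normalize_to_reference(cc, "ctrl")$normalized, rep(1, 3))
  # scale equivariance: multiplying raw values leaves normalized unchanged
  df2 <- dplyr::mutate(df, value = value * 13)
  expect_equal(normalize_to_reference(df2, "young")$normalized,
               out$normalized)
  zero <- tibble::tibble(group = c("a", "a", "b", "b"), value = c(0, 0, 1, 2))
  expect_error(normalize_to_reference(zero, "a"), "zero")
  expect_error(normalize_to_reference(df, "missing"), "reference")
})

test_that("the two-group test matches the pooled-variance formulas", {
  # hand-computable case, n = 3 vs 3
  x <- c(1.1, 2.3, 1.9); y <- c(3.2, 4.1, 3.9)
  df <- tibble::tibble(group = rep(c("a", "b"), each = 3), value = c(x, y))
  res <- compare_two_groups(df, reference = "a")
  want <- oracle_t_test(x, y)
  expect_equal(glance(res)$statistic, want$statistic, tolerance = 1e-10)
  expect_equal(glance(res)$p_value, want$p, tolerance = 1e-10)
  # identical groups: statistic 0, p = 1
  same <- tibble::tibble(group = rep(c("a", "b"), each = 4),
                         value = rep(c(1, 2, 3, 4), 2))
  g0 <- glance(compare_two_groups(same))
  expect_equal(g0$statistic, 0, tolerance = 1e-12)
  expect_equal(g0$p_value, 1, tolerance = 1e-12)
  # large separation, small variance -> tiny p
  far <- tibble::tibble(group = rep(c("a", "b"), each = 5),
                        value = c(rnorm(5, 0, 0.01), rnorm(5, 100, 0.01)))
  expect_lt(glance(compare_two_groups(far))$p_value, 1e-6)
  expect_error(compare_two_groups(
    tibble::tibble(group = c("a", "b"), value = 1:2)), "at least two")
  # summary invariants: sem = sd/sqrt(n), reference normalized mean = 1
  td <- tidy(res)
  expect_equal(td$sem, c(sd(x) / sqrt(3), sd(y) / sqrt(3)))
  expect_equal(td$normalized_mean[td$group == "a"], 1)
})

test_that("one-way ANOVA matches the sum-of-squares oracle and flags the shifted group", {
  set.seed(15)
  vals <- c(rnorm(5, 10, 1), rnorm(5, 10.2, 1), rnorm(5, 30, 1))
  df <- tibble::tibble(group = rep(c("g1", "g2", "g3"), each = 5),
                       value = vals)
  res <- compare_many_groups(df, reference = "g1")
  expect_equal(glance(res)$statistic, oracle_anova_f(vals, df$group),
               tolerance = 1e-10)
  ph <- res$posthoc
  sig <- ph$p_adj < 0.05
  involves3 <- grepl("g3", ph$comparison)
  expect_true(all(sig[involves3]))
  expect_false(any(sig[!involves3]))
  # different letters separate the shifted group only
  td <- tidy(res)
  expect_equal(td$letters[td$group == "g1"], td$letters[td$group == "g2"])
  expect_false(td$letters[td$group == "g3"] == td$letters[td$group == "g1"])
  # all groups identical -> F ~ 0, p ~ 1
  flat <- tibble::tibble(group = rep(c("a", "b", "c"), each = 4),
                         value = rep(c(1, 2, 3, 4), 3))
  gf <- glance(compare_many_groups(flat))
  expect_equal(gf$statistic, 0, tolerance = 1e-12)
  expect_equal(gf$p_value, 1, tolerance = 1e-12)
})

test_that("ANOVA on two groups reproduces the equal-variance t-test (F = t^2)", {
  set.seed(25)
  df <- tibble::tibble(group = rep(c("a", "b"), each = 6),
                       value = c(rnorm(6, 5), rnorm(6, 6)))
  f_stat <- glance(compare_many_groups(df))$statistic
  t_stat <- glance(compare_two_groups(df))$statistic
  expect_equal(f_stat, t_stat^2, tolerance = 1e-9)
})

test_that("dose-response summaries exclude low-viability doses with a reason", {
  df <- tibble::tibble(
    dose = rep(c(0, 100, 200, 400), each = 3),
    area = c(rnorm(3, 0.2, 0.01), rnorm(3, 0.3, 0.01),
             rnorm(3, 0.5, 0.01), rnorm(3, 0.6, 0.01)),
    count = rep(c(300, 280, 250, 80), each = 3),
    viability = rep(c(0.95, 0.9, 0.8, 0.2), each = 3))
  out <- dose_response_summary(df)
  expect_equal(out$excluded, c(FALSE, FALSE, FALSE, TRUE))
  expect_match(out$exclusion_reason[4], "viability")
  expect_true(all(is.na(out$exclusion_reason[1:3])))
  expect_equal(out$dose_um, c(0, 100, 200, 400))
  expect_error(dose_response_summary(dplyr::mutate(df, viability = 50)),
               "fraction")
})
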