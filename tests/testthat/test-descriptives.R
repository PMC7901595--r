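test_that("fixture error tables reproduce the published per-group cells", {
  items <- pkg_items()
  tab <- errorTable(items, "pathologist")
  p13 <- tab[tab$group == "P13", ]
  expect_equal(c(p13$n_tasks, p13$n_errors), c(81L, 26L))
  expect_equal(formatRate(p13$rate), "0.32")
  cat_tab <- errorTable(items, "category")
  grade <- cat_tab[cat_tab$group == "5", ]
  expect_equal(c(grade$n_tasks, grade$n_errors), c(147L, 27L))
  expect_equal(formatRate(grade$rate), "0.18")
})

test_that("median and IQR use type-7 interpolation on unrounded rates", {
  items <- pkg_items()
  s_p <- medianIQR(errorTable(items, "pathologist", totals = FALSE)$rate)
  expect_equal(formatRate(s_p$median), "0.07")
  expect_equal(formatRate(s_p$q1), "0.04")
  expect_equal(formatRate(s_p$q3), "0.11")
  s_l <- medianIQR(errorTable(items, "level", totals = FALSE)$rate)
  expect_equal(formatRate(s_l$median), "0.07")
  expect_equal(formatRate(s_l$q1), "0.07")
  expect_equal(formatRate(s_l$q3), "0.10")
  # degenerate input
  s1 <- medianIQR(0.3)
  expect_equal(c(s1$q1, s1$median, s1$q3), c(0.3, 0.3, 0.3))
  expect_error(medianIQR(numeric(0)), "rates")
})

test_that("medianIQR agrees with a brute-force interpolation oracle", {
  interp_quantile <- function(x, p) {
    x <- sort(x)
    n <- length(x)
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  set.seed(31)
  for (n in c(1, 2, 3, 5, 17, 50, 100)) {
    x <- runif(n)
    s <- medianIQR(x)
    expect_equal(s$median, interp_quantile(x, 0.5), tolerance = 1e-12)
    expect_equal(s$q1, interp_quantile(x, 0.25), tolerance = 1e-12)
    expect_equal(s$q3, interp_quantile(x, 0.75), tolerance = 1e-12)
  }
})

test_that("display rounding is half away from zero", {
  expect_equal(roundHalfUp(0.125, 2), 0.13)  # round() would give 0.12
  expect_equal(roundHalfUp(-0.125, 2), -0.13)
  expect_equal(formatRate(26 / 81), "0.32")
  expect_equal(formatRate(47 / 310), "0.15")
})

test_that("cross-tabulated task rates carry counts and undefined cells", {
  items <- pkg_items()
  by_spec <- crossErrorRates(items, 1, by = "specimen")
  expect_equal(sum(by_spec$n_tasks), 392L)
  expect_equal(sum(by_spec$n_errors), 42L)
  by_lev <- crossErrorRates(items, 2, by = "level")
  expect_equal(sum(by_lev$n_tasks), 258L)
  expect_equal(sum(by_lev$n_errors), 11L)
  # a cell with no answered items is undefined, not zero
  sub <- responseItems(items[items$level != "senior" | items$category != 2, ])
  cross <- crossErrorRates(sub, 2, by = "level")
  expect_true(is.na(cross$rate[cross$group == "senior"]))
  expect_false(any(is.na(cross$rate[cross$group != "senior"])))
})

test_that("a flat simulated study yields flat group rates", {
  design <- generateDesign(designConfig(missing_rate = 0), seed = 6)
  params <- generativeParams(alpha_bar = -1, sigma_alpha = 0, sigma_beta = 0,
                             sigma_gamma = 0, sigma_delta = 0,
                             sigma_epsilon = 0)
  items <- simulateResponses(design, params, seed = 13)
  tab <- errorTable(items, "category", totals = FALSE)
  p <- plogis(-1)
  se <- sqrt(p * (1 - p) / tab$n_tasks)
  expect_true(all(abs(tab$rate - p) < 4 * se))
})

test_that("overall concordance summarizes answered items", {
  items <- pkg_items()
  cc <- concordanceSummary(items)
  expect_equal(cc$n_concordant, 1228L)
  expect_equal(roundHalfUp(cc$concordance_pct, 2), 91.30)
})
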