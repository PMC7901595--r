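test_that("HPDI is the shortest window of sorted draws", {
  h <- hpdi(1:100, 0.89)
  expect_equal(unname(h), c(1, 89))  # ties broken to the lowest start
  set.seed(41)
  z <- rnorm(1e5)
  h <- hpdi(z, 0.89)
  expect_lt(abs(h[["low"]] + 1.598), 0.05)   # symmetric: central interval
  expect_lt(abs(h[["high"]] - 1.598), 0.05)
  e <- hpdi(rexp(1e5), 0.89)
  expect_lt(e[["low"]], 0.05)                # mode at 0: left-anchored
  expect_error(hpdi(1), "at least 2")
  expect_error(hpdi(1:10, 1.2), "mass")
})

test_that("HPDI matches the all-windows search oracle", {
  set.seed(43)
  for (i in 1:20) {
    n <- sample(2:1000, 1)
    draws <- switch(1 + i %% 3, rnorm(n), rexp(n), rbeta(n, 0.5, 2))
    mass <- runif(1, 0.5, 0.98)
    expect_equal(unname(hpdi(draws, mass)), brute_hpdi(draws, mass),
                 tolerance = 1e-12)
  }
})

test_that("prior predictive rates are weakly regularized and reproducible", {
  design <- generateDesign(designConfig(), seed = 9)
  rates <- priorPredictive(design, n_draws = 1000, seed = 10)
  expect_true(all(rates >= 0 & rates <= 1))
  q <- quantile(rates, c(0.05, 0.95))
  expect_gt(q[2] - q[1], 0.5)  # mass spread over most of (0, 1)
  # determinism for a single draw
  expect_identical(priorPredictive(design, n_draws = 1, seed = 3),
                   priorPredictive(design, n_draws = 1, seed = 3))
  # a degenerate prior pinned at very negative log-odds gives ~zero rates
  low <- priorPredictive(design, n_draws = 20, seed = 4,
                         alpha_bar_mean = -10, alpha_bar_sd = 0.001,
                         sigma_rate = 1000)
  expect_true(all(low < 0.01))
})

test_that("average pathologist summaries follow the posterior draws", {
  # degenerate single-draw posterior: closed form
  draws <- matrix(c(-2, 0.5, 0), 1, 3,
                  dimnames = list(NULL, c("alpha_bar", "sigma_alpha",
                                          "beta[junior]")))
  s <- averagePathologist(draws, "junior", mode = "grand_mean")
  expect_equal(s$mean_error_prob, plogis(-2), tolerance = 1e-12)
  expect_equal(s$hpdi_low, s$hpdi_high)
  expect_error(averagePathologist(draws, "attending"), "unknown career level")

  # order invariance of the deterministic mode
  set.seed(44)
  m <- cbind(alpha_bar = rnorm(500, -2, 0.5),
             sigma_alpha = rexp(500, 2),
             `beta[senior]` = rnorm(500, 0.3, 0.2))
  s1 <- averagePathologist(m, "senior", mode = "grand_mean")
  s2 <- averagePathologist(m[sample(500), ], "senior", mode = "grand_mean")
  expect_equal(s1$mean_error_prob, s2$mean_error_prob, tolerance = 1e-12)
  expect_equal(c(s1$hpdi_low, s1$hpdi_high), c(s2$hpdi_low, s2$hpdi_high),
               tolerance = 1e-12)

  # sampling a new rater adds predictive spread
  g <- averagePathologist(m, "senior", mode = "grand_mean")
  n <- averagePathologist(m, "senior", mode = "new_pathologist", seed = 2)
  expect_gte(n$hpdi_high - n$hpdi_low, g$hpdi_high - g$hpdi_low)
})

test_that("career-level predictions on the reconstructed study rank sensibly", {
  cache <- table1_fit()
  pt <- predictiveTable(cache$fit, items = cache$items)
  expect_equal(nrow(pt), 4L)
  expect_true(all(pt$hpdi_low <= pt$hpdi_high))
  expect_true(all(pt$mean_error_prob >= 0 & pt$mean_error_prob <= 1))
  # intermediate career levels outperform residents on average
  res <- pt$mean_error_prob[pt$level == "resident"]
  expect_lte(pt$mean_error_prob[pt$level == "junior"], res)
  expect_lte(pt$mean_error_prob[pt$level == "expert"], res)
})
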