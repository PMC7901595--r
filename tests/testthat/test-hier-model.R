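test_that("log-likelihood matches closed forms", {
  items <- small_items()
  answered <- responseItems(items[items$outcome != "missing", ])
  n <- nrow(answered)
  zero <- modelParams()
  expect_equal(logLikelihood(zero, answered), n * log(0.5), tolerance = 1e-12)

  one <- responseItems(data.frame(
    participant = "P1", level = "senior", case = 1L, subspecialty = "breast",
    specimen = "biopsy", category = 1L, outcome = "error"))
  p <- modelParams(alpha = 2)
  expect_equal(logLikelihood(p, one), log(plogis(2)), tolerance = 1e-12)
  expect_equal(logLikelihood(p, one), -0.126928011, tolerance = 1e-8)

  with_missing <- responseItems(rbind(as.data.frame(one),
    data.frame(participant = "P1", level = "senior", case = 1L,
               subspecialty = "breast", specimen = "biopsy", category = 3L,
               outcome = "missing")))
  expect_error(logLikelihood(p, with_missing), "missing")
})

test_that("log-prior matches the analytic density sum and its support", {
  unit <- modelParams(alpha = rep(0, 17))
  expected <- dnorm(0, 0, 1.5, log = TRUE) + 5 * dexp(1, 1, log = TRUE) +
    31 * dnorm(0, 0, 1, log = TRUE)
  expect_equal(logPrior(unit), expected, tolerance = 1e-12)

  bad <- unit
  bad$sigma_alpha <- -1
  expect_identical(logPrior(bad), -Inf)

  # moving every effect away from its conditional mean decreases the density
  set.seed(8)
  p1 <- random_params()
  p2 <- p1
  p2$alpha <- p1$alpha_bar + 2 * (p1$alpha - p1$alpha_bar)
  for (f in c("beta", "gamma", "delta", "epsilon")) p2[[f]] <- 2 * p1[[f]]
  expect_lt(logPrior(p2), logPrior(p1))
})

test_that("non-centered transform is the documented affine map", {
  raw <- list(alpha_bar = -2, sigma_alpha = 0.5, sigma_beta = 1,
              sigma_gamma = 1, sigma_delta = 1, sigma_epsilon = 1,
              z_alpha = rep(0, 17), z_beta = rep(0, 4), z_gamma = rep(0, 5),
              z_delta = rep(0, 2), z_epsilon = rep(0, 3))
  p <- noncenteredTransform(raw)
  expect_equal(p$alpha, rep(-2, 17))
  expect_equal(c(p$beta, p$gamma, p$delta, p$epsilon), rep(0, 14))
  raw$z_alpha[1] <- 2
  expect_equal(noncenteredTransform(raw)$alpha[1], -1)
})

test_that("log-posterior equals the brute-force oracle on the fixture", {
  items <- pkg_items()
  answered <- responseItems(items[items$outcome != "missing", ])
  md <- modelData(answered)
  set.seed(14)
  for (i in 1:5) {
    p <- random_params()
    mine <- logPosterior(p, md)
    oracle <- brute_log_posterior(p, items)
    expect_lt(abs(mine - oracle) / abs(oracle), 1e-10)
  }
})

test_that("prior-only sampling recovers the prior (sampler correctness)", {
  items <- small_items()
  fit <- fitHier(items, fitConfig(n_chains = 2, n_warmup = 500,
                                  n_samples = 1000, prior_only = TRUE,
                                  seed = 21))
  m <- as.matrix(fit)
  expect_equal(fit$n_divergent, 0L)
  # alpha_bar ~ Normal(0, 1.5); sigmas ~ Exponential(1) (mean 1, sd 1)
  expect_lt(abs(mean(m[, "alpha_bar"])), 0.2)
  expect_lt(abs(sd(m[, "alpha_bar"]) - 1.5), 0.2)
  for (s in paste0("sigma_", c("alpha", "beta", "gamma", "delta", "epsilon")))
    expect_lt(abs(mean(m[, s]) - 1), 0.15)
})

test_that("all parametrizations sample the same posterior on a small dataset", {
  items <- small_items(seed = 99)
  toy <- responseItems(as.data.frame(items[items$outcome != "missing", ])[1:50, ])
  fits <- lapply(c("noncentered", "centered", "mixed"), function(par)
    suppressWarnings(fitHier(toy, fitConfig(n_chains = 2, n_warmup = 500,
                                            n_samples = 800,
                                            parametrization = par,
                                            seed = 22))))
  for (pair in list(1:2, c(1, 3))) {
    for (par in c("alpha_bar", "sigma_alpha", "sigma_gamma")) {
      m1 <- as.matrix(fits[[pair[1]]])[, par]
      m2 <- as.matrix(fits[[pair[2]]])[, par]
      d1 <- fits[[pair[1]]]$diagnostics
      d2 <- fits[[pair[2]]]$diagnostics
      ess1 <- d1$ess[d1$parameter == par]
      ess2 <- d2$ess[d2$parameter == par]
      mcse <- sqrt(var(m1) / ess1 + var(m2) / ess2)
      expect_lt(abs(mean(m1) - mean(m2)), 3 * mcse + 0.02)
    }
  }
})

test_that("posterior matches an independent engine on the same model", {
  # dual route: our NUTS fit versus a Gibbs fit of the identical model in
  # JAGS, on a simulated study
  items <- small_items(seed = 55)
  fit <- suppressWarnings(fitHier(items, fitConfig(n_chains = 2,
                                                   n_warmup = 600,
                                                   n_samples = 800,
                                                   seed = 23)))
  md <- modelData(items)
  mstr <- "model {
    for (i in 1:N) {
      w[i] ~ dbern(p[i])
      logit(p[i]) <- a[pid[i]] + b[lev[i]] + g[cat[i]] + d[spec[i]] + e[sub[i]]
    }
    for (j in 1:NP) { a[j] ~ dnorm(ab, pow(sa, -2)) }
    for (j in 1:4) { b[j] ~ dnorm(0, pow(sb, -2)) }
    for (j in 1:5) { g[j] ~ dnorm(0, pow(sg, -2)) }
    for (j in 1:2) { d[j] ~ dnorm(0, pow(sd_, -2)) }
    for (j in 1:3) { e[j] ~ dnorm(0, pow(se, -2)) }
    ab ~ dnorm(0, 0.44444444)
    sa ~ dexp(1); sb ~ dexp(1); sg ~ dexp(1); sd_ ~ dexp(1); se ~ dexp(1)
  }"
  set.seed(24)
  jm <- rjags::jags.model(
    textConnection(mstr),
    data = list(w = md$w, pid = md$pid, lev = md$lev, cat = md$cat,
                spec = md$spec, sub = md$sub, N = md$n, NP = md$n_raters),
    n.chains = 2, quiet = TRUE)
  update(jm, 3000, progress.bar = "none")
  s <- rjags::coda.samples(jm, c("ab", "sa", "sg", "a"), 8000, thin = 4,
                           progress.bar = "none")
  jags_mean <- summary(s)$statistics[, "Mean"]
  m <- as.matrix(fit)
  expect_lt(abs(mean(m[, "sigma_alpha"]) - jags_mean[["sa"]]), 0.15)
  expect_lt(abs(mean(m[, "sigma_gamma"]) - jags_mean[["sg"]]), 0.2)
  expect_lt(abs(mean(m[, "alpha[1]"]) - jags_mean[["a[1]"]]), 0.3)
  # the grand mean mixes slowly under single-site Gibbs; compare loosely
  expect_lt(abs(mean(m[, "alpha_bar"]) - jags_mean[["ab"]]), 0.6)
})

test_that("posterior for the grand mean concentrates with more raters", {
  # tenfold-roster posterior SD (shared fit) against replicate study-size fits
  sd_tenfold <- sd(as.matrix(tenfold_fit())[, "alpha_bar"])
  for (seed in c(61, 62)) {
    items <- simulateResponses(generateDesign(designConfig(), seed = seed),
                               recovery_truth(), seed = seed + 1)
    fit <- suppressWarnings(fitHier(items, fitConfig(n_chains = 1,
                                                     n_warmup = 300,
                                                     n_samples = 300,
                                                     seed = seed + 2)))
    expect_lt(sd_tenfold, sd(as.matrix(fit)[, "alpha_bar"]))
  }
})

test_that("fit warns on unobserved cluster levels instead of failing", {
  items <- small_items()
  sub <- responseItems(items[items$level != "senior", ])
  expect_warning(modelData(sub), "unobserved")
})
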