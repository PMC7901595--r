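# Shared fixtures and a memoized full-length fit (reused across test files so
# the expensive MCMC on the reconstructed study runs once per suite).

pkg_table1 <- function() {
  readMarginalTable(system.file("extdata", "table1_marginals.csv",
                                package = "pathoconcord"))
}

pkg_items <- function() {
  readResponseTable(system.file("extdata", "items_fixture.csv",
                                package = "pathoconcord"))
}

.fixture_cache <- new.env(parent = emptyenv())

# reconstruction of the published marginals (package default seed) plus the
# default-configuration fit; warnings are collected, not silenced away
table1_fit <- function() {
  if (is.null(.fixture_cache$fit)) {
    items <- reconstructFromMarginals(pkg_table1(), seed = 1)
    warns <- character(0)
    fit <- withCallingHandlers(
      fitHier(items, fitConfig(seed = 1)),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    .fixture_cache$items <- items
    .fixture_cache$fit <- fit
    .fixture_cache$warnings <- warns
  }
  .fixture_cache
}

# small simulated item set for cheap unit tests
small_items <- function(seed = 42) {
  simulateResponses(generateDesign(designConfig(), seed = seed),
                    generativeParams(alpha_bar = -2), seed = seed + 1)
}

# known truth used for recovery and concentration checks
recovery_truth <- function() {
  generativeParams(alpha_bar = -2, sigma_alpha = 0.5, sigma_beta = 0.5,
                   sigma_gamma = 0.5, sigma_delta = 0.5, sigma_epsilon = 0.5)
}

# memoized fit of a tenfold-roster synthetic study (170 raters, 14450 items)
# under recovery_truth(); shared by the recovery and concentration checks
tenfold_fit <- function() {
  if (is.null(.fixture_cache$tenfold)) {
    cfg <- designConfig(n_participants_per_level =
                          10 * c(senior = 2, expert = 5, junior = 6,
                                 resident = 4))
    items <- simulateResponses(generateDesign(cfg, seed = 71),
                               recovery_truth(), seed = 72)
    .fixture_cache$tenfold <- suppressWarnings(
      fitHier(items, fitConfig(n_chains = 1, n_warmup = 400, n_samples = 400,
                               max_treedepth = 7, seed = 73)))
  }
  .fixture_cache$tenfold
}

# independent brute-force log posterior: per-item loop for the likelihood,
# density-by-density sums for the prior (no shared code with the package's
# vectorized implementation)
brute_log_posterior <- function(params, items) {
  ans <- items[items$outcome != "missing", ]
  raters <- unique(ans$participant)
  raters <- raters[order(as.integer(sub("^P", "", raters)))]
  ll <- 0
  for (i in seq_len(nrow(ans))) {
    eta <- params$alpha[match(ans$participant[i], raters)] +
      params$beta[match(ans$level[i], careerLevels())] +
      params$gamma[ans$category[i]] +
      params$delta[match(ans$specimen[i], specimenTypes())] +
      params$epsilon[match(ans$subspecialty[i], subspecialties())]
    p <- 1 / (1 + exp(-eta))
    ll <- ll + if (ans$outcome[i] == "error") log(p) else log(1 - p)
  }
  sds <- c(params$sigma_alpha, params$sigma_beta, params$sigma_gamma,
           params$sigma_delta, params$sigma_epsilon)
  if (any(sds <= 0)) return(-Inf)
  lp <- dnorm(params$alpha_bar, 0, 1.5, log = TRUE) - sum(sds)
  lp <- lp + sum(dnorm(params$alpha, params$alpha_bar, params$sigma_alpha,
                       log = TRUE))
  lp <- lp + sum(dnorm(params$beta, 0, params$sigma_beta, log = TRUE))
  lp <- lp + sum(dnorm(params$gamma, 0, params$sigma_gamma, log = TRUE))
  lp <- lp + sum(dnorm(params$delta, 0, params$sigma_delta, log = TRUE))
  lp <- lp + sum(dnorm(params$epsilon, 0, params$sigma_epsilon, log = TRUE))
  ll + lp
}

random_params <- function(n_raters = 17) {
  modelParams(alpha = rnorm(n_raters, -1, 1), alpha_bar = rnorm(1, 0, 1),
              sigma_alpha = rexp(1) + 0.05, beta = rnorm(4, 0, 0.8),
              sigma_beta = rexp(1) + 0.05, gamma = rnorm(5, 0, 0.8),
              sigma_gamma = rexp(1) + 0.05, delta = rnorm(2, 0, 0.8),
              sigma_delta = rexp(1) + 0.05, epsilon = rnorm(3, 0, 0.8),
              sigma_epsilon = rexp(1) + 0.05)
}

# all-windows HPDI search (quadratic, oracle only)
brute_hpdi <- function(draws, mass = 0.89) {
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1], x[n]))
  best <- c(x[1], x[m])
  for (i in seq_len(n - m + 1)) {
    if (x[i + m - 1] - x[i] < best[2] - best[1] - 1e-15)
      best <- c(x[i], x[i + m - 1])
  }
  best
}
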