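# No-U-Turn Hamiltonian Monte Carlo sampler ------------------------------------
#
# Self-contained NUTS implementation (slice variant with doubling, dual
# averaging of the step size toward a target acceptance statistic, and a
# diagonal or dense metric adapted over expanding warmup windows). The target
# density is supplied as a closure returning the log posterior and its
# gradient on the unconstrained scale.
#
# The metric is the estimated posterior covariance Sigma (the inverse mass
# matrix): momenta are drawn N(0, Sigma^-1), the kinetic energy is
# r' Sigma r / 2, and positions move by eps * Sigma r. A dense Sigma absorbs
# linear posterior correlations (such as the grand mean versus the centered
# rater intercepts); the diagonal variant scales to high-dimensional fits.

newMetric <- function(d, kind) {
  m <- list(kind = kind, d = d)
  if (kind == "diag") m$minv <- rep(1, d)
  else { m$sigma <- diag(d); m$u <- diag(d) }   # u = chol(sigma)
  m
}

metricMult <- function(metric, v) {
  if (metric$kind == "diag") metric$minv * v
  else as.vector(metric$sigma %*% v)
}

# momentum draw: N(0, Sigma^-1); for u = chol(Sigma), u^-1 z has the right
# covariance
metricMomentum <- function(metric) {
  z <- stats::rnorm(metric$d)
  if (metric$kind == "diag") z / sqrt(metric$minv)
  else backsolve(metric$u, z)
}

metricUpdate <- function(metric, draws_mat) {
  n_w <- nrow(draws_mat)
  shrink <- n_w / (n_w + 5)
  v <- apply(draws_mat, 2, stats::var)
  v <- shrink * v + 1e-3 * (1 - shrink)
  v[v <= 0 | !is.finite(v)] <- 1e-3
  if (metric$kind == "diag") {
    metric$minv <- v
  } else if (n_w < metric$d + 10) {
    # too few draws for a stable covariance: diagonal update this window
    metric$sigma <- diag(v, metric$d)
    metric$u <- chol(metric$sigma)
  } else {
    # shrink off-diagonals toward the (regularized) sample diagonal
    s <- shrink * stats::cov(draws_mat) + (1 - shrink) * diag(v, metric$d)
    diag(s) <- diag(s) + 1e-8
    u <- tryCatch(chol(s), error = function(e) NULL)
    if (is.null(u)) {
      s <- diag(v, metric$d)
      u <- chol(s)
    }
    metric$sigma <- s
    metric$u <- u
  }
  metric
}

nutsJoint <- function(state, metric) {
  state$lp - 0.5 * sum(state$r * metricMult(metric, state$r))
}

nutsLeapfrog <- function(state, eps, lpg, metric) {
  r <- state$r + 0.5 * eps * state$grad
  theta <- state$theta + eps * metricMult(metric, r)
  cur <- lpg(theta)
  if (!is.finite(cur$lp)) cur$grad <- rep(0, length(theta))
  list(theta = theta, r = r + 0.5 * eps * cur$grad, lp = cur$lp,
       grad = cur$grad)
}

nutsNoUTurn <- function(minus, plus, metric) {
  dtheta <- plus$theta - minus$theta
  sum(dtheta * metricMult(metric, minus$r)) >= 0 &&
    sum(dtheta * metricMult(metric, plus$r)) >= 0
}

nutsBuildTree <- function(state, logu, dir, depth, eps, joint0, lpg, metric) {
  if (depth == 0L) {
    s1 <- nutsLeapfrog(state, dir * eps, lpg, metric)
    joint1 <- nutsJoint(s1, metric)
    if (!is.finite(joint1)) joint1 <- -Inf
    divergent <- logu - 1000 > joint1
    list(minus = s1, plus = s1, proposal = s1,
         n_valid = as.integer(logu <= joint1), cont = !divergent,
         alpha = min(1, exp(joint1 - joint0)), n_alpha = 1L,
         divergent = divergent)
  } else {
    t1 <- nutsBuildTree(state, logu, dir, depth - 1L, eps, joint0, lpg, metric)
    if (!t1$cont) return(t1)
    from <- if (dir == -1) t1$minus else t1$plus
    t2 <- nutsBuildTree(from, logu, dir, depth - 1L, eps, joint0, lpg, metric)
    if (dir == -1) t1$minus <- t2$minus else t1$plus <- t2$plus
    n_tot <- t1$n_valid + t2$n_valid
    if (t2$n_valid > 0 && stats::runif(1) < t2$n_valid / max(n_tot, 1L))
      t1$proposal <- t2$proposal
    t1$n_valid <- n_tot
    t1$alpha <- t1$alpha + t2$alpha
    t1$n_alpha <- t1$n_alpha + t2$n_alpha
    t1$divergent <- t1$divergent || t2$divergent
    t1$cont <- t2$cont && nutsNoUTurn(t1$minus, t1$plus, metric)
    t1
  }
}

nutsFindInitialStep <- function(state, lpg, metric) {
  eps <- 1
  state$r <- metricMomentum(metric)
  joint0 <- nutsJoint(state, metric)
  s1 <- nutsLeapfrog(state, eps, lpg, metric)
  ratio <- nutsJoint(s1, metric) - joint0
  if (!is.finite(ratio)) ratio <- -Inf
  dir <- if (ratio > log(0.5)) 1 else -1
  for (i in 1:50) {
    eps <- eps * 2^dir
    s1 <- nutsLeapfrog(state, eps, lpg, metric)
    ratio <- nutsJoint(s1, metric) - joint0
    if (!is.finite(ratio)) ratio <- -Inf
    if (dir == 1 && ratio <= log(0.5)) break
    if (dir == -1 && ratio >= log(0.5)) break
  }
  eps
}

# expanding variance-adaptation windows within warmup (Stan-like schedule)
nutsWindows <- function(n_warmup) {
  if (n_warmup < 20) return(list(init = n_warmup, ends = integer(0), term = 0L))
  init <- min(75L, max(1L, floor(0.15 * n_warmup)))
  term <- min(50L, max(1L, floor(0.10 * n_warmup)))
  middle <- n_warmup - init - term
  ends <- integer(0)
  w <- 25L
  pos <- 0L
  while (pos < middle) {
    if (pos + w >= middle || middle - (pos + w) < w * 2L) w <- middle - pos
    pos <- pos + w
    ends <- c(ends, init + pos)
    w <- w * 2L
  }
  list(init = init, ends = ends, term = term)
}

nutsChain <- function(lpg, init, n_warmup, n_samples, target_accept,
                      max_treedepth, seed, metric_kind = "diag") {
  set.seed(seed)
  d <- length(init)
  metric <- newMetric(d, metric_kind)
  cur <- lpg(init)
  state <- list(theta = init, r = numeric(d), lp = cur$lp, grad = cur$grad)
  if (!is.finite(state$lp)) stop("initial point has non-finite log posterior")
  eps <- nutsFindInitialStep(state, lpg, metric)
  mu <- log(10 * eps)
  log_eps_bar <- 0
  h_bar <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  adapt_m <- 0L
  windows <- nutsWindows(n_warmup)
  win_draws <- list()
  draws <- matrix(NA_real_, n_samples, d)
  div_flags <- logical(n_samples)
  accept_sum <- 0
  treedepths <- integer(0)

  total <- n_warmup + n_samples
  for (iter in seq_len(total)) {
    warming <- iter <= n_warmup
    state$r <- metricMomentum(metric)
    joint0 <- nutsJoint(state, metric)
    logu <- joint0 - stats::rexp(1)
    minus <- state; plus <- state
    proposal <- state
    n_valid <- 1L
    depth <- 0L
    alpha <- 0; n_alpha <- 0L
    divergent <- FALSE
    while (depth < max_treedepth) {
      dir <- if (stats::runif(1) < 0.5) -1 else 1
      from <- if (dir == -1) minus else plus
      tree <- nutsBuildTree(from, logu, dir, depth, eps, joint0, lpg, metric)
      if (dir == -1) minus <- tree$minus else plus <- tree$plus
      alpha <- alpha + tree$alpha
      n_alpha <- n_alpha + tree$n_alpha
      divergent <- divergent || tree$divergent
      if (tree$cont && tree$n_valid > 0 &&
          stats::runif(1) < tree$n_valid / n_valid)
        proposal <- tree$proposal
      n_valid <- n_valid + tree$n_valid
      if (!tree$cont || !nutsNoUTurn(minus, plus, metric)) break
      depth <- depth + 1L
    }
    state <- proposal
    accept_stat <- if (n_alpha > 0) alpha / n_alpha else 0

    if (warming) {
      # dual averaging of log step size
      adapt_m <- adapt_m + 1L
      frac <- 1 / (adapt_m + t0)
      h_bar <- (1 - frac) * h_bar + frac * (target_accept - accept_stat)
      log_eps <- mu - sqrt(adapt_m) / gamma * h_bar
      w <- adapt_m^(-kappa)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      eps <- exp(log_eps)
      # metric adaptation at window boundaries
      if (iter > windows$init && length(windows$ends) > 0) {
        win_draws[[length(win_draws) + 1L]] <- state$theta
        if (iter %in% windows$ends) {
          m <- do.call(rbind, win_draws)
          if (nrow(m) >= 10) metric <- metricUpdate(metric, m)
          win_draws <- list()
          # restart dual averaging centred on the current adapted step
          # (the new metric shifts the optimum only moderately)
          mu <- log(10 * eps)
          h_bar <- 0; log_eps_bar <- log(eps); adapt_m <- 0L
        }
      }
      if (iter == n_warmup) eps <- exp(log_eps_bar)
    } else {
      draws[iter - n_warmup, ] <- state$theta
      accept_sum <- accept_sum + accept_stat
      div_flags[iter - n_warmup] <- divergent
      treedepths <- c(treedepths, depth)
    }
  }
  list(draws = draws, n_divergent = sum(div_flags), divergent = div_flags,
       accept_rate = accept_sum / max(n_samples, 1),
       step_size = eps, mean_treedepth = mean(treedepths))
}

# Convergence diagnostics ------------------------------------------------------

#' Split-chain potential scale reduction factor
#'
#' Each chain is split in half and the classical between/within variance
#' ratio is computed on the split halves, so non-stationarity within a chain
#' inflates the statistic. Values near 1 indicate convergence.
#'
#' @param x iterations x chains matrix of draws of one scalar parameter.
#' @return scalar R-hat.
#' @export
splitRhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  halves <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  w <- mean(vars)
  b <- half * stats::var(means)
  if (w == 0) return(1)
  sqrt(((half - 1) / half * w + b / half) / w)
}

effectiveSizeDraws <- function(x) {
  # x: iterations x chains
  x <- as.matrix(x)
  lst <- coda::mcmc.list(lapply(seq_len(ncol(x)), function(j) coda::mcmc(x[, j])))
  as.numeric(coda::effectiveSize(lst))
}

# Fit configuration and driver -------------------------------------------------

#' Sampler configuration for [fitHier()]
#'
#' Defaults: 4 chains of 1000 warmup + 1000 sampling iterations, target
#' acceptance statistic 0.95 (high enough to suppress divergent
#' transitions), non-centered parametrization, dense metric.
#'
#' The non-centered default rewrites every effect as its hyperparameters
#' times a standard-normal offset, removing the prior funnel between effects
#' and their SDs; combined with the dense metric (which absorbs the linear
#' correlations among the grand mean and the cluster offsets) it samples the
#' study-size posterior without divergent transitions. `"centered"` samples
#' the effects directly; `"mixed"` centers only the small, tightly informed
#' clusters (category, specimen, subspecialty). All three agree within
#' Monte Carlo error; the alternatives are retained for sensitivity checks.
#'
#' @param n_chains,n_warmup,n_samples positive integers.
#' @param target_accept dual-averaging target in (0, 1).
#' @param seed integer seed; chain seeds are derived from it.
#' @param parametrization `"noncentered"` (default), `"mixed"` or
#'   `"centered"`.
#' @param max_treedepth cap on trajectory doubling.
#' @param metric `"auto"` (dense for models up to 200 unconstrained
#'   parameters, diagonal beyond), `"dense"` or `"diag"`. The dense metric is
#'   the estimated posterior covariance and absorbs linear correlations such
#'   as the one between the grand mean and the centered rater intercepts.
#' @param prior_only if TRUE the likelihood is switched off and the sampler
#'   draws from the prior (a sampler-correctness check).
#' @return list of class `fit_config`.
#' @export
fitConfig <- function(n_chains = 4, n_warmup = 1000, n_samples = 1000,
                      target_accept = 0.95, seed = 1,
                      parametrization = c("noncentered", "mixed", "centered"),
                      max_treedepth = 10, metric = c("auto", "dense", "diag"),
                      prior_only = FALSE) {
  parametrization <- match.arg(parametrization)
  metric <- match.arg(metric)
  stopifnot(n_chains >= 1, n_warmup >= 1, n_samples >= 1,
            target_accept > 0, target_accept < 1, max_treedepth >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_warmup = as.integer(n_warmup),
                 n_samples = as.integer(n_samples),
                 target_accept = target_accept, seed = as.integer(seed),
                 parametrization = parametrization,
                 max_treedepth = as.integer(max_treedepth), metric = metric,
                 prior_only = prior_only),
            class = "fit_config")
}

#' Fit the hierarchical varying-intercepts model by NUTS
#'
#' Samples the posterior proportional to `exp(logLikelihood + logPrior)`
#' using the built-in No-U-Turn sampler on the unconstrained scale (SDs are
#' sampled as logs with the Jacobian correction). Draws are returned on the
#' constrained scale with labelled columns (`alpha_bar`, `sigma_*`,
#' `alpha[i]`, `beta[level]`, `gamma[k]`, `delta[specimen]`,
#' `epsilon[subspecialty]`). Split R-hat and effective sample size are
#' computed for every parameter; a warning (never a silent pass) is issued
#' when any R-hat exceeds 1.01 or any post-warmup transition diverged.
#'
#' @param items a `response_items` collection (missing outcomes are dropped).
#' @param config a [fitConfig()].
#' @return object of class `hier_fit`: list with `draws` (iterations x
#'   chains x parameters array), `diagnostics` (data.frame with `rhat`,
#'   `ess`), `n_divergent`, `accept_rate`, `config`, `data`.
#' @export
fitHier <- function(items, config = fitConfig()) {
  stopifnot(inherits(config, "fit_config"))
  data <- modelData(items)
  # without a likelihood the centered blocks are a pure prior funnel; the
  # non-centered form samples the identical distribution in benign geometry
  if (config$prior_only) config$parametrization <- "noncentered"
  lpg <- makeLogPosterior(data, config$parametrization,
                          prior_only = config$prior_only)
  layout <- paramLayout(data$n_raters)
  metric_kind <- config$metric
  if (is.null(metric_kind) || metric_kind == "auto")
    metric_kind <- if (layout$n <= 200) "dense" else "diag"
  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$n_chains)
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(chain_seeds[ch])
    init <- stats::runif(layout$n, -2, 2) * 0.1
    chains[[ch]] <- nutsChain(lpg, init, config$n_warmup, config$n_samples,
                              config$target_accept, config$max_treedepth,
                              chain_seeds[ch], metric_kind)
  }
  con <- lapply(chains, function(ch)
    thetaToDraws(ch$draws, layout, config$parametrization, data$raters))
  pnames <- colnames(con[[1]])
  draws <- array(NA_real_,
                 dim = c(config$n_samples, config$n_chains, length(pnames)),
                 dimnames = list(NULL, paste0("chain", seq_len(config$n_chains)),
                                 pnames))
  for (ch in seq_along(con)) draws[, ch, ] <- con[[ch]]
  diagnostics <- data.frame(
    parameter = pnames,
    rhat = vapply(pnames, function(p) splitRhat(draws[, , p]), numeric(1)),
    ess = vapply(pnames, function(p) effectiveSizeDraws(draws[, , p]),
                 numeric(1)),
    row.names = NULL)
  n_divergent <- sum(vapply(chains, function(ch) sum(ch$divergent),
                            integer(1)))
  divergent <- vapply(chains, `[[`, logical(config$n_samples), "divergent")
  fit <- structure(list(
    draws = draws, diagnostics = diagnostics, n_divergent = n_divergent,
    divergent = matrix(divergent, ncol = config$n_chains),
    accept_rate = mean(vapply(chains, `[[`, numeric(1), "accept_rate")),
    step_sizes = vapply(chains, `[[`, numeric(1), "step_size"),
    config = config, data = data), class = "hier_fit")
  if (any(diagnostics$rhat > 1.01, na.rm = TRUE))
    warning(sprintf("convergence: %d parameter(s) with split R-hat > 1.01 (max %.3f)",
                    sum(diagnostics$rhat > 1.01, na.rm = TRUE),
                    max(diagnostics$rhat, na.rm = TRUE)))
  if (n_divergent > 0)
    warning(sprintf("%d divergent transition(s) after warmup", n_divergent))
  fit
}

#' Flatten posterior draws to a matrix
#'
#' @param x a `hier_fit`.
#' @param ... unused.
#' @return (iterations * chains) x parameters numeric matrix.
#' @export
as.matrix.hier_fit <- function(x, ...) {
  d <- x$draws
  out <- matrix(d, nrow = dim(d)[1] * dim(d)[2], ncol = dim(d)[3])
  colnames(out) <- dimnames(d)[[3]]
  out
}

#' @export
print.hier_fit <- function(x, ...) {
  cat(sprintf("<hier_fit> %d chains x %d draws (%s parametrization), %d parameters\n",
              dim(x$draws)[2], dim(x$draws)[1], x$config$parametrization,
              dim(x$draws)[3]))
  cat(sprintf("  divergent transitions: %d; max split R-hat: %.3f; min ESS: %.0f\n",
              x$n_divergent, max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.hier_fit <- function(object, ...) {
  m <- as.matrix(object)
  data.frame(parameter = colnames(m), mean = colMeans(m),
             sd = apply(m, 2, stats::sd),
             q5 = apply(m, 2, stats::quantile, 0.05),
             q95 = apply(m, 2, stats::quantile, 0.95),
             rhat = object$diagnostics$rhat, ess = object$diagnostics$ess,
             row.names = NULL)
}
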