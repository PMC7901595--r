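# Hierarchical varying-intercepts Bernoulli model ------------------------------
#
# W_i ~ Bernoulli(p_i),  logit(p_i) = alpha[PID] + beta[LEVEL] + gamma[CATEGORY]
#                                     + delta[SPECIMEN] + epsilon[SPECIALTY]
# alpha_j ~ Normal(alpha_bar, sigma_alpha)   j = 1..n_raters
# beta_j  ~ Normal(0, sigma_beta)            j = 1..4
# gamma_j ~ Normal(0, sigma_gamma)           j = 1..5
# delta_j ~ Normal(0, sigma_delta)           j = 1..2
# epsilon_j ~ Normal(0, sigma_epsilon)       j = 1..3
# alpha_bar ~ Normal(0, 1.5); every sigma ~ Exponential(1)
#
# Each rater has exactly one career level, so alpha and beta are only weakly
# identified individually; the partial-pooling priors identify the split.

#' Parameters of the hierarchical varying-intercepts model
#'
#' All logit-scale effects: per-rater intercepts `alpha` (default length 17)
#' with grand mean `alpha_bar` and SD `sigma_alpha`; zero-centered effects for
#' career level `beta` (4: senior, expert, junior, resident), task category
#' `gamma` (5), specimen `delta` (2: biopsy, surgery) and subspecialty
#' `epsilon` (3: breast, urology, gastrointestinal), each with its own SD.
#'
#' @param alpha numeric vector of rater intercepts.
#' @param alpha_bar grand mean of the rater intercepts.
#' @param sigma_alpha,sigma_beta,sigma_gamma,sigma_delta,sigma_epsilon SDs.
#' @param beta,gamma,delta,epsilon effect vectors (lengths 4, 5, 2, 3).
#' @return list of class `model_params`.
#' @export
modelParams <- function(alpha = rep(0, 17), alpha_bar = 0, sigma_alpha = 1,
                        beta = rep(0, 4), sigma_beta = 1,
                        gamma = rep(0, 5), sigma_gamma = 1,
                        delta = rep(0, 2), sigma_delta = 1,
                        epsilon = rep(0, 3), sigma_epsilon = 1) {
  if (length(beta) != 4 || length(gamma) != 5 || length(delta) != 2 ||
      length(epsilon) != 3)
    stop("effect vector lengths must be (beta 4, gamma 5, delta 2, epsilon 3)")
  structure(list(alpha = alpha, alpha_bar = alpha_bar,
                 sigma_alpha = sigma_alpha, beta = beta,
                 sigma_beta = sigma_beta, gamma = gamma,
                 sigma_gamma = sigma_gamma, delta = delta,
                 sigma_delta = sigma_delta, epsilon = epsilon,
                 sigma_epsilon = sigma_epsilon),
            class = "model_params")
}

#' Index-coded model data from an item collection
#'
#' Drops unanswered items and encodes the outcome (`error` = 1, `correct` = 0)
#' together with 1-based cluster indices for rater, career level, task
#' category, specimen and subspecialty, in the canonical orders of
#' [careerLevels()] and friends. Warns if a career level, specimen or
#' subspecialty is never observed (its effect is then identified by the prior
#' alone).
#'
#' @param items a `response_items` collection.
#' @return list of class `model_data` with `w`, `pid`, `lev`, `cat`, `spec`,
#'   `sub`, `n`, `n_raters`, `raters` (id vector).
#' @export
modelData <- function(items) {
  stopifnot(inherits(items, "response_items"))
  ans <- items[items$outcome != "missing", , drop = FALSE]
  if (nrow(ans) == 0) stop("no answered items")
  raters <- sortParticipants(ans$participant)
  md <- list(w = as.integer(ans$outcome == "error"),
             pid = match(ans$participant, raters),
             lev = match(ans$level, careerLevels()),
             cat = as.integer(ans$category),
             spec = match(ans$specimen, specimenTypes()),
             sub = match(ans$subspecialty, subspecialties()),
             n = nrow(ans), n_raters = length(raters), raters = raters)
  unseen <- c(setdiff(1:4, md$lev), setdiff(1:5, md$cat) + 10,
              setdiff(1:2, md$spec) + 20, setdiff(1:3, md$sub) + 30)
  if (length(unseen) > 0)
    warning("some cluster levels are unobserved; their effects are identified by the prior only")
  class(md) <- "model_data"
  md
}

linearPredictor <- function(params, data) {
  params$alpha[data$pid] + params$beta[data$lev] + params$gamma[data$cat] +
    params$delta[data$spec] + params$epsilon[data$sub]
}

# log(1 + exp(x)) without overflow
log1pExp <- function(x) {
  out <- x
  small <- x < 35
  out[small] <- log1p(exp(x[small]))
  out
}

#' Bernoulli log-likelihood of the hierarchical model
#'
#' `sum_i [w_i * log(p_i) + (1 - w_i) * log(1 - p_i)]` with
#' `logit(p_i)` the additive linear predictor, computed via the numerically
#' stable identity `w * eta - log(1 + exp(eta))`.
#'
#' @param params a [modelParams()].
#' @param data a [modelData()] (or a `response_items` collection containing no
#'   missing outcomes, which is converted).
#' @return scalar log-likelihood.
#' @export
logLikelihood <- function(params, data) {
  if (inherits(data, "response_items")) {
    if (any(data$outcome == "missing"))
      stop("data contain missing outcomes; filter to answered items first")
    data <- modelData(data)
  }
  if (length(params$alpha) != data$n_raters)
    stop("alpha has length ", length(params$alpha), " but data index ",
         data$n_raters, " raters")
  eta <- linearPredictor(params, data)
  sum(data$w * eta - log1pExp(eta))
}

#' Joint log-prior of the hierarchical model
#'
#' `Normal(alpha_bar | 0, 1.5)` plus `Exponential(1)` on each SD, plus the
#' partial-pooling Normals: `alpha_j ~ N(alpha_bar, sigma_alpha)` and
#' zero-centered Normals for the other clusters. Returns `-Inf` (not an
#' error) when any SD is non-positive.
#'
#' @param params a [modelParams()].
#' @return scalar log-prior density.
#' @export
logPrior <- function(params) {
  sds <- c(params$sigma_alpha, params$sigma_beta, params$sigma_gamma,
           params$sigma_delta, params$sigma_epsilon)
  if (any(sds <= 0)) return(-Inf)
  stats::dnorm(params$alpha_bar, 0, 1.5, log = TRUE) +
    sum(stats::dexp(sds, 1, log = TRUE)) +
    sum(stats::dnorm(params$alpha, params$alpha_bar, params$sigma_alpha,
                     log = TRUE)) +
    sum(stats::dnorm(params$beta, 0, params$sigma_beta, log = TRUE)) +
    sum(stats::dnorm(params$gamma, 0, params$sigma_gamma, log = TRUE)) +
    sum(stats::dnorm(params$delta, 0, params$sigma_delta, log = TRUE)) +
    sum(stats::dnorm(params$epsilon, 0, params$sigma_epsilon, log = TRUE))
}

#' @rdname logPrior
#' @param data see [logLikelihood()].
#' @export
logPosterior <- function(params, data) {
  lp <- logPrior(params)
  if (!is.finite(lp)) return(lp)
  lp + logLikelihood(params, data)
}

#' Map non-centered offsets to model parameters
#'
#' The non-centered parametrization replaces each effect with a
#' standard-normal offset scaled by its hyperparameters:
#' `alpha_j = alpha_bar + sigma_alpha * z_j`, and `beta_j = sigma_beta * z_j`
#' (analogously for gamma, delta, epsilon). Given the hyperparameters the map
#' is bijective; it removes the prior correlation between effects and their
#' SDs that causes divergent Hamiltonian trajectories in the centered form.
#'
#' @param raw list with `alpha_bar`, the five `sigma_*`, and standard-normal
#'   offset vectors `z_alpha`, `z_beta`, `z_gamma`, `z_delta`, `z_epsilon`.
#' @return a [modelParams()].
#' @export
noncenteredTransform <- function(raw) {
  modelParams(alpha = raw$alpha_bar + raw$sigma_alpha * raw$z_alpha,
              alpha_bar = raw$alpha_bar, sigma_alpha = raw$sigma_alpha,
              beta = raw$sigma_beta * raw$z_beta, sigma_beta = raw$sigma_beta,
              gamma = raw$sigma_gamma * raw$z_gamma,
              sigma_gamma = raw$sigma_gamma,
              delta = raw$sigma_delta * raw$z_delta,
              sigma_delta = raw$sigma_delta,
              epsilon = raw$sigma_epsilon * raw$z_epsilon,
              sigma_epsilon = raw$sigma_epsilon)
}

# Unconstrained parameter vector layout (both parametrizations):
# [alpha_bar, log sigma_alpha..epsilon (5), effect block (n_raters+4+5+2+3)]
# In the non-centered form the effect block holds the z offsets; in the
# centered form it holds the effects themselves.
paramLayout <- function(n_raters) {
  sizes <- c(alpha = n_raters, beta = 4, gamma = 5, delta = 2, epsilon = 3)
  offsets <- 7L + c(0L, cumsum(sizes))[1:5]
  list(sizes = sizes, offsets = stats::setNames(offsets, names(sizes)),
       n = 6L + sum(sizes))
}

unpackTheta <- function(theta, layout, parametrization) {
  centered <- centeredBlocks(parametrization)
  ab <- theta[1]
  sig <- exp(theta[2:6])
  blocks <- lapply(seq_along(layout$sizes), function(k)
    theta[layout$offsets[k] + seq_len(layout$sizes[k]) - 1L])
  names(blocks) <- names(layout$sizes)
  means <- c(ab, 0, 0, 0, 0)
  for (k in 1:5)
    if (!centered[k]) blocks[[k]] <- means[k] + sig[k] * blocks[[k]]
  modelParams(alpha = blocks$alpha, alpha_bar = ab, sigma_alpha = sig[1],
              beta = blocks$beta, sigma_beta = sig[2],
              gamma = blocks$gamma, sigma_gamma = sig[3],
              delta = blocks$delta, sigma_delta = sig[4],
              epsilon = blocks$epsilon, sigma_epsilon = sig[5])
}

# which effect blocks are sampled on the centered scale. "mixed" centers the
# small clusters the likelihood pins down tightly (task category, specimen,
# subspecialty: each level sees hundreds of items), for which non-centering
# can create a ridge at large sigma; the rater block (about 80 items per
# rater) and the career-level block confounded with it stay non-centered,
# where the prior funnel dominates. An alternative to the non-centered
# default for sensitivity checks.
centeredBlocks <- function(parametrization) {
  switch(parametrization,
    noncentered = rep(FALSE, 5),
    centered = rep(TRUE, 5),
    mixed = c(FALSE, FALSE, TRUE, TRUE, TRUE),
    stop("unknown parametrization: ", parametrization))
}

# log-posterior and gradient on the unconstrained scale (sigmas sampled as
# log(sigma) with the Exponential(1) prior plus the log Jacobian).
# prior_only drops the likelihood term (sampler correctness checks).
makeLogPosterior <- function(data,
                             parametrization = c("mixed", "noncentered",
                                                 "centered"),
                             prior_only = FALSE) {
  parametrization <- match.arg(parametrization)
  centered <- centeredBlocks(parametrization)
  layout <- paramLayout(data$n_raters)
  idx <- lapply(seq_along(layout$sizes), function(k)
    layout$offsets[k] + seq_len(layout$sizes[k]) - 1L)
  names(idx) <- names(layout$sizes)
  di <- list(data$pid, data$lev, data$cat, data$spec, data$sub)
  nlev <- c(data$n_raters, 4L, 5L, 2L, 3L)

  function(theta) {
    ab <- theta[1]
    ls <- theta[2:6]
    sig <- exp(ls)
    z <- lapply(idx, function(i) theta[i])
    grad <- numeric(layout$n)
    # hyperpriors: alpha_bar ~ N(0, 1.5); sigma ~ Exp(1) with log-scale Jacobian
    lp <- stats::dnorm(ab, 0, 1.5, log = TRUE) + sum(-sig + ls)
    grad[1] <- -ab / 2.25
    grad[2:6] <- -sig + 1

    means <- c(ab, 0, 0, 0, 0)
    eff <- vector("list", 5)
    for (k in 1:5) {
      if (centered[k]) {
        # block holds the effects: N(mean, sigma) prior
        r <- (z[[k]] - means[k]) / sig[k]
        lp <- lp - 0.5 * sum(r^2) - nlev[k] * ls[k]
        grad[idx[[k]]] <- grad[idx[[k]]] - r / sig[k]
        grad[1 + k] <- grad[1 + k] + sum(r^2) - nlev[k]
        if (k == 1) grad[1] <- grad[1] + sum(z[[1]] - ab) / sig[1]^2
        eff[[k]] <- z[[k]]
      } else {
        # block holds standard-normal offsets
        lp <- lp - 0.5 * sum(z[[k]]^2)
        grad[idx[[k]]] <- -z[[k]]
        eff[[k]] <- means[k] + sig[k] * z[[k]]
      }
    }
    if (!prior_only) {
      eta <- eff[[1]][di[[1]]] + eff[[2]][di[[2]]] + eff[[3]][di[[3]]] +
        eff[[4]][di[[4]]] + eff[[5]][di[[5]]]
      lp <- lp + sum(data$w * eta - log1pExp(eta))
      resid <- data$w - stats::plogis(eta)
      geff <- lapply(1:5, function(k)
        as.vector(rowsum(resid, di[[k]], reorder = TRUE)))
      # rowsum drops unobserved indices; re-expand
      for (k in 1:5) {
        full <- numeric(nlev[k])
        full[sort(unique(di[[k]]))] <- geff[[k]]
        geff[[k]] <- full
      }
      for (k in 1:5) {
        if (centered[k]) {
          grad[idx[[k]]] <- grad[idx[[k]]] + geff[[k]]
        } else {
          grad[idx[[k]]] <- grad[idx[[k]]] + sig[k] * geff[[k]]
          grad[1 + k] <- grad[1 + k] + sig[k] * sum(z[[k]] * geff[[k]])
          if (k == 1) grad[1] <- grad[1] + sum(geff[[1]])
        }
      }
    }
    list(lp = lp, grad = grad)
  }
}

# named constrained-scale draws from an unconstrained theta matrix
thetaToDraws <- function(theta_mat, layout, parametrization, raters) {
  centered <- centeredBlocks(parametrization)
  ab <- theta_mat[, 1]
  sig <- exp(theta_mat[, 2:6, drop = FALSE])
  colnames(sig) <- paste0("sigma_", names(layout$sizes))
  blocks <- lapply(seq_along(layout$sizes), function(k)
    theta_mat[, layout$offsets[k] + seq_len(layout$sizes[k]) - 1L,
              drop = FALSE])
  names(blocks) <- names(layout$sizes)
  if (!centered[1]) blocks$alpha <- ab + sig[, 1] * blocks$alpha
  for (k in 2:5)
    if (!centered[k]) blocks[[k]] <- sig[, k] * blocks[[k]]
  colnames(blocks$alpha) <- paste0("alpha[", seq_len(layout$sizes[1]), "]")
  colnames(blocks$beta) <- paste0("beta[", careerLevels(), "]")
  colnames(blocks$gamma) <- paste0("gamma[", 1:5, "]")
  colnames(blocks$delta) <- paste0("delta[", specimenTypes(), "]")
  colnames(blocks$epsilon) <- paste0("epsilon[", subspecialties(), "]")
  out <- cbind(alpha_bar = ab, sig, blocks$alpha, blocks$beta, blocks$gamma,
               blocks$delta, blocks$epsilon)
  attr(out, "raters") <- raters
  out
}
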