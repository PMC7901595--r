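# Prior and posterior predictive simulation ------------------------------------

#' Highest posterior density interval of a sample
#'
#' The shortest contiguous interval of the sorted draws containing
#' `ceiling(mass * n)` of them. Ties between equally short windows are broken
#' to the lowest starting index (determinism). For symmetric unimodal samples
#' this coincides with the central interval; for skewed ones it is shifted
#' toward the mode.
#'
#' @param draws numeric vector, at least 2 values.
#' @param mass probability mass in (0, 1); default 0.89.
#' @return named numeric vector `c(low, high)`.
#' @export
hpdi <- function(draws, mass = 0.89) {
  if (length(draws) < 2) stop("need at least 2 draws")
  if (!is.numeric(mass) || mass <= 0 || mass >= 1)
    stop("mass must lie in (0, 1)")
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(low = x[1], high = x[n]))
  starts <- seq_len(n - m + 1)
  widths <- x[starts + m - 1] - x[starts]
  i <- which.min(widths)  # which.min takes the first minimum: lowest start
  c(low = x[i], high = x[i + m - 1])
}

#' Prior predictive distribution of the study-level error rate
#'
#' For each draw, all hyperparameters are sampled from the priors
#' (`alpha_bar ~ Normal(mean, sd)`, every SD `~ Exponential(rate)`), a full
#' study is simulated from the design via [simulateResponses()], and the
#' overall error rate among answered items is recorded. With the default
#' weakly regularizing priors the implied rates spread over most of (0, 1),
#' which is the sanity check the simulation exists for.
#'
#' @param design a [studyDesign()].
#' @param n_draws number of prior draws (>= 1).
#' @param seed integer seed.
#' @param alpha_bar_mean,alpha_bar_sd hyperprior on the grand mean
#'   (defaults 0 and 1.5).
#' @param sigma_rate rate of the Exponential prior on all SDs (default 1).
#' @return numeric vector of `n_draws` error rates in [0, 1].
#' @export
priorPredictive <- function(design, n_draws = 1000, seed = 1,
                            alpha_bar_mean = 0, alpha_bar_sd = 1.5,
                            sigma_rate = 1) {
  stopifnot(inherits(design, "study_design"), n_draws >= 1)
  set.seed(seed)
  hyper <- data.frame(
    alpha_bar = stats::rnorm(n_draws, alpha_bar_mean, alpha_bar_sd),
    s = matrix(stats::rexp(5 * n_draws, sigma_rate), n_draws, 5))
  item_seeds <- sample.int(.Machine$integer.max - 1L, n_draws)
  vapply(seq_len(n_draws), function(i) {
    params <- generativeParams(
      alpha_bar = hyper$alpha_bar[i], sigma_alpha = hyper$s.1[i],
      sigma_beta = hyper$s.2[i], sigma_gamma = hyper$s.3[i],
      sigma_delta = hyper$s.4[i], sigma_epsilon = hyper$s.5[i])
    items <- simulateResponses(design, params, seed = item_seeds[i])
    ans <- items$outcome[items$outcome != "missing"]
    if (length(ans) == 0) return(NA_real_)
    mean(ans == "error")
  }, numeric(1))
}

#' Posterior predictive performance of an average pathologist by career level
#'
#' For each posterior draw, the error probability of an average pathologist
#' at the given career level is `plogis(alpha_bar + beta[level])`
#' (`grand_mean` mode) or `plogis(alpha_new + beta[level])` with
#' `alpha_new ~ Normal(alpha_bar, sigma_alpha)` drawn per posterior draw
#' (`new_pathologist` mode, the default, which displays the full predictive
#' spread for a rater not in the study). Task-category, specimen and
#' subspecialty effects are deliberately set to zero: the prediction isolates
#' the career-level contrast after adjusting for those factors. Summarized as
#' the posterior mean and an 89% HPDI by default.
#'
#' @param posterior a `hier_fit`, or a matrix of draws with columns
#'   `alpha_bar`, `sigma_alpha` and `beta[<level>]`.
#' @param level one of [careerLevels()].
#' @param mode `"new_pathologist"` (default) or `"grand_mean"`.
#' @param mass HPDI probability mass (default 0.89).
#' @param seed seed for the new-pathologist draws.
#' @param items optional `response_items` for the observed (raw) rate of the
#'   level, reported alongside.
#' @return list of class `predictive_summary` with `level`, `mode`,
#'   `mean_error_prob`, `hpdi_low`, `hpdi_high`, `raw_rate`, `draws`.
#' @export
averagePathologist <- function(posterior, level,
                               mode = c("new_pathologist", "grand_mean"),
                               mass = 0.89, seed = 1, items = NULL) {
  mode <- match.arg(mode)
  if (!level %in% careerLevels())
    stop("unknown career level: ", level)
  m <- if (inherits(posterior, "hier_fit")) as.matrix(posterior)
       else as.matrix(posterior)
  need <- c("alpha_bar", "sigma_alpha", paste0("beta[", level, "]"))
  if (!all(need %in% colnames(m)))
    stop("posterior draws must have columns: ", paste(need, collapse = ", "))
  ab <- m[, "alpha_bar"]
  b <- m[, paste0("beta[", level, "]")]
  if (mode == "new_pathologist") {
    set.seed(seed)
    a_new <- stats::rnorm(length(ab), ab, m[, "sigma_alpha"])
    p <- stats::plogis(a_new + b)
  } else {
    p <- stats::plogis(ab + b)
  }
  h <- if (length(p) >= 2) hpdi(p, mass) else c(low = p, high = p)
  raw <- NA_real_
  if (!is.null(items)) {
    tab <- errorTable(items, "level", totals = FALSE)
    raw <- tab$rate[match(level, tab$group)]
  }
  structure(list(level = level, mode = mode, mass = mass,
                 mean_error_prob = mean(p), hpdi_low = unname(h[1]),
                 hpdi_high = unname(h[2]), raw_rate = raw, draws = p),
            class = "predictive_summary")
}

#' @export
print.predictive_summary <- function(x, ...) {
  cat(sprintf("average pathologist, level %s (%s): mean error %.3f, %d%% HPDI [%.3f, %.3f]%s\n",
              x$level, x$mode, x$mean_error_prob, round(100 * x$mass),
              x$hpdi_low, x$hpdi_high,
              if (is.na(x$raw_rate)) "" else sprintf(", raw %.3f", x$raw_rate)))
  invisible(x)
}

#' Predictive summaries for all career levels
#'
#' @inheritParams averagePathologist
#' @return data.frame with one row per level (the data behind a
#'   performance-by-career-level figure).
#' @export
predictiveTable <- function(posterior, mode = c("new_pathologist", "grand_mean"),
                            mass = 0.89, seed = 1, items = NULL) {
  mode <- match.arg(mode)
  rows <- lapply(careerLevels(), function(lv) {
    s <- averagePathologist(posterior, lv, mode, mass, seed = seed, items = items)
    data.frame(level = lv, mean_error_prob = s$mean_error_prob,
               hpdi_low = s$hpdi_low, hpdi_high = s$hpdi_high,
               raw_rate = s$raw_rate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
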