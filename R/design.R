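# Synthetic study generation --------------------------------------------------

#' Configuration of a synthetic concordance study design
#'
#' Defaults reproduce the emulated study: 17 raters (2 senior, 5 expert,
#' 6 junior, 4 resident), 25 cases (10 breast, 5 urology,
#' 10 gastrointestinal; 14 biopsy, 11 surgery; 8 nontumoral, 7 benign,
#' 10 malignant with grades split 5 grade-2 / 5 grade-3), and per-category
#' eligibility counts `{1:25, 2:16, 3:25, 4:10, 5:9}` giving 85 eligible
#' questions per rater (1445 items in total). Missingness is completely at
#' random at rate `100/1445` by default.
#'
#' The naive reading of the eligibility rules (questions 1 and 3 on all 25
#' cases, 2 on all 17 tumoral, 4 and 5 on all 10 malignant) yields 87
#' questions per rater; the default drops question 2 on one tumoral case and
#' question 5 on one malignant case, one feasible assignment consistent with
#' the published totals (see the methods vignette).
#'
#' @param n_participants_per_level named counts by career level.
#' @param n_subspecialty,n_specimen,n_lesion named case-composition counts.
#' @param n_grade named counts of grade 2/3 among malignant cases.
#' @param eligibility_counts named (by category "1".."5") counts of eligible
#'   cases per category.
#' @param missing_rate probability an eligible item goes unanswered.
#' @return list of class `design_config`.
#' @export
designConfig <- function(
    n_participants_per_level = c(senior = 2, expert = 5, junior = 6, resident = 4),
    n_subspecialty = c(breast = 10, urology = 5, gastrointestinal = 10),
    n_specimen = c(biopsy = 14, surgery = 11),
    n_lesion = c(nontumoral = 8, benign = 7, malignant = 10),
    n_grade = c(`2` = 5, `3` = 5),
    eligibility_counts = c(`1` = 25, `2` = 16, `3` = 25, `4` = 10, `5` = 9),
    missing_rate = 100 / 1445) {
  cfg <- list(n_participants_per_level = n_participants_per_level,
              n_subspecialty = n_subspecialty, n_specimen = n_specimen,
              n_lesion = n_lesion, n_grade = n_grade,
              eligibility_counts = eligibility_counts,
              missing_rate = missing_rate)
  validateDesignConfig(cfg)
  class(cfg) <- "design_config"
  cfg
}

validateDesignConfig <- function(cfg) {
  if (!setequal(names(cfg$n_participants_per_level), careerLevels()))
    stop("n_participants_per_level must name all career levels")
  n_cases <- sum(cfg$n_subspecialty)
  if (sum(cfg$n_specimen) != n_cases || sum(cfg$n_lesion) != n_cases)
    stop("case composition counts must all sum to the same number of cases")
  if (sum(cfg$n_grade) != cfg$n_lesion[["malignant"]])
    stop("grade counts must sum to the number of malignant cases")
  ec <- cfg$eligibility_counts
  if (!setequal(names(ec), as.character(1:5)))
    stop("eligibility_counts must be named by category 1..5")
  ec <- ec[as.character(1:5)]
  n_tumoral <- cfg$n_lesion[["benign"]] + cfg$n_lesion[["malignant"]]
  caps <- c(n_cases, n_tumoral, n_cases, cfg$n_lesion[["malignant"]],
            cfg$n_lesion[["malignant"]])
  over <- which(ec > caps)
  if (length(over) > 0)
    stop(sprintf("infeasible eligibility_counts: category %d asks for %d cases but only %d are eligible",
                 over[1], ec[over[1]], caps[over[1]]))
  if (any(ec < 0)) stop("eligibility_counts must be non-negative")
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1)
    stop("missing_rate must be in [0, 1]")
  invisible(cfg)
}

#' Generate a study design from a configuration
#'
#' Case attributes (subspecialty, specimen, lesion class, grade) are assigned
#' by independent seeded shuffles of the configured marginal compositions, so
#' every marginal count is met exactly. Category eligibility respects the
#' lesion-class constraints: the configured number of eligible cases per
#' category is drawn from the allowed pool (all cases for 1 and 3, tumoral
#' cases for 2, malignant cases for 4 and 5).
#'
#' @param config a [designConfig()].
#' @param seed integer seed; the design is deterministic given the seed.
#' @return a [studyDesign()].
#' @export
generateDesign <- function(config = designConfig(), seed = 1) {
  validateDesignConfig(config)
  set.seed(seed)
  npl <- config$n_participants_per_level[careerLevels()]
  participants <- data.frame(
    id = paste0("P", seq_len(sum(npl))),
    level = rep(careerLevels(), npl),
    stringsAsFactors = FALSE)
  n_cases <- sum(config$n_subspecialty)
  shuf <- function(x) x[sample.int(length(x))]
  lesion <- shuf(rep(lesionClasses(), config$n_lesion[lesionClasses()]))
  grade <- rep(NA_integer_, n_cases)
  grade[lesion == "malignant"] <-
    shuf(rep(c(2L, 3L), config$n_grade[c("2", "3")]))
  cases <- data.frame(
    id = seq_len(n_cases),
    subspecialty = shuf(rep(subspecialties(),
                            config$n_subspecialty[subspecialties()])),
    specimen = shuf(rep(specimenTypes(), config$n_specimen[specimenTypes()])),
    lesion_class = lesion, grade = grade, stringsAsFactors = FALSE)
  elig <- matrix(FALSE, n_cases, 5)
  ec <- config$eligibility_counts[as.character(1:5)]
  for (k in 1:5) {
    pool <- which(categoryAllowed(k, cases$lesion_class))
    elig[pool[sample.int(length(pool), ec[k])], k] <- TRUE
  }
  studyDesign(participants, cases, elig, missing_rate = config$missing_rate)
}

#' Generative (true) parameters for simulation
#'
#' The additive logit-scale effects of the hierarchical model, used as known
#' truth when simulating studies: a grand-mean intercept `alpha_bar` and the
#' standard deviations of the rater, career-level, task-category, specimen
#' and subspecialty effect distributions. Effect vectors may be fixed
#' explicitly; otherwise they are drawn once per simulated study from their
#' Normal distributions (rater intercepts around `alpha_bar`, all other
#' clusters around 0).
#'
#' @param alpha_bar grand-mean log-odds of error.
#' @param sigma_alpha,sigma_beta,sigma_gamma,sigma_delta,sigma_epsilon
#'   non-negative SDs on the logit scale.
#' @param alpha,beta,gamma,delta,epsilon optional fixed effect vectors
#'   (lengths: raters, 4, 5, 2, 3).
#' @return list of class `generative_params`.
#' @export
generativeParams <- function(alpha_bar = -2, sigma_alpha = 0.5,
                             sigma_beta = 0.5, sigma_gamma = 0.5,
                             sigma_delta = 0.5, sigma_epsilon = 0.5,
                             alpha = NULL, beta = NULL, gamma = NULL,
                             delta = NULL, epsilon = NULL) {
  sds <- c(sigma_alpha, sigma_beta, sigma_gamma, sigma_delta, sigma_epsilon)
  if (any(!is.finite(c(alpha_bar, sds))) || any(sds < 0))
    stop("alpha_bar must be finite and all SDs finite and >= 0")
  structure(list(alpha_bar = alpha_bar, sigma_alpha = sigma_alpha,
                 sigma_beta = sigma_beta, sigma_gamma = sigma_gamma,
                 sigma_delta = sigma_delta, sigma_epsilon = sigma_epsilon,
                 alpha = alpha, beta = beta, gamma = gamma, delta = delta,
                 epsilon = epsilon),
            class = "generative_params")
}

#' Simulate item-level responses under the hierarchical model
#'
#' For each eligible (rater, case, category) item, an error is drawn
#' Bernoulli with probability `plogis(alpha[rater] + beta[level] +
#' gamma[category] + delta[specimen] + epsilon[subspecialty])`. Cluster
#' effects are drawn once per study from their Normal distributions unless
#' fixed in `params`. Missingness is applied independently at the design's
#' `missing_rate`. Fully reproducible given the seed.
#'
#' @param design a [studyDesign()].
#' @param params a [generativeParams()].
#' @param seed integer seed.
#' @return a `response_items` collection with attribute `"true_effects"`.
#' @export
simulateResponses <- function(design, params = generativeParams(), seed = 1) {
  stopifnot(inherits(design, "study_design"),
            inherits(params, "generative_params"))
  set.seed(seed)
  np <- nrow(design$participants)
  draw <- function(fixed, n, mean, sd) {
    if (!is.null(fixed)) {
      if (length(fixed) != n) stop("fixed effect vector of wrong length")
      fixed
    } else stats::rnorm(n, mean, sd)
  }
  eff <- list(
    alpha = draw(params$alpha, np, params$alpha_bar, params$sigma_alpha),
    beta = draw(params$beta, 4, 0, params$sigma_beta),
    gamma = draw(params$gamma, 5, 0, params$sigma_gamma),
    delta = draw(params$delta, 2, 0, params$sigma_delta),
    epsilon = draw(params$epsilon, 3, 0, params$sigma_epsilon))
  grid <- designItemGrid(design)
  eta <- eff$alpha[match(grid$participant, design$participants$id)] +
    eff$beta[match(grid$level, careerLevels())] +
    eff$gamma[grid$category] +
    eff$delta[match(grid$specimen, specimenTypes())] +
    eff$epsilon[match(grid$subspecialty, subspecialties())]
  err <- stats::rbinom(nrow(grid), 1, stats::plogis(eta))
  grid$outcome <- ifelse(err == 1, "error", "correct")
  miss <- stats::runif(nrow(grid)) < design$missing_rate
  grid$outcome[miss] <- "missing"
  items <- responseItems(grid[itemColumns()])
  attr(items, "true_effects") <- eff
  items
}

# Reconstruction from marginal tables ------------------------------------------

# depth-first search for a rater -> career-level assignment whose per-level
# task and error sums match the level marginals; sizes come from the design.
assignLevels <- function(path_tasks, path_errors, level_table, sizes) {
  lev <- level_table$group
  sizes <- sizes[lev]
  if (anyNA(sizes)) stop("design career-level sizes do not cover the level marginals")
  n <- length(path_tasks)
  if (sum(sizes) != n)
    stop("level sizes must sum to the number of pathologists")
  rem_size <- as.integer(sizes)
  rem_t <- level_table$n_tasks
  rem_e <- level_table$n_errors
  assign <- integer(n)
  found <- NULL
  dfs <- function(i) {
    if (!is.null(found)) return()
    if (i > n) { found <<- assign; return() }
    for (g in seq_along(lev)) {
      if (rem_size[g] > 0 && rem_t[g] >= path_tasks[i] &&
          rem_e[g] >= path_errors[i]) {
        rem_size[g] <<- rem_size[g] - 1L
        rem_t[g] <<- rem_t[g] - path_tasks[i]
        rem_e[g] <<- rem_e[g] - path_errors[i]
        assign[i] <<- g
        dfs(i + 1L)
        rem_size[g] <<- rem_size[g] + 1L
        rem_t[g] <<- rem_t[g] + path_tasks[i]
        rem_e[g] <<- rem_e[g] + path_errors[i]
        if (!is.null(found)) return()
      }
    }
  }
  dfs(1L)
  if (is.null(found))
    stop("no career-level assignment is consistent with the pathologist and level marginals")
  lev[found]
}

# place `sum(row_margin)` flags on the item grid with exact per-rater margins
# and target counts per category / specimen / subspecialty class, by random
# initial allocation followed by same-rater swap repair (hill climbing on the
# total absolute marginal discrepancy).
placeFlagsWithMargins <- function(grid, row_margin, target_q, target_sp,
                                  target_su, eligible = rep(TRUE, nrow(grid)),
                                  max_steps = 200000L) {
  iq <- grid$category
  isp <- match(grid$specimen, specimenTypes())
  isu <- match(grid$subspecialty, subspecialties())
  raters <- names(row_margin)
  ip <- match(grid$participant, raters)
  flag <- rep(FALSE, nrow(grid))
  for (p in seq_along(raters)) {
    idx <- which(ip == p & eligible)
    if (row_margin[p] > length(idx))
      stop("rater margin exceeds available items for ", raters[p])
    flag[idx[sample.int(length(idx), row_margin[p])]] <- TRUE
  }
  cq <- tabulate(iq[flag], 5)
  csp <- tabulate(isp[flag], 2)
  csu <- tabulate(isu[flag], 3)
  disc <- sum(abs(cq - target_q)) + sum(abs(csp - target_sp)) +
    sum(abs(csu - target_su))
  steps <- 0L
  while (disc > 0 && steps < max_steps) {
    steps <- steps + 1L
    p <- sample.int(length(raters), 1)
    on <- which(flag & ip == p & eligible)
    off <- which(!flag & ip == p & eligible)
    if (length(on) == 0 || length(off) == 0) next
    i <- on[sample.int(length(on), 1)]
    j <- off[sample.int(length(off), 1)]
    delta <- 0
    stepDelta <- function(cls_i, cls_j, cnt, tgt) {
      if (cls_i == cls_j) return(0)
      (abs(cnt[cls_i] - 1 - tgt[cls_i]) - abs(cnt[cls_i] - tgt[cls_i])) +
        (abs(cnt[cls_j] + 1 - tgt[cls_j]) - abs(cnt[cls_j] - tgt[cls_j]))
    }
    delta <- stepDelta(iq[i], iq[j], cq, target_q) +
      stepDelta(isp[i], isp[j], csp, target_sp) +
      stepDelta(isu[i], isu[j], csu, target_su)
    if (delta < 0 || (delta == 0 && stats::runif(1) < 0.5)) {
      flag[i] <- FALSE
      flag[j] <- TRUE
      if (iq[i] != iq[j]) { cq[iq[i]] <- cq[iq[i]] - 1L; cq[iq[j]] <- cq[iq[j]] + 1L }
      if (isp[i] != isp[j]) { csp[isp[i]] <- csp[isp[i]] - 1L; csp[isp[j]] <- csp[isp[j]] + 1L }
      if (isu[i] != isu[j]) { csu[isu[i]] <- csu[isu[i]] - 1L; csu[isu[j]] <- csu[isu[j]] + 1L }
      disc <- disc + delta
    }
  }
  if (disc > 0)
    stop("marginal repair did not converge within the iteration cap; try another seed")
  flag
}

#' Reconstruct an item-level dataset from published marginal tables
#'
#' Builds a `response_items` dataset whose five marginal `(n_tasks, n_errors)`
#' tables (pathologist, career level, task category, specimen, subspecialty)
#' equal the reference tables exactly. The assignment is non-unique; this
#' routine uses seeded greedy allocation with swap-repair passes:
#'
#' 1. the marginals are checked for conservation (all groupings must agree on
#'    total tasks and errors);
#' 2. a capacity-feasible design is searched (case attributes are re-drawn
#'    until every group's eligible-item capacity covers its answered count),
#'    unless a suitable `design` is supplied;
#' 3. raters are assigned to career levels by exact search over partitions
#'    matching the level task/error sums;
#' 4. unanswered items, then error flags, are placed on the item grid with
#'    exact per-rater margins and repaired by same-rater swaps until the
#'    category/specimen/subspecialty margins match.
#'
#' Fails loudly (with advice to change the seed) if repair does not converge
#' within the iteration cap.
#'
#' @param reference list of `group_error_table`s from [readMarginalTable()];
#'   must contain all five groupings.
#' @param design optional [studyDesign()] to carry the counts; by default one
#'   is searched from `config`.
#' @param seed integer seed.
#' @param config [designConfig()] used when searching for a design.
#' @param max_design_tries cap on the design search.
#' @return a `response_items` collection passing
#'   [validateAgainstMarginals()] with zero mismatches.
#' @export
reconstructFromMarginals <- function(reference, design = NULL, seed = 1,
                                     config = designConfig(),
                                     max_design_tries = 20000L) {
  need <- groupingNames()
  if (!all(need %in% names(reference)))
    stop("reference must contain groupings: ", paste(need, collapse = ", "))
  tot_t <- vapply(reference[need], function(x) sum(x$n_tasks), numeric(1))
  tot_e <- vapply(reference[need], function(x) sum(x$n_errors), numeric(1))
  if (length(unique(tot_t)) != 1 || length(unique(tot_e)) != 1)
    stop(sprintf("inconsistent marginals: grouping totals disagree (tasks %s; errors %s)",
                 paste(tot_t, collapse = "/"), paste(tot_e, collapse = "/")))
  path_tab <- reference$pathologist
  ord <- match(sortParticipants(path_tab$group), path_tab$group)
  path_tab <- path_tab[ord, ]
  n_raters <- nrow(path_tab)

  set.seed(seed)
  ans_q <- reference$category$n_tasks[
    match(as.character(1:5), reference$category$group)]
  err_q <- reference$category$n_errors[
    match(as.character(1:5), reference$category$group)]
  ans_sp <- reference$specimen$n_tasks[
    match(specimenTypes(), reference$specimen$group)]
  err_sp <- reference$specimen$n_errors[
    match(specimenTypes(), reference$specimen$group)]
  ans_su <- reference$subspecialty$n_tasks[
    match(subspecialties(), reference$subspecialty$group)]
  err_su <- reference$subspecialty$n_errors[
    match(subspecialties(), reference$subspecialty$group)]
  if (anyNA(c(ans_q, ans_sp, ans_su)))
    stop("reference marginals must cover all categories, specimens and subspecialties")

  capacityOK <- function(d) {
    e_sp <- vapply(specimenTypes(), function(s)
      sum(d$eligibility[d$cases$specimen == s, ]), numeric(1))
    e_su <- vapply(subspecialties(), function(s)
      sum(d$eligibility[d$cases$subspecialty == s, ]), numeric(1))
    e_q <- colSums(d$eligibility)
    all(n_raters * e_sp >= ans_sp) && all(n_raters * e_su >= ans_su) &&
      all(n_raters * e_q >= ans_q)
  }
  if (is.null(design)) {
    for (try in seq_len(max_design_tries)) {
      design <- generateDesign(config,
                               seed = (seed + 7919L * try) %% .Machine$integer.max)
      if (capacityOK(design)) break
      design <- NULL
    }
    if (is.null(design))
      stop("no capacity-feasible design found within the try cap; try another seed")
  } else if (!capacityOK(design)) {
    stop("supplied design cannot carry the reference marginals (eligible-item capacity too small)")
  }
  if (nrow(design$participants) != n_raters)
    stop("design has ", nrow(design$participants), " raters but the pathologist marginal has ",
         n_raters)

  sizes <- table(design$participants$level)
  levels_assigned <- assignLevels(path_tab$n_tasks, path_tab$n_errors,
                                  reference$level, sizes)
  design$participants <- data.frame(id = path_tab$group,
                                    level = levels_assigned,
                                    stringsAsFactors = FALSE)
  grid <- designItemGrid(design)
  nq <- questionsPerParticipant(design)
  miss_margin <- stats::setNames(nq - path_tab$n_tasks, path_tab$group)
  if (any(miss_margin < 0))
    stop("a pathologist answered more items than the design makes eligible")
  e_q <- colSums(design$eligibility) * n_raters
  e_sp <- vapply(specimenTypes(), function(s)
    sum(design$eligibility[design$cases$specimen == s, ]), numeric(1)) * n_raters
  e_su <- vapply(subspecialties(), function(s)
    sum(design$eligibility[design$cases$subspecialty == s, ]), numeric(1)) * n_raters
  miss <- placeFlagsWithMargins(grid, miss_margin, e_q - ans_q, e_sp - ans_sp,
                                e_su - ans_su)
  err_margin <- stats::setNames(path_tab$n_errors, path_tab$group)
  err <- placeFlagsWithMargins(grid, err_margin, err_q, err_sp, err_su,
                               eligible = !miss)
  grid$outcome <- ifelse(miss, "missing", ifelse(err, "error", "correct"))
  items <- responseItems(grid[itemColumns()])
  report <- validateAgainstMarginals(items, reference[need])
  if (attr(report, "n_mismatches") > 0)
    stop("internal error: reconstruction failed validation")
  attr(items, "design") <- design
  items
}
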