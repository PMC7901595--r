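test_that("default design matches the emulated study layout", {
  design <- generateDesign(designConfig(), seed = 1)
  expect_equal(nrow(design$participants), 17L)
  expect_equal(nrow(design$cases), 25L)
  expect_equal(questionsPerParticipant(design), 85L)
  expect_equal(nrow(pathoconcord:::designItemGrid(design)), 1445L)
  # case composition marginals
  counts_of <- function(x, groups)
    vapply(groups, function(g) sum(x == g), integer(1))
  expect_equal(counts_of(design$cases$subspecialty, subspecialties()),
               c(breast = 10L, urology = 5L, gastrointestinal = 10L))
  expect_equal(counts_of(design$cases$specimen, specimenTypes()),
               c(biopsy = 14L, surgery = 11L))
  expect_equal(as.integer(table(design$cases$lesion_class)[
    c("nontumoral", "benign", "malignant")]), c(8L, 7L, 10L))
  expect_equal(as.integer(table(design$cases$grade)), c(5L, 5L))
  # eligibility respects lesion-class constraints
  elig <- design$eligibility
  expect_true(all(elig[, c(1, 3)]))
  expect_true(all(design$cases$lesion_class[elig[, 2]] != "nontumoral"))
  expect_true(all(design$cases$lesion_class[elig[, 4]] == "malignant"))
  expect_true(all(design$cases$lesion_class[elig[, 5]] == "malignant"))
  # deterministic given the seed
  expect_identical(design, generateDesign(designConfig(), seed = 1))
})

test_that("eligibility counts drive the per-rater question total", {
  cfg <- designConfig(eligibility_counts = c(`1` = 25, `2` = 17, `3` = 25,
                                             `4` = 10, `5` = 10))
  expect_equal(questionsPerParticipant(generateDesign(cfg, seed = 2)), 87L)
  expect_error(designConfig(eligibility_counts = c(`1` = 25, `2` = 16,
                                                   `3` = 25, `4` = 10,
                                                   `5` = 11)),
               "infeasible")
})

test_that("simulated error rates follow the inverse-logit of the predictor", {
  design <- generateDesign(designConfig(missing_rate = 0), seed = 3)
  flat <- function(ab) generativeParams(alpha_bar = ab, sigma_alpha = 0,
                                        sigma_beta = 0, sigma_gamma = 0,
                                        sigma_delta = 0, sigma_epsilon = 0)
  for (ab in c(0, -2.35)) {
    items <- simulateResponses(design, flat(ab), seed = 11)
    p <- plogis(ab)
    emp <- mean(items$outcome == "error")
    expect_lt(abs(emp - p), 3 * sqrt(p * (1 - p) / 1445))
  }
  full_missing <- generateDesign(designConfig(missing_rate = 1), seed = 3)
  items <- simulateResponses(full_missing, flat(0), seed = 11)
  expect_true(all(items$outcome == "missing"))
  # reproducibility
  expect_identical(simulateResponses(design, flat(-1), seed = 5),
                   simulateResponses(design, flat(-1), seed = 5))
})

test_that("per-group rates converge to model-implied rates (LLN)", {
  cfg <- designConfig(
    n_participants_per_level = 50 * c(senior = 2, expert = 5, junior = 6,
                                      resident = 4),
    missing_rate = 0)
  design <- generateDesign(cfg, seed = 4)
  params <- generativeParams(
    alpha_bar = -2, sigma_alpha = 0, sigma_beta = 0, sigma_gamma = 0,
    sigma_delta = 0, sigma_epsilon = 0,
    beta = c(0.4, -0.2, 0, 0.8), gamma = c(0.3, -0.5, 0, 0.2, 1),
    delta = c(0.5, -0.5), epsilon = c(0.2, -0.2, 0))
  params$alpha <- rep(-2, 850)
  items <- simulateResponses(design, params, seed = 12)
  grid <- pathoconcord:::designItemGrid(design)
  eta <- -2 + params$beta[match(grid$level, careerLevels())] +
    params$gamma[grid$category] +
    params$delta[match(grid$specimen, specimenTypes())] +
    params$epsilon[match(grid$subspecialty, subspecialties())]
  for (g in c("level", "category", "specimen")) {
    tab <- errorTable(items, g, totals = FALSE)
    expected <- tapply(plogis(eta), grid[[pathoconcord:::groupingColumn(g)]],
                       mean)
    expected <- expected[as.character(tab$group)]
    se <- sqrt(expected * (1 - expected) / tab$n_tasks)
    expect_true(all(abs(tab$rate - expected) < 4 * se))
  }
})

test_that("reconstruction reproduces every reference marginal exactly", {
  t1 <- pkg_table1()
  items <- reconstructFromMarginals(t1, seed = 123)
  report <- validateAgainstMarginals(items, t1)
  expect_equal(attr(report, "n_mismatches"), 0L)
  tab <- errorTable(items, "pathologist")
  expect_equal(unlist(tab[tab$group == "Total", c("n_tasks", "n_errors")],
                      use.names = FALSE), c(1345L, 117L))
  # determinism and non-uniqueness: same seed identical, other seed valid
  expect_identical(as.data.frame(items),
                   as.data.frame(reconstructFromMarginals(t1, seed = 123)))
  items2 <- reconstructFromMarginals(t1, seed = 321)
  expect_equal(attr(validateAgainstMarginals(items2, t1), "n_mismatches"), 0L)
  expect_false(identical(as.data.frame(items), as.data.frame(items2)))
})

test_that("inconsistent marginals are rejected with a conservation error", {
  t1 <- pkg_table1()
  t1$level$n_errors[1] <- t1$level$n_errors[1] + 1L  # totals now 117 vs 118
  expect_error(reconstructFromMarginals(t1, seed = 1),
               "inconsistent marginals")
})
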