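# Descriptive error-rate analytics --------------------------------------------

groupingColumn <- function(grouping) {
  switch(grouping,
    pathologist = "participant",
    level = "level",
    category = "category",
    specimen = "specimen",
    subspecialty = "subspecialty",
    stop("grouping must be one of: ", paste(groupingNames(), collapse = ", "))
  )
}

groupingLevels <- function(items, grouping) {
  switch(grouping,
    pathologist = sortParticipants(items$participant),
    level = intersect(careerLevels(), items$level),
    category = intersect(taskCategories(), items$category),
    specimen = intersect(specimenTypes(), items$specimen),
    subspecialty = intersect(subspecialties(), items$subspecialty)
  )
}

#' Per-group error-count table
#'
#' Counts answered tasks and errors per group of a grouping variable; missing
#' (unanswered) items are excluded from both numerator and denominator. A
#' `Total` row is appended by default; its counts are identical across all
#' five groupings of the same item set (conservation).
#'
#' @param items a `response_items` collection.
#' @param grouping one of `"pathologist"`, `"level"`, `"category"`,
#'   `"specimen"`, `"subspecialty"`.
#' @param totals append a `Total` row (default TRUE).
#' @return A `group_error_table` with unrounded rates.
#' @export
errorTable <- function(items, grouping = "pathologist", totals = TRUE) {
  stopifnot(inherits(items, "response_items"))
  grouping <- match.arg(grouping, groupingNames())
  ans <- items[items$outcome != "missing", , drop = FALSE]
  lev <- groupingLevels(items, grouping)
  if (length(lev) == 0) stop("no groups present for grouping '", grouping, "'")
  g <- factor(as.character(ans[[groupingColumn(grouping)]]),
              levels = as.character(lev))
  n_tasks <- as.integer(table(g))
  n_errors <- as.integer(table(g[ans$outcome == "error"]))
  lab <- as.character(lev)
  if (totals) {
    lab <- c(lab, "Total")
    n_tasks <- c(n_tasks, sum(n_tasks))
    n_errors <- c(n_errors, sum(n_errors))
  }
  groupErrorTable(lab, n_tasks, n_errors, grouping = grouping)
}

#' Overall concordance of an item collection
#'
#' Answered items that are not errors are concordant with the gold-standard
#' (glass slide) diagnosis. The percentage is reported unrounded; display
#' rounding is left to the caller.
#'
#' @param items a `response_items` collection.
#' @return list with `n_answered`, `n_errors`, `n_concordant`,
#'   `concordance_pct`, `error_rate`.
#' @export
concordanceSummary <- function(items) {
  stopifnot(inherits(items, "response_items"))
  n_ans <- sum(items$outcome != "missing")
  if (n_ans == 0) stop("no answered items")
  n_err <- sum(items$outcome == "error")
  list(n_answered = n_ans, n_errors = n_err, n_concordant = n_ans - n_err,
       concordance_pct = 100 * (n_ans - n_err) / n_ans,
       error_rate = n_err / n_ans)
}

#' Round half away from zero
#'
#' Display rounding used for published error-rate cells (e.g. 26/81 = 0.3210
#' prints as 0.32, 47/310 = 0.1516 as 0.15). R's `round()` rounds half to
#' even, which differs on exact halves.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @rdname roundHalfUp
#' @export
formatRate <- function(x, digits = 2) {
  formatC(roundHalfUp(x, digits), format = "f", digits = digits)
}

#' @export
print.group_error_table <- function(x, digits = 2, ...) {
  grouping <- attr(x, "grouping")
  cat(sprintf("<group_error_table>%s\n",
              if (is.null(grouping)) "" else paste0(" by ", grouping)))
  shown <- as.data.frame(x)
  shown$rate <- formatRate(shown$rate, digits)
  print(shown, row.names = FALSE)
  invisible(x)
}

#' Median and interquartile range of group error rates
#'
#' Quantiles use linear interpolation on the unrounded rates (position
#' `1 + (n - 1) * p`, the default "type 7" convention of [stats::quantile()]);
#' display rounding to 2 decimals is a separate presentation step.
#'
#' @param rates numeric vector of proportions in `[0, 1]` (at least one).
#' @return list of class `summary_stats` with `median`, `q1`, `q3`,
#'   `n_groups`.
#' @export
medianIQR <- function(rates) {
  if (length(rates) < 1 || anyNA(rates)) stop("need >= 1 non-missing rates")
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  q <- stats::quantile(rates, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(median = q[2], q1 = q[1], q3 = q[3],
                 n_groups = length(rates)),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, digits = 2, ...) {
  cat(sprintf("median %s (IQR %s-%s), n = %d groups\n",
              formatRate(x$median, digits), formatRate(x$q1, digits),
              formatRate(x$q3, digits), x$n_groups))
  invisible(x)
}

#' Raw error proportions of selected tasks, cross-tabulated
#'
#' The data behind per-task comparison figures: for each requested diagnostic
#' task category and each group of the `by` variable, the raw error
#' proportion with its counts. Cells with no answered items get an `NA` rate
#' (undefined, not zero).
#'
#' @param items a `response_items` collection.
#' @param task_categories subset of 1..5.
#' @param by `"level"` or `"specimen"`.
#' @return data.frame with columns `category, group, n_tasks, n_errors, rate`.
#' @export
crossErrorRates <- function(items, task_categories, by = c("level", "specimen")) {
  stopifnot(inherits(items, "response_items"))
  by <- match.arg(by)
  task_categories <- as.integer(task_categories)
  if (!all(task_categories %in% taskCategories()))
    stop("task_categories must be a subset of 1..5")
  ans <- items[items$outcome != "missing" &
                 items$category %in% task_categories, , drop = FALSE]
  groups <- if (by == "level") intersect(careerLevels(), items$level)
            else intersect(specimenTypes(), items$specimen)
  out <- expand.grid(category = task_categories, group = groups,
                     stringsAsFactors = FALSE)
  cnt <- function(sub) c(nrow(sub), sum(sub$outcome == "error"))
  counts <- t(vapply(seq_len(nrow(out)), function(i) {
    cnt(ans[ans$category == out$category[i] &
              ans[[by]] == out$group[i], , drop = FALSE])
  }, numeric(2)))
  out$n_tasks <- as.integer(counts[, 1])
  out$n_errors <- as.integer(counts[, 2])
  out$rate <- ifelse(out$n_tasks > 0, out$n_errors / out$n_tasks, NA_real_)
  out
}
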