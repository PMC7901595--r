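# Domain vocabulary ----------------------------------------------------------

#' Career levels, diagnostic task categories, specimen types, subspecialties
#'
#' Canonical factor orderings used throughout the package. Career levels are
#' ordered senior, expert, junior, resident (indices j = 1..4 of the
#' level effects); diagnostic task categories are the five questions asked per
#' case (1 neoplastic?, 2 malignant/benign?, 3 diagnosis, 4 histotype,
#' 5 grade); specimen types are biopsy and surgery (j = 1..2); case
#' subspecialties are breast, urology and gastrointestinal (j = 1..3).
#'
#' @return A character (or integer, for categories) vector of valid tokens in
#'   canonical order.
#' @export
careerLevels <- function() c("senior", "expert", "junior", "resident")

#' @rdname careerLevels
#' @export
taskCategories <- function() 1:5

#' @rdname careerLevels
#' @export
specimenTypes <- function() c("biopsy", "surgery")

#' @rdname careerLevels
#' @export
subspecialties <- function() c("breast", "urology", "gastrointestinal")

#' @rdname careerLevels
#' @export
outcomeTokens <- function() c("correct", "error", "missing")

lesionClasses <- function() c("nontumoral", "benign", "malignant")

groupingNames <- function() c("pathologist", "level", "category", "specimen",
                              "subspecialty")

# category eligibility rule: which lesion classes may carry each question.
# Questions 1 and 3 apply to every case; question 2 only to tumoral lesions;
# questions 4 and 5 only to malignant ones.
categoryAllowed <- function(category, lesion_class) {
  switch(as.character(category),
    "1" = ,
    "3" = rep(TRUE, length(lesion_class)),
    "2" = lesion_class != "nontumoral",
    "4" = ,
    "5" = lesion_class == "malignant",
    stop("unknown category: ", category)
  )
}

# natural sort for rater ids P1..P17 (falls back to lexicographic)
sortParticipants <- function(ids) {
  ids <- unique(ids)
  num <- suppressWarnings(as.integer(sub("^P", "", ids)))
  if (anyNA(num)) sort(ids) else ids[order(num)]
}

itemColumns <- function() c("participant", "level", "case", "subspecialty",
                            "specimen", "category", "outcome")

# ResponseItem collection -----------------------------------------------------

#' Build a validated collection of item-level diagnostic responses
#'
#' A response item is one diagnostic answer: a rater (`participant`, with its
#' `level`), a case (`case`, with its `subspecialty` and `specimen`), a task
#' `category` (1-5) and an `outcome` token (`correct`, `error`, or `missing`
#' when the rater left the question unanswered). The career level and the case
#' attributes are carried redundantly on every row; the validator checks they
#' are consistent within participant and within case.
#'
#' @param df A data.frame with columns `participant`, `level`, `case`,
#'   `subspecialty`, `specimen`, `category`, `outcome`.
#' @return The validated data.frame with class `response_items`.
#' @export
responseItems <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(itemColumns(), names(df))
  if (length(missing_cols) > 0)
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  df <- df[itemColumns()]
  df$participant <- as.character(df$participant)
  df$level <- as.character(df$level)
  df$case <- as.integer(df$case)
  df$subspecialty <- as.character(df$subspecialty)
  df$specimen <- as.character(df$specimen)
  df$category <- as.integer(df$category)
  df$outcome <- as.character(df$outcome)
  validateItems(df)
  class(df) <- c("response_items", "data.frame")
  df
}

validateItems <- function(df) {
  checkTokens <- function(values, valid, what) {
    bad <- which(!(values %in% valid))
    if (length(bad) > 0)
      stop(sprintf("row %d: invalid %s '%s' (valid: %s)", bad[1], what,
                   values[bad[1]], paste(valid, collapse = ", ")),
           call. = FALSE)
  }
  checkTokens(df$level, careerLevels(), "level")
  checkTokens(df$subspecialty, subspecialties(), "subspecialty")
  checkTokens(df$specimen, specimenTypes(), "specimen")
  checkTokens(df$category, taskCategories(), "category")
  checkTokens(df$outcome, outcomeTokens(), "outcome")
  if (nrow(df) == 0) return(invisible(df))
  key <- paste(df$participant, df$case, df$category, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0)
    stop(sprintf("row %d: duplicate (participant, case, category) key (%s, %s, %s)",
                 dup[1], df$participant[dup[1]], df$case[dup[1]],
                 df$category[dup[1]]), call. = FALSE)
  # one level per participant, one subspecialty/specimen per case
  if (any(tapply(df$level, df$participant,
                 function(x) length(unique(x))) > 1))
    stop("inconsistent career level within a participant", call. = FALSE)
  for (col in c("subspecialty", "specimen"))
    if (any(tapply(df[[col]], df$case, function(x) length(unique(x))) > 1))
      stop("inconsistent ", col, " within a case", call. = FALSE)
  invisible(df)
}

#' @export
print.response_items <- function(x, ...) {
  answered <- sum(x$outcome != "missing")
  cat(sprintf("<response_items> %d items (%d answered, %d missing), %d raters, %d cases\n",
              nrow(x), answered, nrow(x) - answered,
              length(unique(x$participant)), length(unique(x$case))))
  NextMethod()
}

# Study design ----------------------------------------------------------------

#' Construct a study design
#'
#' The factorial layout of a concordance study: a roster of raters with career
#' levels, a case series with subspecialty, specimen type, lesion class and
#' (for malignant cases) grade, and a case-by-category eligibility matrix
#' recording which of the five diagnostic questions apply to each case.
#'
#' @param participants data.frame with columns `id`, `level`.
#' @param cases data.frame with columns `id`, `subspecialty`, `specimen`,
#'   `lesion_class`, `grade` (NA unless malignant).
#' @param eligibility logical matrix, cases x 5 categories.
#' @param missing_rate probability that an eligible item goes unanswered.
#' @return An object of class `study_design`.
#' @export
studyDesign <- function(participants, cases, eligibility,
                        missing_rate = 100 / 1445) {
  stopifnot(is.data.frame(participants), is.data.frame(cases),
            is.matrix(eligibility))
  if (anyDuplicated(participants$id) > 0)
    stop("duplicate participant ids")
  if (!all(participants$level %in% careerLevels()))
    stop("unknown career level in participants")
  if (!all(cases$subspecialty %in% subspecialties()) ||
      !all(cases$specimen %in% specimenTypes()) ||
      !all(cases$lesion_class %in% lesionClasses()))
    stop("unknown case attribute token")
  mal <- cases$lesion_class == "malignant"
  if (any(is.na(cases$grade[mal])) || any(!is.na(cases$grade[!mal])))
    stop("grade must be present exactly for malignant cases")
  if (!all(is.na(cases$grade) | cases$grade %in% c(2L, 3L)))
    stop("grade must be 2 or 3")
  if (nrow(eligibility) != nrow(cases) || ncol(eligibility) != 5)
    stop("eligibility must be a cases x 5 matrix")
  if (!all(eligibility[, 1]) || !all(eligibility[, 3]))
    stop("categories 1 and 3 must be eligible for every case")
  for (k in c(2L, 4L, 5L)) {
    ok <- categoryAllowed(k, cases$lesion_class)
    if (any(eligibility[, k] & !ok))
      stop("category ", k, " eligible on a case whose lesion class forbids it")
  }
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0,1]")
  structure(list(participants = participants, cases = cases,
                 eligibility = eligibility, missing_rate = missing_rate),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> %d raters (%s), %d cases, %d eligible questions per rater\n",
              nrow(x$participants),
              paste(sprintf("%s=%d", careerLevels(),
                            tabulate(match(x$participants$level, careerLevels()),
                                     4)), collapse = " "),
              nrow(x$cases), sum(x$eligibility)))
  invisible(x)
}

#' Number of eligible questions per participant in a design
#' @param design a `study_design`.
#' @return integer count (the same for every rater).
#' @export
questionsPerParticipant <- function(design) sum(design$eligibility)

# expand a design to its item grid (one row per rater x eligible (case, category))
designItemGrid <- function(design) {
  eq <- which(design$eligibility, arr.ind = TRUE)
  eq <- eq[order(eq[, 1], eq[, 2]), , drop = FALSE]
  np <- nrow(design$participants)
  ni <- nrow(eq)
  grid <- data.frame(
    participant = rep(design$participants$id, each = ni),
    level = rep(design$participants$level, each = ni),
    case = rep.int(eq[, 1], np),
    category = rep.int(eq[, 2], np),
    stringsAsFactors = FALSE
  )
  grid$subspecialty <- design$cases$subspecialty[grid$case]
  grid$specimen <- design$cases$specimen[grid$case]
  grid[itemColumns()[itemColumns() %in% names(grid)]]
  grid
}

# reconstruct a (partial) design from an item table: lesion class and grade are
# inferred from eligibility (categories 4/5 imply malignant, 2 implies tumoral)
designFromItems <- function(items, missing_rate = NULL) {
  participants <- unique(items[, c("participant", "level")])
  participants <- data.frame(id = participants$participant,
                             level = participants$level,
                             stringsAsFactors = FALSE)
  participants <- participants[order(match(participants$id,
                                           sortParticipants(participants$id))), ]
  rownames(participants) <- NULL
  case_ids <- sort(unique(items$case))
  cases <- data.frame(
    id = case_ids,
    subspecialty = items$subspecialty[match(case_ids, items$case)],
    specimen = items$specimen[match(case_ids, items$case)],
    stringsAsFactors = FALSE
  )
  elig <- matrix(FALSE, nrow = length(case_ids), ncol = 5)
  seen <- unique(items[, c("case", "category")])
  elig[cbind(match(seen$case, case_ids), seen$category)] <- TRUE
  elig[, 1] <- TRUE
  elig[, 3] <- TRUE
  cases$lesion_class <- ifelse(elig[, 4] | elig[, 5], "malignant",
                               ifelse(elig[, 2], "benign", "nontumoral"))
  cases$grade <- ifelse(cases$lesion_class == "malignant", 2L, NA_integer_)
  if (is.null(missing_rate))
    missing_rate <- mean(items$outcome == "missing")
  studyDesign(participants, cases, elig, missing_rate = missing_rate)
}

# Delimited-text I/O ----------------------------------------------------------

#' Read an item-level response table from CSV
#'
#' Expects a comma-delimited UTF-8 file with a mandatory header row and
#' columns `participant,level,case,subspecialty,specimen,category,outcome`.
#' All tokens are validated; violations are reported with the offending row
#' number. The study design (rater roster, case attributes, eligibility) is
#' reconstructed from the columns and attached as the `"design"` attribute
#' (lesion class is inferred from which categories appear for each case).
#'
#' @param path file path.
#' @return A `response_items` data.frame with attribute `design`.
#' @seealso [writeResponseTable()]
#' @export
readResponseTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  items <- responseItems(df)
  attr(items, "design") <- if (nrow(items) > 0) designFromItems(items) else NULL
  items
}

#' Write an item-level response table to CSV
#'
#' Inverse of [readResponseTable()]: the written file reads back equal to the
#' input (bit-stable round trip). An empty collection produces a header-only
#' file.
#'
#' @param items a `response_items` collection.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
writeResponseTable <- function(items, path) {
  stopifnot(inherits(items, "response_items"))
  utils::write.csv(as.data.frame(items), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Group error tables ----------------------------------------------------------

#' Build a group error table
#'
#' One row per group with the number of answered tasks, the number of errors
#' and the error rate `n_errors / n_tasks` (kept unrounded; see
#' [formatRate()] for display rounding).
#'
#' @param group character vector of group labels.
#' @param n_tasks,n_errors integer count vectors.
#' @param grouping optional name of the grouping variable.
#' @return data.frame of class `group_error_table`.
#' @export
groupErrorTable <- function(group, n_tasks, n_errors, grouping = NULL) {
  n_tasks <- as.integer(n_tasks)
  n_errors <- as.integer(n_errors)
  if (any(n_errors < 0) || any(n_tasks < 0) || any(n_errors > n_tasks))
    stop("need 0 <= n_errors <= n_tasks")
  out <- data.frame(group = as.character(group), n_tasks = n_tasks,
                    n_errors = n_errors,
                    rate = ifelse(n_tasks > 0, n_errors / n_tasks, NA_real_),
                    stringsAsFactors = FALSE)
  attr(out, "grouping") <- grouping
  class(out) <- c("group_error_table", "data.frame")
  out
}

#' Read a stacked marginal error table
#'
#' Reads a CSV with columns `grouping,group,n_tasks,n_errors` holding the
#' per-group error counts for the five groupings (pathologist, level,
#' category, specimen, subspecialty) plus a `total` row. The packaged copy of
#' the published study's marginal table is at
#' `system.file("extdata", "table1_marginals.csv", package = "pathoconcord")`.
#'
#' @param path file path.
#' @return A named list of `group_error_table` objects, one per grouping,
#'   plus element `total`.
#' @export
readMarginalTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("grouping", "group", "n_tasks", "n_errors")
  if (!all(need %in% names(df)))
    stop("marginal table needs columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$grouping), function(d) {
    tab <- groupErrorTable(d$group, d$n_tasks, d$n_errors,
                           grouping = d$grouping[1])
    # a published table may carry the rounded rate as printed; keep it
    # alongside the exact n_errors/n_tasks ratio
    if ("rate" %in% names(d)) tab$rate_printed <- d$rate
    tab
  })
  unknown <- setdiff(names(out), c(groupingNames(), "total"))
  if (length(unknown) > 0)
    stop("unknown grouping label(s): ", paste(unknown, collapse = ", "))
  out[c(intersect(groupingNames(), names(out)),
        intersect("total", names(out)))]
}

#' Check an item-level dataset against reference marginal tables
#'
#' Recomputes, for every grouping present in `reference`, the per-group
#' `(n_tasks, n_errors)` counts from `items` (answered items only) and
#' compares them with the reference counts. Groups present in the reference
#' but absent from the items are counted as 0 tasks / 0 errors and flagged.
#'
#' @param items a `response_items` collection.
#' @param reference a list of `group_error_table`s as returned by
#'   [readMarginalTable()], or a single `group_error_table` whose grouping
#'   must be named.
#' @return A data.frame report with one row per (grouping, group):
#'   columns `grouping, group, n_tasks, n_errors, ref_n_tasks, ref_n_errors,
#'   match`. Attribute `n_mismatches` gives the total count of `match == FALSE`.
#' @export
validateAgainstMarginals <- function(items, reference) {
  stopifnot(inherits(items, "response_items"))
  if (inherits(reference, "group_error_table"))
    reference <- stats::setNames(list(reference), attr(reference, "grouping"))
  rows <- list()
  for (grouping in names(reference)) {
    ref <- reference[[grouping]]
    if (grouping == "total") {
      computed <- groupErrorTable("Total", sum(items$outcome != "missing"),
                                  sum(items$outcome == "error"))
    } else {
      if (!grouping %in% groupingNames())
        stop("unknown grouping label: ", grouping)
      computed <- if (nrow(items) == 0)
        groupErrorTable(character(0), integer(0), integer(0))
      else errorTable(items, grouping, totals = FALSE)
    }
    idx <- match(ref$group, computed$group)
    rows[[grouping]] <- data.frame(
      grouping = grouping, group = ref$group,
      n_tasks = ifelse(is.na(idx), 0L, computed$n_tasks[idx]),
      n_errors = ifelse(is.na(idx), 0L, computed$n_errors[idx]),
      ref_n_tasks = ref$n_tasks, ref_n_errors = ref$n_errors,
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  report$match <- report$n_tasks == report$ref_n_tasks &
    report$n_errors == report$ref_n_errors
  attr(report, "n_mismatches") <- sum(!report$match)
  report
}
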