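# Likert survey aggregation ----------------------------------------------------

surveyFields <- function() c("attitude", "confidence", "satisfaction")

#' Build a validated collection of Likert survey responses
#'
#' One row per (participant, question): the survey `field` the question
#' belongs to (attitude towards, confidence in, or satisfaction with digital
#' pathology) and a `score` on the 1 (strongly disagree) to 5 (strongly
#' agree) scale.
#'
#' @param df data.frame with columns `participant`, `field`, `question`,
#'   `score`.
#' @return data.frame of class `likert_responses`.
#' @export
likertResponses <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("participant", "field", "question", "score")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  df <- df[need]
  df$score <- as.integer(df$score)
  bad <- which(!df$field %in% surveyFields())
  if (length(bad) > 0)
    stop(sprintf("row %d: invalid field '%s'", bad[1], df$field[bad[1]]))
  bad <- which(!df$score %in% 1:5)
  if (length(bad) > 0)
    stop(sprintf("row %d: score %s outside 1-5", bad[1], df$score[bad[1]]))
  if (anyDuplicated(df[c("participant", "question")]) > 0)
    stop("duplicate (participant, question) response")
  class(df) <- c("likert_responses", "data.frame")
  df
}

#' Aggregate Likert responses of one survey field
#'
#' Counts and proportions of each score 1-5 plus the "very good" proportion
#' (scores 4 or 5, i.e. moderately/strongly agree), reported with its
#' numerator and denominator.
#'
#' @param responses a [likertResponses()] collection.
#' @param field one of `"attitude"`, `"confidence"`, `"satisfaction"`.
#' @return list of class `survey_summary` with `field`, `counts` (named
#'   1-5), `proportions`, `n`, `high_n`, `high_prop`.
#' @export
aggregateSurvey <- function(responses, field) {
  stopifnot(inherits(responses, "likert_responses"))
  field <- match.arg(field, surveyFields())
  scores <- responses$score[responses$field == field]
  if (length(scores) == 0) stop("no responses for field '", field, "'")
  counts <- tabulate(scores, 5)
  names(counts) <- 1:5
  high <- sum(counts[c("4", "5")])
  structure(list(field = field, counts = counts,
                 proportions = counts / length(scores), n = length(scores),
                 high_n = high, high_prop = high / length(scores)),
            class = "survey_summary")
}

#' @export
print.survey_summary <- function(x, ...) {
  cat(sprintf("%s: very good (score 4-5) %d/%d, %s%%\n", x$field, x$high_n,
              x$n, formatC(roundHalfUp(100 * x$high_prop, 1), format = "f",
                           digits = 1)))
  print(round(x$proportions, 3))
  invisible(x)
}

#' Configuration for a synthetic survey
#'
#' Defaults emulate the reported aggregates: 17 participants; 4 attitude,
#' 7 confidence and 6 satisfaction questions (inferred from the printed
#' denominators 68, 119 and 102 divided by 17 participants — an inference,
#' the split is not stated); high-score (4-5) targets 44/68, 75/119, 56/102.
#'
#' @param n_participants number of raters.
#' @param questions_per_field named integer vector over the three fields;
#'   must sum to 17 questions by default study structure.
#' @param high_counts named targets of scores >= 4 per field.
#' @param total_questions required total (default 17).
#' @return list of class `survey_config`.
#' @export
surveyConfig <- function(n_participants = 17,
                         questions_per_field = c(attitude = 4, confidence = 7,
                                                 satisfaction = 6),
                         high_counts = c(attitude = 44, confidence = 75,
                                         satisfaction = 56),
                         total_questions = 17) {
  if (n_participants < 1) stop("need at least one participant")
  if (!setequal(names(questions_per_field), surveyFields()) ||
      !setequal(names(high_counts), surveyFields()))
    stop("questions_per_field and high_counts must name the three fields")
  if (sum(questions_per_field) != total_questions)
    stop(sprintf("questions per field sum to %d; the survey has %d questions",
                 sum(questions_per_field), total_questions))
  totals <- n_participants * questions_per_field[surveyFields()]
  hc <- high_counts[surveyFields()]
  if (any(hc < 0) || any(hc > totals))
    stop("infeasible high-score targets (must lie in [0, participants x questions])")
  structure(list(n_participants = n_participants,
                 questions_per_field = questions_per_field[surveyFields()],
                 high_counts = hc),
            class = "survey_config")
}

#' Synthesize a survey with exact marginal targets
#'
#' Generates a full response set (every participant answers every question)
#' in which, per field, exactly the configured number of responses score 4-5
#' (split uniformly between 4 and 5) and the remainder score 1-3 uniformly.
#' [aggregateSurvey()] on the result reproduces the targets exactly.
#'
#' @param config a [surveyConfig()].
#' @param seed integer seed.
#' @return a [likertResponses()] collection.
#' @export
synthesizeSurvey <- function(config = surveyConfig(), seed = 1) {
  stopifnot(inherits(config, "survey_config"))
  set.seed(seed)
  out <- list()
  qid <- 0L
  for (field in surveyFields()) {
    nq <- config$questions_per_field[[field]]
    if (nq == 0) next
    total <- config$n_participants * nq
    grid <- expand.grid(participant = paste0("P", seq_len(config$n_participants)),
                        question = qid + seq_len(nq), stringsAsFactors = FALSE)
    score <- sample(1:3, total, replace = TRUE)
    hi <- sample.int(total, config$high_counts[[field]])
    score[hi] <- sample(4:5, length(hi), replace = TRUE)
    out[[field]] <- data.frame(participant = grid$participant, field = field,
                               question = paste0("Q", grid$question),
                               score = score, stringsAsFactors = FALSE)
    qid <- qid + nq
  }
  likertResponses(do.call(rbind, out))
}
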