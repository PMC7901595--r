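# End-to-end pipeline ----------------------------------------------------------

#' Pipeline configuration
#'
#' Ties the stages together: ingest (read an item-level CSV, or reconstruct
#' one from a marginal table), describe, fit, predict, survey. All randomness
#' flows from the named seeds; there are no wall-clock defaults, so two runs
#' with the same configuration produce identical outputs.
#'
#' @param output_dir directory for the artifact bundle.
#' @param items_path optional CSV of item-level responses.
#' @param table1_path optional CSV of marginal tables (used to reconstruct an
#'   item-level dataset when `items_path` is absent).
#' @param design_config a [designConfig()].
#' @param fit_config a [fitConfig()] (its `seed` is overridden by
#'   `seeds$fit`).
#' @param survey_config a [surveyConfig()].
#' @param predict_mode,predict_mass passed to [predictiveTable()].
#' @param run_fit set FALSE to skip the MCMC stage (descriptives only).
#' @param seeds named list of integer seeds per stochastic stage
#'   (`reconstruct`, `fit`, `predict`, `survey`).
#' @return list of class `pipeline_config`.
#' @export
pipelineConfig <- function(output_dir,
                           items_path = NULL, table1_path = NULL,
                           design_config = designConfig(),
                           fit_config = fitConfig(),
                           survey_config = surveyConfig(),
                           predict_mode = "new_pathologist",
                           predict_mass = 0.89,
                           run_fit = TRUE,
                           seeds = list(reconstruct = 1, fit = 1, predict = 1,
                                        survey = 1)) {
  need <- c("reconstruct", "fit", "predict", "survey")
  if (!all(need %in% names(seeds)))
    stop("seeds must name: ", paste(need, collapse = ", "))
  if (is.null(items_path) && is.null(table1_path))
    stop("config needs an items_path or a table1_path input")
  structure(list(output_dir = output_dir, items_path = items_path,
                 table1_path = table1_path, design_config = design_config,
                 fit_config = fit_config, survey_config = survey_config,
                 predict_mode = predict_mode, predict_mass = predict_mass,
                 run_fit = isTRUE(run_fit), seeds = seeds),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Recognized top-level keys mirror the arguments of [pipelineConfig()];
#' nested keys configure the design, fit and survey stages.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return a [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (key in c("output_dir", "items_path", "table1_path", "predict_mode",
                "predict_mass", "run_fit"))
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  if (!is.null(raw$seeds)) args$seeds <- as.list(raw$seeds)
  if (!is.null(raw$design)) args$design_config <- do.call(designConfig, lapply(raw$design, unlist))
  if (!is.null(raw$fit)) args$fit_config <- do.call(fitConfig, raw$fit)
  if (!is.null(raw$survey)) args$survey_config <- do.call(surveyConfig, lapply(raw$survey, unlist))
  do.call(pipelineConfig, args)
}

pipelineStage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes ingest/reconstruct, descriptives, model fit, posterior prediction
#' and survey aggregation, writing every table as CSV plus a JSON run
#' manifest (configuration hash, seeds, package and R versions) into
#' `output_dir`. Any stage failure aborts with the stage name and cause.
#' Deterministic given the configuration: rerunning writes byte-identical
#' CSVs.
#'
#' @param config a [pipelineConfig()].
#' @return named list of output file paths (the artifact bundle), invisibly;
#'   component `objects` carries the in-memory results.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  paths <- character(0)
  wpath <- function(name) file.path(config$output_dir, name)

  items <- pipelineStage("ingest", {
    if (!is.null(config$items_path)) {
      if (!file.exists(config$items_path))
        stop("items file not found: ", config$items_path)
      readResponseTable(config$items_path)
    } else {
      if (!file.exists(config$table1_path))
        stop("marginal table file not found: ", config$table1_path)
      reconstructFromMarginals(readMarginalTable(config$table1_path),
                               seed = config$seeds$reconstruct,
                               config = config$design_config)
    }
  })
  writeResponseTable(items, wpath("items.csv"))
  paths["items"] <- wpath("items.csv")

  pipelineStage("describe", {
    tables <- lapply(groupingNames(), function(g) {
      tab <- errorTable(items, g)
      cbind(grouping = g, as.data.frame(tab))
    })
    stacked <- do.call(rbind, tables)
    utils::write.csv(stacked, wpath("error_tables.csv"), row.names = FALSE)
    rates_p <- errorTable(items, "pathologist", totals = FALSE)$rate
    rates_l <- errorTable(items, "level", totals = FALSE)$rate
    st <- rbind(
      data.frame(grouping = "pathologist", unclass(medianIQR(rates_p))),
      data.frame(grouping = "level", unclass(medianIQR(rates_l))))
    utils::write.csv(st, wpath("summary_stats.csv"), row.names = FALSE)
    cross <- rbind(cbind(by = "level", crossErrorRates(items, 1:2, "level")),
                   cbind(by = "specimen", crossErrorRates(items, 1:2, "specimen")))
    utils::write.csv(cross, wpath("cross_rates.csv"), row.names = FALSE)
    out$error_tables <- stacked
    paths["error_tables"] <- wpath("error_tables.csv")
    paths["summary_stats"] <- wpath("summary_stats.csv")
    paths["cross_rates"] <- wpath("cross_rates.csv")
  })

  if (config$run_fit) {
    fit <- pipelineStage("fit", {
      fc <- config$fit_config
      fc$seed <- as.integer(config$seeds$fit)
      fitHier(items, fc)
    })
    pipelineStage("export fit", {
      m <- as.matrix(fit)
      draws_df <- data.frame(chain = rep(seq_len(dim(fit$draws)[2]),
                                         each = dim(fit$draws)[1]),
                             m, check.names = FALSE)
      utils::write.csv(draws_df, wpath("draws.csv"), row.names = FALSE)
      diag <- list(diagnostics = fit$diagnostics,
                   n_divergent = fit$n_divergent,
                   accept_rate = fit$accept_rate)
      jsonlite::write_json(diag, wpath("diagnostics.json"), auto_unbox = TRUE,
                           digits = NA, dataframe = "rows")
      paths["draws"] <- wpath("draws.csv")
      paths["diagnostics"] <- wpath("diagnostics.json")
    })
    pipelineStage("predict", {
      pt <- predictiveTable(fit, mode = config$predict_mode,
                            mass = config$predict_mass,
                            seed = config$seeds$predict, items = items)
      utils::write.csv(pt, wpath("predictive.csv"), row.names = FALSE)
      out$predictive <- pt
      paths["predictive"] <- wpath("predictive.csv")
    })
    out$fit <- fit
  }

  pipelineStage("survey", {
    resp <- synthesizeSurvey(config$survey_config,
                             seed = config$seeds$survey)
    writeLikert(resp, wpath("survey_responses.csv"))
    agg <- do.call(rbind, lapply(surveyFields(), function(f) {
      s <- aggregateSurvey(resp, f)
      data.frame(field = f, t(s$counts), n = s$n, high_n = s$high_n,
                 high_prop = s$high_prop, check.names = FALSE)
    }))
    utils::write.csv(agg, wpath("survey_aggregate.csv"), row.names = FALSE)
    out$survey <- agg
    paths["survey_responses"] <- wpath("survey_responses.csv")
    paths["survey_aggregate"] <- wpath("survey_aggregate.csv")
  })

  pipelineStage("manifest", {
    cfg_json <- jsonlite::toJSON(configForManifest(config), auto_unbox = TRUE,
                                 digits = NA)
    tmp <- tempfile()
    writeLines(cfg_json, tmp)
    manifest <- list(config = jsonlite::fromJSON(cfg_json),
                     config_md5 = unname(tools::md5sum(tmp)),
                     seeds = config$seeds,
                     package_version = as.character(utils::packageVersion("pathoconcord")),
                     r_version = as.character(getRversion()),
                     outputs = as.list(basename(paths)))
    unlink(tmp)
    jsonlite::write_json(manifest, wpath("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths["manifest"] <- wpath("manifest.json")
  })

  out$items <- items
  invisible(c(as.list(paths), list(objects = out)))
}

configForManifest <- function(config) {
  c <- unclass(config)
  c$design_config <- unclass(c$design_config)
  c$fit_config <- unclass(c$fit_config)
  c$survey_config <- unclass(c$survey_config)
  c
}

#' Read/write Likert survey responses as CSV
#'
#' @param path file path.
#' @param responses a [likertResponses()] collection.
#' @return `readLikert` returns a `likert_responses` collection;
#'   `writeLikert` returns `path` invisibly.
#' @export
readLikert <- function(path) {
  likertResponses(utils::read.csv(path, stringsAsFactors = FALSE,
                                  fileEncoding = "UTF-8"))
}

#' @rdname readLikert
#' @export
writeLikert <- function(responses, path) {
  stopifnot(inherits(responses, "likert_responses"))
  utils::write.csv(as.data.frame(responses), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
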