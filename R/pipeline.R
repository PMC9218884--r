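#' Format a percentage the way clinical reports print it
#'
#' Renders `100 * numerator / denominator` rounded half-up to the requested
#' number of decimals (e.g. 380/1310 at 2 decimals is `"29.01"`, 135/218 at
#' 1 decimal is `"61.9"`). `form = "n_over_N"` gives the full
#' `"29.01% (380/1310)"` style.
#'
#' @param numerator,denominator Integers; `denominator` must be positive.
#' @param decimals Decimal places (default 1).
#' @param form `"plain"` (just the number) or `"n_over_N"`.
#' @return A character scalar.
#' @export
#' @examples
#' format_percentage(380, 1310, 2)
#' format_percentage(135, 218, 1, form = "n_over_N")
format_percentage <- function(numerator, denominator, decimals = 1,
                              form = c("plain", "n_over_N")) {
  form <- match.arg(form)
  if (length(denominator) != 1 || is.na(denominator) || denominator <= 0) {
    abort("`denominator` must be a positive integer",
          class = "asthmawarn_precondition_error")
  }
  pct <- round_half_up(100 * numerator / denominator, decimals)
  s <- formatC(pct, format = "f", digits = decimals)
  if (form == "n_over_N") {
    s <- sprintf("%s%% (%d/%d)", s, as.integer(numerator),
                 as.integer(denominator))
  }
  s
}

#' Assemble a pipeline run configuration
#'
#' @param sim A [sim_config()] describing the synthetic cohort (ignored when
#'   `events_path` is given).
#' @param events_path Optional path to an existing events CSV; when set, the
#'   pipeline reads it instead of simulating.
#' @param train_years Integer index years used for training instances.
#' @param test_year Integer index year scored and classified; the evaluation
#'   (outcome) year is `test_year + 1`.
#' @param cutoff_fraction Top fraction flagged positive (default 0.10).
#' @param engine Classifier engine (`"xgboost"` or `"logistic"`).
#' @param rules A [code_rules()].
#' @param spec A [feature_spec()].
#' @param seed Integer seed driving model training (the simulator uses the
#'   seed inside `sim`).
#' @param decimals Decimal places for report percentages.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(sim = sim_config(), events_path = NULL,
                       train_years = c(2016, 2017), test_year = 2018,
                       cutoff_fraction = 0.10,
                       engine = c("xgboost", "logistic"),
                       rules = code_rules(), spec = feature_spec(),
                       seed = 1L, decimals = 1) {
  structure(
    list(sim = sim, events_path = events_path,
         train_years = as.integer(train_years),
         test_year = as.integer(test_year),
         cutoff_fraction = cutoff_fraction, engine = match.arg(engine),
         rules = rules, spec = spec, seed = as.integer(seed),
         decimals = decimals),
    class = "run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' The file mirrors the [run_config()] / [sim_config()] field names, with
#' optional `rules` (a [code_rules()] field list) and top-level `sim` block.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "asthmawarn_config_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  if (!is.null(raw$sim)) args$sim <- do.call(sim_config, raw$sim)
  if (!is.null(raw$rules)) args$rules <- do.call(code_rules, raw$rules)
  for (f in c("events_path", "train_years", "test_year", "cutoff_fraction",
              "engine", "seed", "decimals")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  do.call(run_config, args)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
}

#' Run the full backtesting pipeline
#'
#' Sequences the stages: simulate (or load) the event table; build annual
#' instances for the training years and the test year; train the risk model
#' on the training instances; score the test cohort and apply the
#' top-fraction cutoff, freezing the classification threshold; compute
#' confusion metrics against the test labels; run the daily lead-time scan
#' for every test-cohort patient with a home-system asthma hospital visit in
#' the evaluation year, with the warning curve and distribution summary; and
#' evaluate the surrogate-outcome indicators and corticosteroid multiplicity
#' histogram over the false-positive patients.
#'
#' When `out_dir` is given, writes `instances.csv`, `metrics.json`,
#' `leadtimes.csv`, `warning_curve.csv`, `fp_breakdown.csv`,
#' `steroid_histogram.csv` and a `manifest.json` (config hash, seed,
#' package/R versions, per-stage row counts). Given the same configuration
#' and seed, all numeric outputs are reproduced byte-identically.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if missing).
#' @param quiet Suppress per-stage progress messages?
#' @return A list of class `"pipeline_result"` with elements `events`,
#'   `demographics`, `instances_train`, `instances_test`, `model`,
#'   `classified`, `metrics`, `leadtimes`, `curve`, `leadtime_summary`,
#'   `fp_flags`, `fp_breakdown`, `histogram`, `config`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- "simulate"
  demographics <- NULL
  if (!is.null(config$events_path)) {
    if (!file.exists(config$events_path)) {
      abort(sprintf("events file not found: %s", config$events_path),
            class = "asthmawarn_config_error")
    }
    events <- read_events(config$events_path)
    say("[load] %d events from %s", nrow(events), config$events_path)
  } else {
    events <- simulate_cohort(config$sim)
    demographics <- simulate_demographics(config$sim)
    say("[simulate] %d events, %d patients", nrow(events),
        config$sim$n_patients)
  }
  if (is.null(demographics) && config$spec$include_demographics) {
    abort("feature spec needs demographics but events were loaded from file",
          class = "asthmawarn_config_error")
  }

  span_start <- attr(events, "span_start") %||% min(events$date)
  span_end <- attr(events, "span_end") %||% max(events$date)

  inst_train <- build_instances(events, config$train_years,
                                rules = config$rules, spec = config$spec,
                                demographics = demographics,
                                span_end = span_end)
  inst_test <- build_instances(events, config$test_year,
                               rules = config$rules, spec = config$spec,
                               demographics = demographics,
                               span_end = span_end)
  say("[instances] %d training, %d test", nrow(inst_train), nrow(inst_test))

  model <- train_risk_model(inst_train, engine = config$engine,
                            cutoff_fraction = config$cutoff_fraction,
                            seed = config$seed)
  scores <- tibble(patient_id = inst_test$patient_id,
                   score = risk_scores(model, inst_test))
  classified <- apply_cutoff(scores, config$cutoff_fraction)
  model <- set_frozen_threshold(model, attr(classified, "threshold"))
  say("[cutoff] flagged %d of %d (threshold %.4f)",
      sum(classified$flagged), nrow(classified), model$frozen_threshold)

  labels <- inst_test[, c("patient_id", "label")]
  metrics <- confusion_metrics(classified, labels)
  say("[metrics] TP=%d FP=%d TN=%d FN=%d", metrics$tp, metrics$fp,
      metrics$tn, metrics$fn)

  eval_year <- config$test_year + 1L
  leadtimes <- compute_leadtimes(events, model, eval_year,
                                 spec = config$spec, rules = config$rules,
                                 patients = inst_test$patient_id,
                                 demographics = demographics,
                                 span_start = span_start)
  curve <- warning_curve(leadtimes)
  lt_summary <- if (nrow(leadtimes) > 0) {
    summarize_leadtimes(leadtimes, decimals = config$decimals)
  } else NULL
  say("[leadtime] %d event patients, mean k = %s", nrow(leadtimes),
      if (is.null(lt_summary)) "-" else sprintf("%.1f", lt_summary$mean))

  fp_ids <- classified$patient_id[classified$flagged &
                                    !labels$label[match(classified$patient_id,
                                                        labels$patient_id)]]
  as_of <- as.Date(sprintf("%d-12-31", config$test_year))
  flags <- compute_fp_flags(events, fp_ids, as_of, rules = config$rules,
                            span_end = span_end)
  breakdown <- fp_breakdown(flags, decimals = 2)
  histogram <- multiplicity_histogram(flags)
  say("[fp] %d false positives, %d with any indicator", length(fp_ids),
      breakdown$n[breakdown$indicator == "any_1234"])

  result <- structure(
    list(events = events, demographics = demographics,
         instances_train = inst_train, instances_test = inst_test,
         model = model, classified = classified, metrics = metrics,
         leadtimes = leadtimes, curve = curve,
         leadtime_summary = lt_summary, fp_flags = flags,
         fp_breakdown = breakdown, histogram = histogram, config = config),
    class = "pipeline_result"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    readr::write_csv(dplyr::bind_rows(inst_train, inst_test),
                     p("instances.csv"))
    write_json_report(as.list(metrics), p("metrics.json"))
    readr::write_csv(as_tibble(leadtimes), p("leadtimes.csv"))
    readr::write_csv(as_tibble(curve), p("warning_curve.csv"))
    readr::write_csv(as_tibble(breakdown), p("fp_breakdown.csv"))
    readr::write_csv(as_tibble(histogram), p("steroid_histogram.csv"))
    manifest <- list(
      config_hash = rlang::hash(config),
      seed = config$seed,
      package_version = as.character(utils::packageVersion("asthmawarn")),
      r_version = as.character(getRversion()),
      rows = list(events = nrow(events), instances_train = nrow(inst_train),
                  instances_test = nrow(inst_test),
                  event_patients = nrow(leadtimes),
                  false_positives = nrow(flags))
    )
    write_json_report(manifest, p("manifest.json"))
    say("[report] bundle written to %s", out_dir)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  test cohort: %d patients, %d flagged, %d events in year %d\n",
              nrow(x$instances_test), sum(x$classified$flagged),
              sum(x$instances_test$label), x$config$test_year + 1L))
  if (!is.null(x$leadtime_summary)) print(x$leadtime_summary)
  invisible(x)
}
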