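#' Predict risk status on an arbitrary date
#'
#' Scores the feature vector built from the patient's history up to `date`
#' and compares it with the model's frozen classification threshold. This is
#' the primitive the daily lead-time scan repeats.
#'
#' @param timeline A [patient_timeline()].
#' @param date As-of `Date`.
#' @param model A `risk_model` with `frozen_threshold` set.
#' @param spec A [feature_spec()].
#' @return Logical: is the patient predicted positive as of `date`?
#' @export
predict_at <- function(timeline, date, model, spec = feature_spec()) {
  if (is.na(model$frozen_threshold)) {
    abort("model has no frozen threshold; run apply_cutoff()/set_frozen_threshold() first",
          class = "asthmawarn_precondition_error")
  }
  score <- risk_scores(model, build_feature_matrix(timeline, date, spec))
  as.vector(score >= model$frozen_threshold)
}

#' Advance-warning lead time (k) for one event patient
#'
#' Implements the timeliness statistic: for a patient whose first asthma
#' hospital visit of the evaluation year starts on date `T`, the scan starts
#' at `T - 365` and moves forward one day at a time to find the earliest
#' date `T'` (`T - 365 <= T' <= T - 1`) on which the model, fed only history
#' up to `T'`, predicts a future asthma hospital visit. The model then gave
#' `k = (first asthma hospital visit strictly after T') - T'` days of
#' advance warning (note the first visit after `T'` may predate `T`, e.g. a
#' prior-year visit inside the scan window); predictions on dates after `T'`
#' never change `k`. If no scan date is predicted positive, `k = 0`: the
#' model warned only on the day of the visit itself.
#'
#' @param timeline A [patient_timeline()].
#' @param T_date The patient's first asthma hospital visit date in the
#'   evaluation year.
#' @param model A `risk_model` with a frozen threshold.
#' @param spec A [feature_spec()].
#' @param span_start Start of the observable data span; scan dates earlier
#'   than this are skipped (the scan then starts at `span_start`).
#' @param home_only Should the "first visit after `T'`" lookup consider
#'   home-system visits only (default `TRUE`, matching an outcome defined on
#'   the home system)?
#' @return One-row tibble: `patient_id`, `T`, `T_prime` (`NA` when never
#'   warned), `k` (integer days, `0 <= k <= 365`).
#' @export
advance_warning_days <- function(timeline, T_date, model,
                                 spec = feature_spec(), span_start = NULL,
                                 home_only = TRUE) {
  T_date <- as.Date(T_date)
  span_start <- as.Date(span_start %||% min(timeline$events$date))
  if (T_date < span_start) {
    abort("`T_date` precedes the data span",
          class = "asthmawarn_precondition_error")
  }
  scan_from <- max(T_date - 365, span_start)
  no_warning <- tibble(patient_id = timeline$patient_id, T = T_date,
                       T_prime = as.Date(NA), k = 0L)
  if (scan_from > T_date - 1) return(no_warning)
  scan_dates <- seq(scan_from, T_date - 1, by = "day")
  scores <- risk_scores(model, build_feature_matrix(timeline, scan_dates, spec))
  if (is.na(model$frozen_threshold)) {
    abort("model has no frozen threshold",
          class = "asthmawarn_precondition_error")
  }
  hit <- which(scores >= model$frozen_threshold)
  if (length(hit) == 0) return(no_warning)
  t_prime <- scan_dates[hit[1]]
  nxt <- first_asthma_hospital_visit_after(timeline, t_prime,
                                           home_only = home_only)
  tibble(patient_id = timeline$patient_id, T = T_date, T_prime = t_prime,
         k = as.integer(nxt - t_prime))
}

#' Lead times for every event patient in an evaluation year
#'
#' Finds each patient (optionally restricted to a cohort) with at least one
#' home-system asthma hospital visit in `eval_year`, takes the first such
#' visit as `T`, and runs [advance_warning_days()].
#'
#' @param events An event table.
#' @param model A `risk_model` with a frozen threshold.
#' @param eval_year Evaluation calendar year.
#' @param spec A [feature_spec()].
#' @param rules A [code_rules()].
#' @param patients Optional character vector restricting the event patients
#'   considered (e.g. the test-year cohort).
#' @param demographics Optional demographics tibble.
#' @param span_start Start of the observable span; defaults to the
#'   simulation attribute on `events`, else the earliest event date.
#' @return Tibble of class `"leadtime_results"`: one row per event patient
#'   with `patient_id`, `T`, `T_prime`, `k`.
#' @export
compute_leadtimes <- function(events, model, eval_year,
                              spec = feature_spec(), rules = code_rules(),
                              patients = NULL, demographics = NULL,
                              span_start = NULL) {
  span_start <- as.Date(span_start %||% attr(events, "span_start") %||%
                          min(events$date))
  yr <- as.integer(format(events$date, "%Y"))
  hosp <- is_asthma_hospital_visit(events, rules) & events$source == "home" &
    yr == eval_year
  firsts <- events[hosp, c("patient_id", "date")] |>
    group_by(.data$patient_id) |>
    summarise(T = min(.data$date), .groups = "drop")
  if (!is.null(patients)) {
    firsts <- filter(firsts, .data$patient_id %in% patients)
  }
  out <- map_dfr(seq_len(nrow(firsts)), function(i) {
    tl <- patient_timeline(events, firsts$patient_id[i],
                           demographics = demographics, rules = rules)
    advance_warning_days(tl, firsts$T[i], model, spec = spec,
                         span_start = span_start)
  })
  if (nrow(out) == 0) {
    out <- tibble(patient_id = character(), T = as.Date(character()),
                  T_prime = as.Date(character()), k = integer())
  }
  class(out) <- c("leadtime_results", class(out))
  out
}

#' Warning survival curve
#'
#' For each horizon `c = 0, ..., 365`, the number of event patients whose
#' initial warning came at least `c` days ahead (`k >= c`). The curve is
#' non-increasing and starts at the number of event patients.
#'
#' @param results A tibble of lead-time results (column `k`).
#' @return Tibble of class `"warning_curve"` with columns `c` and
#'   `n_with_at_least`.
#' @export
warning_curve <- function(results) {
  ks <- sort(results$k)
  cs <- 0:365
  # |{k >= c}| = n - |{k <= c - 1}|
  n_at_least <- length(ks) - findInterval(cs - 1, ks)
  out <- tibble(c = cs, n_with_at_least = as.integer(n_at_least))
  class(out) <- c("warning_curve", class(out))
  out
}

#' Summarise the lead-time distribution
#'
#' Mean and SD of `k` over event patients, plus counts and percentages of
#' patients warned at least each threshold ahead. The default thresholds map
#' the reporting horizons 12 / 6 / 3 / 1 months, 2 weeks and 1 day to 365 /
#' 180 / 90 / 30 / 14 / 1 days.
#'
#' @param results A tibble of lead-time results (column `k`); must be
#'   non-empty.
#' @param thresholds Integer day horizons.
#' @param decimals Decimal places for the percentage strings.
#' @return A list of class `"leadtime_summary"`: `n`, `mean`, `sd`,
#'   `median`, and a `thresholds` tibble (`threshold_days`, `n_at_least`,
#'   `pct`).
#' @export
summarize_leadtimes <- function(results, thresholds = c(365, 180, 90, 30, 14, 1),
                                decimals = 1) {
  ks <- results$k
  if (length(ks) == 0) {
    abort("no lead-time results to summarise",
          class = "asthmawarn_precondition_error")
  }
  thr <- tibble(
    threshold_days = as.integer(thresholds),
    n_at_least = vapply(thresholds, function(t) sum(ks >= t), integer(1))
  ) |>
    mutate(pct = map_chr(.data$n_at_least, format_percentage,
                         denominator = length(ks), decimals = decimals))
  structure(
    list(n = length(ks), mean = mean(ks),
         sd = if (length(ks) > 1) sd(ks) else 0,
         median = median(ks), thresholds = thr),
    class = "leadtime_summary"
  )
}

#' @export
print.leadtime_summary <- function(x, ...) {
  cat(sprintf("Lead-time summary over %d event patients\n", x$n))
  cat(sprintf("  mean k = %.1f days (SD %.1f), median %.0f\n",
              x$mean, x$sd, x$median))
  for (i in seq_len(nrow(x$thresholds))) {
    cat(sprintf("  warned >= %3d days ahead: %d (%s%%)\n",
                x$thresholds$threshold_days[i], x$thresholds$n_at_least[i],
                x$thresholds$pct[i]))
  }
  invisible(x)
}

#' Plot a warning survival curve
#'
#' @param object A [warning_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.warning_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$c,
                                       y = .data$n_with_at_least)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(
      x = "c (days of advance warning)",
      y = "patients warned at least c days ahead",
      title = "Warning survival curve"
    ) +
    ggplot2::theme_minimal()
}
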