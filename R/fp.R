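#' Surrogate-outcome indicator flags for one patient
#'
#' For a patient predicted positive at `as_of` but without a home-system
#' asthma hospital visit in the 12-month outcome window, evaluates the four
#' surrogate / poor-outcome indicators:
#'
#' 1. `ind1_steroid_rx` - at least one systemic-corticosteroid order in the
#'    following 12 months, i.e. `(as_of, as_of + 365]`;
#' 2. `ind2_exacerbation_visit` - at least one visit of any type with an
#'    exacerbation principal diagnosis in the same window (home-system
#'    records, mirroring indicators computed from the home data warehouse);
#' 3. `ind3_later_hospital_visit` - at least one asthma hospital visit
#'    between 13 and 24 months later, i.e. `(as_of + 365, as_of + 730]`
#'    (home-system by default; set `ind3_home_only = FALSE` to count any
#'    source);
#' 4. `ind4_external_hospital_visit` - at least one external-registry asthma
#'    hospital visit in the following 12 months.
#'
#' `steroid_multiplicity` counts every corticosteroid order in the 12-month
#' window (counting multiplicity), so `ind1_steroid_rx` is equivalent to
#' `steroid_multiplicity >= 1`. When `as_of + 730` extends past the data
#' span, indicator 3 cannot be evaluated: it is reported `FALSE` with
#' `ind3_evaluable = FALSE` and a warning.
#'
#' @param timeline A [patient_timeline()].
#' @param as_of Anchor `Date` (end of the index year).
#' @param rules A [code_rules()].
#' @param ind3_home_only Restrict indicator 3 to home-system visits?
#' @param span_end End of the observable span; defaults to the latest event
#'   date on the timeline's source table if unknown.
#' @return One-row tibble: `patient_id`, the four indicator logicals,
#'   `ind3_evaluable`, and `steroid_multiplicity`.
#' @export
indicator_flags <- function(timeline, as_of, rules = code_rules(),
                            ind3_home_only = TRUE, span_end = NULL) {
  a <- as.numeric(as.Date(as_of))
  idx <- timeline$index
  in_window <- function(d, lo, hi) d[d > a + lo & d <= a + hi]

  mult <- length(in_window(idx$steroid, 0, 365))
  ind1 <- mult >= 1
  ind2 <- length(in_window(idx$exacerbation, 0, 365)) > 0

  ind3_pool <- if (ind3_home_only) idx$asthma_hosp_home else
    idx$asthma_hosp_any
  ind3_evaluable <- TRUE
  if (!is.null(span_end) && as.numeric(as.Date(span_end)) < a + 730) {
    ind3_evaluable <- FALSE
    warn(sprintf(
      "indicator 3 window for %s extends past the data span; reported FALSE",
      timeline$patient_id), class = "asthmawarn_window_warning")
  }
  ind3 <- ind3_evaluable && length(in_window(ind3_pool, 365, 730)) > 0
  ind4 <- length(in_window(idx$asthma_hosp_external, 0, 365)) > 0

  tibble(patient_id = timeline$patient_id,
         ind1_steroid_rx = ind1,
         ind2_exacerbation_visit = ind2,
         ind3_later_hospital_visit = ind3,
         ind4_external_hospital_visit = ind4,
         ind3_evaluable = ind3_evaluable,
         steroid_multiplicity = as.integer(mult))
}

#' Indicator flags for a set of false-positive patients
#'
#' Convenience wrapper running [indicator_flags()] for every patient id in
#' `patients` at a common anchor date.
#'
#' @param events An event table.
#' @param patients Character vector of (false-positive) patient ids.
#' @param as_of Common anchor `Date`.
#' @param rules A [code_rules()].
#' @param ind3_home_only Restrict indicator 3 to home-system visits?
#' @param span_end End of observable span (defaults to the events
#'   attribute, else the latest event date).
#' @return Tibble with one row per patient.
#' @export
compute_fp_flags <- function(events, patients, as_of, rules = code_rules(),
                             ind3_home_only = TRUE, span_end = NULL) {
  span_end <- span_end %||% attr(events, "span_end") %||% max(events$date)
  map_dfr(patients, function(id) {
    tl <- patient_timeline(events, id, rules = rules)
    indicator_flags(tl, as_of, rules = rules,
                    ind3_home_only = ind3_home_only, span_end = span_end)
  })
}

FP_OUTCOME_LABELS <- c(
  ind1_steroid_rx = "(1) >=1 systemic-corticosteroid prescription, following 12 months",
  ind2_exacerbation_visit = "(2) visit with exacerbation principal diagnosis, following 12 months",
  ind3_later_hospital_visit = "(3) asthma hospital visit, months 13-24",
  ind4_external_hospital_visit = "(4) external asthma hospital visit, following 12 months",
  any_123 = "Any of (1), (2), and (3)",
  any_1234 = "Any of (1), (2), (3), and (4)"
)

#' Break down false-positive patients by surrogate indicator
#'
#' Counts, for a set of per-patient indicator flags, how many patients meet
#' each indicator and the unions "any of (1)-(3)" and "any of (1)-(4)",
#' with percentages of the false-positive total.
#'
#' @param flags Tibble of [indicator_flags()] rows.
#' @param decimals Decimal places for percentages (default 2).
#' @return Tibble of class `"fp_breakdown"` with columns `indicator`,
#'   `outcome`, `n`, `pct` (numeric, round-half-up) and attribute `n_fp`.
#' @export
fp_breakdown <- function(flags, decimals = 2) {
  n_fp <- nrow(flags)
  ind <- flags[, c("ind1_steroid_rx", "ind2_exacerbation_visit",
                   "ind3_later_hospital_visit",
                   "ind4_external_hospital_visit")]
  counts <- c(
    colSums(ind),
    any_123 = sum(ind[[1]] | ind[[2]] | ind[[3]]),
    any_1234 = sum(ind[[1]] | ind[[2]] | ind[[3]] | ind[[4]])
  )
  out <- tibble(
    indicator = names(counts),
    outcome = unname(FP_OUTCOME_LABELS[names(counts)]),
    n = as.integer(unname(counts)),
    pct = if (n_fp > 0) unname(round_half_up(100 * counts / n_fp, decimals))
      else rep(NA_real_, length(counts))
  )
  attr(out, "n_fp") <- n_fp
  class(out) <- c("fp_breakdown", class(out))
  out
}

#' Corticosteroid-order multiplicity histogram
#'
#' Distribution of the number of systemic-corticosteroid orders in the
#' 12-month window, over the patients with at least one such order
#' (indicator 1 true).
#'
#' @param flags Tibble of [indicator_flags()] rows.
#' @return Tibble of class `"steroid_histogram"` (`multiplicity`, `n`) with
#'   attribute `max_multiplicity` (`NA` when no indicator-1 patients).
#' @export
multiplicity_histogram <- function(flags) {
  sel <- flags |> filter(.data$ind1_steroid_rx)
  out <- sel |>
    count(multiplicity = .data$steroid_multiplicity, name = "n") |>
    arrange(.data$multiplicity)
  attr(out, "max_multiplicity") <- if (nrow(sel) > 0) {
    max(sel$steroid_multiplicity)
  } else NA_integer_
  class(out) <- c("steroid_histogram", class(out))
  out
}

#' Plot a false-positive indicator breakdown
#'
#' @param object An [fp_breakdown()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fp_breakdown <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(indicator = factor(.data$indicator, levels = rev(.data$indicator)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$indicator)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = sprintf("patients (of %d false positives)",
                              attr(object, "n_fp")),
                  y = NULL, title = "Surrogate indicators among false positives") +
    ggplot2::theme_minimal()
}

#' Plot a corticosteroid multiplicity histogram
#'
#' @param object A [multiplicity_histogram()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.steroid_histogram <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$multiplicity, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "corticosteroid orders in the 12-month window (counting multiplicity)",
                  y = "patients",
                  title = "Corticosteroid order multiplicity") +
    ggplot2::theme_minimal()
}
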