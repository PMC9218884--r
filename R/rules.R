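#' Diagnosis- and medication-code rule set
#'
#' Collects the code rules used throughout: asthma case-finding prefixes,
#' the exacerbation principal-diagnosis code set, and the medication classes
#' counted as systemic corticosteroids. Matching is performed on dot-stripped
#' codes, so `"J45.909"` and `"J45909"` classify identically.
#'
#' The default asthma prefixes implement the standard administrative
#' case-finding rule: ICD-10 J45.x or ICD-9 493.0x/493.1x/493.8x/493.9x.
#' No authoritative exacerbation code list exists for the analysis the
#' package implements, so the default covers the ICD "with (acute)
#' exacerbation" and status-asthmaticus families and is configurable.
#'
#' @param asthma_prefixes Character vector of code prefixes (dot-insensitive)
#'   identifying asthma diagnoses.
#' @param exacerbation_codes Character vector of principal-diagnosis codes
#'   identifying asthma-exacerbation visits.
#' @param steroid_med_classes Character vector of `med_class` values counted
#'   as systemic corticosteroids.
#' @return A list of class `"code_rules"`.
#' @export
#' @examples
#' rules <- code_rules()
#' is_asthma_code(c("J45.909", "493.22"), rules)
code_rules <- function(asthma_prefixes = c("J45", "4931", "4930", "4939", "4938"),
                       exacerbation_codes = c("J45.21", "J45.31", "J45.41",
                                              "J45.51", "J45.901", "J45.902",
                                              "493.02", "493.12", "493.92"),
                       steroid_med_classes = "systemic_corticosteroid") {
  if (length(asthma_prefixes) < 1 || any(!nzchar(asthma_prefixes))) {
    abort("`asthma_prefixes` must be non-empty strings",
          class = "asthmawarn_config_error")
  }
  structure(
    list(asthma_prefixes = as.character(asthma_prefixes),
         exacerbation_codes = as.character(exacerbation_codes),
         steroid_med_classes = as.character(steroid_med_classes)),
    class = "code_rules"
  )
}

strip_dots <- function(x) gsub(".", "", x, fixed = TRUE)

# empty codes are simply non-matches here; the exported predicate enforces
# the non-empty precondition
asthma_code_match <- function(codes, rules) {
  stripped <- strip_dots(codes)
  prefixes <- strip_dots(rules$asthma_prefixes)
  out <- rep(FALSE, length(codes))
  for (p in prefixes) out <- out | startsWith(stripped, p)
  out & nzchar(stripped)
}

#' Classify diagnosis codes as asthma
#'
#' A code is an asthma code when its dot-stripped form starts with any of the
#' rule set's asthma prefixes (default: ICD-10 J45.x, ICD-9
#' 493.0x/1x/8x/9x).
#'
#' @param code Character vector of non-empty diagnosis codes.
#' @param rules A [code_rules()].
#' @return Logical vector.
#' @export
is_asthma_code <- function(code, rules = code_rules()) {
  if (length(code) == 0 || any(is.na(code)) || any(!nzchar(code))) {
    abort("`code` must be non-empty", class = "asthmawarn_precondition_error")
  }
  asthma_code_match(code, rules)
}

VISIT_TYPES <- c("outpatient", "ED", "inpatient", "external_ED",
                 "external_inpatient")
HOSPITAL_TYPES <- c("ED", "inpatient", "external_ED", "external_inpatient")

# any diagnosis code on the row (principal or secondary) is an asthma code
row_has_asthma_code <- function(events, rules) {
  codes <- strsplit(events$diagnosis_codes, ";", fixed = TRUE)
  principal <- events$principal_code
  map_lgl(seq_along(codes), function(i) {
    cand <- c(principal[i], codes[[i]])
    cand <- cand[nzchar(cand)]
    length(cand) > 0 && any(asthma_code_match(cand, rules))
  })
}

#' Identify the asthma cohort for a calendar year
#'
#' Case-finding rule: a patient has asthma in a given year when their visit
#' billing records in that year include at least one asthma diagnosis code;
#' patients who died during that year are excluded.
#'
#' @param events An event table.
#' @param year Calendar year (integer).
#' @param rules A [code_rules()].
#' @return Sorted character vector of qualifying patient ids.
#' @export
find_asthma_patients <- function(events, year, rules = code_rules()) {
  yr <- as.integer(format(events$date, "%Y"))
  in_year <- yr == year
  visits <- events[in_year & events$event_type %in% VISIT_TYPES, , drop = FALSE]
  qualifying <- unique(visits$patient_id[row_has_asthma_code(visits, rules)])
  died <- unique(events$patient_id[in_year & events$event_type == "death"])
  sort(setdiff(qualifying, died))
}

#' Classify events as asthma hospital visits
#'
#' An asthma hospital visit is an ED visit or inpatient stay (home or
#' external) whose principal diagnosis is asthma.
#'
#' @param events An event table (or any tibble with `event_type` and
#'   `principal_code` columns).
#' @param rules A [code_rules()].
#' @return Logical vector, one element per row.
#' @export
is_asthma_hospital_visit <- function(events, rules = code_rules()) {
  events$event_type %in% HOSPITAL_TYPES &
    asthma_code_match(events$principal_code, rules)
}

#' Classify events as asthma-exacerbation visits
#'
#' Any type of visit (including outpatient) whose principal diagnosis is in
#' the rule set's exacerbation code set.
#'
#' @inheritParams is_asthma_hospital_visit
#' @return Logical vector, one element per row.
#' @export
is_exacerbation_visit <- function(events, rules = code_rules()) {
  exac <- strip_dots(rules$exacerbation_codes)
  events$event_type %in% VISIT_TYPES &
    strip_dots(events$principal_code) %in% exac &
    nzchar(events$principal_code)
}

#' Build a per-patient timeline
#'
#' Extracts one patient's chronologically sorted events, deduplicated on
#' `(date, event_type, principal_code)`, together with the death date (if
#' any), optional demographics, and precomputed per-category event-date
#' vectors used by the feature extractor and the lead-time scan.
#'
#' @param events An event table.
#' @param patient_id A single patient id.
#' @param demographics Optional demographics tibble
#'   (see [simulate_demographics()]).
#' @param rules A [code_rules()].
#' @return A list of class `"patient_timeline"`.
#' @export
patient_timeline <- function(events, patient_id, demographics = NULL,
                             rules = code_rules()) {
  ev <- events |>
    filter(.data$patient_id == !!patient_id) |>
    distinct(.data$date, .data$event_type, .data$principal_code,
             .keep_all = TRUE) |>
    arrange(.data$date, .data$event_type)
  death_date <- if (any(ev$event_type == "death")) {
    min(ev$date[ev$event_type == "death"])
  } else as.Date(NA)

  d <- as.numeric(ev$date)
  home <- ev$source == "home"
  asthma_any <- row_has_asthma_code(ev, rules)
  hosp <- is_asthma_hospital_visit(ev, rules)
  exac <- is_exacerbation_visit(ev, rules)
  steroid <- ev$event_type == "prescription" &
    ev$med_class %in% rules$steroid_med_classes
  visit <- ev$event_type %in% VISIT_TYPES

  dates_of <- function(keep) sort(d[keep])
  index <- list(
    ED = dates_of(ev$event_type == "ED"),
    inpatient = dates_of(ev$event_type == "inpatient"),
    hospital = dates_of(ev$event_type %in% c("ED", "inpatient")),
    outpatient = dates_of(ev$event_type == "outpatient"),
    asthma_dx = dates_of(visit & home & asthma_any),
    steroid = dates_of(steroid),
    exacerbation = dates_of(exac & home),
    asthma_hosp_home = dates_of(hosp & home),
    asthma_hosp_any = dates_of(hosp),
    asthma_hosp_external = dates_of(hosp & !home)
  )

  demo <- NULL
  if (!is.null(demographics)) {
    row <- demographics[demographics$patient_id == patient_id, , drop = FALSE]
    if (nrow(row) == 1) {
      demo <- list(birth_date = row$birth_date[[1]], sex = row$sex[[1]])
    }
  }

  structure(
    list(patient_id = patient_id, events = ev, death_date = death_date,
         index = index, demographics = demo),
    class = "patient_timeline"
  )
}

#' First asthma hospital visit strictly after a date
#'
#' @param timeline A [patient_timeline()].
#' @param date A `Date`; the search is strictly after this day.
#' @param home_only Restrict to home-system visits (default `TRUE`)?
#' @return A `Date`, or `NA` when no later qualifying visit exists.
#' @export
first_asthma_hospital_visit_after <- function(timeline, date,
                                              home_only = TRUE) {
  pool <- if (home_only) timeline$index$asthma_hosp_home else
    timeline$index$asthma_hosp_any
  later <- pool[pool > as.numeric(date)]
  if (length(later) == 0) return(as.Date(NA))
  as.Date(later[1], origin = "1970-01-01")
}
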