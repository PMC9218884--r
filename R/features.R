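#' Feature specification for as-of-date extraction
#'
#' A feature specification is a tibble with one row per dynamic feature:
#' `name` (unique), `filter` (an event category: one of `ED`, `inpatient`,
#' `hospital`, `outpatient`, `asthma_dx`, `steroid`, `exacerbation`),
#' `window` (trailing window in days) and `agg` (`count`, `days_since_last`
#' or `binary`). Dynamic features read only home-system events at or before
#' the as-of date; `days_since_last` returns `window + 1` as a sentinel when
#' no matching event falls inside the window. Optionally the static features
#' `age` (years at the as-of date) and `sex` (indicator, male = 1) are
#' appended; these require a demographics table.
#'
#' The default is a compact utilization panel (ED / inpatient / outpatient /
#' asthma-diagnosis / corticosteroid counts over 90-, 180- and 365-day
#' windows plus recency features), a configurable stand-in for the richer
#' feature sets production asthma risk models use.
#'
#' @param features Tibble with columns `name`, `filter`, `window`, `agg`;
#'   defaults to the panel described above.
#' @param include_demographics Append static `age` and `sex` features?
#' @return A list of class `"feature_spec"`.
#' @export
feature_spec <- function(features = default_features(),
                         include_demographics = TRUE) {
  features <- as_tibble(features)
  stopifnot(all(c("name", "filter", "window", "agg") %in% names(features)))
  if (anyDuplicated(features$name)) {
    abort("feature names must be unique", class = "asthmawarn_config_error")
  }
  if (any(features$window <= 0)) {
    abort("feature windows must be positive", class = "asthmawarn_config_error")
  }
  bad <- setdiff(features$agg, c("count", "days_since_last", "binary"))
  if (length(bad) > 0) {
    abort(sprintf("unknown aggregation: %s", paste(bad, collapse = ", ")),
          class = "asthmawarn_config_error")
  }
  structure(list(features = features,
                 include_demographics = isTRUE(include_demographics)),
            class = "feature_spec")
}

#' @rdname feature_spec
#' @export
default_features <- function() {
  tibble::tribble(
    ~name,                  ~filter,        ~window, ~agg,
    "ed_count_90",          "ED",           90,      "count",
    "ed_count_180",         "ED",           180,     "count",
    "ed_count_365",         "ED",           365,     "count",
    "inpatient_count_365",  "inpatient",    365,     "count",
    "hospital_count_365",   "hospital",     365,     "count",
    "outpatient_count_90",  "outpatient",   90,      "count",
    "outpatient_count_365", "outpatient",   365,     "count",
    "asthma_dx_count_180",  "asthma_dx",    180,     "count",
    "asthma_dx_count_365",  "asthma_dx",    365,     "count",
    "steroid_count_90",     "steroid",      90,      "count",
    "steroid_count_365",    "steroid",      365,     "count",
    "exac_count_365",       "exacerbation", 365,     "count",
    "days_since_ed",        "ED",           365,     "days_since_last",
    "days_since_asthma_dx", "asthma_dx",    365,     "days_since_last",
    "days_since_steroid",   "steroid",      365,     "days_since_last"
  )
}

feature_names <- function(spec) {
  c(spec$features$name,
    if (spec$include_demographics) c("age", "sex_male"))
}

#' Extract as-of-date features for one patient
#'
#' Computes the feature vector(s) defined by a [feature_spec()] from a
#' patient timeline, using only events dated at or before each as-of date
#' (counts cover the half-open trailing window `(as_of - window, as_of]`).
#' `build_feature_matrix()` evaluates many as-of dates at once, which the
#' daily lead-time scan relies on.
#'
#' @param timeline A [patient_timeline()].
#' @param as_of A `Date` (a vector of dates for `build_feature_matrix()`).
#' @param spec A [feature_spec()].
#' @return `build_features()`: a named numeric vector.
#'   `build_feature_matrix()`: a numeric matrix, one row per as-of date.
#' @export
build_features <- function(timeline, as_of, spec = feature_spec()) {
  drop(build_feature_matrix(timeline, as_of, spec))
}

#' @rdname build_features
#' @export
build_feature_matrix <- function(timeline, as_of, spec = feature_spec()) {
  a <- as.numeric(as_of)
  fts <- spec$features
  cols <- vector("list", nrow(fts))
  for (j in seq_len(nrow(fts))) {
    d <- timeline$index[[fts$filter[j]]]
    if (is.null(d)) {
      abort(sprintf("unknown event filter: %s", fts$filter[j]),
            class = "asthmawarn_config_error")
    }
    w <- fts$window[j]
    n_le <- function(x) findInterval(x, d)      # |{d_i <= x}|
    cols[[j]] <- switch(
      fts$agg[j],
      count = n_le(a) - n_le(a - w),
      binary = as.numeric(n_le(a) - n_le(a - w) > 0),
      days_since_last = {
        idx <- n_le(a)
        gap <- ifelse(idx > 0, a - d[pmax(idx, 1)], Inf)
        ifelse(gap > w, w + 1, gap)
      }
    )
  }
  m <- do.call(cbind, cols)
  colnames(m) <- fts$name
  if (spec$include_demographics) {
    demo <- timeline$demographics
    if (is.null(demo)) {
      abort(sprintf(
        "feature spec includes demographics but timeline for %s has none",
        timeline$patient_id), class = "asthmawarn_precondition_error")
    }
    age <- floor((a - as.numeric(demo$birth_date)) / 365.25)
    m <- cbind(m, age = age, sex_male = rep(as.numeric(demo$sex == "M"),
                                            length(a)))
  }
  rownames(m) <- NULL
  m
}

#' Build annual prediction instances
#'
#' For each index year, identifies the year's asthma cohort
#' ([find_asthma_patients()]), anchors an as-of date at 31 December, extracts
#' the feature vector from history up to the as-of date, and labels the
#' instance with whether the patient has at least one home-system asthma
#' hospital visit within the following 365 days (the half-open window
#' `(as_of, as_of + 365]`). Labels therefore read only post-as-of events and
#' features only pre-as-of events.
#'
#' @param events An event table.
#' @param years Integer vector of index years; each outcome window
#'   (`year + 1`) must fit inside the data span.
#' @param rules A [code_rules()].
#' @param spec A [feature_spec()].
#' @param demographics Optional demographics tibble (required when `spec`
#'   includes static features).
#' @param span_end End of the observable span; defaults to the simulation
#'   attribute on `events`, else the latest event date.
#' @return A tibble: `patient_id`, `year`, `as_of`, one column per feature,
#'   and `label` (logical).
#' @export
build_instances <- function(events, years, rules = code_rules(),
                            spec = feature_spec(), demographics = NULL,
                            span_end = NULL) {
  span_end <- span_end %||% attr(events, "span_end") %||% max(events$date)
  for (year in years) {
    if (as.Date(sprintf("%d-12-31", year)) + 365 > span_end) {
      abort(sprintf(
        "outcome window for index year %d extends past the data span", year),
        class = "asthmawarn_precondition_error")
    }
  }
  map_dfr(years, function(year) {
    as_of <- as.Date(sprintf("%d-12-31", year))
    ids <- find_asthma_patients(events, year, rules)
    map_dfr(ids, function(id) {
      tl <- patient_timeline(events, id, demographics = demographics,
                             rules = rules)
      x <- build_features(tl, as_of, spec)
      hosp <- tl$index$asthma_hosp_home
      a <- as.numeric(as_of)
      label <- any(hosp > a & hosp <= a + 365)
      vctr <- as.list(x)
      names(vctr) <- names(x)
      tibble(patient_id = id, year = year, as_of = as_of, !!!vctr,
             label = label)
    })
  })
}
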