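# hand-built event rows and independent brute-force oracles used across files

ev <- function(date, type, principal = "", patient = "P1", codes = NULL,
               med = "", source = NULL) {
  source <- source %||% if (startsWith(type, "external")) "external" else "home"
  tibble::tibble(
    patient_id = patient, date = as.Date(date), event_type = type,
    diagnosis_codes = codes %||% principal, principal_code = principal,
    med_class = med, source = source
  )
}

events_tbl <- function(...) dplyr::bind_rows(...)

`%||%` <- rlang::`%||%`

# session-level cache so expensive simulations are built once per test run
aw_cache <- new.env(parent = emptyenv())
cached <- function(name, make) {
  if (!exists(name, envir = aw_cache)) assign(name, make(), envir = aw_cache)
  get(name, envir = aw_cache)
}

# --- independent oracle: naive feature tally from the raw event rows -------
# restates the category definitions without using the package's index
naive_category_dates <- function(events, filter) {
  is_visit <- events$event_type %in% c("outpatient", "ED", "inpatient",
                                       "external_ED", "external_inpatient")
  strip <- function(x) gsub(".", "", x, fixed = TRUE)
  asthma <- function(code) {
    code <- strip(code)
    nzchar(code) & (startsWith(code, "J45") | startsWith(code, "4931") |
                      startsWith(code, "4930") | startsWith(code, "4939") |
                      startsWith(code, "4938"))
  }
  any_asthma <- vapply(seq_len(nrow(events)), function(i) {
    cand <- c(events$principal_code[i],
              strsplit(events$diagnosis_codes[i], ";", fixed = TRUE)[[1]])
    cand <- cand[nzchar(cand)]
    length(cand) > 0 && any(asthma(cand))
  }, logical(1))
  keep <- switch(
    filter,
    ED = events$event_type == "ED",
    inpatient = events$event_type == "inpatient",
    hospital = events$event_type %in% c("ED", "inpatient"),
    outpatient = events$event_type == "outpatient",
    asthma_dx = is_visit & events$source == "home" & any_asthma,
    steroid = events$event_type == "prescription" &
      events$med_class == "systemic_corticosteroid",
    exacerbation = is_visit & events$source == "home" &
      strip(events$principal_code) %in%
        strip(c("J45.21", "J45.31", "J45.41", "J45.51", "J45.901",
                "J45.902", "493.02", "493.12", "493.92")),
    stop("unknown filter in oracle: ", filter)
  )
  as.numeric(events$date[keep])
}

naive_feature <- function(events, as_of, filter, window, agg) {
  d <- naive_category_dates(events, filter)
  a <- as.numeric(as_of)
  inside <- d[d > a - window & d <= a]
  switch(agg,
         count = length(inside),
         binary = as.numeric(length(inside) > 0),
         days_since_last = if (length(inside) == 0) window + 1 else
           a - max(inside))
}

# naive daily-scan lead-time oracle for a linear scorer: no vectorisation,
# no short-circuits, its own feature tally
naive_leadtime <- function(patient_events, T_date, spec_tbl, weights,
                           intercept, threshold, span_start,
                           home_only = TRUE) {
  a0 <- max(as.Date(T_date) - 365, as.Date(span_start))
  t_prime <- NULL
  d <- a0
  while (d <= T_date - 1) {
    x <- vapply(seq_len(nrow(spec_tbl)), function(j) {
      naive_feature(patient_events, d, spec_tbl$filter[j], spec_tbl$window[j],
                    spec_tbl$agg[j])
    }, numeric(1))
    names(x) <- spec_tbl$name
    score <- intercept + sum(weights * x[names(weights)])
    if (score >= threshold) { t_prime <- d; break }
    d <- d + 1
  }
  if (is.null(t_prime)) {
    return(list(T_prime = as.Date(NA), k = 0L))
  }
  strip <- function(x) gsub(".", "", x, fixed = TRUE)
  hosp_types <- c("ED", "inpatient", "external_ED", "external_inpatient")
  is_hosp <- patient_events$event_type %in% hosp_types &
    nzchar(patient_events$principal_code) &
    (startsWith(strip(patient_events$principal_code), "J45") |
       startsWith(strip(patient_events$principal_code), "4931") |
       startsWith(strip(patient_events$principal_code), "4930") |
       startsWith(strip(patient_events$principal_code), "4939") |
       startsWith(strip(patient_events$principal_code), "4938"))
  if (home_only) is_hosp <- is_hosp & patient_events$source == "home"
  later <- sort(patient_events$date[is_hosp & patient_events$date > t_prime])
  list(T_prime = t_prime, k = as.integer(later[1] - t_prime))
}

# fixture: 218 lead times reproducing the published warning-count bins
fixture_leadtimes_218 <- function() {
  tibble::tibble(k = c(rep(365L, 67), rep(90L, 68), rep(1L, 49), rep(0L, 34)))
}

# fixture: 1310 false-positive indicator rows reproducing the published
# per-indicator counts (316/126/18/39) and unions (358/380)
fixture_fp_flags_1310 <- function() {
  n <- 1310
  ind1 <- ind2 <- ind3 <- ind4 <- logical(n)
  ind1[1:316] <- TRUE
  ind2[215:340] <- TRUE         # 126 exacerbation, 102 overlapping ind1
  ind3[341:358] <- TRUE         # 18 later hospital visits, disjoint
  ind4[342:380] <- TRUE         # 39 external, 17 overlap {1,2,3}, 22 new
  stopifnot(sum(ind2) == 126, sum(ind3) == 18, sum(ind4) == 39,
            sum(ind1 | ind2 | ind3) == 358,
            sum(ind1 | ind2 | ind3 | ind4) == 380)
  tibble::tibble(
    patient_id = sprintf("F%04d", seq_len(n)),
    ind1_steroid_rx = ind1,
    ind2_exacerbation_visit = ind2,
    ind3_later_hospital_visit = ind3,
    ind4_external_hospital_visit = ind4,
    ind3_evaluable = TRUE,
    steroid_multiplicity = as.integer(ind1)
  )
}

# shared small simulated cohort + fitted pipeline (used by several files)
shared_pipeline <- function() {
  cached("pipeline_n300", function() {
    run_pipeline(run_config(sim = sim_config(n_patients = 300, seed = 42),
                            seed = 42), quiet = TRUE)
  })
}
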