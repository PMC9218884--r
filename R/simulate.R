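#' Simulation configuration for the synthetic EHR cohort
#'
#' Bundles and validates the parameters of the synthetic longitudinal
#' event-stream generator. All rates are marginal expectations per
#' patient-year; per-patient heterogeneity is added through a mean-one
#' log-normal frailty on the hazards, so the configured rates remain the
#' population means.
#'
#' @param n_patients Number of patients to simulate (positive integer).
#' @param span_start,span_end Calendar bounds (`Date` or ISO-8601 string) of
#'   the simulated observation window; `span_start` must precede `span_end`.
#' @param baseline_event_rate Expected asthma hospital visits per
#'   patient-year (>= 0), before frailty scaling.
#' @param outpatient_rate Expected outpatient visits per patient-year (>= 0).
#' @param prodrome_lead_days Length `L` (days, integer >= 0) of the prodromal
#'   window planted before each hospital visit: utilization is elevated over
#'   `[T - L, T)` for a hospital visit on day `T`.
#' @param prodrome_intensity Multiplier (>= 1) applied to the outpatient-visit
#'   hazard (and to the odds of asthma-specific coding) inside prodromal
#'   windows.
#' @param external_visit_fraction Probability in `[0, 1]` that a hospital
#'   visit occurs outside the home system (recorded via the external
#'   registry, with `source = "external"`).
#' @param steroid_rate_base,steroid_rate_prodrome Systemic-corticosteroid
#'   orders per patient-year outside / inside prodromal windows (>= 0).
#' @param death_rate Deaths per patient-year (>= 0); a death censors all of
#'   the patient's later events.
#' @param severity_sigma Standard deviation (log scale, >= 0) of the mean-one
#'   log-normal frailty multiplying each patient's hazards; `0` disables
#'   frailty so event counts are exactly Poisson at the configured rates.
#' @param asthma_codes Character menu of ICD asthma codes stamped on
#'   simulated asthma visits.
#' @param seed Integer master seed. Each patient draws from an RNG stream
#'   derived from `(seed, patient index)`, so enlarging the cohort leaves
#'   existing patients' histories unchanged.
#'
#' @return A validated list of class `"sim_config"`.
#' @seealso [simulate_cohort()], [simulate_demographics()]
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 20, seed = 7)
#' events <- simulate_cohort(cfg)
sim_config <- function(n_patients = 500,
                       span_start = "2015-01-01",
                       span_end = "2020-12-31",
                       baseline_event_rate = 0.3,
                       outpatient_rate = 5,
                       prodrome_lead_days = 60,
                       prodrome_intensity = 6,
                       external_visit_fraction = 0.15,
                       steroid_rate_base = 0.6,
                       steroid_rate_prodrome = 8,
                       death_rate = 0.01,
                       severity_sigma = 1,
                       asthma_codes = c("J45.909", "J45.21", "493.90", "493.12"),
                       seed = 1L) {
  cfg <- list(
    n_patients = n_patients,
    span_start = as.Date(span_start),
    span_end = as.Date(span_end),
    baseline_event_rate = baseline_event_rate,
    outpatient_rate = outpatient_rate,
    prodrome_lead_days = as.integer(prodrome_lead_days),
    prodrome_intensity = prodrome_intensity,
    external_visit_fraction = external_visit_fraction,
    steroid_rate_base = steroid_rate_base,
    steroid_rate_prodrome = steroid_rate_prodrome,
    death_rate = death_rate,
    severity_sigma = severity_sigma,
    asthma_codes = as.character(asthma_codes),
    seed = as.integer(seed)
  )
  check_scalar <- function(field, ok, what) {
    x <- cfg[[field]]
    if (length(x) != 1 || is.na(x) || !ok(x)) {
      abort(sprintf("invalid simulation config: `%s` must be %s", field, what),
            class = "asthmawarn_config_error")
    }
  }
  check_scalar("n_patients", function(x) x >= 1 && x == trunc(x),
               "a positive integer")
  if (is.na(cfg$span_start) || is.na(cfg$span_end) ||
      !(cfg$span_start < cfg$span_end)) {
    abort("invalid simulation config: `span_start` must precede `span_end`",
          class = "asthmawarn_config_error")
  }
  for (f in c("baseline_event_rate", "outpatient_rate", "steroid_rate_base",
              "steroid_rate_prodrome", "death_rate", "severity_sigma")) {
    check_scalar(f, function(x) x >= 0, "a non-negative number")
  }
  check_scalar("prodrome_lead_days", function(x) x >= 0,
               "an integer >= 0")
  check_scalar("prodrome_intensity", function(x) x >= 1, "a number >= 1")
  check_scalar("external_visit_fraction", function(x) x >= 0 && x <= 1,
               "a probability in [0, 1]")
  if (length(cfg$asthma_codes) < 1 || any(!nzchar(cfg$asthma_codes))) {
    abort("invalid simulation config: `asthma_codes` must be non-empty codes",
          class = "asthmawarn_config_error")
  }
  check_scalar("seed", function(x) TRUE, "an integer")
  structure(cfg, class = "sim_config")
}

# deterministic per-patient RNG stream: patient i keeps its stream when the
# cohort grows or shrinks
patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 65521) * 32749 + i) %% 2147483647L
}

NOISE_CODES <- c("I10", "E11.9", "Z00.00", "M54.5", "K21.9")
EXACERBATION_LEANING <- c("J45.901", "J45.21")

# simulate one patient; returns a list of row vectors (assembled by caller)
simulate_patient <- function(i, cfg, n_days) {
  set.seed(patient_seed(cfg$seed, i))
  pid <- sprintf("P%05d", i)
  sev <- if (cfg$severity_sigma > 0) {
    rlnorm(1, meanlog = -cfg$severity_sigma^2 / 2, sdlog = cfg$severity_sigma)
  } else 1

  p_death <- 1 - exp(-cfg$death_rate * n_days / 365)
  death_day <- if (runif(1) < p_death) sample.int(n_days, 1L) else NA_integer_

  p_hosp <- min(cfg$baseline_event_rate * sev / 365, 1)
  hosp_days <- which(runif(n_days) < p_hosp)

  prodrome <- logical(n_days)
  L <- cfg$prodrome_lead_days
  if (L > 0) {
    for (t in hosp_days) {
      if (t > 1) prodrome[max(1L, t - L):(t - 1L)] <- TRUE
    }
  }

  p_out <- pmin(cfg$outpatient_rate * sev / 365 *
                  ifelse(prodrome, cfg$prodrome_intensity, 1), 1)
  out_days <- which(runif(n_days) < p_out)

  p_ster <- pmin(ifelse(prodrome, cfg$steroid_rate_prodrome,
                        cfg$steroid_rate_base) * sev / 365, 1)
  ster_days <- which(runif(n_days) < p_ster)

  # censor at death: no events strictly after the death date
  if (!is.na(death_day)) {
    hosp_days <- hosp_days[hosp_days <= death_day]
    out_days <- out_days[out_days <= death_day]
    ster_days <- ster_days[ster_days <= death_day]
  }

  n_h <- length(hosp_days)
  n_o <- length(out_days)
  n_s <- length(ster_days)

  hosp_type <- hosp_ext <- hosp_code <- character(0)
  if (n_h > 0) {
    is_ed <- runif(n_h) < 0.7
    is_ext <- runif(n_h) < cfg$external_visit_fraction
    hosp_type <- ifelse(is_ext,
                        ifelse(is_ed, "external_ED", "external_inpatient"),
                        ifelse(is_ed, "ED", "inpatient"))
    hosp_ext <- ifelse(is_ext, "external", "home")
    hosp_code <- sample(cfg$asthma_codes, n_h, replace = TRUE)
  }

  out_code <- character(0)
  if (n_o > 0) {
    # asthma-specific coding is more likely during the prodrome; otherwise a
    # mix of asthma and non-asthma codes keeps case-finding non-trivial
    in_prod <- prodrome[out_days]
    p_asthma <- ifelse(in_prod, 0.9, 0.5)
    asthma_coded <- runif(n_o) < p_asthma
    exac_coded <- asthma_coded & in_prod & (runif(n_o) < 0.5)
    out_code <- ifelse(exac_coded,
                       sample(EXACERBATION_LEANING, n_o, replace = TRUE),
                       ifelse(asthma_coded,
                              sample(cfg$asthma_codes, n_o, replace = TRUE),
                              sample(NOISE_CODES, n_o, replace = TRUE)))
  }

  add_secondary <- function(codes, k) {
    if (k == 0) return(character(0))
    sec <- runif(k) < 0.3
    ifelse(sec, paste(codes, sample(NOISE_CODES, k, replace = TRUE), sep = ";"),
           codes)
  }

  day <- c(hosp_days, out_days, ster_days,
           if (!is.na(death_day)) death_day else integer(0))
  tibble(
    patient_id = pid,
    day = day,
    event_type = c(hosp_type, rep("outpatient", n_o),
                   rep("prescription", n_s),
                   if (!is.na(death_day)) "death" else character(0)),
    diagnosis_codes = c(add_secondary(hosp_code, n_h),
                        add_secondary(out_code, n_o),
                        rep("", n_s),
                        if (!is.na(death_day)) "" else character(0)),
    principal_code = c(hosp_code, out_code, rep("", n_s),
                       if (!is.na(death_day)) "" else character(0)),
    med_class = c(rep("", n_h + n_o),
                  rep("systemic_corticosteroid", n_s),
                  if (!is.na(death_day)) "" else character(0)),
    source = c(hosp_ext, rep("home", n_o + n_s),
               if (!is.na(death_day)) "home" else character(0))
  )
}

#' Simulate a longitudinal synthetic EHR event table
#'
#' Generates per-patient clinical event streams over the configured calendar
#' span. Each patient carries a latent severity (mean-one log-normal frailty)
#' scaling all utilization hazards; asthma hospital visits are drawn from a
#' daily Bernoulli hazard, and for each hospital visit on day `T` the
#' outpatient-visit and corticosteroid hazards are elevated over the
#' prodromal window `[T - L, T)`, planting a detectable early-warning signal.
#' Hospital visits relocate to an external facility with probability
#' `external_visit_fraction`; deaths censor all later events.
#'
#' The output is an event table: one row per clinical event with columns
#' `patient_id`, `date`, `event_type` (one of `outpatient`, `ED`,
#' `inpatient`, `prescription`, `death`, `external_ED`,
#' `external_inpatient`), `diagnosis_codes` (`;`-joined), `principal_code`,
#' `med_class` and `source` (`home`/`external`). The simulated span is
#' attached as attributes `span_start`/`span_end`.
#'
#' This generator is a synthetic stand-in for real enterprise-data-warehouse
#' and external-registry extracts; see the methods vignette for what it does
#' and does not emulate.
#'
#' @param config A [sim_config()].
#' @return A tibble of events, sorted by patient and date.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  n_days <- as.integer(config$span_end - config$span_start) + 1L
  rows <- map(seq_len(config$n_patients), simulate_patient,
              cfg = config, n_days = n_days)
  events <- bind_rows(rows)
  if (nrow(events) == 0) {
    events <- tibble(patient_id = character(), day = integer(),
                     event_type = character(), diagnosis_codes = character(),
                     principal_code = character(), med_class = character(),
                     source = character())
  }
  events <- events |>
    mutate(date = config$span_start + .data$day - 1L) |>
    select("patient_id", "date", "event_type", "diagnosis_codes",
           "principal_code", "med_class", "source") |>
    arrange(.data$patient_id, .data$date, .data$event_type,
            .data$principal_code)
  attr(events, "span_start") <- config$span_start
  attr(events, "span_end") <- config$span_end
  events
}

#' Simulate per-patient demographics
#'
#' Companion generator supplying the static attributes (birth date, sex) that
#' the default feature specification uses. Draws come from the same
#' per-patient RNG streams as [simulate_cohort()], offset so the two
#' generators do not interfere, and are therefore reproducible per patient
#' regardless of cohort size. Ages at `span_end` are uniform over 18-90
#' years (an adult asthma cohort).
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `patient_id`, `birth_date`, `sex`
#'   (`"F"`/`"M"`).
#' @export
simulate_demographics <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  map_dfr(seq_len(config$n_patients), function(i) {
    set.seed((patient_seed(config$seed, i) + 1000003L) %% 2147483647L)
    age_years <- runif(1, 18, 90)
    tibble(
      patient_id = sprintf("P%05d", i),
      birth_date = config$span_end - round(age_years * 365.25),
      sex = sample(c("F", "M"), 1)
    )
  })
}

EVENT_COLUMNS <- c("patient_id", "date", "event_type", "diagnosis_codes",
                   "principal_code", "med_class", "source")

#' Write / read an event table
#'
#' Events round-trip through a plain CSV with a fixed column order
#' (`patient_id, date, event_type, diagnosis_codes, principal_code,
#' med_class, source`) and ISO-8601 dates. `read_events()` validates dates
#' strictly and reports the first offending line.
#'
#' @param events An event table, as produced by [simulate_cohort()].
#' @param path File path.
#' @return `write_events()` returns `path` invisibly; `read_events()` returns
#'   the event tibble.
#' @export
write_events <- function(events, path) {
  stopifnot(all(EVENT_COLUMNS %in% names(events)))
  out <- events |>
    select(dplyr::all_of(EVENT_COLUMNS)) |>
    mutate(date = format(.data$date, "%Y-%m-%d"))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      date = readr::col_character(),
      event_type = readr::col_character(),
      diagnosis_codes = readr::col_character(),
      principal_code = readr::col_character(),
      med_class = readr::col_character(),
      source = readr::col_character()
    ),
    na = character(),
    progress = FALSE
  )
  if (!identical(names(raw), EVENT_COLUMNS)) {
    abort(paste0("malformed events file: expected columns ",
                 paste(EVENT_COLUMNS, collapse = ", ")),
          class = "asthmawarn_parse_error")
  }
  parsed <- as.Date(raw$date, format = "%Y-%m-%d", optional = TRUE)
  # as.Date() silently rolls some malformed dates; re-render to catch them
  ok <- !is.na(parsed) & format(parsed, "%Y-%m-%d") == raw$date
  if (nrow(raw) > 0 && any(!ok)) {
    line <- which(!ok)[1]
    abort(sprintf("malformed date %s on line %d of %s",
                  dQuote(raw$date[line], q = FALSE), line + 1L, path),
          class = "asthmawarn_parse_error")
  }
  raw |>
    mutate(date = parsed) |>
    as_tibble()
}
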