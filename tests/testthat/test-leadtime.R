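lt_spec <- feature_spec(tibble::tribble(
  ~name,              ~filter,      ~window, ~agg,
  "steroid_count_365", "steroid",    365,     "count",
  "out_count_90",      "outpatient", 90,      "count"
), include_demographics = FALSE)

test_that("predict_at needs a frozen threshold and ignores the future", {
  tl <- patient_timeline(events_tbl(
    ev("2019-06-01", "prescription", med = "systemic_corticosteroid"),
    ev("2019-08-01", "ED", "J45.909")
  ), "P1")
  unset <- linear_risk_model(c(steroid_count_365 = 1))
  expect_error(predict_at(tl, as.Date("2019-01-01"), unset, lt_spec),
               class = "asthmawarn_precondition_error")
  m <- linear_risk_model(c(steroid_count_365 = 1), frozen_threshold = 1)
  expect_false(predict_at(tl, as.Date("2019-05-31"), m, lt_spec))
  expect_true(predict_at(tl, as.Date("2019-06-01"), m, lt_spec))
})

test_that("empty-history predictions are constant across dates", {
  tl <- patient_timeline(ev("2019-01-01", "outpatient", "I10",
                            patient = "other"), "P1")
  m <- linear_risk_model(c(steroid_count_365 = 1), intercept = 0.4,
                         frozen_threshold = 0.5)
  days <- as.Date("2019-01-01") + seq(0, 300, by = 30)
  expect_identical(unique(vapply(as.list(days), predict_at, logical(1),
                                 timeline = tl, model = m, spec = lt_spec)),
                   FALSE)
})

test_that("an always-positive model warns at the scan start", {
  T_date <- as.Date("2019-07-01")
  tl <- patient_timeline(ev(T_date, "ED", "J45.909"), "P1")
  always <- linear_risk_model(c(steroid_count_365 = 0), intercept = 1,
                              frozen_threshold = 0.5)
  r <- advance_warning_days(tl, T_date, always, lt_spec,
                            span_start = as.Date("2015-01-01"))
  expect_equal(r$T_prime, T_date - 365)
  expect_equal(r$k, 365L)   # T is the only visit in the scan window
})

test_that("an always-negative model gives k = 0 on the day of the visit", {
  T_date <- as.Date("2019-07-01")
  tl <- patient_timeline(ev(T_date, "ED", "J45.909"), "P1")
  never <- linear_risk_model(c(steroid_count_365 = 0), intercept = 0,
                             frozen_threshold = 0.5)
  r <- advance_warning_days(tl, T_date, never, lt_spec,
                            span_start = as.Date("2015-01-01"))
  expect_true(is.na(r$T_prime))
  expect_equal(r$k, 0L)
})

test_that("k runs to the first hospital visit after T', not to T", {
  T_date <- as.Date("2019-10-01")
  tl <- patient_timeline(events_tbl(
    ev(T_date, "ED", "J45.909"),
    ev(T_date - 100, "ED", "J45.21"),
    # a steroid order at T-200 turns the score positive from then on
    ev(T_date - 200, "prescription", med = "systemic_corticosteroid")
  ), "P1")
  m <- linear_risk_model(c(steroid_count_365 = 1), frozen_threshold = 1)
  r <- advance_warning_days(tl, T_date, m, lt_spec,
                            span_start = as.Date("2015-01-01"))
  expect_equal(r$T_prime, T_date - 200)
  expect_equal(r$k, 100L)
  # result invariants
  expect_true(r$T_prime >= r$T - 365 && r$T_prime <= r$T - 1)
  expect_true(r$k >= 1 && r$k <= as.integer(r$T - r$T_prime))
})

test_that("the scan clips to the span start when history is short", {
  T_date <- as.Date("2016-03-01")
  tl <- patient_timeline(ev(T_date, "ED", "J45.909"), "P1")
  always <- linear_risk_model(c(steroid_count_365 = 0), intercept = 1,
                              frozen_threshold = 0.5)
  r <- advance_warning_days(tl, T_date, always, lt_spec,
                            span_start = as.Date("2016-01-01"))
  expect_equal(r$T_prime, as.Date("2016-01-01"))
  expect_equal(r$k, as.integer(T_date - as.Date("2016-01-01")))
})

test_that("the daily scan matches a naive day-by-day oracle on random timelines", {
  events <- simulate_cohort(sim_config(n_patients = 120, seed = 17))
  spec <- lt_spec
  weights <- c(steroid_count_365 = 1, out_count_90 = 1)
  inst <- build_instances(events, 2018, spec = spec)
  cls <- apply_cutoff(tibble::tibble(patient_id = inst$patient_id,
                                     score = risk_scores(
                                       linear_risk_model(weights), inst)),
                      0.10)
  m <- linear_risk_model(weights,
                         frozen_threshold = attr(cls, "threshold"))
  lt <- compute_leadtimes(events, m, 2019, spec = spec,
                          patients = inst$patient_id)
  expect_gte(nrow(lt), 15)
  for (i in seq_len(min(nrow(lt), 20))) {
    pe <- dplyr::filter(events, patient_id == lt$patient_id[i])
    oracle <- naive_leadtime(pe, lt$T[i], spec$features, weights, 0,
                             m$frozen_threshold,
                             attr(events, "span_start"))
    expect_equal(lt$T_prime[i], oracle$T_prime,
                 info = lt$patient_id[i])
    expect_equal(lt$k[i], oracle$k, info = lt$patient_id[i])
  }
})

test_that("warning curves count patients warned at least c days ahead", {
  curve <- warning_curve(tibble::tibble(k = c(0L, 0L, 365L)))
  expect_equal(curve$n_with_at_least[curve$c == 0], 3)
  expect_equal(curve$n_with_at_least[curve$c == 1], 1)
  expect_equal(curve$n_with_at_least[curve$c == 365], 1)
  empty <- warning_curve(tibble::tibble(k = integer()))
  expect_true(all(empty$n_with_at_least == 0))
})

test_that("warning curves are non-increasing and anchored at the cohort size", {
  set.seed(23)
  for (i in 1:10) {
    ks <- sample(0:365, sample(1:200, 1), replace = TRUE)
    curve <- warning_curve(tibble::tibble(k = ks))
    expect_true(all(diff(curve$n_with_at_least) <= 0))
    expect_equal(curve$n_with_at_least[1], length(ks))
    expect_equal(curve$n_with_at_least[curve$c == 1] + sum(ks == 0),
                 length(ks))
    # agreement with the direct definition at random horizons
    for (cc in sample(0:365, 5)) {
      expect_equal(curve$n_with_at_least[curve$c == cc], sum(ks >= cc))
    }
  }
})

test_that("lead-time summaries match direct formulas", {
  one <- summarize_leadtimes(tibble::tibble(k = 10L))
  expect_equal(one$mean, 10)
  expect_equal(one$sd, 0)
  set.seed(31)
  ks <- sample(0:365, 50, replace = TRUE)
  s <- summarize_leadtimes(tibble::tibble(k = ks))
  expect_equal(s$mean, mean(ks))
  expect_equal(s$sd, sd(ks))
  expect_equal(s$thresholds$n_at_least,
               vapply(c(365, 180, 90, 30, 14, 1),
                      function(t) sum(ks >= t), integer(1)))
  expect_error(summarize_leadtimes(tibble::tibble(k = integer())),
               class = "asthmawarn_precondition_error")
})

test_that("warning-curve plots build without error", {
  p <- autoplot(warning_curve(tibble::tibble(k = c(0L, 10L, 200L))))
  expect_s3_class(p, "ggplot")
})
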