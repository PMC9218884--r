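as_of <- as.Date("2018-12-31")

test_that("steroid orders in the 12-month window set indicator 1 with multiplicity", {
  tl <- patient_timeline(events_tbl(
    ev("2019-02-01", "prescription", med = "systemic_corticosteroid"),
    ev("2019-10-01", "prescription", med = "systemic_corticosteroid"),
    ev("2018-12-31", "prescription", med = "systemic_corticosteroid"),  # at as_of: outside
    ev("2020-02-01", "prescription", med = "systemic_corticosteroid")   # beyond 365d
  ), "P1")
  f <- indicator_flags(tl, as_of)
  expect_true(f$ind1_steroid_rx)
  expect_equal(f$steroid_multiplicity, 2L)
})

test_that("window edges are half-open at as_of and closed at as_of + 365", {
  edge <- patient_timeline(events_tbl(
    ev(as_of + 365, "prescription", med = "systemic_corticosteroid")
  ), "P1")
  expect_equal(indicator_flags(edge, as_of)$steroid_multiplicity, 1L)
  beyond <- patient_timeline(events_tbl(
    ev(as_of + 366, "prescription", med = "systemic_corticosteroid")
  ), "P1")
  expect_equal(indicator_flags(beyond, as_of)$steroid_multiplicity, 0L)
})

test_that("exacerbation and later/external hospital visits flag indicators 2-4", {
  tl <- patient_timeline(events_tbl(
    ev("2019-03-01", "outpatient", "J45.901"),        # exacerbation visit
    ev("2020-06-01", "ED", "J45.909"),                # months 13-24, home
    ev("2019-05-01", "external_inpatient", "493.12")  # external in window
  ), "P1")
  f <- indicator_flags(tl, as_of)
  expect_true(f$ind2_exacerbation_visit)
  expect_true(f$ind3_later_hospital_visit)
  expect_true(f$ind4_external_hospital_visit)
})

test_that("an external visit at as_of + 400 counts for neither ind4 nor home-only ind3", {
  tl <- patient_timeline(events_tbl(
    ev(as_of + 400, "external_ED", "J45.909")
  ), "P1")
  home <- indicator_flags(tl, as_of, ind3_home_only = TRUE)
  expect_false(home$ind4_external_hospital_visit)  # outside the 365-day window
  expect_false(home$ind3_later_hospital_visit)     # external source excluded
  any_src <- indicator_flags(tl, as_of, ind3_home_only = FALSE)
  expect_true(any_src$ind3_later_hospital_visit)
})

test_that("an empty post-anchor history yields all-false flags", {
  tl <- patient_timeline(events_tbl(
    ev("2018-06-01", "ED", "J45.909"),
    ev("2018-07-01", "prescription", med = "systemic_corticosteroid")
  ), "P1")
  f <- indicator_flags(tl, as_of)
  expect_false(any(unlist(f[c("ind1_steroid_rx", "ind2_exacerbation_visit",
                              "ind3_later_hospital_visit",
                              "ind4_external_hospital_visit")])))
  expect_equal(f$steroid_multiplicity, 0L)
})

test_that("an unobservable months-13-24 window is reported unevaluable", {
  tl <- patient_timeline(events_tbl(ev("2019-01-01", "ED", "J45.909")), "P1")
  expect_warning(
    f <- indicator_flags(tl, as_of, span_end = as.Date("2019-12-31")),
    class = "asthmawarn_window_warning"
  )
  expect_false(f$ind3_later_hospital_visit)
  expect_false(f$ind3_evaluable)
})

test_that("indicator 1 is equivalent to positive multiplicity on simulated patients", {
  res <- shared_pipeline()
  expect_identical(res$fp_flags$ind1_steroid_rx,
                   res$fp_flags$steroid_multiplicity >= 1L)
})

test_that("the breakdown reproduces brute-force set unions on random flags", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    flags <- tibble::tibble(
      patient_id = sprintf("P%04d", seq_len(n)),
      ind1_steroid_rx = runif(n) < 0.3,
      ind2_exacerbation_visit = runif(n) < 0.2,
      ind3_later_hospital_visit = runif(n) < 0.1,
      ind4_external_hospital_visit = runif(n) < 0.1,
      ind3_evaluable = TRUE,
      steroid_multiplicity = 0L
    )
    flags$steroid_multiplicity <- ifelse(flags$ind1_steroid_rx, 2L, 0L)
    b <- fp_breakdown(flags)
    ids <- function(col) flags$patient_id[flags[[col]]]
    u123 <- union(union(ids("ind1_steroid_rx"), ids("ind2_exacerbation_visit")),
                  ids("ind3_later_hospital_visit"))
    u1234 <- union(u123, ids("ind4_external_hospital_visit"))
    expect_equal(b$n[b$indicator == "any_123"], length(u123))
    expect_equal(b$n[b$indicator == "any_1234"], length(u1234))
    # union inequalities
    singles <- b$n[1:4]
    expect_true(max(singles[1:3]) <= b$n[b$indicator == "any_123"])
    expect_true(max(singles) <= b$n[b$indicator == "any_1234"])
    expect_true(b$n[b$indicator == "any_123"] <=
                  b$n[b$indicator == "any_1234"])
    expect_true(b$n[b$indicator == "any_1234"] <= min(sum(singles), n))
  }
})

test_that("all-false flags break down to zeros", {
  flags <- fixture_fp_flags_1310()[1:5, ]
  flags[2:6] <- FALSE
  flags$steroid_multiplicity <- 0L
  b <- fp_breakdown(flags)
  expect_true(all(b$n == 0))
  expect_true(all(b$pct == 0))
})

test_that("the multiplicity histogram covers exactly the indicator-1 patients", {
  flags <- tibble::tibble(
    patient_id = c("A", "B", "C", "D"),
    ind1_steroid_rx = c(TRUE, TRUE, TRUE, FALSE),
    ind2_exacerbation_visit = FALSE,
    ind3_later_hospital_visit = FALSE,
    ind4_external_hospital_visit = FALSE,
    ind3_evaluable = TRUE,
    steroid_multiplicity = c(1L, 1L, 3L, 0L)
  )
  h <- multiplicity_histogram(flags)
  expect_equal(h$n[h$multiplicity == 1], 2)
  expect_equal(h$n[h$multiplicity == 3], 1)
  expect_equal(attr(h, "max_multiplicity"), 3L)
  expect_equal(sum(h$n), sum(flags$ind1_steroid_rx))
  none <- dplyr::mutate(flags, ind1_steroid_rx = FALSE)
  expect_equal(nrow(multiplicity_histogram(none)), 0)
  # consistency on simulated false positives
  res <- shared_pipeline()
  expect_equal(sum(multiplicity_histogram(res$fp_flags)$n),
               sum(res$fp_flags$ind1_steroid_rx))
})

test_that("external hospital-visit rates track the configured probability", {
  cfg <- sim_config(n_patients = 500, external_visit_fraction = 0.3,
                    seed = 19)
  events <- simulate_cohort(cfg)
  hosp <- events[is_asthma_hospital_visit(events), ]
  p_hat <- mean(hosp$source == "external")
  se <- sqrt(0.3 * 0.7 / nrow(hosp))
  expect_lt(abs(p_hat - 0.3), 3 * se)
})
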