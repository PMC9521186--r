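mini_cohort <- function(n, discharge = as.Date("2012-01-01"), organ = "kidney") {
  data.table(person_id = sprintf("P%02d", seq_len(n)), organ = organ,
             region = "RGA", discharge = discharge)
}

test_that("follow-up ends at the earliest competing event with the right reason", {
  co <- mini_cohort(3)
  start <- co$discharge[1] + 30
  ev <- data.table(person_id = c("P01", "P02", "P02"),
                   event = c("death", "death", "cancer"),
                   date = c(start + 400, start + 400, start + 600))
  fu <- build_followup(co, ev, outcome = "death")
  expect_equal(fu[person_id == "P01", reason], "outcome")
  expect_equal(as.numeric(fu[person_id == "P01", end - start]), 400)
  # no events: five-year cap or study end, whichever first
  expect_equal(fu[person_id == "P03", reason], "5-years")
  expect_equal(as.numeric(fu[person_id == "P03", end - start]), 1826)

  late <- mini_cohort(1, discharge = as.Date("2019-06-01"))
  fu2 <- build_followup(late, ev[0], outcome = "death")
  expect_equal(fu2$reason, "end-of-study")
  expect_equal(fu2$end, as.Date("2019-12-31"))

  # as-treated truncates at the first treatment change
  tc <- data.table(person_id = "P01", date = start + 200)
  fu3 <- build_followup(co, ev, outcome = "death", mode = "as-treated",
                        treatment_change = tc)
  expect_equal(fu3[person_id == "P01", reason], "treatment-change")
  expect_equal(as.numeric(fu3[person_id == "P01", end - start]), 200)
  expect_error(build_followup(co, ev, mode = "as-treated"), "treatment_change")

  # ITT person-time dominates as-treated person-time for every person
  expect_true(all(fu3$end <= fu$end))

  # outcome before start: prevalent, excluded from the risk set
  evp <- data.table(person_id = "P01", event = "cancer", date = start - 10)
  fup <- build_followup(co, evp, outcome = "cancer")
  expect_true(fup[person_id == "P01", prevalent])
  expect_false(fup[person_id == "P01", event])
})

test_that("person-years are exact day counts conserved across year splits", {
  co <- mini_cohort(1, discharge = as.Date("2011-11-02"))
  ev <- data.table(person_id = "P01", event = "death",
                   date = co$discharge + 30 + 365)
  fu <- build_followup(co, ev, outcome = "death")
  py <- person_years(fu)
  expect_equal(attr(py, "total_py"), 365 / 365.25)
  # the interval spans 2012; the split conserves the total
  expect_equal(sum(py$py), 365 / 365.25)
  expect_gte(nrow(py), 2)

  # 100 simulated persons: sum of year cells equals interval days / 365.25
  g <- generate_regional_claims(simulation_config(n_persons = 100, seed = 33,
                                                  planted_negatives = 0))
  ds <- pool_regions(lapply(g$bundles, build_analytical_dataset))
  co2 <- apply_eligibility(find_index_episodes(ds), ds)$cohort
  fu2 <- build_followup(co2, claims_events(ds), outcome = "death")
  py2 <- person_years(fu2)
  brute <- sum(as.numeric(fu2[prevalent == FALSE & no_time == FALSE,
                              end - start])) / 365.25
  expect_equal(attr(py2, "total_py"), brute, tolerance = 1e-9)
  expect_true(all(py2[, diff(cum_py) >= 0, by = organ]$V1))
})

test_that("incidence rates reproduce printed arithmetic and error on bad input", {
  expect_equal(incidence_rate(269, 13720.5)$rate, 1.96)
  expect_equal(incidence_rate(0, 100)$rate, 0)
  expect_equal(incidence_rate(0, 100)$lower, 0)
  expect_equal(incidence_rate(67, 620.8)$rate, 10.79)
  ir <- incidence_rate(269, 13720.5)
  expect_lt(ir$lower, ir$rate)
  expect_gt(ir$upper, ir$rate)
  expect_error(incidence_rate(5, 0), "person_years")
  expect_error(incidence_rate(-1, 10), "negative")
})

test_that("the product-limit estimator matches closed forms and survfit", {
  co <- mini_cohort(4)
  start <- co$discharge[1] + 30
  ev <- data.table(person_id = "P01", event = "death", date = start + 1)
  fu <- build_followup(co, ev, outcome = "death")
  km <- kaplan_meier(fu)
  expect_equal(km$survival[1], 0.75)
  expect_true(all(diff(km$survival) <= 0))
  expect_lte(max(km$survival), 1)

  # all censored: survival stays at 1
  fu0 <- build_followup(co, ev[0], outcome = "death")
  expect_true(all(kaplan_meier(fu0)$survival == 1))

  # frozen hand-computed product-limit table on a 10-subject fixture
  times <- c(2, 4, 4, 6, 8, 8, 10, 12, 13, 15)
  event <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  rec <- data.table(person_id = sprintf("P%02d", 1:10), organ = "kidney",
                    region = "RGA", start = as.Date("2012-01-31"),
                    end = as.Date("2012-01-31") + times,
                    reason = ifelse(event, "outcome", "end-of-study"),
                    prevalent = FALSE, event = event, no_time = FALSE)
  km10 <- kaplan_meier(rec)
  # risk sets: t=2 ->10, t=4 ->9 (1 event, 1 censor), t=6 ->7, t=8 ->6
  # (2 events), t=12 ->3; hand-computed product over risk sets:
  expect_equal(km10[km10$time == 2, survival], 9 / 10)
  expect_equal(km10[km10$time == 4, survival], 9 / 10 * 8 / 9)
  expect_equal(km10[km10$time == 6, survival], 9 / 10 * 8 / 9 * 6 / 7)
  expect_equal(km10[km10$time == 8, survival], 9 / 10 * 8 / 9 * 6 / 7 * 4 / 6)
  expect_equal(km10[km10$time == 12, survival],
               9 / 10 * 8 / 9 * 6 / 7 * 4 / 6 * 2 / 3)

  skip_if_not_installed("survival")
  sf <- survival::survfit(survival::Surv(times, event) ~ 1)
  at_events <- km10[km10$n_event > 0]
  sf_surv <- summary(sf, times = at_events$time)$surv
  expect_equal(at_events$survival, sf_surv, tolerance = 1e-12)
})

test_that("a constant simulated hazard is recovered by the incidence estimator", {
  hz <- matrix(0, nrow = 6, ncol = 5,
               dimnames = list(c("kidney", "liver", "heart", "lung",
                                 "pancreas", "intestine"),
                               c("death", "reject", "infection", "diabetes",
                                 "cancer")))
  hz[, "death"] <- 0.05
  cfg <- simulation_config(n_persons = 1200, seed = 40,
                           planted_negatives = 0, outcome_hazards = hz,
                           transfer_hazard = 0)
  g <- generate_regional_claims(cfg)
  ds <- pool_regions(lapply(g$bundles, build_analytical_dataset))
  co <- apply_eligibility(find_index_episodes(ds), ds)$cohort
  fu <- build_followup(co, claims_events(ds), outcome = "death")
  r <- fu[prevalent == FALSE & no_time == FALSE]
  cases <- sum(r$event)
  pys <- sum(as.numeric(r$end - r$start)) / 365.25
  est <- incidence_rate(cases, pys)
  se <- 100 * sqrt(cases) / pys
  expect_lt(abs(est$rate_raw - 5.0), 3.5 * se)
  # product-limit curve hugs the exponential envelope
  km <- kaplan_meier(fu)
  mid <- km[which.min(abs(km$time - 730))]
  expect_lt(abs(mid$survival - exp(-0.05 * 2)), 0.05)
})
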