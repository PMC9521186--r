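# Follow-up construction (ITT / as-treated), person-years, incidence rates
# with exact Poisson intervals, product-limit survival.

.fu_reasons <- c("outcome", "death", "treatment-change", "transfer-out",
                 "5-years", "end-of-study")

#' Extract event streams from an analytical dataset
#'
#' Death from the mortality-linked persons table, out-of-region transfer
#' from the registration end, and study outcomes (rejection/graft failure,
#' infection, diabetes, cancer) as the first discharge diagnosis matching
#' the shipped ICD-9-CM prefix lists.
#'
#' @param dataset an `analytical_dataset`
#' @return data.table (`person_id`, `event`, `date`), first date per person
#'   and event
#' @export
claims_events <- function(dataset) {
  pr <- dataset$persons
  ev <- list(
    pr[!is.na(death_date), .(person_id, event = "death", date = death_date)],
    pr[!is.na(registration_end),
       .(person_id, event = "transfer_out", date = registration_end)])
  codes <- outcome_code_list()
  dg <- dataset$diagnoses
  for (o in unique(codes$outcome)) {
    pref <- codes[outcome == o, icd9_prefix]
    hit <- dg[Reduce(`|`, lapply(pref, function(p) startsWith(code, p)))]
    if (nrow(hit))
      ev[[length(ev) + 1L]] <- hit[, .(date = min(date)), by = person_id][
        , .(person_id, event = o, date)]
  }
  out <- rbindlist(ev, use.names = TRUE)
  out[, .(date = min(date)), by = .(person_id, event)][]
}

#' Build follow-up records
#'
#' Follow-up runs from 30 days post-discharge (the landmark) to the earliest
#' of: the outcome of interest, death, transfer out of region, five years of
#' follow-up, or the administrative study end. Under `as-treated`, follow-up
#' is additionally truncated at the first treatment change. Outcome events on
#' or before the start are prevalent: the person is excluded from that
#' outcome's risk set (`prevalent = TRUE`). Persons whose follow-up start
#' falls on or after the study end contribute no time (`no_time = TRUE`).
#'
#' @param cohort cohort table from [apply_eligibility()]
#' @param events event table from [claims_events()]
#' @param outcome event name analyzed as the outcome (e.g. `"death"`,
#'   `"cancer"`); ends with reason `"outcome"`
#' @param mode `"itt"` or `"as-treated"`
#' @param treatment_change optional data.table (`person_id`, `date`) of first
#'   treatment-change dates (required for `as-treated`)
#' @param study_end administrative censoring date
#' @return data.table of follow-up records: `person_id`, `organ`, `region`,
#'   `start`, `end`, `reason`, `event`, `prevalent`, `no_time`
#' @export
build_followup <- function(cohort, events, outcome = "death",
                           mode = c("itt", "as-treated"),
                           treatment_change = NULL,
                           study_end = .study$study_end) {
  mode <- match.arg(mode)
  if (mode == "as-treated" && is.null(treatment_change))
    stop("as-treated follow-up needs a treatment_change table")
  ev <- as.data.table(events)
  first_of <- function(type) {
    e <- ev[event == type, .(person_id, d = date)]
    e[match(cohort$person_id, person_id), d]
  }
  start <- cohort$discharge + .study$landmark_days
  d_out <- if (outcome %in% ev$event) first_of(outcome) else as.Date(rep(NA, nrow(cohort)))
  d_death <- first_of("death")
  d_tr <- first_of("transfer_out")
  d_tc <- if (!is.null(treatment_change)) {
    tc <- as.data.table(treatment_change)
    tc[match(cohort$person_id, person_id), date]
  } else as.Date(rep(NA, nrow(cohort)))
  prevalent <- !is.na(d_out) & d_out <= start
  d_out[prevalent] <- NA

  cap <- start + .study$fu_cap_days
  cand <- data.table(outcome = d_out, death = d_death)
  if (outcome == "death") cand[, death := as.Date(NA)]
  cand[, `:=`("treatment-change" = if (mode == "as-treated") d_tc else as.Date(NA),
              "transfer-out" = d_tr,
              "5-years" = cap,
              "end-of-study" = rep(study_end, .N))]
  setnames(cand, "outcome", "outcome")
  # events strictly before start are prevalent/ignored for follow-up
  for (col in c("death", "treatment-change", "transfer-out"))
    cand[[col]][!is.na(cand[[col]]) & cand[[col]] <= start] <- NA
  m <- as.matrix(cand[, lapply(.SD, as.numeric)])
  end_num <- apply(m, 1, min, na.rm = TRUE)
  # reason: first candidate (in priority order) attaining the minimum
  pri <- c("outcome", "death", "treatment-change", "transfer-out", "5-years",
           "end-of-study")
  reason <- pri[apply(m[, pri, drop = FALSE] == end_num, 1,
                      function(z) which(z)[1])]
  out <- data.table(person_id = cohort$person_id, organ = cohort$organ,
                    region = cohort$region, start = start,
                    end = as_date(end_num), reason = reason,
                    prevalent = prevalent)
  out[, event := reason == "outcome" & !prevalent]
  out[, no_time := start >= end]
  out[prevalent == TRUE, `:=`(event = FALSE)]
  out[]
}

#' Accumulate person-years by organ and calendar year
#'
#' Exact day counts over half-open intervals `[start, end)`, split at
#' calendar-year boundaries and converted at 365.25 days per year. Splitting
#' conserves each interval's total person-time exactly.
#'
#' @param records follow-up records from [build_followup()] (prevalent and
#'   zero-time records are skipped)
#' @return data.table (`organ`, `year`, `py`, `cum_py`) plus total PY in
#'   attribute `total_py`
#' @export
person_years <- function(records) {
  r <- records[prevalent == FALSE & no_time == FALSE]
  pieces <- lapply(seq_len(nrow(r)), function(i) {
    s <- r$start[i]; e <- r$end[i]
    yrs <- seq(as.integer(format(s, "%Y")), as.integer(format(e, "%Y")))
    dt <- data.table(organ = r$organ[i], year = yrs)
    ys <- as.Date(paste0(yrs, "-01-01")); ye <- as.Date(paste0(yrs + 1L, "-01-01"))
    dt[, days := as.numeric(pmin(e, ye) - pmax(s, ys))]
    dt[days > 0]
  })
  out <- rbindlist(pieces)[, .(py = sum(days) / .study$days_per_year),
                           by = .(organ, year)]
  setorder(out, organ, year)
  out[, cum_py := cumsum(py), by = organ]
  setattr(out, "total_py", sum(out$py))
  out[]
}

#' Incidence rate per 100 person-years with exact Poisson interval
#'
#' Rate = cases / person-years x 100, displayed to two decimals (half-up).
#' The confidence interval is the exact Poisson (chi-square inversion)
#' interval on the case count.
#'
#' @param cases incident case count
#' @param person_years accumulated person-years at risk
#' @param conf confidence level
#' @return data.table: `cases`, `person_years`, `rate` (2 dp), `lower`,
#'   `upper`, `rate_raw`
#' @examples
#' incidence_rate(269, 13720.5)$rate  # 1.96
#' @export
incidence_rate <- function(cases, person_years, conf = 0.95) {
  if (person_years <= 0) stop("incidence rate error: person_years must be > 0")
  if (cases < 0) stop("incidence rate error: negative case count")
  a <- (1 - conf) / 2
  lo <- if (cases == 0) 0 else qchisq(a, 2 * cases) / 2
  hi <- qchisq(1 - a, 2 * (cases + 1)) / 2
  raw <- 100 * cases / person_years
  data.table(cases = cases, person_years = person_years,
             rate = round_half_up(raw, 2),
             lower = round_half_up(100 * lo / person_years, 2),
             upper = round_half_up(100 * hi / person_years, 2),
             rate_raw = raw)
}

#' Incidence rates by organ from follow-up records
#'
#' @param records follow-up records from [build_followup()]
#' @param outcome outcome name for labelling
#' @return data.table, one row per organ: n at risk, cases, person-years,
#'   rate per 100 PY with exact Poisson CI
#' @export
incidence_table <- function(records, outcome = "outcome") {
  r <- records[prevalent == FALSE & no_time == FALSE]
  r[, .(outcome = outcome, n = .N, cases = sum(event),
        person_years = sum(as.numeric(end - start)) / .study$days_per_year),
    by = organ][
      , c("rate", "lower", "upper") := {
        ir <- lapply(seq_len(.N), function(i) incidence_rate(cases[i], person_years[i]))
        list(vapply(ir, function(x) x$rate, 0),
             vapply(ir, function(x) x$lower, 0),
             vapply(ir, function(x) x$upper, 0))
      }][]
}

#' Product-limit (Kaplan-Meier) survival estimate
#'
#' Right-censored product-limit estimator on follow-up records: time is days
#' from follow-up start, events are outcome occurrences. At tied times,
#' events precede censorings (both remain in the risk set at that time).
#'
#' @param records follow-up records from [build_followup()]
#' @return data.table of the step function: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival` (starts at 1, non-increasing, piecewise constant)
#' @export
kaplan_meier <- function(records) {
  r <- records[prevalent == FALSE & no_time == FALSE]
  if (!nrow(r)) stop("no follow-up records")
  tvec <- as.numeric(r$end - r$start)
  evec <- r$event
  tt <- sort(unique(tvec))
  out <- data.table(
    time = tt,
    n_risk = vapply(tt, function(t) sum(tvec >= t), 0),
    n_event = vapply(tt, function(t) sum(tvec == t & evec), 0),
    n_censor = vapply(tt, function(t) sum(tvec == t & !evec), 0))
  out[, survival := cumprod(1 - n_event / n_risk)]
  out[]
}
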