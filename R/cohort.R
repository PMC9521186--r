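# Incident-transplant cohort selection with a 30-day landmark, and the
# attrition report.

#' Find index transplant episodes
#'
#' Scans all procedure positions of every hospitalization for transplant
#' codes and returns, per person, the first transplant hospitalization in the
#' scan window (2007-01-01 onward). Episodes whose discharge falls outside
#' the enrolment window (2009-01-01 to 2019-12-01) are flagged, not dropped.
#' When an admission carries several transplant codes, the organ of the
#' lowest procedure position is taken as the episode organ and the number of
#' distinct organs is recorded (multi-organ detection).
#'
#' @param dataset an `analytical_dataset` (usually pooled)
#' @return data.table of episodes: `person_id`, `organ`, `n_organs`,
#'   `admission`, `discharge`, `hospital`, `region`, `in_enrolment`
#' @export
find_index_episodes <- function(dataset) {
  tp <- dataset$transplant_procedures[admission_date >= .study$scan_start]
  if (!nrow(tp))
    return(data.table(person_id = character(0), organ = character(0),
                      n_organs = integer(0), admission = as.Date(character(0)),
                      discharge = as.Date(character(0)), hospital = character(0),
                      region = character(0), in_enrolment = logical(0)))
  ep <- tp[, .(organ = organ[which.min(slot)], n_organs = uniqueN(organ),
               hospital = hospital[1], region = region[1]),
           by = .(person_id, admission_date, discharge_date)]
  setorder(ep, person_id, admission_date, discharge_date)
  idx <- ep[, .SD[1], by = person_id]
  setnames(idx, c("admission_date", "discharge_date"), c("admission", "discharge"))
  idx[, in_enrolment := discharge >= .study$enrol_start &
        discharge <= .study$enrol_end]
  setcolorder(idx, c("person_id", "organ", "n_organs", "admission", "discharge",
                     "hospital", "region", "in_enrolment"))
  idx[]
}

# eligibility rules; each returns the logical keep-vector for `ep` rows
.eligibility_rules <- function() {
  list(
    first_in_study_period = function(ep, ds) ep$in_enrolment,
    multi_organ = function(ep, ds) ep$n_organs == 1L,
    washout_2y = function(ep, ds) {
      tp <- ds$transplant_procedures
      prior <- merge(tp, ep[, .(person_id, admission, discharge)],
                     by = "person_id")
      prior <- prior[discharge_date >= discharge - .study$washout_days &
                       discharge_date < admission]
      !ep$person_id %in% unique(prior$person_id)
    },
    registered_alive_30d = function(ep, ds) {
      pr <- ds$persons[match(ep$person_id, person_id)]
      landmark <- ep$discharge + .study$landmark_days
      !is.na(pr$person_id) &
        pr$registration_start <= ep$discharge &
        (is.na(pr$registration_end) | pr$registration_end > landmark) &
        (is.na(pr$death_date) | pr$death_date > landmark)
    },
    no_prior_L04 = function(ep, ds) {
      l04 <- ds$dispensings[startsWith(atc, "L04")]
      prior <- merge(l04, ep[, .(person_id, discharge)], by = "person_id")
      prior <- prior[dispensing_date >= discharge - .study$lookback_l04 &
                       dispensing_date < discharge]
      !ep$person_id %in% unique(prior$person_id)
    },
    post_dispensing_30d = function(ep, ds) {
      l04 <- ds$dispensings[startsWith(atc, "L04")]
      post <- merge(l04, ep[, .(person_id, discharge)], by = "person_id")
      post <- post[dispensing_date >= discharge &
                     dispensing_date < discharge + .study$landmark_days]
      ep$person_id %in% unique(post$person_id)
    })
}

#' Apply the incident-use eligibility algorithm
#'
#' Applies, in order: (1) first transplant hospitalization in the study
#' period; (2) no multiple-organ transplant in the index admission; (3) no
#' transplantation in the two years before the index discharge; (4)
#' registered in the regional system and alive through day 30 after
#' discharge; (5) no immunosuppressant (ATC L04) dispensed in the 180 days
#' before discharge; (6) at least one L04 dispensing in the 30 days after
#' discharge. Each step is logged in the attrition report. The step order is
#' configurable; the final cohort membership is order-invariant, per-step
#' counts are not.
#'
#' @param episodes output of [find_index_episodes()]
#' @param dataset the `analytical_dataset` the episodes came from
#' @param steps character vector naming the rules to apply, in order
#' @return list with `cohort` (episodes of eligible persons joined with sex,
#'   birth date, death date and follow-up start) and `attrition` (an
#'   `attrition_report` data.table: step, remaining, removed)
#' @export
apply_eligibility <- function(episodes, dataset,
                              steps = names(.eligibility_rules())) {
  rules <- .eligibility_rules()
  if (!all(steps %in% names(rules)))
    stop("unknown eligibility step: ",
         paste(setdiff(steps, names(rules)), collapse = ", "))
  ep <- copy(episodes)
  att <- data.table(step = "identified", remaining = nrow(ep), removed = 0L)
  for (s in steps) {
    keep <- rules[[s]](ep, dataset)
    att <- rbind(att, data.table(step = s, remaining = sum(keep),
                                 removed = sum(!keep)))
    ep <- ep[keep]
  }
  pr <- dataset$persons[, .(person_id, sex, birth_date, death_date,
                            registration_end)]
  cohort <- merge(ep, pr, by = "person_id", all.x = TRUE, sort = FALSE)
  cohort[, fu_start := discharge + .study$landmark_days]
  setattr(att, "class", c("attrition_report", class(att)))
  list(cohort = cohort[], attrition = att)
}

#' Inclusion proportion from an attrition report
#'
#' Final cohort size over the initially identified count, as a percentage
#' rounded half-up to one decimal (display convention of flow-chart
#' figures).
#'
#' @param report an `attrition_report`
#' @return numeric percentage
#' @examples
#' pct(7369, 14765)  # the same ratio helper: 49.9
#' @export
attrition_proportion <- function(report) {
  n0 <- report$remaining[1]
  if (n0 == 0) stop("undefined proportion: initial count is zero")
  pct(report$remaining[nrow(report)], n0)
}
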