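# Index immunosuppressive regimen classification, adherence (PDC/MPR) and
# switching from dispensing streams.

# annotate dispensing rows with agent/role/formulation/brand from the
# dictionary (AIC product match first, ATC fallback)
.annotate_dispensings <- function(dispensings, dictionary) {
  d <- as.data.table(dispensings)
  dict <- as.data.table(dictionary)
  d <- merge(d, dict[, .(aic, agent, role, brand_status, formulation,
                         days_per_package)],
             by = "aic", all.x = TRUE, sort = FALSE)
  if (anyNA(d$agent)) {
    byatc <- unique(dict[, .(atc, agent2 = agent, role2 = role)], by = "atc")
    d <- merge(d, byatc, by = "atc", all.x = TRUE, sort = FALSE)
    d[is.na(agent), `:=`(agent = agent2, role = role2)]
    d[, c("agent2", "role2") := NULL]
  }
  d[!is.na(agent)]
}

#' Classify the index immunosuppressive regimen
#'
#' From the dispensings in the 30-day post-discharge window: backbone from
#' calcineurin-inhibitor presence (TAC-based, CsA-based, or No-CNI);
#' companion from antimetabolite / mTOR-inhibitor presence (`mono`,
#' `+antimet`, `+mTOR`, with combinations outside these — antimet and mTOR
#' together, or residual agents — as `other`); steroid flag from any H02AB
#' dispensing. A No-CNI regimen with only steroids or residual agents is
#' `other` (mainly steroid-based). When both TAC and CsA appear, the backbone
#' is the earliest-dispensed CNI, with same-day ties going to TAC
#' (configurable).
#'
#' @param dispensings one person's dispensing rows within the index window
#'   (columns `dispensing_date`, `atc`, `aic`)
#' @param dictionary a [drug_dictionary()]
#' @param tie_backbone backbone assigned when both CNIs first appear on the
#'   same day
#' @return list: `backbone`, `companion`, `steroid`, `antimet_agent`,
#'   `mtor_agent`, `label`
#' @export
classify_index_regimen <- function(dispensings, dictionary = drug_dictionary(),
                                   tie_backbone = "TAC-based") {
  d <- .annotate_dispensings(dispensings, dictionary)
  if (!nrow(d))
    stop("classification error: no dictionary drug in the index window")
  cni <- d[role == "CNI"]
  backbone <- if (!nrow(cni)) "No-CNI" else {
    first <- cni[, .(t = min(dispensing_date)), by = agent]
    if (nrow(first) == 1L) {
      if (first$agent == "TAC") "TAC-based" else "CsA-based"
    } else if (first[agent == "TAC", t] < first[agent == "CsA", t]) "TAC-based"
      else if (first[agent == "TAC", t] > first[agent == "CsA", t]) "CsA-based"
      else tie_backbone
  }
  has_am <- nrow(d[role == "antimet"]) > 0
  has_mt <- nrow(d[role == "mTOR"]) > 0
  has_other <- nrow(d[role == "other"]) > 0
  companion <-
    if (has_am && has_mt) "other"
    else if (has_am) "+antimet"
    else if (has_mt) "+mTOR"
    else if (backbone == "No-CNI" || has_other) "other"
    else "mono"
  steroid <- nrow(d[role == "steroid"]) > 0
  am <- d[role == "antimet"][order(dispensing_date)]
  antimet_agent <- if (companion == "+antimet" || (has_am && companion == "other"))
    am$agent[1] else "none"
  mt <- d[role == "mTOR"][order(dispensing_date)]
  mtor_agent <- if (nrow(mt)) mt$agent[1] else "none"
  list(backbone = backbone, companion = companion, steroid = steroid,
       antimet_agent = antimet_agent, mtor_agent = mtor_agent,
       label = regimen_label(backbone, companion, steroid))
}

#' Classify tacrolimus formulation in the index window
#'
#' @param dispensings one person's index-window dispensing rows
#' @param dictionary a [drug_dictionary()]
#' @return `"IR"`, `"ER"`, `"mixed"` (both in the window) or `"n/a"` (no TAC)
#' @export
classify_tac_formulation <- function(dispensings,
                                     dictionary = drug_dictionary()) {
  d <- .annotate_dispensings(dispensings, dictionary)
  tac <- d[agent == "TAC"]
  if (!nrow(tac)) return("n/a")
  f <- unique(tac$formulation)
  if (anyNA(f) || any(!nzchar(f)))
    stop("dictionary error: TAC product without formulation flag")
  if (length(f) > 1) "mixed" else f
}

#' Classify brand/generic status per agent
#'
#' Computed only for persons whose index date falls on or after the first
#' generic availability of the agent; earlier enrollees are `not-evaluable`.
#'
#' @param dispensings one person's index-window dispensing rows
#' @param dictionary a [drug_dictionary()]
#' @param availability a [generic_availability()] calendar
#' @param index_date the person's cohort entry date
#' @param agents agents to evaluate
#' @return named character vector per agent: `brand`, `generic`, `mixed`,
#'   `not-evaluable` or `n/a` (agent not dispensed)
#' @export
classify_brand_status <- function(dispensings, dictionary = drug_dictionary(),
                                  availability = generic_availability(),
                                  index_date, agents = c("TAC", "MMF", "CsA")) {
  d <- .annotate_dispensings(dispensings, dictionary)
  out <- setNames(rep("n/a", length(agents)), agents)
  for (ag in agents) {
    gdate <- availability$first_generic_date[availability$agent == ag]
    if (!length(gdate))
      stop("configuration error: agent missing from availability calendar: ", ag)
    rows <- d[agent == ag]
    if (!nrow(rows)) next
    if (index_date < gdate) { out[ag] <- "not-evaluable"; next }
    st <- unique(rows$brand_status)
    out[ag] <- if (length(st) > 1) "mixed" else st
  }
  out
}

#' Classify index regimens for a whole cohort
#'
#' Applies [classify_index_regimen()], [classify_tac_formulation()] and
#' [classify_brand_status()] to each cohort member's dispensings in the
#' 30-day post-discharge window.
#'
#' @param cohort cohort table from [apply_eligibility()]
#' @param dispensings dispensing table of the analytical dataset
#' @param dictionary a [drug_dictionary()]
#' @param availability a [generic_availability()] calendar
#' @return data.table, one row per person, with classification fields and
#'   per-agent brand status columns `brand_TAC`, `brand_MMF`, `brand_CsA`
#' @export
classify_cohort <- function(cohort, dispensings,
                            dictionary = drug_dictionary(),
                            availability = generic_availability()) {
  disp <- as.data.table(dispensings)
  win <- merge(disp, cohort[, .(person_id, discharge)], by = "person_id")
  win <- win[dispensing_date >= discharge &
               dispensing_date < discharge + .study$landmark_days]
  ann <- .annotate_dispensings(win, dictionary)
  if (!all(cohort$person_id %in% ann$person_id))
    stop("classification error: no dictionary drug in the index window for ",
         sum(!cohort$person_id %in% ann$person_id), " person(s)")
  first_agent <- function(role_, agent, role, date) {
    k <- which(role == role_)
    if (!length(k)) NA_character_ else agent[k[which.min(date[k])]]
  }
  status_of <- function(st) {
    u <- unique(st)
    if (!length(u)) "n/a" else if (length(u) > 1) "mixed" else u
  }
  per <- ann[, {
    t_tac <- suppressWarnings(min(dispensing_date[agent == "TAC"]))
    t_csa <- suppressWarnings(min(dispensing_date[agent == "CsA"]))
    fr <- unique(formulation[agent == "TAC"])
    list(has_tac = any(agent == "TAC"), has_csa = any(agent == "CsA"),
         t_tac = t_tac, t_csa = t_csa,
         has_am = any(role == "antimet"), has_mt = any(role == "mTOR"),
         has_other = any(role == "other"),
         steroid = any(role == "steroid"),
         am_agent = first_agent("antimet", agent, role, dispensing_date),
         mt_agent = first_agent("mTOR", agent, role, dispensing_date),
         tac_formulation = if (!any(agent == "TAC")) "n/a"
           else if (length(fr) > 1) "mixed" else fr,
         st_TAC = status_of(brand_status[agent == "TAC"]),
         st_MMF = status_of(brand_status[agent == "MMF"]),
         st_CsA = status_of(brand_status[agent == "CsA"]))
  }, by = person_id]
  per[, backbone := fifelse(has_tac & (!has_csa | t_tac < t_csa |
                                         t_tac == t_csa), "TAC-based",
                    fifelse(has_csa, "CsA-based", "No-CNI"))]
  per[, companion := fifelse(has_am & has_mt, "other",
                     fifelse(has_am, "+antimet",
                     fifelse(has_mt, "+mTOR",
                     fifelse(backbone == "No-CNI" | has_other, "other",
                             "mono"))))]
  per[, antimet_agent := fifelse(has_am & companion %in% c("+antimet", "other"),
                                 am_agent, "none")]
  per[, mtor_agent := fifelse(is.na(mt_agent), "none", mt_agent)]
  per[, label := regimen_label(backbone, companion, steroid)]
  # brand status: evaluable only in the era where a generic existed
  for (ag in c("TAC", "MMF", "CsA")) {
    gdate <- availability$first_generic_date[availability$agent == ag]
    if (!length(gdate))
      stop("configuration error: agent missing from availability calendar: ", ag)
    col <- paste0("st_", ag)
    idx_date <- cohort$discharge[match(per$person_id, cohort$person_id)]
    per[, (paste0("brand_", ag)) :=
          fifelse(get(col) == "n/a", "n/a",
                  fifelse(idx_date < gdate, "not-evaluable", get(col)))]
  }
  out <- merge(cohort[, .(person_id, organ, region)], per, by = "person_id",
               sort = FALSE)
  out[, .(person_id, organ, region, backbone, companion, steroid,
          antimet_agent, mtor_agent, label, tac_formulation,
          brand_TAC, brand_MMF, brand_CsA)]
}

#' Compute adherence (PDC and MPR)
#'
#' Proportion of days covered and medication possession ratio over a period
#' anchored at the follow-up start. Supplies are package counts mapped to
#' days via the dictionary's days-per-package; overlapping supplies are
#' shifted forward (stockpiling), so PDC is permutation-invariant in the
#' dispensing order and never exceeds 1. MPR is total days supplied over the
#' period, reported raw and capped at 1.
#'
#' @param dispensings one person's dispensing rows
#' @param start period anchor date (follow-up start)
#' @param period_days period length in days (e.g. 180, 365, 730)
#' @param dictionary a [drug_dictionary()]
#' @param agents optional agent scope (default: all immunosuppressants in
#'   the dictionary)
#' @return list: `pdc`, `mpr`, `mpr_capped`, `period_days`, `n_dispensings`
#' @export
compute_adherence <- function(dispensings, start, period_days,
                              dictionary = drug_dictionary(), agents = NULL) {
  if (period_days <= 0) stop("adherence error: zero-length period")
  d <- .annotate_dispensings(dispensings, dictionary)
  if (!is.null(agents)) d <- d[agent %in% agents]
  end <- start + period_days
  d <- d[dispensing_date >= start & dispensing_date < end]
  if (!nrow(d))
    return(list(pdc = 0, mpr = 0, mpr_capped = 0, period_days = period_days,
                n_dispensings = 0L))
  d[, supply := n_packages * days_per_package]
  setorder(d, dispensing_date)
  covered <- 0; cur_end <- as.numeric(start)
  for (i in seq_len(nrow(d))) {
    s <- max(as.numeric(d$dispensing_date[i]), cur_end)
    e <- s + d$supply[i]
    covered <- covered + max(0, min(e, as.numeric(end)) - min(max(s, as.numeric(start)), as.numeric(end)))
    cur_end <- e
  }
  mpr <- sum(d$supply) / period_days
  list(pdc = covered / period_days, mpr = mpr, mpr_capped = min(mpr, 1),
       period_days = period_days, n_dispensings = nrow(d))
}

#' Detect treatment switches, add-ons and discontinuation
#'
#' Scans a person's dispensing stream from the follow-up start over a
#' horizon and emits dated events: `within-class switch` when a different
#' agent of an already-used class (CNI, antimet, mTOR) appears; `add-on`
#' when a class absent from the index regimen appears; `discontinuation`
#' when the immunosuppressant supply is exhausted for longer than the grace
#' period.
#'
#' @param dispensings one person's dispensing rows
#' @param classification output of [classify_index_regimen()]
#' @param start follow-up start date
#' @param horizon_days scan horizon from `start`
#' @param grace_days permissible supply gap before discontinuation
#' @param dictionary a [drug_dictionary()]
#' @return data.table of events (`type`, `date`, `detail`), possibly empty
#' @export
detect_switches <- function(dispensings, classification, start,
                            horizon_days = 730, grace_days = 60,
                            dictionary = drug_dictionary()) {
  d <- .annotate_dispensings(dispensings, dictionary)
  d <- d[role %in% c("CNI", "antimet", "mTOR", "other") &
           dispensing_date >= start &
           dispensing_date < start + horizon_days]
  setorder(d, dispensing_date)
  events <- list()
  current <- c(CNI = switch(classification$backbone, "TAC-based" = "TAC",
                            "CsA-based" = "CsA", NA_character_),
               antimet = if (classification$antimet_agent == "none")
                 NA_character_ else classification$antimet_agent,
               mTOR = if (classification$mtor_agent == "none")
                 NA_character_ else classification$mtor_agent)
  for (i in seq_len(nrow(d))) {
    cls <- d$role[i]; ag <- d$agent[i]
    if (!cls %in% names(current)) next
    cur <- current[[cls]]
    if (is.na(cur)) {
      events[[length(events) + 1L]] <- data.table(
        type = "add-on", date = d$dispensing_date[i],
        detail = paste0(cls, ":", ag))
      current[[cls]] <- ag
    } else if (ag != cur) {
      events[[length(events) + 1L]] <- data.table(
        type = "within-class switch", date = d$dispensing_date[i],
        detail = paste0(cls, ":", cur, "->", ag))
      current[[cls]] <- ag
    }
  }
  # discontinuation: gap in overall immunosuppressant coverage > grace
  if (nrow(d)) {
    d[, supply := n_packages * days_per_package]
    cur_end <- as.numeric(d$dispensing_date[1])
    disc <- NULL
    for (i in seq_len(nrow(d))) {
      t <- as.numeric(d$dispensing_date[i])
      if (t > cur_end + grace_days) { disc <- cur_end; break }
      cur_end <- max(cur_end, t) + d$supply[i]
    }
    if (is.null(disc) && cur_end + grace_days < as.numeric(start) + horizon_days)
      disc <- cur_end
    if (!is.null(disc))
      events[[length(events) + 1L]] <- data.table(
        type = "discontinuation", date = as_date(disc), detail = "supply-gap")
  } else {
    events[[length(events) + 1L]] <- data.table(
      type = "discontinuation", date = start, detail = "no-dispensing")
  }
  if (!length(events))
    return(data.table(type = character(0), date = as.Date(character(0)),
                      detail = character(0)))
  out <- rbindlist(events)
  setorder(out, date)
  out[]
}
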