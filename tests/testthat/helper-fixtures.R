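library(data.table)

# product row lookup from the shipped dictionary
aic_of <- function(agent, status = "brand", form = NULL) {
  dict <- as.data.frame(drug_dictionary())
  r <- dict[dict$agent == agent & dict$brand_status == status, ]
  if (!is.null(form)) r <- r[r$formulation == form, ]
  r[1, c("aic", "atc")]
}

# dispensing rows for an agent list, one per (agent, day)
disp_fixture <- function(agents, days = 0, origin = as.Date("2015-06-01"),
                         status = "brand", forms = NULL, n_packages = 1L) {
  if (length(days) == 1) days <- rep(days, length(agents))
  if (length(status) == 1) status <- rep(status, length(agents))
  rows <- rbindlist(lapply(seq_along(agents), function(i)
    aic_of(agents[i], status[i], if (is.null(forms)) NULL else forms[i])))
  data.table(person_id = "P1", dispensing_date = origin + days,
             atc = rows$atc, aic = rows$aic, n_packages = n_packages)
}

hosp_row <- function(person_id, admission, discharge, procs = "",
                     diags = "585", hospital = "H1", drg = "302") {
  p <- c(procs, rep("", 6L - length(procs)))
  d <- c(diags, rep("", 3L - length(diags)))
  data.table(person_id = person_id, admission_date = as.Date(admission),
             discharge_date = as.Date(discharge), hospital = hospital,
             drg = drg, diag1 = d[1], diag2 = d[2], diag3 = d[3],
             proc1 = p[1], proc2 = p[2], proc3 = p[3], proc4 = p[4],
             proc5 = p[5], proc6 = p[6])
}

l04_disp <- function(person_id, dates) {
  data.table(person_id = person_id, dispensing_date = as.Date(dates),
             atc = "L04AD02", aic = "036782014", n_packages = 1L)
}

mk_bundle <- function(hosp, disp = NULL, inhab = NULL, mort = NULL,
                      region = "RGA") {
  ids <- unique(c(hosp$person_id, if (!is.null(disp)) disp$person_id))
  if (is.null(inhab))
    inhab <- data.table(person_id = ids, sex = "M",
                        birth_date = as.Date("1970-01-01"),
                        registration_start = as.Date("2000-01-01"),
                        registration_end = as.Date(NA))
  if (is.null(disp))
    disp <- data.table(person_id = character(0),
                       dispensing_date = as.Date(character(0)),
                       atc = character(0), aic = character(0),
                       n_packages = integer(0))
  if (is.null(mort))
    mort <- data.table(person_id = character(0),
                       death_date = as.Date(character(0)),
                       cause_icd9 = character(0))
  structure(list(hospital_discharge = hosp, drug_dispensing = disp,
                 inhabitant = inhab, mortality = mort, emergency = NULL,
                 exemption = NULL, outpatient = NULL, region = region),
            class = "claims_bundle")
}

mk_dataset <- function(...) build_analytical_dataset(mk_bundle(...),
                                                     validate = FALSE)

binom_bounds <- function(n, p, conf = 0.99) {
  a <- (1 - conf) / 2
  stats::qbinom(c(a, 1 - a), n, p)
}

# independent day-grid PDC oracle: daily pill-taking simulation with
# stockpiling, equivalent in intent but not in mechanism to forward-shifting
pdc_grid <- function(dates, supply_days, start, period_days) {
  stock <- 0; covered <- 0
  for (day in seq_len(period_days) - 1L) {
    today <- start + day
    stock <- stock + sum(supply_days[dates == today])
    if (stock > 0) { covered <- covered + 1; stock <- stock - 1 }
  }
  covered / period_days
}
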