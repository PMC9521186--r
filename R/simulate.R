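# Synthetic regional claims and national transplant registry with known truth.

.organ_proc_codes <- c(kidney = "55.69", liver = "50.59", heart = "37.51",
                       lung = "33.50", pancreas = "52.80", intestine = "46.97")
.indication_codes <- c(kidney = "585", liver = "571.5", heart = "425.4",
                       lung = "515", pancreas = "250.40", intestine = "557.0")
.age_mean <- c(kidney = 52.1, liver = 52.7, heart = 43.7, lung = 44.7,
               pancreas = 45, intestine = 40)
.age_sd   <- c(kidney = 14.3, liver = 14.0, heart = 19.1, lung = 15.6,
               pancreas = 12, intestine = 15)
.stay_mean <- c(kidney = 17.3, liver = 24.7, heart = 44.1, lung = 35.9,
                pancreas = 20, intestine = 30)
.stay_sd   <- c(kidney = 10.3, liver = 20.1, heart = 31.9, lung = 21.9,
                pancreas = 10, intestine = 15)
.male_share <- c(kidney = 0.645, liver = 0.774, heart = 0.705, lung = 0.665,
                 pancreas = 0.6, intestine = 0.55)

.rdate <- function(n, from, to) {
  from <- as.Date(from); to <- as.Date(to)
  as_date(as.integer(from) + floor(runif(n) * (as.integer(to) - as.integer(from) + 1)))
}

.mix_organ <- function(organ) {
  # pancreas/intestine recipients (exclusion fodder) borrow the kidney mixture
  ifelse(organ %in% c("pancreas", "intestine"), "kidney", organ)
}

# sample a regimen cell (backbone, companion, steroid prob) per person
.sample_regimen_cells <- function(organs, mixture) {
  n <- length(organs)
  out <- data.table(backbone = character(n), companion = character(n),
                    p_ster = numeric(n))
  mo <- .mix_organ(organs)
  for (o in unique(mo)) {
    rows <- mixture[organ == o]
    idx <- which(mo == o)
    k <- sample.int(nrow(rows), length(idx), replace = TRUE, prob = rows$p)
    out[idx, `:=`(backbone = rows$backbone[k], companion = rows$companion[k],
                  p_ster = rows$n_steroid[k] / rows$n[k])]
  }
  out
}

# resolve agents dispensed for a (backbone, companion) cell
.cell_agents <- function(backbone, companion, organ) {
  ag <- character(0)
  if (backbone == "TAC-based") ag <- "TAC"
  if (backbone == "CsA-based") ag <- "CsA"
  antimet <- if (runif(1) < .agent_shares$mmf_of_antimet[[organ]]) "MMF" else "AZA"
  mtor <- if (runif(1) < .agent_shares$eve_of_mtor[[organ]]) "EVE" else "SIR"
  if (companion == "+antimet") ag <- c(ag, antimet)
  if (companion == "+mTOR") ag <- c(ag, mtor)
  if (companion == "other")
    ag <- if (backbone == "No-CNI") c(ag, "BELA") else c(ag, antimet, mtor)
  ag
}

#' Generate synthetic regional claims bundles with known ground truth
#'
#' Simulates one transplant recipient population and materializes, per
#' region, the seven administrative source tables the pipeline reads
#' (hospital discharge with ICD-9-CM procedure/diagnosis codes, ATC/AIC-coded
#' drug dispensings, inhabitant registry, mortality registry, emergency
#' visits, co-payment exemptions, outpatient tests). Outcome and death times
#' are exponential waiting times at the configured constant hazards, anchored
#' at the follow-up start (30 days post-discharge) so that unplanted persons
#' always satisfy the eligibility rules. Planted negatives violate exactly one
#' eligibility rule each, at the configured per-rule rates.
#'
#' @param config a [simulation_config()]
#' @return list with `bundles` (named list of `claims_bundle`, one per region)
#'   and `truth` (the truth manifest data.table, one row per recipient, with
#'   true organ, regimen cell, event dates, registry identifier and planted
#'   negative rule)
#' @export
generate_regional_claims <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_persons
  study <- .study

  organ <- sample(names(config$organ_mix), n, TRUE, prob = config$organ_mix)
  region <- sample(config$region_ids, n, TRUE)
  person_id <- sprintf("P%06d", seq_len(n))
  sex <- ifelse(runif(n) < .male_share[organ], "M", "F")
  age <- pmin(pmax(rnorm(n, .age_mean[organ], .age_sd[organ]), 1), 78)
  stay <- pmax(3L, as.integer(round(rnorm(n, .stay_mean[organ], .stay_sd[organ]))))
  discharge <- .rdate(n, study$enrol_start, study$enrol_end)
  hospital <- paste0(region, "-H", sample.int(3, n, TRUE))
  birth_date <- discharge - round(age * study$days_per_year)

  # planted eligibility-rule violations, at most one rule per person
  p <- config$planted_negatives
  planted <- sample(c(names(p), "none"), n, TRUE, prob = c(p, 1 - sum(p)))
  # rules needing room for a pre-study prior transplant constrain the index date
  i_pre <- which(planted == "first_pre_study")
  if (length(i_pre))
    discharge[i_pre] <- .rdate(length(i_pre), "2011-01-01", study$enrol_end)
  i_wash <- which(planted == "washout_2y")
  if (length(i_wash)) {
    discharge[i_wash] <- .rdate(length(i_wash), "2009-02-01", "2010-06-30")
    stay[i_wash] <- sample(5:15, length(i_wash), TRUE)
  }
  admission <- discharge - stay
  fu_start <- discharge + study$landmark_days

  # true regimen cell and dispensed (possibly noise-corrupted) cell
  cells <- .sample_regimen_cells(organ, config$regimen_mixture)
  steroid <- runif(n) < cells$p_ster
  truth_backbone <- cells$backbone; truth_companion <- cells$companion
  disp_backbone <- truth_backbone; disp_companion <- truth_companion
  disp_steroid <- steroid
  noisy <- which(runif(n) < config$label_noise_rate)
  for (i in noisy) {
    repeat {
      alt <- .sample_regimen_cells(organ[i], config$regimen_mixture)
      s <- runif(1) < alt$p_ster
      if (alt$backbone != truth_backbone[i] || alt$companion != truth_companion[i] ||
          s != steroid[i]) break
    }
    disp_backbone[i] <- alt$backbone; disp_companion[i] <- alt$companion
    disp_steroid[i] <- s
  }

  # event dates: exponential waiting times from follow-up start (days)
  hz <- config$outcome_hazards
  ev_date <- function(outcome) {
    rate <- hz[organ, outcome] / study$days_per_year
    t <- rexp(n, pmax(rate, 1e-12))
    t[rate <= 0] <- NA          # zero hazard: event never occurs
    fu_start + ceiling(t)
  }
  death_date <- ev_date("death")
  reject_date <- ev_date("reject"); infection_date <- ev_date("infection")
  diabetes_date <- ev_date("diabetes"); cancer_date <- ev_date("cancer")
  tr_rate <- config$transfer_hazard / study$days_per_year
  transfer_date <- if (tr_rate > 0) fu_start + ceiling(rexp(n, tr_rate)) else
    rep(as.Date(NA), n)
  i_ed <- which(planted == "early_death")
  death_date[i_ed] <- discharge[i_ed] + sample(5:25, length(i_ed), TRUE)
  i_dr <- which(planted == "deregistered")
  transfer_date[i_dr] <- discharge[i_dr] + sample(5:25, length(i_dr), TRUE)

  # drug products: per-person formulation and brand assignment, era-aware.
  # flat key lookup (agent:status:formulation) keeps the per-person loop cheap
  dict <- drug_dictionary()
  avail <- generic_availability()
  dkey <- paste(dict$agent, dict$brand_status,
                fifelse(nzchar(dict$formulation), dict$formulation, "-"),
                sep = ":")
  aic_by_key <- setNames(dict$aic, dkey)
  atc_by_key <- setNames(dict$atc, dkey)
  avail_date <- setNames(avail$first_generic_date, avail$agent)
  gshares <- list(TAC = .agent_shares$generic_of_tac,
                  MMF = .agent_shares$generic_of_mmf,
                  CsA = .agent_shares$generic_of_csa)
  tac_ir <- runif(n) < .agent_shares$ir_of_tac[.mix_organ(organ)]
  pick_key <- function(ag, i) {
    status <- "brand"
    gs <- gshares[[ag]]
    if (!is.null(gs) && !is.na(avail_date[ag]) && discharge[i] >= avail_date[ag] &&
        runif(1) < gs[[.mix_organ(organ[i])]]) status <- "generic"
    paste(ag, status, if (ag == "TAC") (if (tac_ir[i]) "IR" else "ER") else "-",
          sep = ":")
  }

  # dispensing streams: full index fill, then Bernoulli-thinned 30-day refills
  end_obs <- pmin(death_date, study$study_end,
                  fu_start + study$fu_cap_days + 90L, na.rm = TRUE)
  end_obs <- pmin(end_obs, transfer_date, na.rm = TRUE)
  steroid_agents <- c("PRED", "MPRED", "PREDNISOLONE")
  acc_pid <- vector("list", n); acc_date <- vector("list", n)
  acc_atc <- vector("list", n); acc_aic <- vector("list", n)
  for (i in seq_len(n)) {
    agent_i <- .cell_agents(disp_backbone[i], disp_companion[i], .mix_organ(organ[i]))
    if (disp_steroid[i]) agent_i <- c(agent_i, sample(steroid_agents, 1,
                                                      prob = c(0.8, 0.1, 0.1)))
    keys <- vapply(agent_i, pick_key, "", i = i)
    aics <- aic_by_key[keys]; atcs <- atc_by_key[keys]
    m <- length(keys)
    offset <- sample(0:6, 1)
    first_date <- discharge[i] + offset
    if (planted[i] == "no_index_dispensing") first_date <- discharge[i] + 40L
    nk <- max(0L, (as.integer(end_obs[i] - first_date) %/% 30L) + 1L)
    dates <- as_date(integer(0)); atc_v <- character(0); aic_v <- character(0)
    if (nk > 0L) {
      cyc <- first_date + 30L * (seq_len(nk) - 1L) + sample(0:2, nk, TRUE)
      keep <- c(rep(TRUE, m), runif(m * (nk - 1L)) < config$adherence)
      dd <- rep(cyc, each = m)[keep]
      atc_v <- rep(atcs, nk)[keep]; aic_v <- rep(aics, nk)[keep]
      dates <- dd
    }
    if (planted[i] == "prior_L04") {
      pk <- pick_key(if (disp_backbone[i] == "CsA-based") "CsA" else "TAC", i)
      dates <- c(dates, discharge[i] - 90L)
      atc_v <- c(atc_v, atc_by_key[[pk]]); aic_v <- c(aic_v, aic_by_key[[pk]])
    }
    if (length(dates)) {
      acc_pid[[i]] <- rep(person_id[i], length(dates))
      acc_date[[i]] <- as_date(unlist(dates))
      acc_atc[[i]] <- unname(atc_v); acc_aic[[i]] <- unname(aic_v)
    }
  }
  dispensing <- data.table(
    person_id = unlist(acc_pid),
    dispensing_date = as_date(unlist(acc_date)),
    atc = unlist(acc_atc), aic = unlist(acc_aic), n_packages = 1L)
  dispensing <- merge(dispensing, data.table(person_id = person_id, region = region),
                      by = "person_id", sort = FALSE)

  # comedication noise (pre-index, non-L04)
  i_com <- which(runif(n) < 0.4)
  comed <- if (length(i_com)) rbindlist(lapply(i_com, function(i) {
    m <- sample(1:3, 1)
    data.table(person_id = person_id[i],
               dispensing_date = discharge[i] - sample(40:700, m, TRUE),
               atc = sample(c("B01AA03", "B01AC06", "C10AA01"), m, TRUE),
               aic = "099999019", n_packages = 1L, region = region[i])
  })) else NULL
  dispensing <- rbindlist(list(dispensing, comed), use.names = TRUE)
  dispensing <- dispensing[dispensing_date <= study$study_end]

  # hospital discharge rows
  hosp_index <- data.table(
    person_id = person_id, admission_date = admission, discharge_date = discharge,
    hospital = hospital, drg = sprintf("%03d", sample.int(600, n, TRUE)),
    diag1 = .indication_codes[organ], diag2 = "", diag3 = "",
    proc1 = .organ_proc_codes[organ], proc2 = "", proc3 = "", proc4 = "",
    proc5 = "", proc6 = "", region = region)
  # a share of index rows carry the transplant code in a secondary slot
  i_sec <- which(runif(n) < 0.10 & planted != "multi_organ")
  for (i in i_sec) {
    pos <- sample(2:6, 1)
    set(hosp_index, i, paste0("proc", pos), hosp_index$proc1[i])
    set(hosp_index, i, "proc1", "38.93")
  }
  i_mo <- which(planted == "multi_organ")
  for (i in i_mo) {
    other <- sample(setdiff(names(.organ_proc_codes), organ[i]), 1)
    set(hosp_index, i, paste0("proc", sample(2:6, 1)), .organ_proc_codes[[other]])
  }

  # pre-study prior transplants: first_pre_study lies > 730 days before the
  # index (fires only the first-hospitalization rule); washout_2y lies within
  # 730 days but still pre-2009 (fires the washout rule when steps permute)
  prior_rows <- NULL
  i_prior <- c(i_pre, i_wash)
  if (length(i_prior)) {
    pd <- as.Date(rep(NA, length(i_prior)))
    if (length(i_pre)) {
      gap <- vapply(i_pre, function(i)
        sample(731:as.integer(discharge[i] - as.Date("2007-01-15")), 1), 1L)
      pd[seq_along(i_pre)] <- discharge[i_pre] - gap
    }
    if (length(i_wash)) {
      lo <- as.integer(discharge[i_wash] - 700L)
      hi <- as.integer(as.Date("2008-12-31"))
      pd[length(i_pre) + seq_along(i_wash)] <-
        as_date(lo + floor(runif(length(i_wash)) * (hi - lo + 1)))
    }
    prior_rows <- data.table(
      person_id = person_id[i_prior], admission_date = pd - 10L, discharge_date = pd,
      hospital = hospital[i_prior], drg = "302",
      diag1 = .indication_codes[organ[i_prior]], diag2 = "", diag3 = "",
      proc1 = .organ_proc_codes[organ[i_prior]], proc2 = "", proc3 = "",
      proc4 = "", proc5 = "", proc6 = "", region = region[i_prior])
  }

  # outcome hospitalizations (observable claims only)
  outc <- list(reject = reject_date, infection = infection_date,
               diabetes = diabetes_date, cancer = cancer_date)
  out_rows <- rbindlist(lapply(names(outc), function(o) {
    d <- outc[[o]]
    keep <- which(!is.na(d) & d <= study$study_end & d < death_date &
                    (is.na(transfer_date) | d < transfer_date))
    if (!length(keep)) return(NULL)
    data.table(person_id = person_id[keep], admission_date = d[keep],
               discharge_date = pmin(d[keep] + 3L, study$study_end),
               hospital = hospital[keep],
               drg = "316", diag1 = .outcome_gen_codes[[o]], diag2 = "", diag3 = "",
               proc1 = "", proc2 = "", proc3 = "", proc4 = "", proc5 = "",
               proc6 = "", region = region[keep])
  }))

  # baseline comorbidity noise (pre-index, non-transplant admissions)
  i_cm <- which(runif(n) < 0.3)
  cm_codes <- comorbidity_code_list()
  cm_rows <- if (length(i_cm)) {
    adm <- discharge[i_cm] - sample(100:700, length(i_cm), TRUE)
    data.table(
      person_id = person_id[i_cm], admission_date = adm,
      discharge_date = adm + 4L, hospital = hospital[i_cm], drg = "127",
      diag1 = paste0(sample(cm_codes$icd9_prefix, length(i_cm), TRUE), ".0"),
      diag2 = "", diag3 = "", proc1 = "", proc2 = "", proc3 = "", proc4 = "",
      proc5 = "", proc6 = "", region = region[i_cm])
  } else NULL
  hosp <- rbindlist(list(hosp_index, prior_rows, out_rows, cm_rows),
                    use.names = TRUE)

  inhabitant <- data.table(
    person_id = person_id, sex = sex, birth_date = birth_date,
    registration_start = pmin(birth_date, admission - 1100L),
    registration_end = fifelse(!is.na(transfer_date) &
                                 transfer_date <= study$study_end,
                               transfer_date, as.Date(NA)),
    region = region)

  mortality <- data.table(person_id = person_id, death_date = death_date,
                          cause_icd9 = "427.5", region = region)
  mortality <- mortality[death_date <= study$study_end &
                           (is.na(transfer_date) | death_date < transfer_date)]

  i_er <- which(runif(n) < 0.1)
  emergency <- data.table(person_id = person_id[i_er],
                          admission_date = discharge[i_er] + sample(40:300, length(i_er), TRUE),
                          discharge_date = NA, reason = "R69",
                          region = region[i_er])
  emergency[, discharge_date := admission_date]
  emergency <- emergency[admission_date <= study$study_end]
  i_ex <- which(runif(n) < 0.2)
  exemption <- data.table(person_id = person_id[i_ex], exemption_code = "052",
                          start_date = discharge[i_ex] - 400L, region = region[i_ex])
  i_ot <- which(runif(n) < 0.3)
  outpatient <- data.table(person_id = person_id[i_ot],
                           test_date = discharge[i_ot] + sample(30:400, length(i_ot), TRUE),
                           test_code = "90.27.1", lab = "LAB01",
                           region = region[i_ot])
  outpatient <- outpatient[test_date <= study$study_end]

  truth <- data.table(
    person_id = person_id, region = region,
    pid = paste0(region, "::", person_id),
    sit_id = sprintf("SIT%06d", seq_len(n)),
    organ = organ, sex = sex, birth_date = birth_date,
    admission = admission, discharge = discharge, hospital = hospital,
    backbone = truth_backbone, companion = truth_companion, steroid = steroid,
    label = regimen_label(truth_backbone, truth_companion, steroid),
    dispensed_label = regimen_label(disp_backbone, disp_companion, disp_steroid),
    death_date = death_date, reject_date = reject_date,
    infection_date = infection_date, diabetes_date = diabetes_date,
    cancer_date = cancer_date, transfer_date = transfer_date,
    planted_negative = ifelse(planted == "none", NA_character_, planted))

  tabs <- list(hospital_discharge = hosp, drug_dispensing = dispensing,
               inhabitant = inhabitant, mortality = mortality,
               emergency = emergency, exemption = exemption,
               outpatient = outpatient)
  bundles <- lapply(setNames(config$region_ids, config$region_ids), function(r) {
    b <- lapply(tabs, function(dt) dt[region == r, !"region"])
    structure(c(b, list(region = r)), class = "claims_bundle")
  })
  list(bundles = bundles, truth = truth)
}

#' Generate the synthetic national transplant registry
#'
#' One registry row per recipient in the truth manifest, carrying the five
#' pseudonymous quasi-identifiers used for linkage (sex, organ, year+month of
#' birth, year+month of transplant, transplant hospital), donor attributes and
#' the physician-reported maintenance therapy. With probability
#' `key_perturbation_rate` exactly one quasi-identifier field is corrupted
#' (recorded in the synthetic-diagnostic column `perturbed_field`); with
#' probability `sit_disagreement_rate` the reported therapy differs from the
#' claims truth label.
#'
#' @param truth truth manifest from [generate_regional_claims()]
#' @param config the same [simulation_config()]
#' @return data.table registry, one row per recipient
#' @export
generate_sit_registry <- function(truth, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!nrow(truth)) stop("truth manifest is empty")
  rate <- config$key_perturbation_rate
  if (rate < 0 || rate > 1) stop("configuration error: perturbation rate in [0,1]")
  set.seed(child_seed(config$seed, "sit-registry"))
  ym <- function(d) format(d, "%Y-%m")
  reg <- data.table(
    sit_id = truth$sit_id, sex = truth$sex, organ = truth$organ,
    birth_ym = ym(truth$birth_date), tx_ym = ym(truth$admission),
    hospital = truth$hospital,
    donor_age = pmin(pmax(round(rnorm(nrow(truth), 52, 17)), 1), 85),
    donor_sex = ifelse(runif(nrow(truth)) < 0.5, "M", "F"),
    reported_therapy = truth$label,
    perturbed_field = NA_character_)
  # physician-reported therapy disagreement
  labs <- unique(regimen_label(
    rep(c("TAC-based", "CsA-based", "No-CNI"), each = 8),
    rep(rep(c("mono", "+antimet", "+mTOR", "other"), each = 2), 3),
    rep(c(TRUE, FALSE), 12)))
  i_dis <- which(runif(nrow(reg)) < config$sit_disagreement_rate)
  for (i in i_dis)
    reg$reported_therapy[i] <- sample(setdiff(labs, truth$label[i]), 1)
  # single-field quasi-identifier corruption
  shift_ym <- function(s, k) {
    y <- as.integer(substr(s, 1, 4)); m <- as.integer(substr(s, 6, 7)) + k
    y <- y + (m - 1) %/% 12; m <- (m - 1) %% 12 + 1
    sprintf("%04d-%02d", y, m)
  }
  i_pert <- which(runif(nrow(reg)) < rate)
  fields <- c("sex", "organ", "birth_ym", "tx_ym", "hospital")
  for (i in i_pert) {
    f <- sample(fields, 1)
    reg$perturbed_field[i] <- f
    if (f == "sex") reg$sex[i] <- if (reg$sex[i] == "M") "F" else "M"
    if (f == "organ")
      reg$organ[i] <- sample(setdiff(names(.organ_proc_codes), reg$organ[i]), 1)
    if (f == "birth_ym") reg$birth_ym[i] <- shift_ym(reg$birth_ym[i], sample(c(-1, 1), 1))
    if (f == "tx_ym") reg$tx_ym[i] <- shift_ym(reg$tx_ym[i], sample(c(-1, 1), 1))
    if (f == "hospital") reg$hospital[i] <- paste0(reg$hospital[i], "X")
  }
  reg[]
}

#' Write a claims bundle (and optional manifest) to CSV files
#'
#' One CSV per source table, named `<table>.csv`, under `dir`.
#'
#' @param bundle a `claims_bundle`
#' @param dir output directory (created if needed)
#' @return invisibly, the directory
#' @export
write_claims_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tb in setdiff(names(bundle), "region"))
    fwrite(bundle[[tb]], file.path(dir, paste0(tb, ".csv")))
  invisible(dir)
}

#' Read a claims bundle from a directory of CSV files
#'
#' @param dir directory written by [write_claims_bundle()]
#' @param region region label to attach
#' @return a `claims_bundle`
#' @export
read_claims_bundle <- function(dir, region) {
  tbs <- c("hospital_discharge", "drug_dispensing", "inhabitant", "mortality",
           "emergency", "exemption", "outpatient")
  b <- lapply(setNames(tbs, tbs), function(tb) {
    f <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(f)) return(NULL)
    # read everything as character so code fields keep leading zeros,
    # then restore dates and quantities
    dt <- fread(f, colClasses = "character")
    for (col in grep("date$|^admission|^discharge|^registration",
                     names(dt), value = TRUE))
      set(dt, j = col, value = as.Date(fifelse(nzchar(dt[[col]]),
                                               dt[[col]], NA_character_)))
    if ("n_packages" %in% names(dt))
      set(dt, j = "n_packages", value = as.integer(dt$n_packages))
    dt
  })
  structure(c(b, list(region = region)), class = "claims_bundle")
}

#' Write the truth manifest as JSON
#'
#' @param truth truth manifest data.table
#' @param path output path
#' @export
write_truth_manifest <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, na = "null",
                       Date = "ISO8601")
  invisible(path)
}
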