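# Code systems and dictionaries shared by the generator and the pipeline.

#' Organ transplant procedure code map
#'
#' ICD-9-CM procedure codes identifying solid organ transplants: kidney 55.6
#' (excluding 55.61, auto-transplant), liver 50.5, heart 37.5, lung 33.5,
#' pancreas 52.8 and intestine 46.97. Matching is prefix-based on the dotted
#' code, with the kidney exclusion applied explicitly.
#'
#' @return data.table with columns `organ`, `prefix`, `exclude` (comma-free
#'   exact codes that must not match)
#' @export
organ_code_map <- function() {
  data.table(
    organ   = c("kidney", "liver", "heart", "lung", "pancreas", "intestine"),
    prefix  = c("55.6", "50.5", "37.5", "33.5", "52.8", "46.97"),
    exclude = c("55.61", "", "", "", "", "")
  )
}

#' Map ICD-9-CM procedure codes to transplant organs
#'
#' @param codes character vector of dotted ICD-9-CM procedure codes
#' @return character vector of organ names, `NA` for non-transplant codes
#' @export
organ_from_procedure <- function(codes) {
  map <- organ_code_map()
  out <- rep(NA_character_, length(codes))
  for (i in seq_len(nrow(map))) {
    hit <- startsWith(codes, map$prefix[i])
    if (nzchar(map$exclude[i])) hit <- hit & !startsWith(codes, map$exclude[i])
    out[hit & is.na(out)] <- map$organ[i]
  }
  out
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "txclaims")
  if (!nzchar(path)) path <- file.path("inst", "extdata", file)  # pre-install
  path
}

#' Immunosuppressant drug dictionary
#'
#' Product-level dictionary mapping AIC market-authorization codes to ATC
#' code, agent, pharmacological role (CNI / antimet / mTOR / steroid / other),
#' brand-vs-generic status, tacrolimus formulation (IR immediate release, ER
#' extended release) and a days-per-package supply convention. Dispensation
#' records carry package counts, not days supplied; the supply convention is
#' isolated here so it stays auditable.
#'
#' @param path optional path to a dictionary CSV with the same columns
#' @return data.table, one row per product
#' @export
drug_dictionary <- function(path = NULL) {
  dd <- fread(path %||% .extdata("drug_dictionary.csv"),
              colClasses = list(character = c("aic", "atc", "agent", "role",
                                              "brand_status", "formulation")))
  stopifnot(!anyDuplicated(dd$aic))
  roles <- split(dd$agent, dd$role)
  # role sets must be disjoint at the agent level
  stopifnot(!anyDuplicated(unlist(lapply(roles, unique))))
  dd
}

#' Generic availability calendar
#'
#' First date on which a generic version of each agent was on the market.
#' Brand-vs-generic comparisons are restricted to persons whose index date
#' falls after this date for the agent in question.
#'
#' @param path optional path to a calendar CSV (`agent`, `first_generic_date`)
#' @return data.table
#' @export
generic_availability <- function(path = NULL) {
  av <- fread(path %||% .extdata("generic_availability.csv"))
  av[, first_generic_date := as.Date(first_generic_date)]
  av[]
}

#' Outcome ascertainment code lists
#'
#' ICD-9-CM diagnosis prefixes used to detect study outcomes (rejection/graft
#' failure, severe infection, incident diabetes, cancer) in hospital
#' discharge diagnoses.
#'
#' @return data.table (`outcome`, `icd9_prefix`)
#' @export
outcome_code_list <- function() {
  fread(.extdata("outcome_codes.csv"),
        colClasses = list(character = "icd9_prefix"))
}

comorbidity_code_list <- function() {
  fread(.extdata("comorbidity_codes.csv"),
        colClasses = list(character = "icd9_prefix"))
}

comedication_code_list <- function() {
  fread(.extdata("comedication_codes.csv"))
}

charlson_code_list <- function() {
  fread(.extdata("charlson_codes.csv"),
        colClasses = list(character = "icd9_prefix"))
}

# diagnosis code the generator writes for each outcome event
.outcome_gen_codes <- c(reject = "996.81", infection = "038.9",
                        diabetes = "250.00", cancer = "199.1")

#' Index regimen taxonomy and reference mixture
#'
#' The regimen cells used throughout: backbone (TAC-based, CsA-based, No-CNI)
#' by companion (mono, +antimet, +mTOR, other), with per-cell steroid co-use.
#' The shipped reference mixture reflects the observed post-discharge index
#' therapy distribution by organ in a multi-region Italian transplant cohort;
#' it is the generator default.
#'
#' @return data.table (`organ`, `backbone`, `companion`, `n`, `n_steroid`)
#' @export
regimen_reference_mixture <- function() {
  k <- function(b, c, n, s) list(b, c, n, s)
  build <- function(organ, rows) {
    dt <- rbindlist(lapply(rows, function(r)
      data.table(backbone = r[[1]], companion = r[[2]], n = r[[3]], n_steroid = r[[4]])))
    dt[, organ := organ]
    dt
  }
  kidney <- build("kidney", list(
    k("TAC-based", "mono", 261, 210), k("TAC-based", "+antimet", 1980, 1682),
    k("TAC-based", "+mTOR", 559, 398), k("TAC-based", "other", 35, 25),
    k("CsA-based", "mono", 85, 74), k("CsA-based", "+antimet", 617, 416),
    k("CsA-based", "+mTOR", 79, 69), k("CsA-based", "other", 6, 5),
    k("No-CNI", "+antimet", 78, 60), k("No-CNI", "+mTOR", 30, 27),
    k("No-CNI", "other", 299, 294)))
  liver <- build("liver", list(
    k("TAC-based", "mono", 927, 786), k("TAC-based", "+antimet", 690, 579),
    k("TAC-based", "+mTOR", 211, 129), k("TAC-based", "other", 39, 27),
    k("CsA-based", "mono", 225, 162), k("CsA-based", "+antimet", 39, 34),
    k("CsA-based", "+mTOR", 7, 2),
    k("No-CNI", "+antimet", 16, 12), k("No-CNI", "+mTOR", 16, 11),
    k("No-CNI", "other", 49, 46)))
  heart <- build("heart", list(
    k("TAC-based", "mono", 21, 19), k("TAC-based", "+antimet", 45, 40),
    k("CsA-based", "mono", 84, 64), k("CsA-based", "+antimet", 231, 181),
    k("CsA-based", "+mTOR", 14, 10), k("CsA-based", "other", 4, 3),
    k("No-CNI", "+antimet", 17, 9), k("No-CNI", "+mTOR", 2, 1),
    k("No-CNI", "other", 16, 16)))
  lung <- build("lung", list(
    k("TAC-based", "mono", 42, 36), k("TAC-based", "+antimet", 81, 78),
    k("CsA-based", "mono", 13, 12), k("CsA-based", "+antimet", 63, 59),
    k("No-CNI", "+antimet", 10, 6), k("No-CNI", "other", 6, 6)))
  out <- rbindlist(list(kidney, liver, heart, lung))
  setcolorder(out, c("organ", "backbone", "companion", "n", "n_steroid"))
  out[]
}

# per-organ agent splits used by the generator (shares among users of the class)
.agent_shares <- list(
  mmf_of_antimet = c(kidney = 0.920, liver = 0.999, heart = 0.785, lung = 0.274,
                     pancreas = 0.920, intestine = 0.920),
  ir_of_tac      = c(kidney = 0.507, liver = 0.688, heart = 0.500, lung = 0.500,
                     pancreas = 0.507, intestine = 0.507),
  eve_of_mtor    = c(kidney = 0.700, liver = 0.700, heart = 0.700, lung = 0.700,
                     pancreas = 0.700, intestine = 0.700),
  generic_of_tac = c(kidney = 0.250, liver = 0.314, heart = 0.197, lung = 0.250,
                     pancreas = 0.250, intestine = 0.250),
  generic_of_mmf = c(kidney = 0.450, liver = 0.450, heart = 0.450, lung = 0.667,
                     pancreas = 0.450, intestine = 0.450),
  generic_of_csa = c(kidney = 0.300, liver = 0.300, heart = 0.300, lung = 0.300,
                     pancreas = 0.300, intestine = 0.300)
)

#' Canonical regimen label
#'
#' Joint label used for truth bookkeeping and claims-vs-registry concordance:
#' `backbone/companion/steroid-flag`.
#'
#' @param backbone,companion character vectors
#' @param steroid logical vector
#' @return character vector
#' @export
regimen_label <- function(backbone, companion, steroid) {
  paste0(backbone, "/", companion, ifelse(steroid, "/+ster", "/-ster"))
}
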