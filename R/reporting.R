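# Descriptive outputs: regimen share tables, figure-style agent splits,
# claims-vs-registry concordance, median odds ratio, baseline table.

#' Regimen share table (index therapy by organ)
#'
#' Backbone-by-companion cell counts per organ with column percentages (one
#' decimal, half-up) and steroid co-use counts; backbone subtotal rows
#' included. Within each organ the cell counts partition the cohort.
#'
#' @param classifications output of [classify_cohort()]
#' @return data.table: `organ`, `backbone`, `companion` (`"(all)"` for the
#'   backbone subtotal), `n`, `pct`, `n_steroid`
#' @export
regimen_share_table <- function(classifications) {
  cl <- as.data.table(classifications)
  cells <- cl[, .(n = .N, n_steroid = sum(steroid)),
              by = .(organ, backbone, companion)]
  subtot <- cl[, .(companion = "(all)", n = .N, n_steroid = sum(steroid)),
               by = .(organ, backbone)]
  out <- rbind(cells, subtot, use.names = TRUE)
  tot <- cl[, .(organ_n = .N), by = organ]
  out <- merge(out, tot, by = "organ")
  out[, pct := pct(n, organ_n)]
  ord <- c("TAC-based", "CsA-based", "No-CNI")
  cord <- c("(all)", "mono", "+antimet", "+mTOR", "other")
  out[, `:=`(backbone = factor(backbone, ord),
             companion = factor(companion, cord))]
  setorder(out, organ, backbone, companion)
  out[, `:=`(backbone = as.character(backbone),
             companion = as.character(companion))]
  out[, organ_n := NULL]
  out[]
}

#' Figure-style agent split shares
#'
#' Per organ: mycophenolate vs azathioprine share among antimetabolite
#' users; immediate- vs extended-release share among tacrolimus users; and
#' brand vs generic share per agent among persons enrolled in the era where
#' both versions were available (`mixed` categories are disclosed alongside,
#' not forced into the binary split).
#'
#' @param classifications output of [classify_cohort()]
#' @return data.table: `organ`, `measure`, `level`, `n`, `denom`, `pct`
#' @export
agent_split_shares <- function(classifications) {
  cl <- as.data.table(classifications)
  out <- list()
  add <- function(dt, measure) {
    if (!is.null(dt) && nrow(dt)) {
      dt[, measure := measure]
      out[[length(out) + 1L]] <<- dt
    }
  }
  am <- cl[antimet_agent %in% c("MMF", "AZA")]
  if (nrow(am))
    add(am[, .N, by = .(organ, level = antimet_agent)][
      , `:=`(denom = sum(N)), by = organ], "antimet-agent")
  tac <- cl[tac_formulation %in% c("IR", "ER", "mixed")]
  if (nrow(tac))
    add(tac[, .N, by = .(organ, level = tac_formulation)][
      , `:=`(denom = sum(N)), by = organ], "tac-formulation")
  for (ag in c("TAC", "MMF", "CsA")) {
    col <- paste0("brand_", ag)
    b <- cl[get(col) %in% c("brand", "generic", "mixed")]
    if (nrow(b))
      add(b[, .N, by = .(organ, level = get(col))][
        , `:=`(denom = sum(N)), by = organ], paste0("brand-", ag))
  }
  res <- rbindlist(out, use.names = TRUE)
  setnames(res, "N", "n")
  res[, pct := pct(n, denom)]
  setcolorder(res, c("organ", "measure", "level", "n", "denom", "pct"))
  setorder(res, organ, measure, level)
  res[]
}

#' Claims-vs-registry regimen concordance
#'
#' Agreement between the physician-reported maintenance therapy in the
#' transplant registry and the claims-derived index regimen, on the joint
#' backbone/companion/steroid label, computed on linked persons only:
#' overall proportion agreement, per-label agreement, and Cohen's kappa as
#' the chance-corrected coefficient. A degenerate contingency (fewer than
#' two categories on a margin) is flagged and reported as kappa 1 when the
#' sides agree everywhere.
#'
#' @param pairs data.table with columns `claims` and `registry` (one row per
#'   linked person)
#' @return list: `n`, `agreement`, `kappa`, `per_cell` (data.table),
#'   `degenerate`
#' @export
concordance <- function(pairs) {
  p <- as.data.table(pairs)
  if (!nrow(p)) stop("concordance error: zero linked pairs")
  po <- mean(p$claims == p$registry)
  labs <- union(p$claims, p$registry)
  rowm <- table(factor(p$claims, labs)) / nrow(p)
  colm <- table(factor(p$registry, labs)) / nrow(p)
  pe <- sum(rowm * colm)
  degenerate <- length(unique(p$claims)) < 2 || length(unique(p$registry)) < 2
  kappa <- if (abs(1 - pe) < 1e-12) {
    if (po >= 1 - 1e-12) 1 else 0
  } else (po - pe) / (1 - pe)
  per_cell <- p[, .(n = .N, agreement = mean(claims == registry)), by = claims]
  setorder(per_cell, -n)
  list(n = nrow(p), agreement = po, kappa = kappa, per_cell = per_cell,
       degenerate = degenerate)
}

#' Median odds ratio from a cluster-level variance
#'
#' Summarizes between-hospital heterogeneity in treatment choice from the
#' cluster (hospital) variance of a mixed-effects logistic model:
#' MOR = exp(sqrt(2 sigma^2) * z_0.75), where z_0.75 is the 75th-percentile
#' standard-normal quantile (0.6745). The variance is supplied by the
#' caller; MOR is 1 at zero variance and strictly increasing in it.
#'
#' @param cluster_variance random-intercept variance, >= 0
#' @return the median odds ratio (numeric scalar)
#' @examples
#' median_odds_ratio(0)  # 1
#' @export
median_odds_ratio <- function(cluster_variance) {
  if (any(cluster_variance < 0))
    stop("median odds ratio error: negative variance")
  exp(sqrt(2 * cluster_variance) * qnorm(0.75))
}

.age_band <- function(age) {
  cut(age, c(-Inf, 17, 64, Inf), labels = c("<18", "18-64", "65+"))
}

#' Baseline characteristics table
#'
#' Recipient demographics (sex, age bands and mean at index, transplant stay
#' length), code-list comorbidity flags and a simple Charlson band
#' (distinct shipped Charlson categories: 0-1, 2, 3+) from a 2-year
#' pre-admission lookback in discharge diagnoses, comedication flags from
#' dispensings in the same window, and — when registry and linkage are
#' supplied — donor sex and age bands for linked persons. The shipped
#' Charlson code list is editable and makes no claim of equivalence to any
#' validated mapping.
#'
#' @param cohort cohort table from [apply_eligibility()]
#' @param dataset the pooled `analytical_dataset`
#' @param registry optional registry table with donor fields
#' @param linkage optional `linkage_result` for the cohort
#' @return long data.table: `organ`, `variable`, `level`, `n`, `pct`,
#'   `mean` (NA except for summary rows)
#' @export
baseline_table <- function(cohort, dataset, registry = NULL, linkage = NULL) {
  co <- as.data.table(cohort)
  co[, age := as.numeric(discharge - birth_date) / .study$days_per_year]
  co[, stay := as.numeric(discharge - admission)]
  rows <- list()
  addn <- function(dt, variable) {
    dt <- merge(dt, co[, .(tot = .N), by = organ], by = "organ")
    dt[, `:=`(pct = pct(n, tot), variable = variable, mean = NA_real_)]
    dt[, tot := NULL]
    rows[[length(rows) + 1L]] <<- dt
  }
  addm <- function(dt, variable) {
    dt[, `:=`(variable = variable, level = "mean", n = NA_integer_,
              pct = NA_real_)]
    rows[[length(rows) + 1L]] <<- dt
  }
  addn(co[, .(n = .N), by = .(organ, level = sex)], "sex")
  addn(co[, .(n = .N), by = .(organ, level = as.character(.age_band(age)))],
       "age_band")
  addm(co[, .(mean = mean(age)), by = organ], "age_years")
  addm(co[, .(mean = mean(stay)), by = organ], "stay_days")

  # 2-year pre-admission lookback windows
  dg <- merge(dataset$diagnoses,
              co[, .(person_id, admission, discharge)], by = "person_id")
  dg <- dg[date >= discharge - .study$washout_days & date < admission]
  cm <- comorbidity_code_list()
  for (cond in unique(cm$condition)) {
    pref <- cm[condition == cond, icd9_prefix]
    hit <- unique(dg[Reduce(`|`, lapply(pref, function(p) startsWith(code, p))),
                     person_id])
    addn(co[, .(n = sum(person_id %in% hit)), by = organ][
      , level := "yes"], paste0("comorbidity_", cond))
  }
  ch <- charlson_code_list()
  dgc <- copy(dg)
  dgc[, charlson := NA_character_]
  for (i in seq_len(nrow(ch)))
    dgc[startsWith(code, ch$icd9_prefix[i]), charlson := ch$category[i]]
  cnt <- dgc[!is.na(charlson), .(k = uniqueN(charlson)), by = person_id]
  co[, charlson_n := cnt[match(co$person_id, person_id), k]]
  co[is.na(charlson_n), charlson_n := 0L]
  co[, charlson_band := cut(charlson_n, c(-Inf, 1, 2, Inf),
                            labels = c("0-1", "2", "3+"))]
  addn(co[, .(n = .N), by = .(organ, level = as.character(charlson_band))],
       "charlson_band")

  dp <- merge(dataset$dispensings,
              co[, .(person_id, admission, discharge)], by = "person_id")
  dp <- dp[dispensing_date >= discharge - .study$washout_days &
             dispensing_date < admission]
  cmed <- comedication_code_list()
  for (cls in unique(cmed$class)) {
    pref <- cmed[class == cls, atc_prefix]
    hit <- unique(dp[Reduce(`|`, lapply(pref, function(p) startsWith(atc, p))),
                     person_id])
    addn(co[, .(n = sum(person_id %in% hit)), by = organ][
      , level := "yes"], paste0("comedication_", cls))
  }

  if (!is.null(registry) && !is.null(linkage)) {
    m <- merge(linkage$matched,
               co[, .(cohort_id = person_id, organ)], by = "cohort_id")
    m <- merge(m, as.data.table(registry)[, .(registry_id = sit_id, donor_sex,
                                              donor_age)], by = "registry_id")
    dn <- m[, .(n = .N), by = .(organ, level = donor_sex)]
    dn <- merge(dn, m[, .(tot = .N), by = organ], by = "organ")
    dn[, `:=`(pct = pct(n, tot), variable = "donor_sex", mean = NA_real_)]
    dn[, tot := NULL]
    rows[[length(rows) + 1L]] <- dn
    dm <- m[, .(mean = mean(donor_age)), by = organ]
    dm[, `:=`(variable = "donor_age_years", level = "mean", n = NA_integer_,
              pct = NA_real_)]
    rows[[length(rows) + 1L]] <- dm
  }
  out <- rbindlist(rows, use.names = TRUE, fill = TRUE)
  setcolorder(out, c("organ", "variable", "level", "n", "pct", "mean"))
  setorder(out, organ, variable, level)
  out[]
}
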