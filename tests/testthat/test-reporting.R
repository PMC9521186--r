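mk_class <- function(n, organ = "kidney", backbone = "TAC-based",
                     companion = "+antimet", steroid = TRUE,
                     antimet_agent = "MMF", tac_formulation = "IR",
                     brand_TAC = "brand", brand_MMF = "brand",
                     brand_CsA = "n/a") {
  data.table(person_id = sprintf("%s%03d", organ, seq_len(n)), organ = organ,
             region = "RGA", backbone = backbone, companion = companion,
             steroid = steroid, antimet_agent = antimet_agent,
             mtor_agent = "none",
             label = regimen_label(backbone, companion, steroid),
             tac_formulation = tac_formulation, brand_TAC = brand_TAC,
             brand_MMF = brand_MMF, brand_CsA = brand_CsA)
}

test_that("regimen share tables partition the cohort and print table shares", {
  cl <- rbind(mk_class(60), mk_class(25, companion = "mono",
                                     antimet_agent = "none"),
              mk_class(15, backbone = "CsA-based", tac_formulation = "n/a",
                       brand_TAC = "n/a", brand_CsA = "brand"))
  tab <- regimen_share_table(cl)
  cells <- tab[tab$companion != "(all)"]
  expect_equal(sum(cells$n), 100L)
  expect_equal(sum(cells$pct), 100.0, tolerance = 0.11)
  expect_equal(tab[backbone == "TAC-based" & companion == "(all)", n], 85L)

  one <- regimen_share_table(mk_class(1))
  expect_true(all(one$pct == 100.0))

  # the printed worked shares are plain ratio arithmetic
  expect_equal(pct(1682, 2835), 59.3)  # kidney TAC+antimet+steroid of TAC
  expect_equal(pct(786, 1867), 42.1)   # liver TAC mono+steroid of TAC
  expect_equal(pct(181, 333), 54.4)    # heart CsA+antimet+steroid of CsA
  expect_equal(pct(78, 123), 63.4)     # lung TAC+antimet+steroid of TAC

  # synthetic cohort from a known mixture lands within binomial bounds
  cfg <- simulation_config(n_persons = 800, seed = 50, planted_negatives = 0,
                           organ_mix = c(kidney = 1))
  g <- generate_regional_claims(cfg)
  ds <- pool_regions(lapply(g$bundles, build_analytical_dataset))
  co <- apply_eligibility(find_index_episodes(ds), ds)$cohort
  cl2 <- classify_cohort(co, ds$dispensings)
  mix <- regimen_reference_mixture()[organ == "kidney"]
  p_tac <- mix[backbone == "TAC-based", sum(n)] / mix[, sum(n)]
  b <- binom_bounds(nrow(cl2), p_tac)
  n_tac <- sum(cl2$backbone == "TAC-based")
  expect_gte(n_tac, b[1]); expect_lte(n_tac, b[2])
})

test_that("agent split shares use the figure denominators", {
  cl <- rbind(mk_class(70), mk_class(30, antimet_agent = "AZA"),
              mk_class(10, companion = "mono", antimet_agent = "none"))
  sh <- agent_split_shares(cl)
  mmf <- sh[measure == "antimet-agent" & level == "MMF"]
  expect_equal(mmf$n, 70L); expect_equal(mmf$denom, 100L)
  expect_equal(mmf$pct, 70.0)

  # all antimet users on MMF -> 100%
  sh2 <- agent_split_shares(mk_class(20))
  expect_equal(sh2[measure == "antimet-agent" & level == "MMF", pct], 100.0)

  # brand shares computed only among evaluable persons
  cl3 <- rbind(mk_class(6, brand_TAC = "generic"),
               mk_class(4, brand_TAC = "brand"),
               mk_class(5, brand_TAC = "not-evaluable"))
  sh3 <- agent_split_shares(cl3)
  gt <- sh3[measure == "brand-TAC" & level == "generic"]
  expect_equal(gt$denom, 10L)
  expect_equal(gt$pct, 60.0)
})

test_that("concordance returns agreement, per-cell breakdown and kappa", {
  same <- data.table(claims = rep(c("A", "B"), 10),
                     registry = rep(c("A", "B"), 10))
  cc <- concordance(same)
  expect_equal(cc$agreement, 1.0)
  expect_equal(cc$kappa, 1.0)
  expect_false(cc$degenerate)

  one_cell <- data.table(claims = rep("A", 5), registry = rep("A", 5))
  cd <- concordance(one_cell)
  expect_equal(cd$kappa, 1.0)
  expect_true(cd$degenerate)

  expect_error(concordance(same[0]), "zero linked pairs")

  # random contingency tables against the e1071 oracle
  skip_if_not_installed("e1071")
  set.seed(7)
  for (r in 1:20) {
    n <- 200
    p <- data.table(claims = sample(LETTERS[1:4], n, TRUE),
                    registry = sample(LETTERS[1:4], n, TRUE))
    got <- concordance(p)
    tab <- table(factor(p$claims, LETTERS[1:4]),
                 factor(p$registry, LETTERS[1:4]))
    expect_equal(got$kappa, e1071::classAgreement(tab)$kappa,
                 tolerance = 1e-12)
    expect_equal(got$agreement, e1071::classAgreement(tab)$diag,
                 tolerance = 1e-12)
  }
})

test_that("synthetic registry disagreement propagates into concordance", {
  cfg <- simulation_config(n_persons = 700, seed = 52, planted_negatives = 0,
                           key_perturbation_rate = 0,
                           sit_disagreement_rate = 0.2)
  g <- generate_regional_claims(cfg)
  reg <- generate_sit_registry(g$truth, cfg)
  ds <- pool_regions(lapply(g$bundles, build_analytical_dataset))
  co <- apply_eligibility(find_index_episodes(ds), ds)$cohort
  lk <- stepwise_link(cohort_linkage_frame(co), registry_linkage_frame(reg))
  cl <- classify_cohort(co, ds$dispensings)
  pairs <- merge(lk$matched, cl[, .(cohort_id = person_id, claims = label)],
                 by = "cohort_id")
  pairs <- merge(pairs, reg[, .(registry_id = sit_id,
                                registry = reported_therapy)],
                 by = "registry_id")
  cc <- concordance(pairs[, .(claims, registry)])
  b <- binom_bounds(cc$n, 0.8)
  expect_gte(cc$agreement * cc$n, b[1])
  expect_lte(cc$agreement * cc$n, b[2])
})

test_that("median odds ratio follows its closed form", {
  expect_equal(median_odds_ratio(0), 1.0)
  expect_equal(median_odds_ratio(1), exp(qnorm(0.75) * sqrt(2)),
               tolerance = 1e-12)
  v <- seq(0, 3, by = 0.25)
  expect_true(all(diff(median_odds_ratio(v)) > 0))
  expect_error(median_odds_ratio(-0.1), "negative variance")
})

test_that("baseline table computes bands, means and lookback flags", {
  co <- data.table(person_id = c("P1", "P2"), organ = "kidney",
                   region = "RGA",
                   admission = as.Date(c("2015-01-01", "2015-02-01")),
                   discharge = as.Date(c("2015-01-11", "2015-02-21")),
                   hospital = "H1", sex = c("M", "F"),
                   birth_date = as.Date(c("1965-01-11", "1965-02-21")))
  ds <- mk_dataset(rbind(
    hosp_row("P1", "2015-01-01", "2015-01-11", procs = "55.69"),
    hosp_row("P2", "2015-02-01", "2015-02-21", procs = "55.69"),
    hosp_row("P1", "2014-05-01", "2014-05-04", diags = "401.1")),
    rbind(l04_disp(c("P1", "P2"), "2015-01-15"),
          data.table(person_id = "P2", dispensing_date = as.Date("2014-06-01"),
                     atc = "C10AA01", aic = "099999019", n_packages = 1L)))
  bt <- baseline_table(co, ds)
  expect_equal(bt[variable == "age_band" & level == "18-64", n], 2L)
  expect_equal(bt[variable == "stay_days" & level == "mean", mean],
               mean(c(10, 20)))
  expect_equal(bt[variable == "comorbidity_hypertension", n], 1L)
  expect_equal(bt[variable == "comedication_statins", n], 1L)
  expect_equal(bt[variable == "sex" & level == "F", pct], 50.0)
})
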