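test_that("index regimen classification follows the rule table", {
  cl <- classify_index_regimen(disp_fixture(c("TAC", "MMF", "PRED")))
  expect_equal(cl$backbone, "TAC-based")
  expect_equal(cl$companion, "+antimet")
  expect_true(cl$steroid)
  expect_equal(cl$antimet_agent, "MMF")

  cl2 <- classify_index_regimen(disp_fixture("CsA"))
  expect_equal(cl2[c("backbone", "companion", "steroid")],
               list(backbone = "CsA-based", companion = "mono",
                    steroid = FALSE))

  cl3 <- classify_index_regimen(disp_fixture(c("EVE", "PRED")))
  expect_equal(cl3$backbone, "No-CNI")
  expect_equal(cl3$companion, "+mTOR")
  expect_true(cl3$steroid)

  # exhaustive presence patterns vs a hand-written oracle
  oracle <- function(tac, csa, am, mt) {
    backbone <- if (tac) "TAC-based" else if (csa) "CsA-based" else "No-CNI"
    companion <- if (am && mt) "other" else if (am) "+antimet"
      else if (mt) "+mTOR" else if (backbone == "No-CNI") "other" else "mono"
    list(backbone = backbone, companion = companion)
  }
  for (tac in c(TRUE, FALSE)) for (csa in c(TRUE, FALSE))
    for (am in c(TRUE, FALSE)) for (mt in c(TRUE, FALSE)) {
      agents <- c("TAC", "CsA", "MMF", "EVE")[c(tac, csa, am, mt)]
      if (!length(agents)) next
      got <- classify_index_regimen(disp_fixture(agents, days = 0))
      exp <- oracle(tac, csa, am, mt)  # same-day dual-CNI tie goes to TAC
      expect_equal(got$backbone, exp$backbone,
                   label = paste(agents, collapse = "+"))
      expect_equal(got$companion, exp$companion,
                   label = paste(agents, collapse = "+"))
    }

  # dual CNI: earliest dispensing decides; same-day tie goes to TAC
  d <- disp_fixture(c("CsA", "TAC", "MMF"), days = c(0, 5, 1))
  expect_equal(classify_index_regimen(d)$backbone, "CsA-based")
  d2 <- disp_fixture(c("CsA", "TAC"), days = c(5, 0))
  expect_equal(classify_index_regimen(d2)$backbone, "TAC-based")
  d3 <- disp_fixture(c("CsA", "TAC"), days = c(0, 0))
  expect_equal(classify_index_regimen(d3)$backbone, "TAC-based")
  expect_equal(classify_index_regimen(d3, tie_backbone = "CsA-based")$backbone,
               "CsA-based")

  expect_error(classify_index_regimen(disp_fixture("TAC")[0]),
               "classification error")
})

test_that("tacrolimus formulation and brand status are product-level calls", {
  er <- disp_fixture(c("TAC", "TAC"), days = c(0, 10), forms = c("ER", "ER"))
  expect_equal(classify_tac_formulation(er), "ER")
  mixed <- disp_fixture(c("TAC", "TAC"), days = c(0, 10),
                        forms = c("IR", "ER"))
  expect_equal(classify_tac_formulation(mixed), "mixed")
  expect_equal(classify_tac_formulation(disp_fixture("CsA")), "n/a")

  avail <- generic_availability()
  # enrolled before generic TAC existed: not evaluable
  bs <- classify_brand_status(disp_fixture("TAC", forms = "IR"),
                              index_date = as.Date("2010-06-01"))
  expect_equal(bs[["TAC"]], "not-evaluable")
  # generic era, all generic MMF
  gm <- disp_fixture(c("MMF", "MMF"), days = c(0, 20),
                     status = c("generic", "generic"))
  bs2 <- classify_brand_status(gm, index_date = as.Date("2015-06-01"))
  expect_equal(bs2[["MMF"]], "generic")
  expect_equal(bs2[["TAC"]], "n/a")
  mixedb <- disp_fixture(c("MMF", "MMF"), days = c(0, 20),
                         status = c("brand", "generic"))
  expect_equal(classify_brand_status(mixedb,
                                     index_date = as.Date("2015-06-01"))[["MMF"]],
               "mixed")
  expect_error(classify_brand_status(gm, index_date = as.Date("2015-06-01"),
                                     agents = "EVE"),
               "availability calendar")
})

test_that("PDC and MPR match their definitions and the day-grid oracle", {
  start <- as.Date("2015-06-01")
  a <- compute_adherence(disp_fixture(rep("TAC", 3), days = c(0, 30, 60),
                                      origin = start),
                         start = start, period_days = 180)
  expect_equal(a$pdc, 0.5)
  expect_equal(a$mpr, 0.5)

  # stockpiling: two same-day supplies shift forward
  b <- compute_adherence(disp_fixture(rep("TAC", 2), days = c(0, 0),
                                      origin = start),
                         start = start, period_days = 60)
  expect_equal(b$pdc, 1.0)
  expect_equal(b$mpr, 1.0)

  z <- compute_adherence(disp_fixture("TAC")[0], start = start,
                         period_days = 180)
  expect_equal(z$pdc, 0)
  expect_equal(z$mpr, 0)

  expect_error(compute_adherence(disp_fixture("TAC"), start, 0), "period")

  # randomized fixtures vs the brute-force day-grid oracle
  set.seed(42)
  for (r in 1:60) {
    k <- sample(1:8, 1)
    days <- sort(sample(0:170, k, replace = TRUE))
    period <- sample(c(90, 180, 365), 1)
    d <- disp_fixture(rep("TAC", k), days = days, origin = start)
    got <- compute_adherence(d, start = start, period_days = period)
    exp_pdc <- pdc_grid(d$dispensing_date, rep(30, k), start, period)
    expect_equal(got$pdc, exp_pdc, tolerance = 1e-12)
    expect_lte(got$pdc, 1)
    expect_lte(got$pdc, got$mpr + 1e-12)
    # permutation invariance
    perm <- d[sample(.N)]
    expect_equal(compute_adherence(perm, start = start,
                                   period_days = period)$pdc, got$pdc)
  }
})

test_that("switch detection labels within-class switches, add-ons and discontinuation", {
  start <- as.Date("2015-06-01")
  base <- classify_index_regimen(disp_fixture(c("TAC", "MMF")))

  cont <- disp_fixture(rep("TAC", 13), days = seq(0, 360, by = 30),
                       origin = start)
  ev0 <- detect_switches(cont, classify_index_regimen(cont), start,
                         horizon_days = 365)
  expect_equal(nrow(ev0), 0L)

  # TAC through day 90, CsA from day 100: one within-class switch
  sw <- rbind(disp_fixture(rep("TAC", 4), days = c(0, 30, 60, 90),
                           origin = start),
              disp_fixture(rep("CsA", 3), days = c(100, 130, 160),
                           origin = start))
  ev1 <- detect_switches(sw, classify_index_regimen(disp_fixture("TAC")),
                         start, horizon_days = 200)
  sws <- ev1[ev1$type == "within-class switch"]
  expect_equal(nrow(sws), 1L)
  expect_equal(sws$date, start + 100)
  expect_equal(sws$detail, "CNI:TAC->CsA")

  # EVE added at day 200 on a TAC backbone: add-on
  ao <- rbind(disp_fixture(rep("TAC", 10), days = seq(0, 270, 30),
                           origin = start),
              disp_fixture(rep("EVE", 3), days = c(200, 230, 260),
                           origin = start))
  ev2 <- detect_switches(ao, classify_index_regimen(disp_fixture("TAC")),
                         start, horizon_days = 300)
  adds <- ev2[ev2$type == "add-on"]
  expect_equal(nrow(adds), 1L)
  expect_equal(adds$date, start + 200)
  expect_equal(adds$detail, "mTOR:EVE")

  # supply gap beyond the grace period: discontinuation
  gap <- disp_fixture(rep("TAC", 2), days = c(0, 150), origin = start)
  ev3 <- detect_switches(gap, classify_index_regimen(disp_fixture("TAC")),
                         start, horizon_days = 200, grace_days = 60)
  expect_true("discontinuation" %in% ev3$type)
  expect_equal(ev3[ev3$type == "discontinuation", date], start + 30)
})

test_that("cohort classification recovers the generated mixture", {
  # clean mixture: exact recovery
  cfg <- simulation_config(n_persons = 500, seed = 26, planted_negatives = 0)
  g <- generate_regional_claims(cfg)
  ds <- pool_regions(lapply(g$bundles, build_analytical_dataset))
  co <- apply_eligibility(find_index_episodes(ds), ds)$cohort
  cl <- classify_cohort(co, ds$dispensings)
  tm <- g$truth[match(cl$person_id, pid)]
  agree <- cl$backbone == tm$backbone & cl$companion == tm$companion &
    cl$steroid == tm$steroid
  expect_equal(mean(agree), 1.0)

  # regimen cells plus "other" partition the cohort
  tab <- regimen_share_table(cl)
  cells <- tab[tab$companion != "(all)"]
  expect_equal(sum(cells$n), nrow(cl))

  # label noise: agreement tracks 1 - eps within binomial bounds
  eps <- 0.15
  cfgn <- simulation_config(n_persons = 600, seed = 27,
                            planted_negatives = 0, label_noise_rate = eps)
  gn <- generate_regional_claims(cfgn)
  dsn <- pool_regions(lapply(gn$bundles, build_analytical_dataset))
  con <- apply_eligibility(find_index_episodes(dsn), dsn)$cohort
  cln <- classify_cohort(con, dsn$dispensings)
  tmn <- gn$truth[match(cln$person_id, pid)]
  agr <- cln$backbone == tmn$backbone & cln$companion == tmn$companion &
    cln$steroid == tmn$steroid
  b <- binom_bounds(nrow(cln), 1 - eps)
  expect_gte(sum(agr), b[1])
  expect_lte(sum(agr), b[2])
})
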