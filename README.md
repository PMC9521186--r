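# txclaims

Pharmacoepidemiology of maintenance immunosuppressive therapy after solid
organ transplant, from regional healthcare claims organised in a common data
model (CDM).

After a kidney, liver, heart or lung transplant, patients receive long-term
immunosuppression built from a calcineurin-inhibitor backbone (tacrolimus,
TAC, or cyclosporine, CsA), an antimetabolite (mycophenolate, MMF, or
azathioprine, AZA) or an mTOR inhibitor (everolimus or sirolimus), with or
without corticosteroids. Which combination a patient actually receives, how
adherent they are, and what happens to them afterwards can be read off
administrative claims — hospital discharge records coded in ICD-9-CM, drug
dispensings coded in ATC/AIC, inhabitant and mortality registries — provided
the claims from several regions are harmonised, the incident-user cohort is
selected correctly, and the regional data are linked to the national
transplant registry without direct identifiers.

`txclaims` implements that pipeline end to end for researchers who study
drug utilisation and outcomes in transplant populations:

- **synthetic data** — a seeded generator that emulates the seven regional
  source tables and a national transplant registry with known ground truth
  (organ mix, regimen mixture, adherence behaviour, constant outcome
  hazards, quasi-identifier corruption), so every downstream stage is
  testable without any data access;
- **CDM core** — a versioned YAML schema, structural/code-format validation,
  data-minimised per-region analytical datasets, and pooling with
  region-namespaced person identifiers;
- **cohort builder** — incident-transplant selection: first transplant
  hospitalization in the study period (organ from ICD-9-CM procedure codes,
  any procedure position), no multi-organ transplant, 2-year transplant
  washout, registered and alive through a 30-day post-discharge landmark,
  immunosuppressant-naive (no ATC L04 in 180 days pre-discharge), and at
  least one L04 dispensing in the landmark window — with an attrition report;
- **registry linkage** — stepwise deterministic matching on concatenated
  pseudonymous keys (sex | organ | year-month of birth | year-month of
  transplant | hospital), duplicates set aside per step, one-to-one by
  construction;
- **exposure** — index regimen classification (backbone x companion x
  steroid co-use, TAC formulation, brand/generic status in the generic era),
  adherence as proportion of days covered, PDC = covered days / period
  (with forward-shifting of overlapping supplies), and medication
  possession ratio, MPR = days supplied / period; switching, add-on and
  discontinuation detection;
- **outcomes** — intention-to-treat and as-treated follow-up from the
  landmark, person-years by organ and calendar year, incidence rates
  IR = cases / person-years x 100 with exact Poisson intervals, and a
  product-limit (Kaplan-Meier) survival estimator;
- **reporting** — regimen share tables, figure-style agent splits,
  claims-vs-registry concordance (proportion agreement and Cohen's kappa),
  and the median odds ratio MOR = exp(sqrt(2 sigma^2) * 0.6745) summarising
  between-hospital variability in treatment choice.

## Worked example

```r
library(txclaims)

cfg <- simulation_config(n_persons = 1000, seed = 1)
g   <- generate_regional_claims(cfg)
ds  <- pool_regions(lapply(g$bundles, build_analytical_dataset))
el  <- apply_eligibility(find_index_episodes(ds), ds)
el$attrition
#>                     step remaining removed
#> 1:            identified      1000       0
#> 2: first_in_study_period       962      38
#> 3:           multi_organ       907      55
#> 4:            washout_2y       907       0
#> 5:  registered_alive_30d       852      55
#> 6:          no_prior_L04       809      43
#> 7:   post_dispensing_30d       740      69
```

1,000 simulated recipients enter; each eligibility step logs how many
persons it removes (the planted rule violations), leaving an incident-user
cohort of 740. Linking the cohort to the synthetic national registry and
classifying the index regimen from landmark-window dispensings:

```r
reg <- generate_sit_registry(g$truth, cfg)
lk  <- stepwise_link(cohort_linkage_frame(el$cohort),
                     registry_linkage_frame(reg))
linkage_report(lk)$rate_pct
#> [1] 100

cl <- classify_cohort(el$cohort, ds$dispensings)
regimen_share_table(cl)[organ == "kidney" & companion == "(all)"]
#>     organ  backbone companion   n n_steroid  pct
#> 1: kidney TAC-based     (all) 274       214 64.0
#> 2: kidney CsA-based     (all)  98        77 22.9
#> 3: kidney    No-CNI     (all)  56        54 13.1
```

64% of simulated kidney recipients start TAC-based therapy, mostly with
steroids — the backbone mix the generator was configured with. Follow-up and
incidence (rates per 100 person-years, exact Poisson 95% CI):

```r
fu <- build_followup(el$cohort, claims_events(ds), outcome = "death")
incidence_table(fu, "mortality")[organ == "kidney"]
#>     organ   outcome   n cases person_years rate lower upper
#> 1: kidney mortality 428    26     1581.79  1.64  1.07  2.41

incidence_rate(269, 13720.5)
#>    cases person_years rate lower upper rate_raw
#> 1:   269      13720.5 1.96  1.73  2.21  1.96057

median_odds_ratio(1)
#> [1] 2.595742
```

`incidence_rate()` is the same arithmetic used on observed case and
person-year counts: 269 deaths over 13,720.5 person-years is 1.96 per
100 person-years. `median_odds_ratio(1)` converts a hospital-level variance
of 1 into the median odds ratio between two randomly chosen hospitals.

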