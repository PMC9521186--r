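---
title: "Methods: a multi-region claims pipeline for post-transplant immunosuppression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a multi-region claims pipeline for post-transplant immunosuppression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(txclaims)
```

`txclaims` turns regional healthcare claims into descriptive
pharmacoepidemiology of maintenance immunosuppressive therapy after solid
organ transplant. This vignette records the model behind each stage, the
parameters that matter, and the design choices we made where the design was
genuinely open. Nothing here asserts an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The study skeleton

Time zero (the index date) is the discharge date of the index transplant
hospitalization. All covariate windows are anchored on it: a 180-day
pre-discharge immunosuppressant washout, a 730-day pre-index transplant
washout and comorbidity/comedication lookback, and a 30-day post-discharge
*landmark* window in which the index regimen is read off dispensings.
Follow-up starts at the end of the landmark (discharge + 30 days) and ends
at the earliest of the outcome of interest, death, transfer out of region,
five years, or the administrative study end (2019-12-31). Under the
as-treated rule, follow-up is additionally censored at the first treatment
change. Enrolment covers discharges from 2009-01-01 to 2019-12-01, with
hospitalizations scanned from 2007-01-01 so that the washout is observable
for early enrollees.

## Synthetic data: what it emulates, and what it does not

No claims or registry data can be redistributed, so the package ships a
seeded generator whose output *is* the study condition for every test:

* **Source-table shapes.** Seven per-region tables (hospital discharge with
  six ICD-9-CM procedure and three diagnosis slots, ATC/AIC drug
  dispensings, inhabitant, mortality, emergency, exemption, outpatient).
  Emergency/exemption/outpatient carry shape only; the pipeline does not
  read their content.
* **Organ mix** defaults to kidney 58.3%, liver 32.1%, heart 6.3%, lung
  3.1%, with pancreas and intestine at 0.1% each — present chiefly as
  multi-organ-exclusion fodder, since no such cohorts are analysed.
* **Regimen mixture.** Index therapy is drawn per organ from the shipped
  reference mixture (`regimen_reference_mixture()`), a backbone x companion
  table with per-cell steroid co-use reflecting observed Italian
  multi-region practice (TAC-based dominant in kidney/liver/lung, CsA-based
  in heart). Agent splits (MMF vs AZA, IR vs ER tacrolimus, generic uptake)
  are per-organ shares in `.agent_shares`.
* **Dispensing streams.** Every agent of the regimen is filled once within
  days 0–6 of discharge (the landmark guarantee implied by the inclusion
  criteria), then refilled on a 30-day cycle; each refill is dispensed with
  probability `adherence` (default 0.85), the generator's one-parameter
  adherence model. Claims carry package counts, not days supplied; a
  product dictionary maps AIC code to a 30-days-per-package convention,
  kept in one editable CSV because it is an assumption, not a fact of the
  data.
* **Outcomes.** Death, rejection/graft failure, severe infection, incident
  diabetes and cancer are exponential waiting times from follow-up start at
  per-organ constant hazards (defaults match observed incidence magnitudes,
  e.g. kidney mortality 0.0196/PY, lung mortality 0.1079/PY). Constant
  hazards are the simplest model for which incidence-rate recovery has a
  closed form, which is exactly what the acceptance checks exploit.
* **Planted negatives.** At 5% per rule (2.5% for paired sub-rules), persons
  are given exactly one eligibility violation: a pre-study first transplant,
  a within-730-day prior transplant, a second organ procedure in the index
  admission, death or deregistration inside the landmark, a pre-discharge
  L04 dispensing, or an empty landmark window. Because event times for
  clean persons are drawn strictly after follow-up start, the set of
  ineligible persons equals the planted set exactly, and the suite asserts
  that set equality.
* **Registry.** One row per recipient with the five quasi-identifiers,
  donor attributes and the physician-reported therapy label. With
  probability `key_perturbation_rate` exactly one quasi-identifier is
  corrupted (sex flip, organ swap, ±1 month, hospital suffix); with
  probability `sit_disagreement_rate` the reported therapy label differs
  from truth. The corrupted field is recorded in a synthetic-diagnostic
  column, which a real registry would not carry.

What the generator does *not* emulate: realistic Italian coding dialects
beyond the specific fields the pipeline reads, dose strengths, induction
therapy, seasonal or regional prescribing trends, informative censoring,
and correlated outcomes. Passing tests therefore demonstrate algorithmic
correctness against a known mechanism, not validity on real claims.

## Cohort algorithm

Organ is mapped from ICD-9-CM procedure codes in any of the six positions:
kidney 55.6 excluding 55.61, liver 50.5, heart 37.5, lung 33.5, pancreas
52.8, intestine 46.97. (Printed sources sometimes carry the impossible code
"469.7" for intestine; the shipped map uses 46.97 and we flag rather than
silently assume.) The index episode is the person's first transplant
hospitalization in the 2007–2019 scan; episodes outside the 2009–2019
enrolment window are flagged and removed at step 1.

One structural consequence is worth recording: when the only evidence of a
prior transplant is the discharge table itself, the 730-day washout (step 3)
is logically subsumed by the first-hospitalization rule — any transplant
within 730 days before a 2009+ index makes the earlier admission the
person's first episode, so step 1 removes them first. Both rules are
implemented and independently exercised; under the default order the
washout step logs zero removals, and the suite asserts what is actually
invariant: the *final cohort set* is identical under any permutation of
steps 2–6, while per-step counts are order-dependent.

Other choices: the washout window is `[discharge − 730 days, admission)`,
half-open, without leap handling, to keep arithmetic reproducible;
multi-organ means ≥ 2 distinct organ procedures in the same admission (the
conservative reading of an undefined window); "alive within 30 days" is
`death_date > discharge + 30`; and "registered" requires the registration
interval to cover the discharge through the landmark.

## Linkage

"Stepwise deterministic" is realised as exact one-to-one matching over a
configurable ladder of key definitions: all five quasi-identifiers first,
then the five leave-one-out four-field keys in a fixed order. The ladder is
configuration (YAML), not code. Keys are canonicalised (case-folded,
zero-padded months, three-letter organ codes) and concatenated with a
reserved separator; a field containing the separator is an error, never a
mangled key. Records with a duplicated key on either side are set aside
*for that step only* — they may still match later if a relaxed key is
unique — and a record that never matches reports `duplicate-key` or
`no-candidate`. Deterministic linkage must not guess: a relaxed key
matching several candidates yields no match. Two properties follow by
construction and are asserted on every run: no registry row is consumed
twice, and adding a relaxation step never decreases total matches. With
unperturbed keys the rate is exactly 1.0 on globally unique keys; with 10%
single-field corruption the leave-one-out ladder recovers ≥ 95% of true
pairs at n = 1,000.

## Regimen classification

Backbone comes from CNI presence in the landmark window (TAC > CsA > none);
companion from antimetabolite/mTOR presence, with their co-occurrence — or
residual agents — classed `other`; steroids are a flag from any H02AB
dispensing (no dose threshold: claims carry no dose regimen). A No-CNI
regimen with only steroids or residual immunosuppressants is `other`
("mainly steroid-based"). Two deliberate choices:

* **Dual-CNI tie.** The share tables have no dual-CNI cell, so when both
  CNIs appear the backbone is the earliest-dispensed one, same-day ties to
  TAC; the rule is logged and config-overridable.
* **Steroid-only regimens vs the L04 inclusion rule.** At least one L04
  dispensing is required for cohort entry, but H02AB steroids are not L04.
  The generator's No-CNI/`other` cell therefore includes a residual L04
  agent (belatacept, L04AA28, role `other` in the dictionary), which
  reconciles steroid-based No-CNI regimens with the inclusion criteria.

TAC formulation (IR/ER) and per-agent brand status are product-level (AIC)
calls; brand status is evaluated only for persons whose index date falls in
the era where a generic existed (shipped availability calendar: CsA/AZA
from study start, MMF 2011, TAC 2014), and `mixed` is disclosed as its own
category rather than forced into the binary split.

## Adherence, switching, follow-up, estimation

PDC definitions are not standardised in claims sources, so we adopt and
flag: PDC = covered days / period with forward-shifting of overlapping
supplies (stockpiling), anchored at follow-up start, counting only
dispensings inside the period; MPR = total days supplied / period, raw and
capped at 1. PDC is permutation-invariant and ≤ 1 by construction, and the
suite checks it against an independent day-grid pill-taking simulation on
randomized fixtures. Switching scans the stream for a different agent in an
already-used class (within-class switch), a class absent from the index
regimen (add-on), and supply gaps longer than a 60-day grace period
(discontinuation, configurable).

Person-years are exact day counts over half-open intervals, split at
calendar-year boundaries (the split conserves totals to 1e-9) and converted
at 365.25 days/year; the five-year cap is 1,826 days. Incidence rates are
cases/PY x 100, displayed to two decimals with half-up rounding (as are all
percentages, at one decimal); confidence intervals use the exact Poisson
chi-square inversion. Published CI values for such rates are not always
reproducible from any standard Poisson method, so the CI method here is
*declared*, not reverse-engineered, and only the point rates are treated as
checkable arithmetic. The survival curve is the product-limit estimator
with right censoring, ties handled events-before-censorings; it is checked
exactly against a hand-computed 10-subject table and against
`survival::survfit` on random fixtures.

Outcome ascertainment takes the first matching discharge diagnosis after
follow-up start; persons with the outcome on or before start are prevalent
and excluded from that outcome's risk set, which is why outcome-specific
denominators are smaller than the cohort.

Concordance between claims-derived and registry-reported regimens is
proportion agreement plus Cohen's kappa on the joint
backbone/companion/steroid label, computed on linked persons only; a
contingency with fewer than two categories on a margin is flagged
degenerate and reported as kappa 1 when the sides agree everywhere. The
median odds ratio is the closed form exp(sqrt(2σ²)·z₀.₇₅); the
mixed-effects model that produces σ² is out of scope, so the variance is a
caller input.

## Problem sizes and reproducibility

Simulation-based checks run at the sizes where their statistical guarantees
are tight but cheap: eligibility set-equality and hazard recovery at
n = 2,000, linkage recovery and label-noise agreement at n = 1,000, PDC
against the day-grid oracle on 1,000 randomized fixtures, binomial checks
at 99% bounds. Identical `(config, seed)` pairs produce byte-identical
outputs; `scripts/acceptance.R --seed N` drives every random stream from
one integer. The analysis drivers under `analysis/` run the same pipeline
at n = 5,000 as a worked study.

## Known limitations

The pipeline is descriptive: no propensity-score or hazard-ratio modelling,
no competing-risk estimators, no cost analyses. Validation is structural
and format-level, not terminological. The comorbidity, comedication and
Charlson code lists are short, editable CSVs with no claim of equivalence
to validated mappings. "Distributed" is modelled as independent per-region
invocations of the same code plus pooling — there is no remote-execution
framework. And every quantitative guarantee is a property of the synthetic
mechanism; real claims bring coding error, interrupted eligibility and
informative censoring that the generator deliberately does not model.
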