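Package: txclaims
Title: Multi-Region Claims Pipeline for Post-Transplant Immunosuppression
    Pharmacoepidemiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study maintenance immunosuppressive drug therapy after
    solid organ transplant from regional healthcare claims organised in a
    common data model. Includes a seeded synthetic-data generator for regional
    claims bundles and a national transplant registry with known ground truth;
    common-data-model validation, analytical-dataset construction and
    cross-region pooling; incident-transplant cohort selection with a 30-day
    landmark and an attrition report; stepwise deterministic record linkage on
    concatenated pseudonymous keys; index immunosuppressive regimen
    classification (calcineurin-inhibitor backbone, antimetabolite/mTOR
    companion, steroid co-use, tacrolimus formulation, brand/generic status),
    adherence (PDC/MPR) and switching; intention-to-treat and as-treated
    follow-up with person-years, incidence rates with exact Poisson intervals,
    and product-limit survival; and descriptive reporting including regimen
    share tables, claims-versus-registry concordance and the median odds
    ratio transform.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
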