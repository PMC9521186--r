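#!/usr/bin/env Rscript
# Link the cohort to the national transplant registry by stepwise
# deterministic matching on concatenated pseudonymous keys (all five
# quasi-identifiers, then leave-one-out relaxations), and report per-step
# counts, the linkage rate and the false-match rate against the truth
# manifest.
source("analysis/_common.R")

co <- load_cohort()
reg <- fread(paths$registry)
truth <- load_truth()

steps <- default_linkage_steps()
write_linkage_steps(steps, file.path(paths$tables, "linkage_steps.yaml"))
lk <- stepwise_link(cohort_linkage_frame(co), registry_linkage_frame(reg),
                    steps)
rp <- linkage_report(lk, truth)

fwrite(lk$matched, file.path(paths$derived, "linkage_matched.csv"))
fwrite(lk$unmatched, file.path(paths$derived, "linkage_unmatched.csv"))
jsonlite::write_json(rp, file.path(paths$tables, "linkage_report.json"),
                     auto_unbox = TRUE)

message("linked ", rp$n_matched, " of ", nrow(co), " (", rp$rate_pct, "%)")
message("per-step: ", paste(rp$steps$matched, collapse = ", "))
message("false-match rate vs truth: ", signif(rp$false_match_rate, 3))
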