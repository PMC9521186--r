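#!/usr/bin/env Rscript
# Simulate the multi-region study data: four regional claims bundles in the
# CDM source-table shapes, a national transplant registry with pseudonymous
# quasi-identifiers, and a truth manifest for downstream validation.
source("analysis/_common.R")

cfg <- simulation_config(
  n_persons = 5000,
  seed = 20260901,
  key_perturbation_rate = 0.05,
  sit_disagreement_rate = 0.10)
write_simulation_config(cfg, paths$config)

g <- generate_regional_claims(cfg)
for (r in names(g$bundles))
  write_claims_bundle(g$bundles[[r]], file.path(paths$data, r))
write_truth_manifest(g$truth, paths$truth)

reg <- generate_sit_registry(g$truth, cfg)
fwrite(reg, paths$registry)

message("persons: ", nrow(g$truth))
message("organ mix: ", paste(names(table(g$truth$organ)),
                             table(g$truth$organ), collapse = ", "))
message("planted negatives: ", sum(!is.na(g$truth$planted_negative)))
message("registry rows perturbed: ", sum(!is.na(reg$perturbed_field)))
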