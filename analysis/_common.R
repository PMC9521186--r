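# Shared paths and loaders for the analysis drivers. Each numbered script can
# be run on its own from the repository root after its predecessors.
suppressPackageStartupMessages({
  library(data.table)
  library(txclaims)
})

# bulky per-person intermediates live under scratch/ (reproducible from the
# seeded config); only compact summary tables go under results/
paths <- list(
  data    = "scratch/data",
  cdm     = "scratch/cdm",
  derived = "scratch/derived",
  tables  = "results/tables",
  config  = "scratch/data/simulation_config.yaml",
  truth   = "scratch/data/truth_manifest.json",
  registry = "scratch/data/sit_registry.csv"
)
for (p in c(paths$data, paths$cdm, paths$derived, paths$tables))
  dir.create(p, recursive = TRUE, showWarnings = FALSE)

load_config <- function() read_simulation_config(paths$config)

load_bundles <- function(cfg = load_config()) {
  lapply(setNames(cfg$region_ids, cfg$region_ids), function(r)
    read_claims_bundle(file.path(paths$data, r), region = r))
}

load_pooled <- function(cfg = load_config()) {
  pool_regions(lapply(load_bundles(cfg), build_analytical_dataset))
}

load_truth <- function() {
  tr <- as.data.table(jsonlite::read_json(paths$truth, simplifyVector = TRUE))
  for (col in grep("date$|^admission|^discharge", names(tr), value = TRUE))
    tr[, (col) := as.Date(get(col))]
  tr
}

load_cohort <- function() {
  co <- fread(file.path(paths$derived, "cohort.csv"),
              colClasses = list(character = "person_id"))
  for (col in c("admission", "discharge", "birth_date", "death_date",
                "registration_end", "fu_start"))
    co[, (col) := as.Date(get(col))]
  co
}
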