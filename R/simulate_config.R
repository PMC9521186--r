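# Simulation configuration: the study conditions the generator emulates.

.default_organ_mix <- c(kidney = 0.583, liver = 0.321, heart = 0.063,
                        lung = 0.031, pancreas = 0.001, intestine = 0.001)

.default_hazards <- local({
  m <- rbind(
    kidney    = c(0.0196, 0.0212, 0.0938, 0.0362, 0.0236),
    liver     = c(0.0367, 0.0175, 0.0424, 0.0420, 0.0595),
    heart     = c(0.0289, 0.0135, 0.0795, 0.0216, 0.0158),
    lung      = c(0.1079, 0.0666, 0.3738, 0.1732, 0.0310),
    pancreas  = c(0.0196, 0.0212, 0.0938, 0.0362, 0.0236),
    intestine = c(0.0196, 0.0212, 0.0938, 0.0362, 0.0236))
  colnames(m) <- c("death", "reject", "infection", "diabetes", "cancer")
  m
})

.default_planted <- c(first_pre_study = 0.025, washout_2y = 0.025,
                      multi_organ = 0.05, early_death = 0.025,
                      deregistered = 0.025, prior_L04 = 0.05,
                      no_index_dispensing = 0.05)

#' Build a simulation configuration
#'
#' Parameterizes the synthetic regional-claims generator. Defaults encode the
#' study conditions the package emulates: a 2009--2019 multi-region transplant
#' cohort with the shipped organ mix and per-organ regimen mixture, constant
#' outcome hazards (events per person-year), per-person refill probability as
#' the adherence model, and planted eligibility-rule violations at 5% per rule
#' so every exclusion criterion can fire.
#'
#' @param n_persons number of transplant recipients to simulate
#' @param region_ids region labels; persons are spread uniformly across them
#' @param organ_mix named proportions over
#'   kidney/liver/heart/lung/pancreas/intestine (must sum to 1)
#' @param regimen_mixture optional data.table like
#'   [regimen_reference_mixture()]; `NULL` uses the shipped reference mixture
#' @param adherence per-person probability that each 30-day refill cycle is
#'   filled, in \[0,1\]
#' @param outcome_hazards organ x outcome matrix of constant hazards
#'   (events per person-year) for death, reject, infection, diabetes, cancer
#' @param transfer_hazard constant hazard of out-of-region transfer per
#'   person-year
#' @param key_perturbation_rate probability that a registry row carries one
#'   corrupted quasi-identifier field
#' @param sit_disagreement_rate probability that the physician-reported
#'   therapy in the registry differs from the claims truth label
#' @param label_noise_rate probability that the dispensed regimen differs
#'   from the manifest truth label (classification noise)
#' @param planted_negatives named per-rule rates, a single rate recycled over
#'   all rules, or 0 for none
#' @param seed integer RNG seed; identical configs produce identical output
#' @return object of class `simulation_config`
#' @export
simulation_config <- function(n_persons = 1000L,
                              region_ids = c("LOM", "VEN", "LAZ", "SAR"),
                              organ_mix = .default_organ_mix,
                              regimen_mixture = NULL,
                              adherence = 0.85,
                              outcome_hazards = .default_hazards,
                              transfer_hazard = 0.01,
                              key_perturbation_rate = 0.05,
                              sit_disagreement_rate = 0,
                              label_noise_rate = 0,
                              planted_negatives = .default_planted,
                              seed = 1L) {
  if (!is.numeric(n_persons) || length(n_persons) != 1 || n_persons < 1)
    stop("configuration error: n_persons must be a positive integer")
  if (length(region_ids) < 1) stop("configuration error: need >= 1 region")
  organ_mix <- organ_mix[organ_mix > 0]
  if (abs(sum(organ_mix) - 1) > 1e-9)
    stop("configuration error: organ_mix proportions must sum to 1")
  if (!all(names(organ_mix) %in% rownames(.default_hazards)))
    stop("configuration error: unknown organ in organ_mix")
  for (r in c(adherence, key_perturbation_rate, sit_disagreement_rate,
              label_noise_rate))
    if (r < 0 || r > 1) stop("configuration error: rates must be in [0,1]")
  if (any(outcome_hazards < 0) || transfer_hazard < 0)
    stop("configuration error: hazards must be >= 0")
  if (length(planted_negatives) == 1 && is.null(names(planted_negatives)))
    planted_negatives <- setNames(rep(planted_negatives, length(.default_planted)),
                                  names(.default_planted))
  if (is.null(names(planted_negatives)) ||
      !all(names(planted_negatives) %in% names(.default_planted)))
    stop("configuration error: unknown planted-negative rule")
  if (any(planted_negatives < 0) || sum(planted_negatives) > 1)
    stop("configuration error: planted-negative rates invalid")
  mix <- if (is.null(regimen_mixture)) regimen_reference_mixture()
         else as.data.table(regimen_mixture)
  mix[, p := n / sum(n), by = organ]
  bad <- mix[, abs(sum(p) - 1) > 1e-9, by = organ]$V1
  if (any(bad)) stop("configuration error: regimen_mixture must sum to 1 per organ")
  structure(list(
    n_persons = as.integer(n_persons), region_ids = region_ids,
    organ_mix = organ_mix, regimen_mixture = mix, adherence = adherence,
    outcome_hazards = outcome_hazards, transfer_hazard = transfer_hazard,
    key_perturbation_rate = key_perturbation_rate,
    sit_disagreement_rate = sit_disagreement_rate,
    label_noise_rate = label_noise_rate,
    planted_negatives = planted_negatives,
    seed = as.integer(seed)), class = "simulation_config")
}

#' Write / read a simulation configuration as YAML
#'
#' @param config a `simulation_config`
#' @param path file path
#' @return `read_simulation_config` returns a `simulation_config`
#' @export
write_simulation_config <- function(config, path) {
  x <- unclass(config)
  x$organ_mix <- as.list(x$organ_mix)
  x$planted_negatives <- as.list(x$planted_negatives)
  x$outcome_hazards <- lapply(seq_len(nrow(x$outcome_hazards)), function(i)
    as.list(x$outcome_hazards[i, ]))
  names(x$outcome_hazards) <- rownames(config$outcome_hazards)
  x$regimen_mixture <- NULL  # reference mixture is shipped, not serialized
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  x <- yaml::read_yaml(path)
  hz <- do.call(rbind, lapply(x$outcome_hazards, function(r) unlist(r)))
  simulation_config(
    n_persons = x$n_persons, region_ids = unlist(x$region_ids),
    organ_mix = unlist(x$organ_mix), adherence = x$adherence,
    outcome_hazards = hz, transfer_hazard = x$transfer_hazard,
    key_perturbation_rate = x$key_perturbation_rate,
    sit_disagreement_rate = x$sit_disagreement_rate,
    label_noise_rate = x$label_noise_rate,
    planted_negatives = unlist(x$planted_negatives), seed = x$seed)
}
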