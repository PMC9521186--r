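# Stepwise deterministic record linkage on concatenated pseudonymous keys.

.key_fields <- c("sex", "organ", "birth_ym", "tx_ym", "hospital")
.key_sep <- "|"
.organ_short <- c(kidney = "KID", liver = "LIV", heart = "HEA", lung = "LUN",
                  pancreas = "PAN", intestine = "INT")

.canon_field <- function(field, x) {
  x <- as.character(x)
  out <- switch(field,
    sex = toupper(trimws(x)),
    organ = {
      o <- .organ_short[tolower(trimws(x))]
      ifelse(is.na(o), toupper(trimws(x)), o)
    },
    birth_ym = ,
    tx_ym = {
      d <- as.Date(x, format = "%Y-%m-%d")  # NA when already year-month
      ifelse(!is.na(d), format(d, "%Y-%m"), trimws(x))
    },
    toupper(trimws(x)))
  out
}

#' Build linkage keys
#'
#' Canonicalized concatenation of the requested quasi-identifier fields
#' (case-folded, months zero-padded, organs encoded as three-letter codes)
#' with a reserved separator. The key is injective given identical field
#' values; a field value containing the separator is an error, never a
#' mangled key. Keys carry no day-of-birth or other minimized fields.
#'
#' @param records data.table with the quasi-identifier columns
#' @param fields ordered field names, a subset of
#'   `sex, organ, birth_ym, tx_ym, hospital`
#' @return character vector of keys, one per record row
#' @export
build_key <- function(records, fields = .key_fields) {
  records <- as.data.table(records)
  miss <- setdiff(fields, names(records))
  if (length(miss))
    stop("key construction error: missing field(s): ",
         paste(miss, collapse = ", "))
  parts <- lapply(fields, function(f) {
    v <- .canon_field(f, records[[f]])
    if (any(grepl(.key_sep, v, fixed = TRUE)))
      stop("key construction error: field '", f,
           "' contains the reserved separator")
    if (anyNA(v)) stop("key construction error: missing value in field '", f, "'")
    v
  })
  do.call(paste, c(parts, sep = .key_sep))
}

#' Default linkage ladder
#'
#' Step 1 uses all five quasi-identifiers; subsequent steps drop one field at
#' a time in a fixed order (hospital, transplant month, birth month, organ,
#' sex), from most to least specific. The ladder is configuration, not code.
#'
#' @return list of character vectors
#' @export
default_linkage_steps <- function() {
  c(list(.key_fields),
    lapply(rev(seq_along(.key_fields)), function(i) .key_fields[-i]))
}

#' Write / read a linkage ladder as YAML
#' @param steps list of field vectors
#' @param path file path
#' @export
write_linkage_steps <- function(steps, path) {
  yaml::write_yaml(lapply(steps, as.list), path)
  invisible(path)
}

#' @rdname write_linkage_steps
#' @export
read_linkage_steps <- function(path) {
  lapply(yaml::read_yaml(path), unlist)
}

#' Quasi-identifier frames for linkage
#'
#' `cohort_linkage_frame` derives the five pseudonymous fields from a built
#' cohort (year+month of birth and of transplant admission, sex, organ,
#' transplant hospital); `registry_linkage_frame` standardizes a transplant
#' registry table. Both return `id` plus the five key fields.
#'
#' @param cohort cohort table from [apply_eligibility()]
#' @return data.table with columns `id`, `sex`, `organ`, `birth_ym`,
#'   `tx_ym`, `hospital`
#' @export
cohort_linkage_frame <- function(cohort) {
  data.table(id = cohort$person_id, sex = cohort$sex, organ = cohort$organ,
             birth_ym = format(cohort$birth_date, "%Y-%m"),
             tx_ym = format(cohort$admission, "%Y-%m"),
             hospital = cohort$hospital)
}

#' @rdname cohort_linkage_frame
#' @param registry registry table (e.g. from [generate_sit_registry()])
#' @export
registry_linkage_frame <- function(registry) {
  data.table(id = registry$sit_id, sex = registry$sex, organ = registry$organ,
             birth_ym = registry$birth_ym, tx_ym = registry$tx_ym,
             hospital = registry$hospital)
}

#' Stepwise deterministic record linkage
#'
#' At each step, keys are built on both sides from that step's fields,
#' restricted to still-unmatched records. Records whose key is duplicated on
#' either side at that step are set aside for the step (they remain eligible
#' at later steps if their later key is unique); unique keys are matched by
#' exact equality, one-to-one. Adding a relaxation step never decreases the
#' total match count.
#'
#' @param cohort_frame,registry_frame frames from [cohort_linkage_frame()] /
#'   [registry_linkage_frame()]
#' @param steps ordered list of field vectors, most to least specific
#' @return object of class `linkage_result`: `matched` (cohort id, registry
#'   id, step), `unmatched` (cohort id, reason `duplicate-key` or
#'   `no-candidate`), `step_counts`, `n_cohort`, `rate`
#' @export
stepwise_link <- function(cohort_frame, registry_frame,
                          steps = default_linkage_steps()) {
  if (!length(steps)) stop("configuration error: empty step list")
  cf <- as.data.table(cohort_frame); rf <- as.data.table(registry_frame)
  un_c <- cf$id; un_r <- rf$id
  ever_dup <- character(0)
  matched <- list(); step_counts <- integer(length(steps))
  for (s in seq_along(steps)) {
    fields <- steps[[s]]
    cc <- cf[id %in% un_c]; rr <- rf[id %in% un_r]
    if (!nrow(cc) || !nrow(rr)) break
    cc[, key := build_key(.SD, fields)]
    rr[, key := build_key(.SD, fields)]
    dup_c <- cc$key[duplicated(cc$key)]
    dup_r <- rr$key[duplicated(rr$key)]
    ever_dup <- union(ever_dup, cc$id[cc$key %in% dup_c])
    cu <- cc[!key %in% dup_c]; ru <- rr[!key %in% dup_r]
    m <- merge(cu[, .(cohort_id = id, key)], ru[, .(registry_id = id, key)],
               by = "key")
    step_counts[s] <- nrow(m)
    if (nrow(m)) {
      m[, step := s]
      matched[[length(matched) + 1L]] <- m[, .(cohort_id, registry_id, step)]
      un_c <- setdiff(un_c, m$cohort_id)
      un_r <- setdiff(un_r, m$registry_id)
    }
  }
  matched <- if (length(matched)) rbindlist(matched) else
    data.table(cohort_id = character(0), registry_id = character(0),
               step = integer(0))
  unmatched <- data.table(cohort_id = un_c)
  unmatched[, reason := fifelse(cohort_id %in% ever_dup, "duplicate-key",
                                "no-candidate")]
  structure(list(matched = matched, unmatched = unmatched,
                 step_counts = step_counts, n_cohort = nrow(cf),
                 rate = nrow(matched) / nrow(cf)),
            class = "linkage_result")
}

#' Summarize a linkage result
#'
#' Per-step match counts, the overall linkage rate (as a percentage, one
#' decimal) and, when a truth manifest is supplied, the false-match rate
#' among matched pairs.
#'
#' @param result a `linkage_result`
#' @param truth optional truth manifest with `pid` and `sit_id`
#' @return list with `steps` (data.table), `rate_pct`, `n_matched`,
#'   `n_unmatched`, `reasons`, and `false_match_rate` when truth is given
#' @export
linkage_report <- function(result, truth = NULL) {
  stopifnot(inherits(result, "linkage_result"))
  out <- list(
    steps = data.table(step = seq_along(result$step_counts),
                       matched = result$step_counts),
    n_matched = nrow(result$matched),
    n_unmatched = nrow(result$unmatched),
    reasons = if (nrow(result$unmatched))
      result$unmatched[, .N, by = reason] else
      data.table(reason = character(0), N = integer(0)),
    rate_pct = pct(nrow(result$matched), result$n_cohort))
  if (!is.null(truth) && nrow(result$matched)) {
    m <- merge(result$matched,
               as.data.table(truth)[, .(cohort_id = pid, true_sit = sit_id)],
               by = "cohort_id", all.x = TRUE)
    out$false_match_rate <- mean(m$registry_id != m$true_sit, na.rm = TRUE)
  }
  out
}
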