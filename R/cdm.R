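# Common data model: schema, structural validation, analytical datasets,
# cross-region pooling.

#' Load the common data model schema
#'
#' The CDM is shipped as a versioned YAML declaration: per-table ordered field
#' lists with semantic types (identifier, date, code-with-codesystem,
#' quantity, category), per-code-system format regexes and a service-date
#' window. Every table carries the anonymous person identifier; no direct
#' identifiers appear anywhere. Validation is structural plus code-format
#' only — no external terminology dictionaries.
#'
#' @param path optional path to an alternative schema YAML
#' @return list of class `cdm_schema`
#' @export
cdm_schema <- function(path = NULL) {
  s <- yaml::read_yaml(path %||% .extdata("cdm_schema.yaml"))
  s$date_window <- lapply(s$date_window, as.Date)
  structure(s, class = "cdm_schema")
}

#' Validate a claims bundle against the CDM schema
#'
#' Non-mutating structural validation: missing fields, malformed codes
#' (regex per code system; empty strings are allowed in code slots), dates
#' outside the service window, and person identifiers orphaned from the
#' inhabitant registry. A missing mandatory table is a hard error, distinct
#' from row-level violations.
#'
#' @param bundle a `claims_bundle`
#' @param schema a [cdm_schema()]
#' @return object of class `validation_report`: per-table row counts, a
#'   violation table (`table`, `row`, `field`, `reason`) and a `pass` flag
#'   that is TRUE iff no violations were found
#' @export
validate_bundle <- function(bundle, schema = cdm_schema()) {
  stopifnot(inherits(bundle, "claims_bundle"))
  viol <- list()
  add <- function(tb, rows, field, reason) {
    if (!length(rows)) return(invisible())
    viol[[length(viol) + 1L]] <<- data.table(table = tb, row = rows,
                                             field = field, reason = reason)
  }
  counts <- list()
  known_ids <- if (!is.null(bundle$inhabitant)) unique(bundle$inhabitant$person_id)
               else character(0)
  for (tb in names(schema$tables)) {
    spec <- schema$tables[[tb]]
    dt <- bundle[[tb]]
    if (is.null(dt)) {
      if (isTRUE(spec$mandatory))
        stop("missing mandatory table: ", tb, call. = FALSE)
      next
    }
    counts[[tb]] <- nrow(dt)
    for (f in spec$fields) {
      if (!f$name %in% names(dt)) {
        add(tb, NA_integer_, f$name, "missing-field")
        next
      }
      x <- dt[[f$name]]
      if (f$type == "date") {
        d <- if (inherits(x, "Date")) x else suppressWarnings(as.Date(as.character(x)))
        add(tb, which(!is.na(x) & is.na(d)), f$name, "unparseable-date")
        if (isTRUE(f$window))
          add(tb, which(!is.na(d) & (d < schema$date_window$start |
                                       d > schema$date_window$end)),
              f$name, "date-outside-window")
      } else if (f$type == "code") {
        rx <- schema$code_systems[[f$system]]
        xx <- as.character(x)
        add(tb, which(!is.na(xx) & nzchar(xx) & !grepl(rx, xx)),
            f$name, "bad-code-format")
      } else if (f$type == "quantity") {
        add(tb, which(!is.na(x) & (!is.numeric(x) | x < 0)),
            f$name, "bad-quantity")
      } else if (f$type == "identifier") {
        add(tb, which(is.na(x) | !nzchar(as.character(x))),
            f$name, "empty-identifier")
        if (tb != "inhabitant")
          add(tb, which(!as.character(x) %in% known_ids),
              f$name, "orphan-person-id")
      }
    }
  }
  v <- if (length(viol)) rbindlist(viol) else
    data.table(table = character(0), row = integer(0), field = character(0),
               reason = character(0))
  structure(list(region = bundle$region,
                 row_counts = counts, violations = v,
                 pass = nrow(v) == 0L), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("CDM validation:", if (x$pass) "PASS" else "FAIL",
      sprintf("(%d violations)\n", nrow(x$violations)))
  if (nrow(x$violations)) print(x$violations[, .N, by = .(table, field, reason)])
  invisible(x)
}

.minimal_tables <- c("persons", "transplant_procedures", "dispensings",
                     "diagnoses")

#' Build the per-region analytical dataset
#'
#' Reduces a validated claims bundle to the minimal person-level event data
#' the study uses (data minimization): persons with vital status and
#' registration interval, transplant procedure rows with organ mapped from
#' ICD-9-CM codes in any procedure position, immunosuppressant and study
#' comedication dispensings, and dated discharge diagnoses.
#'
#' @param bundle a `claims_bundle`
#' @param schema a [cdm_schema()]
#' @param validate validate first and refuse on failure (default TRUE)
#' @return object of class `analytical_dataset`
#' @export
build_analytical_dataset <- function(bundle, schema = cdm_schema(),
                                     validate = TRUE) {
  if (validate) {
    rep <- validate_bundle(bundle, schema)
    if (!rep$pass) {
      cond <- simpleError(sprintf("bundle failed CDM validation (%d violations)",
                                  nrow(rep$violations)))
      cond$report <- rep
      stop(cond)
    }
  }
  region <- bundle$region
  hosp <- copy(bundle$hospital_discharge)
  persons <- copy(bundle$inhabitant)
  persons <- merge(persons, bundle$mortality[, .(person_id, death_date)],
                   by = "person_id", all.x = TRUE)
  persons[, region := region]

  proc_cols <- grep("^proc", names(hosp), value = TRUE)
  tp <- melt(hosp[, c("person_id", "admission_date", "discharge_date",
                      "hospital", proc_cols), with = FALSE],
             id.vars = c("person_id", "admission_date", "discharge_date",
                         "hospital"),
             variable.name = "slot", value.name = "proc_code")
  tp <- tp[nzchar(proc_code)]
  tp[, organ := organ_from_procedure(proc_code)]
  tp <- tp[!is.na(organ)]
  tp[, slot := as.integer(sub("proc", "", slot))]
  tp[, region := region]
  setorder(tp, person_id, admission_date, slot)

  diag_cols <- grep("^diag", names(hosp), value = TRUE)
  dg <- melt(hosp[, c("person_id", "admission_date", diag_cols), with = FALSE],
             id.vars = c("person_id", "admission_date"),
             variable.name = "slot", value.name = "code")
  dg <- dg[nzchar(code)][, slot := NULL]
  setnames(dg, "admission_date", "date")
  dg[, region := region]

  keep_atc <- paste0("^(L04|H02AB|",
                     paste(comedication_code_list()$atc_prefix, collapse = "|"),
                     ")")
  disp <- bundle$drug_dispensing[grepl(keep_atc, atc),
                                 .(person_id, dispensing_date, atc, aic,
                                   n_packages)]
  disp[, region := region]

  structure(list(persons = persons, transplant_procedures = tp,
                 dispensings = disp, diagnoses = dg,
                 schema_version = schema$version, pooled = FALSE,
                 regions = region), class = "analytical_dataset")
}

#' Pool per-region analytical datasets
#'
#' Union of the regional datasets with the region label retained. Person
#' identifiers are namespaced as `region::id`, so identical raw identifiers
#' in different regions can never collide. Pooling is associative and
#' order-insensitive up to row order.
#'
#' @param datasets list of `analytical_dataset`
#' @return a pooled `analytical_dataset`
#' @export
pool_regions <- function(datasets) {
  stopifnot(length(datasets) >= 1)
  vers <- unique(vapply(datasets, `[[`, "", "schema_version"))
  if (length(vers) != 1)
    stop("schema version mismatch across datasets: ",
         paste(vers, collapse = ", "))
  ns <- function(dt, pooled) {
    dt <- copy(dt)
    if (!pooled) dt[, person_id := paste0(region, "::", person_id)]
    dt
  }
  tabs <- lapply(setNames(.minimal_tables, .minimal_tables), function(tb)
    rbindlist(lapply(datasets, function(d) ns(d[[tb]], d$pooled)),
              use.names = TRUE))
  structure(c(tabs, list(schema_version = vers, pooled = TRUE,
                         regions = unlist(lapply(datasets, `[[`, "regions")))),
            class = "analytical_dataset")
}
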