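# Delimited-text readers/writers and the column-mapping schema.
#
# All tables are RFC-4180 CSV, UTF-8, ISO 8601 dates (YYYY-MM accepted for
# month-precision fields).  Event codes may arrive in long layout (one row
# per code) or wide layout (one column per slot, as inpatient extracts are
# usually supplied); the schema declares which.

#' Default cohort schema
#'
#' The column mapping used by [write_cohort()] and by the synthetic
#' generator: identity mapping onto the canonical column names, long event
#' layout.  Override entries to read other extracts; a wide event entry
#' looks like
#' `list(layout = "wide", source = "inpatient", person = "person_id",
#'  event_id = "event_id", date = "admission_date", slots = list(
#'    diagnosis = list(prefix = "diag", n = 55, code_system = "ICD10")))`.
#'
#' @return Nested list describing each table's layout and column names.
#' @export
default_schema <- function() {
  list(
    persons = list(columns = stats::setNames(as.list(PERSON_COLS), PERSON_COLS)),
    events = list(layout = "long",
                  columns = stats::setNames(as.list(EVENT_COLS), EVENT_COLS)),
    registry = list(columns = stats::setNames(as.list(REGISTRY_COLS),
                                              REGISTRY_COLS)),
    coverage = list(columns = list(source = "source", start = "start",
                                   end = "end"))
  )
}

#' Read a cohort schema from a YAML file
#'
#' @param path Path to a YAML file with the structure of [default_schema()].
#' @return Schema list.
#' @export
read_schema <- function(path) {
  sch <- yaml::read_yaml(path)
  base <- default_schema()
  for (nm in names(base)) if (is.null(sch[[nm]])) sch[[nm]] <- base[[nm]]
  sch
}

read_csv_chr <- function(path) {
  utils::read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = c("", "NA"), fileEncoding = "UTF-8")
}

map_columns <- function(df, mapping, table, path) {
  have <- vapply(mapping, function(src) src %in% names(df), logical(1))
  if (!all(have)) {
    stop(sprintf("schema error: %s table '%s' missing mapped column(s): %s",
                 table, path,
                 paste(unlist(mapping[!have]), collapse = ", ")),
         call. = FALSE)
  }
  out <- df[unlist(mapping)]
  names(out) <- names(mapping)
  out
}

coerce_or_report <- function(x, fn, col, table) {
  res <- tryCatch(fn(x), error = function(e) e)
  if (inherits(res, "error")) {
    probe <- vapply(seq_along(x), function(i) {
      inherits(tryCatch(fn(x[i]), error = function(e) e), "error")
    }, logical(1))
    stop(sprintf("%s table: invalid %s at row(s) %s", table, col,
                 paste(utils::head(which(probe), 5L), collapse = ", ")),
         call. = FALSE)
  }
  res
}

gather_wide_events <- function(df, spec, path) {
  for (req in c("person", "event_id", "date", "source", "slots")) {
    if (is.null(spec[[req]]))
      stop("schema error: wide event table '", path, "' missing '", req, "'",
           call. = FALSE)
  }
  base_cols <- c(spec$person, spec$event_id, spec$date)
  miss <- setdiff(base_cols, names(df))
  if (length(miss))
    stop("schema error: event table '", path, "' missing mapped column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  pieces <- list()
  for (role in names(spec$slots)) {
    sl <- spec$slots[[role]]
    cols <- paste0(sl$prefix, seq_len(sl$n))
    cols <- cols[cols %in% names(df)]
    if (!length(cols)) next
    for (k in seq_along(cols)) {
      code <- df[[cols[k]]]
      keep <- !is.na(code) & nzchar(trimws(code))
      if (!any(keep)) next
      pieces[[length(pieces) + 1L]] <- data.frame(
        event_id = df[[spec$event_id]][keep],
        person_id = df[[spec$person]][keep],
        source = spec$source,
        event_date = df[[spec$date]][keep],
        slot_role = role,
        code_system = sl$code_system,
        code = trimws(code[keep]),
        slot = k,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(pieces)) {
    return(data.frame(event_id = character(0), person_id = character(0),
                      source = character(0), event_date = character(0),
                      slot_role = character(0), code_system = character(0),
                      code = character(0), slot = integer(0)))
  }
  out <- do.call(rbind, pieces)
  out[order(out$person_id, out$event_id, out$slot_role, out$slot), ,
      drop = FALSE]
}

#' Read a linked cohort from delimited-text tables
#'
#' @param paths Named list of file paths: `persons`, `registry`, `coverage`
#'   and `events`.  `events` may be a single path or a named character
#'   vector of paths; each entry is read with the matching entry of
#'   `schema$events` (a single spec is reused for all).
#' @param schema Column-mapping configuration, see [default_schema()] and
#'   [read_schema()].
#' @return A validated [cohort()].
#' @export
read_cohort <- function(paths, schema = default_schema()) {
  p_raw <- read_csv_chr(paths$persons)
  persons <- map_columns(p_raw, schema$persons$columns, "persons",
                         paths$persons)
  persons$age_at_baseline <- coerce_or_report(
    persons$age_at_baseline, function(x) {
      v <- suppressWarnings(as.numeric(x))
      if (anyNA(v) && !all(is.na(x) == is.na(v))) stop("bad")
      v
    }, "age_at_baseline", "persons")
  persons$ses_quintile <- as.integer(persons$ses_quintile)
  persons$border_resident <- as.logical(persons$border_resident)
  coerce_or_report(persons$baseline_date, parse_study_date,
                   "baseline_date", "persons")
  coerce_or_report(persons$death_date, parse_study_date,
                   "death_date", "persons")

  ev_paths <- paths$events
  if (is.null(names(ev_paths)) && length(ev_paths) == 1L)
    names(ev_paths) <- "events"
  ev_schema <- schema$events
  single_spec <- !is.null(ev_schema$layout)
  events_list <- lapply(names(ev_paths), function(nm) {
    spec <- if (single_spec) ev_schema else ev_schema[[nm]]
    if (is.null(spec))
      stop("schema error: no event schema entry for '", nm, "'",
           call. = FALSE)
    df <- read_csv_chr(ev_paths[[nm]])
    if (identical(spec$layout, "wide")) {
      gather_wide_events(df, spec, ev_paths[[nm]])
    } else {
      out <- map_columns(df, spec$columns, "events", ev_paths[[nm]])
      out$slot <- as.integer(out$slot)
      out
    }
  })
  events <- do.call(rbind, events_list)
  rownames(events) <- NULL
  coerce_or_report(events$event_date, parse_study_date, "event_date",
                   "events")

  r_raw <- read_csv_chr(paths$registry)
  registry <- map_columns(r_raw, schema$registry$columns, "registry",
                          paths$registry)
  registry$age_at_diagnosis <- as.numeric(registry$age_at_diagnosis)
  coerce_or_report(registry$diagnosis_month, parse_study_date,
                   "diagnosis_month", "registry")

  cov_raw <- read_csv_chr(paths$coverage)
  coverage <- map_columns(cov_raw, schema$coverage$columns, "coverage",
                          paths$coverage)

  cohort(persons, events, registry, coverage)
}

#' Write a cohort as CSV tables
#'
#' Writes `persons.csv`, `events.csv` (long layout), `registry.csv` and
#' `coverage.csv` under `dir` with the canonical column names, so that
#' `read_cohort()` with the default schema round-trips field for field.
#'
#' @param x A `"cohort"` object.
#' @param dir Output directory (created if needed).
#' @return Named list of the written paths, invisibly.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(persons = file.path(dir, "persons.csv"),
                events = file.path(dir, "events.csv"),
                registry = file.path(dir, "registry.csv"),
                coverage = file.path(dir, "coverage.csv"))
  utils::write.csv(x$persons, paths$persons, row.names = FALSE, na = "")
  utils::write.csv(x$events, paths$events, row.names = FALSE, na = "")
  utils::write.csv(x$registry, paths$registry, row.names = FALSE, na = "")
  utils::write.csv(x$coverage, paths$coverage, row.names = FALSE, na = "")
  invisible(paths)
}
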