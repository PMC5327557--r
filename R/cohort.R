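# The linked-cohort container.
#
# A cohort bundles four plain data.frames: one row per person, one row per
# coded slot of each administrative event (long layout), one row per
# registry diagnosis, and one row per source giving its coverage period.
# person_id is assumed already linked across tables; probabilistic linkage
# is upstream of this package.

EVENT_SOURCES <- c("inpatient", "emergency", "claims_medical",
                   "claims_pharma", "death")
SLOT_ROLES <- c("diagnosis", "procedure", "item", "cause_of_death")
CODE_SYSTEMS <- c("ICD10", "ICD9", "SNOMED", "ACHI", "MBS_ITEM", "PBS_ITEM")

PERSON_COLS <- c("person_id", "baseline_date", "age_at_baseline", "sex",
                 "ses_quintile", "remoteness", "border_resident",
                 "death_date")
EVENT_COLS <- c("event_id", "person_id", "source", "event_date", "slot_role",
                "code_system", "code", "slot")
REGISTRY_COLS <- c("person_id", "cancer_type", "diagnosis_month",
                   "spread_of_disease", "age_at_diagnosis")

#' Construct a validated linked cohort
#'
#' @param persons data.frame with columns `person_id`, `baseline_date`,
#'   `age_at_baseline`, `sex`, `ses_quintile` (1-5, most to least
#'   advantaged is 5 = most disadvantaged convention of area-level
#'   disadvantage quintiles), `remoteness` (`"metropolitan"` /
#'   `"non_metropolitan"`), `border_resident` (logical), `death_date`
#'   (ISO date or `NA`).
#' @param events data.frame in long code layout with columns `event_id`,
#'   `person_id`, `source`, `event_date`, `slot_role`, `code_system`,
#'   `code`, `slot` (1-based slot order within the event).
#' @param registry data.frame with columns `person_id`, `cancer_type`,
#'   `diagnosis_month` (`"YYYY-MM"`), `spread_of_disease`,
#'   `age_at_diagnosis`.
#' @param coverage data.frame with columns `source`, `start`, `end`
#'   (`"YYYY-MM"`), one row per source present plus optionally `registry`.
#' @return An object of class `"cohort"`.
#' @export
cohort <- function(persons, events, registry, coverage) {
  obj <- structure(list(persons = as.data.frame(persons),
                        events = as.data.frame(events),
                        registry = as.data.frame(registry),
                        coverage = as.data.frame(coverage)),
                   class = "cohort")
  validate_cohort(obj)
}

#' Validate a cohort's structural invariants
#'
#' Checks column presence, categorical domains, date well-formedness,
#' referential integrity (every event and registry row names a known
#' person), slot-count ceilings (55 diagnosis and 50 procedure slots per
#' inpatient admission; 1 underlying plus up to 20 contributing causes per
#' death record), source coverage containment, and per-person uniqueness.
#' Failures raise errors that name the offending rows.
#'
#' @param x A `"cohort"` object or plain list with the four tables.
#' @return The validated cohort, invisibly classed `"cohort"`.
#' @export
validate_cohort <- function(x) {
  p <- x$persons; e <- x$events; r <- x$registry; cov <- x$coverage
  miss <- setdiff(PERSON_COLS, names(p))
  if (length(miss)) stop("persons table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(EVENT_COLS, names(e))
  if (length(miss)) stop("events table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(REGISTRY_COLS, names(r))
  if (length(miss)) stop("registry table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(p$person_id))
    stop("duplicate person_id in persons table", call. = FALSE)
  if (any(p$age_at_baseline < 0, na.rm = TRUE))
    stop("negative age_at_baseline", call. = FALSE)

  parse_study_date(p$baseline_date)
  parse_study_date(p$death_date)
  parse_study_date(e$event_date)
  rm_ <- parse_study_date(r$diagnosis_month)
  if (any(!is.na(rm_$day)))
    stop("registry diagnosis_month must be month precision (YYYY-MM)",
         call. = FALSE)

  bad <- !e$source %in% EVENT_SOURCES
  if (any(bad)) stop("unknown event source at row(s): ",
                     paste(utils::head(which(bad), 5L), collapse = ", "),
                     call. = FALSE)
  bad <- !e$slot_role %in% SLOT_ROLES
  if (any(bad)) stop("unknown slot_role at row(s): ",
                     paste(utils::head(which(bad), 5L), collapse = ", "),
                     call. = FALSE)
  bad <- !e$code_system %in% CODE_SYSTEMS
  if (any(bad)) stop("unknown code_system at row(s): ",
                     paste(utils::head(which(bad), 5L), collapse = ", "),
                     call. = FALSE)

  bad <- !e$person_id %in% p$person_id
  if (any(bad)) stop("event person_id absent from persons table at row(s): ",
                     paste(utils::head(which(bad), 5L), collapse = ", "),
                     call. = FALSE)
  bad <- !r$person_id %in% p$person_id
  if (any(bad)) stop("registry person_id absent from persons table at row(s): ",
                     paste(utils::head(which(bad), 5L), collapse = ", "),
                     call. = FALSE)

  if (nrow(e)) {
    key <- paste(e$person_id, e$event_id, e$slot_role)
    cnt <- table(key)
    src_of <- e$source[match(names(cnt), key)]
    role_of <- e$slot_role[match(names(cnt), key)]
    over <- (src_of == "inpatient" & role_of == "diagnosis" & cnt > 55L) |
            (src_of == "inpatient" & role_of == "procedure" & cnt > 50L) |
            (src_of == "death" & role_of == "cause_of_death" & cnt > 21L)
    if (any(over)) stop("slot-count ceiling exceeded for event(s): ",
                        paste(utils::head(names(cnt)[over], 5L), collapse = "; "),
                        call. = FALSE)
  }

  if (!is.null(cov) && nrow(cov)) {
    cs <- month_index(cov$start); ce <- month_index(cov$end)
    if (any(cs > ce)) stop("coverage start after end for source(s): ",
                           paste(cov$source[cs > ce], collapse = ", "),
                           call. = FALSE)
    if (nrow(e)) {
      em <- month_index(e$event_date)
      i <- match(e$source, cov$source)
      if (anyNA(i)) stop("event source(s) without coverage row: ",
                         paste(unique(e$source[is.na(i)]), collapse = ", "),
                         call. = FALSE)
      out <- em < cs[i] | em > ce[i]
      if (any(out)) stop("event(s) outside source coverage at row(s): ",
                         paste(utils::head(which(out), 5L), collapse = ", "),
                         call. = FALSE)
    }
  }
  class(x) <- "cohort"
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat("Linked cohort\n")
  cat(sprintf("  persons : %d\n", nrow(x$persons)))
  cat(sprintf("  events  : %d coded slots, %d records, sources: %s\n",
              nrow(x$events),
              length(unique(paste(x$events$person_id, x$events$event_id,
                                  x$events$source))),
              paste(sort(unique(x$events$source)), collapse = ", ")))
  cat(sprintf("  registry: %d diagnoses (%s)\n", nrow(x$registry),
              paste(sort(unique(x$registry$cancer_type)), collapse = ", ")))
  if (!is.null(x$coverage) && nrow(x$coverage)) {
    for (i in seq_len(nrow(x$coverage)))
      cat(sprintf("  coverage: %-14s %s to %s\n", x$coverage$source[i],
                  x$coverage$start[i], x$coverage$end[i]))
  }
  invisible(x)
}
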