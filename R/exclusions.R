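# Cohort eligibility filtering.

#' Apply cohort eligibility exclusions
#'
#' Removes (i) persons below the minimum baseline age and (ii) persons with
#' irreconcilable linked records, operationalised as any administrative
#' event dated strictly after the person's death (month-level comparison:
#' an event is irreconcilable when its month index exceeds the death month
#' index, so a same-month admission and death is accepted).  All events and
#' registry records of excluded persons are dropped.  The operation is
#' idempotent.
#'
#' @param x A `"cohort"` object.
#' @param min_age Minimum eligible age at baseline in years (default 45,
#'   the usual floor for a mid-to-older-age cohort study).
#' @return List with elements `cohort` (the filtered cohort) and `report`
#'   (data.frame `person_id`, `reason` with reasons `"under_min_age"` and
#'   `"event_after_death"`; persons failing both are reported once, under
#'   `"under_min_age"`).
#' @export
apply_exclusions <- function(x, min_age = 45) {
  stopifnot(inherits(x, "cohort"))
  p <- x$persons
  under <- !is.na(p$age_at_baseline) & p$age_at_baseline < min_age

  death_mi <- rep(NA_integer_, nrow(p))
  has_death <- !is.na(p$death_date)
  if (any(has_death)) death_mi[has_death] <- month_index(p$death_date[has_death])
  after_death <- rep(FALSE, nrow(p))
  if (nrow(x$events)) {
    em <- month_index(x$events$event_date)
    dm <- death_mi[match(x$events$person_id, p$person_id)]
    bad <- !is.na(dm) & em > dm
    after_death <- p$person_id %in% unique(x$events$person_id[bad])
  }

  reason <- ifelse(under, "under_min_age",
                   ifelse(after_death, "event_after_death", NA_character_))
  excl <- !is.na(reason)
  report <- data.frame(person_id = p$person_id[excl],
                       reason = reason[excl],
                       stringsAsFactors = FALSE)

  keep_ids <- p$person_id[!excl]
  out <- x
  out$persons <- p[!excl, , drop = FALSE]
  out$events <- x$events[x$events$person_id %in% keep_ids, , drop = FALSE]
  out$registry <- x$registry[x$registry$person_id %in% keep_ids, , drop = FALSE]
  rownames(out$persons) <- rownames(out$events) <- rownames(out$registry) <- NULL
  list(cohort = validate_cohort(out), report = report)
}
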