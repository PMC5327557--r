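# What the surrogate buys once the registry runs out: incremental cases and
# the date-agnostic PPV.

#' Count incremental cases beyond the registry's coverage
#'
#' The payoff of a validated surrogate indicator is follow-up beyond the
#' registry's last release.  Relative to the base of incident registry
#' cases (diagnosed after the person's baseline and no later than
#' `registry_end`), the surrogate adds persons first ascertained after
#' `registry_end` who have no registry record of the cancer type at all.
#'
#' @param asc_extended An `"ascertainment"` set computed over a window
#'   extending past `registry_end`.
#' @param registry Registry table (full available history).
#' @param cancer_type Cancer type evaluated.
#' @param registry_end `"YYYY-MM"`: last month of registry coverage.
#' @param baseline_dates Named character vector (or persons data.frame)
#'   giving each person's baseline date.
#' @return An `"increment_report"`: list with `base`, `added` and
#'   `percent_increase` (rounded to the nearest integer percent; `NA` when
#'   the base is zero).
#' @export
count_incremental_cases <- function(asc_extended, registry, cancer_type,
                                    registry_end, baseline_dates) {
  if (is.data.frame(baseline_dates)) {
    baseline_dates <- stats::setNames(baseline_dates$baseline_date,
                                      baseline_dates$person_id)
  }
  re <- month_index(registry_end)
  r <- registry[registry$cancer_type == cancer_type, , drop = FALSE]
  rmi <- month_index(r$diagnosis_month)
  base_mi <- month_index(unname(baseline_dates[r$person_id]))
  base_ids <- unique(r$person_id[rmi > base_mi & rmi <= re])

  ever_registry <- unique(r$person_id)
  fmi <- month_index(asc_extended$first_date)
  added_ids <- asc_extended$person_id[fmi > re &
                                      !asc_extended$person_id %in% ever_registry]
  base <- length(base_ids)
  added <- length(added_ids)
  structure(list(base = base, added = added,
                 percent_increase = if (base > 0)
                   round(100 * added / base) else NA_real_,
                 cancer_type = cancer_type, registry_end = registry_end),
            class = "increment_report")
}

#' @export
print.increment_report <- function(x, ...) {
  cat(sprintf(
    "Incremental cases (%s, registry to %s): base %d + added %d (%s%%)\n",
    x$cancer_type, x$registry_end, x$base, x$added,
    ifelse(is.na(x$percent_increase), "NA", x$percent_increase)))
  invisible(x)
}

#' Date-agnostic positive predictive value
#'
#' The proportion of ascertained persons with a registry record of the
#' cancer type at any date, ignoring the matching window entirely.  Always
#' at least the windowed PPV; the gap measures how much of the apparent
#' false-positive load is prevalent disease rather than miscoding.
#'
#' @param asc An `"ascertainment"` set.
#' @param registry_full_history Registry table over its full history.
#' @param cancer_type Cancer type evaluated.
#' @return Proportion in `[0, 1]`, or `NA` for an empty ascertainment set.
#' @export
date_agnostic_ppv <- function(asc, registry_full_history, cancer_type) {
  if (nrow(asc) == 0L) return(NA_real_)
  r_ids <- unique(registry_full_history$person_id[
    registry_full_history$cancer_type == cancer_type])
  mean(asc$person_id %in% r_ids)
}
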