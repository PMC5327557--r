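# Triage of discordant death-record cases: people flagged by a death-record
# indicator with no in-window registry record of the cancer.

#' Triage false-positive death-record cases
#'
#' Each person labelled `FP` in a classification built from a death-record
#' indicator is assigned the first matching category, in order:
#'
#' 1. `registry_prior_to_window` — the full registry history holds a record
#'    of the cancer type dated before the evaluation window (a prevalent,
#'    not incident, case);
#' 2. `possible_secondary` — any linked record carries a secondary/
#'    metastatic-site code (C77-C79 by default), suggesting a secondary
#'    cancer miscertified as primary on the death certificate;
#' 3. `other_disease` — neither, i.e. possibly some other disease of the
#'    site.
#'
#' The categories partition the triaged set.
#'
#' @param mc A `"match_classification"` from a death-containing indicator.
#' @param events Event table (searched for secondary-site codes).
#' @param registry_full_history Registry table that may extend before the
#'   evaluation window.
#' @param cancer_type Cancer type (defaults to the classification's).
#' @param secondary_codes Code set flagging secondary malignancies.
#' @return A `"discordance_triage"`: list with `counts` (named integer
#'   vector over the three categories), `n` and per-person `assignments`.
#' @export
triage_death_fps <- function(mc, events, registry_full_history,
                             cancer_type = attr(mc, "cancer_type"),
                             secondary_codes = default_code_sets()$secondary) {
  ew <- attr(mc, "eval_window")
  ws <- month_index(ew[1])
  fp_ids <- mc$person_id[mc$label == "FP"]

  r <- registry_full_history[
    registry_full_history$cancer_type == cancer_type, , drop = FALSE]
  prior_ids <- unique(r$person_id[month_index(r$diagnosis_month) < ws])

  sec <- events[events$slot_role %in% c("diagnosis", "cause_of_death") &
                events$code_system == "ICD10", , drop = FALSE]
  sec_ids <- if (nrow(sec))
    unique(sec$person_id[code_matches(sec$code, secondary_codes)])
  else character(0)

  category <- ifelse(fp_ids %in% prior_ids, "registry_prior_to_window",
              ifelse(fp_ids %in% sec_ids, "possible_secondary",
                     "other_disease"))
  counts <- vapply(c("registry_prior_to_window", "possible_secondary",
                     "other_disease"),
                   function(k) sum(category == k), integer(1))
  structure(list(counts = counts, n = length(fp_ids),
                 assignments = data.frame(person_id = fp_ids,
                                          category = category,
                                          stringsAsFactors = FALSE),
                 cancer_type = cancer_type),
            class = "discordance_triage")
}

#' @export
print.discordance_triage <- function(x, ...) {
  cat(sprintf("Death-record discordance triage (%s): %d FP case(s)\n",
              x$cancer_type, x$n))
  for (k in names(x$counts))
    cat(sprintf("  %-24s %d\n", k, x$counts[[k]]))
  invisible(x)
}
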